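# Independent brute-force reference implementations used as oracles.
# Deliberately written with different algorithms/representations than the
# package code paths they check.

# one-pass Z-score reference: plain loops over a well table
oracle_zscores <- function(wells, background = TRUE) {
  cw <- wells[wells$role == "compound", ]
  lines <- unique(cw$cell_line)
  compounds <- unique(cw$compound_id)
  z <- matrix(NA_real_, length(compounds), length(lines),
              dimnames = list(compounds, lines))
  for (l in lines) {
    bg <- 0
    if (background) {
      cf <- wells$intensity[wells$role == "cellfree" & wells$cell_line == l]
      if (length(cf)) bg <- sum(cf) / length(cf)
    }
    lx <- numeric(length(compounds))
    for (k in seq_along(compounds)) {
      v <- cw$intensity[cw$cell_line == l & cw$compound_id == compounds[k]]
      lx[k] <- mean(log(v - bg))
    }
    z[, l] <- (lx - mean(lx)) / sd(lx)
  }
  z
}

# pair-counting Mann-Whitney U (no ranks)
oracle_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exact two-sided WMW p by bitmask enumeration of all label assignments
oracle_wmw_exact <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  us <- c()
  for (m in 0:(2^N - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(N - 1))) > 0)
    if (length(idx) != n1) next
    us <- c(us, oracle_U(pool[idx], pool[-idx]))
  }
  u_obs <- oracle_U(x, y)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# exact two-sided signed-rank p by explicit 2^n sign enumeration
oracle_signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    vs[m + 1] <- sum(r[signs])
  }
  eps <- 1e-9
  min(1, 2 * min(mean(vs <= v_obs + eps), mean(vs >= v_obs - eps)))
}

# literal per-record re-application of the printed hard-filter rules
oracle_hard_filter <- function(rec) {
  fails <- character(0)
  cls <- tolower(rec$variant_class)
  chk <- function(key, op, cut) {
    v <- rec[[key]]
    if (is.null(v) || is.na(v)) return(NULL)
    hit <- if (op == "<") v < cut else v > cut
    if (hit) sprintf("%s%s%g", key, op, cut) else NULL
  }
  if (cls == "snp") {
    fails <- c(fails, chk("QD", "<", 2.0), chk("MQ", "<", 40.0),
               chk("FS", ">", 60.0), chk("ReadPosRankSum", "<", -8.0),
               chk("MQRankSum", "<", -12.5))
  } else if (cls == "indel") {
    fails <- c(fails, chk("QD", "<", 2.0), chk("FS", ">", 200.0),
               chk("ReadPosRankSum", "<", -20.0))
  } else {
    stop("unknown class")
  }
  paste(fails, collapse = ";")
}

# O(n*m) interval-overlap check on 0-based half-open coordinates
oracle_overlaps <- function(segments, regions) {
  hit <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    for (j in seq_len(nrow(regions))) {
      if (sub("^chr", "", segments$chrom[i]) ==
            sub("^chr", "", regions$chrom[j]) &&
          segments$start[i] < regions$end[j] &&
          regions$start[j] < segments$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# step-up BH by the textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# hand-written CNA decision table (independent of call_segment)
oracle_cna_call <- function(log2, qc) {
  thr <- if (qc > 0.2) 0.3 else 0.2
  if (log2 >= 1.5) "amplification"
  else if (log2 >= thr) "gain"
  else if (log2 <= -1.5) "homozygous loss"
  else if (log2 <= -thr) "loss"
  else "neutral"
}

# small fixed four-line two-group panel used across tests
panel_2x2 <- function() {
  data.frame(cell_line = c("SI1", "SI2", "PAN1", "PAN2"),
             group = c("SINET", "SINET", "PanNET", "PanNET"),
             stringsAsFactors = FALSE)
}
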