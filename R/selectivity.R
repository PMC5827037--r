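## Differential-sensitivity statistics.
##
## For each compound, its per-cell-line Z-scores are averaged within each
## group; the selectivity statistic is
##   delta = mean Z(SINET) - mean Z(PanNET).
## A normal distribution fitted (by maximum likelihood) to all compounds'
## deltas provides an empirical-null "p-score" per compound, and target
## classes are tested for enrichment by a Wilcoxon-Mann-Whitney rank test
## of the class deltas against all other compounds' deltas, with
## Benjamini-Hochberg FDR across classes.

#' Per-compound group means and selectivity delta
#'
#' @param norm a [normalize_screen()] result (or any matrix of Z-scores
#'   with compounds as rows, cell lines as columns).
#' @param group_map data.frame `cell_line`, `group` assigning each screen
#'   cell line to a group.
#' @param contrast the two groups whose mean-Z difference defines
#'   `delta = mean Z(first) - mean Z(second)`.
#' @param annotation optional data.frame `compound_id`, `class` to attach
#'   target classes.
#' @return data.frame, one row per compound: `compound_id`, optional
#'   `class`, one `mean_z_<group>` column per group in `group_map`, and
#'   `delta`.
#' @export
group_deltas <- function(norm, group_map,
                         contrast = c("SINET", "PanNET"),
                         annotation = NULL) {
  z <- if (inherits(norm, "normalized_screen")) norm$z else as.matrix(norm)
  assert_that(is.data.frame(group_map) &&
                all(c("cell_line", "group") %in% names(group_map)),
              "group_map needs columns cell_line and group")
  missing_lines <- setdiff(group_map$cell_line, colnames(z))
  if (length(missing_lines))
    stopf("cell line '%s' in group_map is absent from the screen",
          missing_lines[1L])
  assert_that(length(contrast) == 2L && all(contrast %in% group_map$group),
              "both contrast groups must appear in group_map")
  groups <- unique(group_map$group)
  out <- data.frame(compound_id = rownames(z), stringsAsFactors = FALSE)
  for (g in groups) {
    members <- group_map$cell_line[group_map$group == g]
    out[[paste0("mean_z_", g)]] <- rowMeans(z[, members, drop = FALSE])
  }
  out$delta <- out[[paste0("mean_z_", contrast[1L])]] -
    out[[paste0("mean_z_", contrast[2L])]]
  if (!is.null(annotation)) {
    assert_that(all(c("compound_id", "class") %in% names(annotation)),
                "annotation needs columns compound_id and class")
    out$class <- annotation$class[match(out$compound_id,
                                        annotation$compound_id)]
  }
  attr(out, "contrast") <- contrast
  out
}

#' Empirical-null p-scores from a fitted normal
#'
#' Fits `N(mu, sigma)` to all deltas by maximum likelihood (sigma with the
#' n denominator) and scores each compound by its two-sided tail
#' probability `2 * pnorm(-|delta - mu| / sigma)`; the bulk of the library
#' is taken as the null.  One-sided scores (`pnorm` of the lower or upper
#' tail) are available by flag.
#'
#' @param records output of [group_deltas()].
#' @param sided `"two"` (default), `"lower"` or `"upper"`.
#' @param min_compounds fit-stability guard on the library size.
#' @return `records` with columns `p_score` in (0, 1]; attributes
#'   `null_mean`, `null_sd` carry the fit.
#' @export
empirical_null_pscores <- function(records, sided = c("two", "lower", "upper"),
                                   min_compounds = 20L) {
  sided <- match.arg(sided)
  d <- records$delta
  assert_that(is.numeric(d) && length(d) >= min_compounds,
              "need >= %d compounds for a stable null fit", min_compounds)
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))  # ML: n denominator
  if (sigma == 0) stopf("degenerate null: all deltas identical")
  zs <- (d - mu) / sigma
  records$p_score <- switch(sided,
                            two = 2 * pnorm(-abs(zs)),
                            lower = pnorm(zs),
                            upper = pnorm(zs, lower.tail = FALSE))
  attr(records, "null_mean") <- mu
  attr(records, "null_sd") <- sigma
  records
}

#' Target-class enrichment by Wilcoxon-Mann-Whitney with BH FDR
#'
#' Each class's deltas are compared against the deltas of all other
#' compounds (two-sided); p-values are BH-adjusted across the tested
#' classes.  Classes smaller than `min_class_size` are reported as
#' untested (NA statistics), not dropped.
#'
#' @param records output of [group_deltas()] carrying a `class` column.
#' @param min_class_size smallest class that is tested.
#' @param exact_max use exact enumeration of the rank-sum distribution
#'   when both groups have at most this many members, else the normal
#'   approximation with tie correction and continuity correction.
#' @return data.frame per class: `class`, `n_in_class`, `U`, `p`, `q`,
#'   `direction` (`"SINET-selective"` if the class median delta is
#'   negative, i.e. stronger viability reduction in the first contrast
#'   group, else `"PanNET-selective"`), `tested`.
#' @export
class_enrichment <- function(records, min_class_size = 5L, exact_max = 10L) {
  assert_that("class" %in% names(records) && !anyNA(records$class),
              "every compound needs exactly one class label")
  contrast <- attr(records, "contrast") %||% c("SINET", "PanNET")
  classes <- sort(unique(records$class))
  rows <- lapply(classes, function(cl) {
    x <- records$delta[records$class == cl]
    y <- records$delta[records$class != cl]
    if (!length(y)) stopf("class '%s' equals the full library (empty complement)", cl)
    tested <- length(x) >= min_class_size
    if (tested) {
      wt <- wmw_test(x, y, exact_max = exact_max)
      U <- wt$U; p <- wt$p
    } else {
      U <- NA_real_; p <- NA_real_
    }
    data.frame(class = cl, n_in_class = length(x), U = U, p = p,
               direction = if (median(x) < 0)
                 paste0(contrast[1L], "-selective") else
                 paste0(contrast[2L], "-selective"),
               tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out[order(out$q, out$p, out$class), c("class", "n_in_class", "U", "p",
                                        "q", "direction", "tested")]
}

#' Paired group comparison for one target class (signed-rank)
#'
#' For every compound of a class, its mean Z in group A is paired with
#' its mean Z in group B; the two-sided Wilcoxon signed-rank test is
#' applied to the differences (zero differences dropped, Wilcoxon
#' convention).
#'
#' @param records output of [group_deltas()] with a `class` column.
#' @param class target-class label.
#' @param group_pair the two group labels to compare.
#' @param min_members feasibility guard on the class size.
#' @return list: `class`, `n` (nonzero pairs), `V` (positive-rank sum),
#'   `p` (two-sided), `method` (`"exact"` or `"normal"`).
#' @export
group_effect_test <- function(records, class, group_pair, min_members = 6L) {
  assert_that("class" %in% names(records), "records carry no class column")
  cols <- paste0("mean_z_", group_pair)
  assert_that(length(group_pair) == 2L && all(cols %in% names(records)),
              "group_pair must name two groups present in records")
  rr <- records[records$class == class, ]
  assert_that(nrow(rr) >= min_members,
              "class '%s' has %d members (< %d)", class, nrow(rr), min_members)
  d <- rr[[cols[1L]]] - rr[[cols[2L]]]
  st <- signed_rank_test(d)
  c(list(class = class), st)
}

#' Wilcoxon-Mann-Whitney rank-sum test (two-sided)
#'
#' U is the Mann-Whitney statistic of `x` against `y` computed from
#' midranks.  When both samples have at most `exact_max` members the
#' two-sided p-value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` label assignments of the pooled values (ties are
#' thereby handled exactly); otherwise by the normal approximation with
#' midrank tie correction and 0.5 continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max per-group enumeration threshold; any split with
#'   `length(x) + length(y) <= 12` is also enumerated exactly, covering
#'   small unbalanced splits.
#' @return list `U`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
wmw_test <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  assert_that(n1 >= 1L && n2 >= 1L, "both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if ((n1 <= exact_max && n2 <= exact_max) || N <= 12L) {
    ## all assignments of n1 labels to the pooled midranks
    Us <- combn(N, n1, FUN = function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    M <- length(Us)
    eps <- 1e-9
    p <- min(1, 2 * min(sum(Us <= U + eps), sum(Us >= U - eps)) / M)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

#' Wilcoxon signed-rank test (two-sided) on paired differences
#'
#' Zero differences are dropped; |d| are midranked and V is the sum of
#' ranks of positive differences.  For n <= `exact_max` the exact
#' tie-adjusted null distribution of V is computed by dynamic programming
#' over all 2^n sign assignments; beyond that the normal approximation
#' with continuity correction and Var(V) = sum(r^2)/4 is used.
#'
#' @param d paired differences.
#' @param exact_max exact-path size limit.
#' @return list `n`, `V`, `p`, `method`.
#' @export
signed_rank_test <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (!n) stopf("no nonzero differences: signed-rank test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    ## distribution of V over 2^n sign vectors; midranks doubled so all
    ## sums are integers
    dr <- as.integer(round(2 * r))
    f <- numeric(sum(dr) + 1L)  # f[s + 1] = #assignments with 2V = s
    f[1L] <- 1
    for (k in dr) {
      g <- numeric(length(f))
      g[(k + 1L):length(f)] <- f[seq_len(length(f) - k)]
      f <- f + g
    }
    tot <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(v2 + 1L)]) / tot
    p_ge <- sum(f[(v2 + 1L):length(f)]) / tot
    list(n = n, V = V, p = min(1, 2 * min(p_le, p_ge)), method = "exact")
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    z <- (V - mu - sign(V - mu) * 0.5) / sig
    list(n = n, V = V, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}
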