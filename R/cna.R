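## Copy-number segment classification.
##
## Segments (mean log2 ratio over a genomic interval, produced upstream
## by a segmentation algorithm) are classified against fixed thresholds.
## The gain/loss threshold depends on the array's QC value: arrays with
## QC > 0.2 were segmented at higher stringency and use +/-0.3, all
## others +/-0.2.  Amplification and homozygous loss are +/-1.5 in both
## regimes.  Boundary values take the more extreme call.

#' Select the calling regime for an array
#'
#' @param qc per-array QC scalar.
#' @return list: `regime` (`"standard"` or `"high"`), `gain`, `loss`,
#'   `amplification`, `homozygous_loss` thresholds.
#' @export
select_regime <- function(qc) {
  assert_that(is.numeric(qc) && length(qc) == 1L && is.finite(qc),
              "qc must be a single finite number")
  high <- qc > 0.2  # strictly: qc == 0.2 stays standard
  thr <- if (high) 0.3 else 0.2
  list(regime = if (high) "high" else "standard",
       gain = thr, loss = -thr,
       amplification = 1.5, homozygous_loss = -1.5)
}

#' Classify a segment mean log2 ratio
#'
#' Decision table (boundaries belong to the more extreme call):
#' `log2 >= 1.5` amplification; `gain <= log2 < 1.5` gain;
#' `-1.5 < log2 <= loss` loss; `log2 <= -1.5` homozygous loss; otherwise
#' neutral.
#'
#' @param log2 numeric vector of segment mean log2 ratios.
#' @param regime a [select_regime()] result (or a QC scalar).
#' @return character vector of calls.
#' @export
call_segment <- function(log2, regime) {
  if (is.numeric(regime)) regime <- select_regime(regime)
  assert_that(all(is.finite(log2)), "non-finite log2 ratio")
  ifelse(log2 >= regime$amplification, "amplification",
  ifelse(log2 >= regime$gain, "gain",
  ifelse(log2 <= regime$homozygous_loss, "homozygous loss",
  ifelse(log2 <= regime$loss, "loss", "neutral"))))
}

#' Call all segments of one array
#'
#' @param segments data.frame `chrom`, `start`, `end` (0-based,
#'   half-open), `log2`.
#' @param qc the array's QC value (selects the regime).
#' @param cnv_regions optional known-CNV region table for
#'   [exclude_regions()].
#' @return `segments` with columns `call`, `excluded`, `exclude_reason`
#'   and attribute `regime`.
#' @export
call_segments <- function(segments, qc, cnv_regions = NULL) {
  check_segments(segments)
  regime <- select_regime(qc)
  segments$call <- call_segment(segments$log2, regime)
  segments <- exclude_regions(segments, cnv_regions)
  attr(segments, "regime") <- regime
  segments
}

#' Flag segments excluded from CNA analysis
#'
#' Sex-chromosome segments and segments overlapping a previously
#' reported copy-number-variation region by at least one base are
#' flagged (reason recorded), never removed.  Idempotent.
#'
#' @param segments segment table (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param cnv_regions optional BED-like data.frame `chrom`, `start`,
#'   `end` of known CNV regions.
#' @return `segments` with logical `excluded` and character
#'   `exclude_reason` (`""` when retained).
#' @export
exclude_regions <- function(segments, cnv_regions = NULL) {
  check_segments(segments)
  chrom <- sub("^chr", "", segments$chrom)
  excluded <- chrom %in% c("X", "Y")
  reason <- ifelse(excluded, "sex chromosome", "")
  if (!is.null(cnv_regions) && nrow(cnv_regions)) {
    assert_that(all(c("chrom", "start", "end") %in% names(cnv_regions)),
                "cnv_regions needs chrom, start, end")
    if (any(cnv_regions$end <= cnv_regions$start))
      stopf("malformed CNV region: end <= start at row %d",
            which(cnv_regions$end <= cnv_regions$start)[1L])
    cnv_chrom <- sub("^chr", "", cnv_regions$chrom)
    lv <- union(chrom, cnv_chrom)  # shared seqlevels: silence mismatch notes
    gr_seg <- GenomicRanges::GRanges(
      factor(chrom, lv), IRanges::IRanges(segments$start + 1L, segments$end))
    gr_cnv <- GenomicRanges::GRanges(
      factor(cnv_chrom, lv),
      IRanges::IRanges(cnv_regions$start + 1L, cnv_regions$end))
    hit <- IRanges::overlapsAny(gr_seg, gr_cnv)
    reason[hit & !excluded] <- "known-CNV overlap"
    excluded <- excluded | hit
  }
  segments$excluded <- excluded
  segments$exclude_reason <- reason
  segments
}

#' Per-gene copy-number context
#'
#' Maps called segments onto a gene table and reports, per gene, the
#' copy context used by the bi-allelic-inactivation logic
#' ([biallelic_call()]): the most extreme overlapping call, translated
#' as homozygous loss -> `"homozygous loss"`, loss -> `"single-copy"`,
#' amplification -> `"amplification"`, otherwise `"normal"`.
#'
#' @param segments a [call_segments()] result.
#' @param genes data.frame `gene`, `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param use_excluded include excluded segments (default FALSE).
#' @return data.frame `gene`, `copy_context`.
#' @export
gene_copy_context <- function(segments, genes, use_excluded = FALSE) {
  assert_that(all(c("gene", "chrom", "start", "end") %in% names(genes)),
              "genes needs gene, chrom, start, end")
  seg <- segments
  if (!use_excluded && "excluded" %in% names(seg))
    seg <- seg[!seg$excluded, , drop = FALSE]
  seg_chrom <- sub("^chr", "", seg$chrom)
  gene_chrom <- sub("^chr", "", genes$chrom)
  lv <- union(seg_chrom, gene_chrom)
  gr_seg <- GenomicRanges::GRanges(
    factor(seg_chrom, lv), IRanges::IRanges(seg$start + 1L, seg$end))
  gr_gene <- GenomicRanges::GRanges(
    factor(gene_chrom, lv), IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
  severity <- c("homozygous loss" = 4, "amplification" = 3, "loss" = 2,
                "gain" = 1, "neutral" = 0)
  context <- rep("normal", nrow(genes))
  for (g in unique(S4Vectors::queryHits(ov))) {
    calls <- seg$call[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]]
    top <- calls[which.max(severity[calls])]
    context[g] <- switch(top,
                         "homozygous loss" = "homozygous loss",
                         "loss" = "single-copy",
                         "amplification" = "amplification",
                         "normal")
  }
  data.frame(gene = genes$gene, copy_context = context,
             stringsAsFactors = FALSE)
}

#' Simulate a copy-number segment table with truth calls
#'
#' Draws `n` segments on random intervals, assigns each a true class and
#' a mean log2 ratio representative of that class (the class's
#' `log2_means` value plus truncated jitter that stays inside the
#' class's decision interval at the given `qc_value`), and records the
#' truth call computed from the same thresholds the caller applies.
#'
#' @param n segment count.
#' @param chrom_set chromosomes to draw from (subset of 1:22, "X", "Y").
#' @param log2_means named numeric: representative mean log2 ratio per
#'   class.
#' @param class_probs sampling weights over `names(log2_means)`.
#' @param qc_value per-array QC (fixes the regime for truth calls).
#' @param jitter_sd SD of the within-class jitter.
#' @param seed integer seed.
#' @return list of class `segment_sim`: `segments` (chrom, start, end,
#'   log2), `truth` (true_class per segment), `qc_value`.
#' @export
generate_segments <- function(n = 100L,
                              chrom_set = c(1:22, "X", "Y"),
                              log2_means = c(neutral = 0, gain = 0.5,
                                             loss = -0.5,
                                             amplification = 1.8,
                                             "homozygous loss" = -1.8),
                              class_probs = c(0.6, 0.15, 0.15, 0.05, 0.05),
                              qc_value = 0.1, jitter_sd = 0.05,
                              seed = 1L) {
  assert_that(all(as.character(chrom_set) %in% c(as.character(1:22), "X", "Y")),
              "chrom_set must come from {1..22, X, Y}")
  regime <- select_regime(qc_value)
  classes <- names(log2_means)
  assert_that(all(classes %in% c("neutral", "gain", "loss", "amplification",
                                 "homozygous loss")),
              "log2_means must be named by call classes")
  ## decision interval per class under this regime
  bounds <- list(
    "amplification" = c(regime$amplification, Inf),
    "gain" = c(regime$gain, regime$amplification - 1e-6),
    "neutral" = c(regime$loss + 1e-6, regime$gain - 1e-6),
    "loss" = c(regime$homozygous_loss + 1e-6, regime$loss),
    "homozygous loss" = c(-Inf, regime$homozygous_loss))
  with_seed(seed, {
    cls <- sample(classes, n, replace = TRUE, prob = class_probs)
    log2 <- log2_means[cls] + rnorm(n, 0, jitter_sd)
    lo <- vapply(bounds[cls], `[`, numeric(1), 1L)
    hi <- vapply(bounds[cls], `[`, numeric(1), 2L)
    log2 <- pmin(pmax(log2, lo), hi)
    start <- sample.int(2e8, n, replace = TRUE)
    width <- sample.int(5e6, n, replace = TRUE)
    segments <- data.frame(
      chrom = as.character(sample(as.character(chrom_set), n, replace = TRUE)),
      start = start, end = start + width, log2 = unname(log2),
      stringsAsFactors = FALSE)
    truth <- data.frame(true_class = unname(cls),
                        truth_call = call_segment(segments$log2, regime),
                        stringsAsFactors = FALSE)
    structure(list(segments = segments, truth = truth, qc_value = qc_value),
              class = "segment_sim")
  })
}

check_segments <- function(segments) {
  need <- c("chrom", "start", "end")
  assert_that(is.data.frame(segments) && all(need %in% names(segments)),
              "segment table needs columns %s", paste(need, collapse = ", "))
  assert_that(all(segments$end > segments$start),
              "segments must satisfy end > start (0-based half-open)")
  invisible(TRUE)
}
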