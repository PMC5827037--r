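## Plate QC and per-cell-line Z-score normalization of raw well
## intensities.  For each cell line, compound-well fluorescence is
## (optionally background-subtracted,) log-transformed, and standardized
## across the library: z_i = (log x_i - mean_j log x_j) / sd_j log x_j,
## with the usual n-1 sd.  Controls are never part of the mean/sd.

#' Per-plate control quality report
#'
#' Summarises the DMSO vehicle-control wells of every plate (mean, CV,
#' count) and the cell-free background, and flags plates whose control CV
#' exceeds a limit.  Flagged plates are reported, not dropped.
#'
#' @param wells long-format well table with columns `plate`, `well`,
#'   `cell_line`, `role` (`compound` / `dmso` / `cellfree`),
#'   `compound_id`, `intensity`.
#' @param control_cv_limit flag plates with DMSO-control CV above this.
#' @return data.frame, one row per plate: `plate`, `cell_line`,
#'   `n_controls`, `dmso_mean`, `dmso_cv`, `cellfree_mean`, `flag`
#'   (`""`, `"high control CV"` or `"no controls"`).
#' @export
plate_qc <- function(wells, control_cv_limit = 0.2) {
  check_wells(wells)
  plates <- unique(wells$plate)
  out <- lapply(plates, function(p) {
    w <- wells[wells$plate == p, ]
    ctrl <- w$intensity[w$role == "dmso"]
    cf <- w$intensity[w$role == "cellfree"]
    m <- if (length(ctrl)) mean(ctrl) else NA_real_
    cv <- if (length(ctrl) >= 2L && m != 0) sd(ctrl) / m else
      if (length(ctrl) == 1L) 0 else NA_real_
    flag <- if (!length(ctrl) && !length(cf)) "no controls"
      else if (isTRUE(cv > control_cv_limit)) "high control CV"
      else ""
    data.frame(plate = p, cell_line = w$cell_line[1L],
               n_controls = length(ctrl), dmso_mean = m, dmso_cv = cv,
               cellfree_mean = if (length(cf)) mean(cf) else NA_real_,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalize a screen to per-cell-line Z-scores
#'
#' @param wells well table (see [plate_qc()]); replicate wells of one
#'   compound in one cell line are averaged on the log scale before
#'   standardization.
#' @param background background policy: `"subtract"` removes each cell
#'   line's cell-free plate mean before the log transform (0 if no
#'   cell-free wells exist), `"none"` uses raw intensities.
#' @param log_base base of the log transform; Z-scores are invariant to
#'   it, so this is metadata.
#' @param control_cv_limit passed to [plate_qc()].
#' @param min_compounds minimum library size per cell line for a stable
#'   sd (guard; lower it only in tests).
#' @return object of class `normalized_screen`: `z` (matrix compounds x
#'   cell lines), `qc` (the [plate_qc()] table), `background` per cell
#'   line, and transform metadata.
#' @export
normalize_screen <- function(wells, background = c("subtract", "none"),
                             log_base = exp(1), control_cv_limit = 0.2,
                             min_compounds = 3L) {
  check_wells(wells)
  background <- match.arg(background)
  qc <- plate_qc(wells, control_cv_limit)
  cw <- wells[wells$role == "compound", ]
  assert_that(nrow(cw) > 0, "no compound wells in input")
  lines <- unique(cw$cell_line)
  compounds <- unique(cw$compound_id)
  bg <- setNames(numeric(length(lines)), lines)
  if (background == "subtract") {
    for (l in lines) {
      cf <- wells$intensity[wells$role == "cellfree" & wells$cell_line == l]
      bg[[l]] <- if (length(cf)) mean(cf) else 0
    }
  }
  z <- matrix(NA_real_, nrow = length(compounds), ncol = length(lines),
              dimnames = list(compounds, lines))
  for (l in lines) {
    wl <- cw[cw$cell_line == l, ]
    x <- wl$intensity - bg[[l]]
    bad <- which(x <= 0)
    if (length(bad))
      stopf("non-positive intensity after background policy in well %s of plate %s",
            wl$well[bad[1L]], wl$plate[bad[1L]])
    lx <- log(x, base = log_base)
    ## average replicate wells on the log scale
    lx <- tapply(lx, wl$compound_id, mean)
    assert_that(length(lx) >= min_compounds,
                "cell line %s has %d compounds (< %d): sd unstable",
                l, length(lx), min_compounds)
    s <- sd(lx)
    if (!is.finite(s) || s == 0)
      stopf("zero variance of log-intensities for cell line %s", l)
    z[names(lx), l] <- (lx - mean(lx)) / s
  }
  assert_that(!anyNA(z), "missing (compound, cell line) combinations")
  structure(list(z = z, qc = qc, background = bg,
                 meta = list(log_base = log_base,
                             background_policy = background)),
            class = "normalized_screen")
}

#' @export
print.normalized_screen <- function(x, ...) {
  cat(sprintf("normalized_screen: %d compounds x %d cell lines (log base %.4g, background %s)\n",
              nrow(x$z), ncol(x$z), x$meta$log_base, x$meta$background_policy))
  nf <- sum(x$qc$flag != "")
  if (nf) cat(sprintf("  %d plate(s) flagged by control QC\n", nf))
  invisible(x)
}

#' Percent-of-DMSO viability
#'
#' Auxiliary readout: `100 * (well - background) / (plate DMSO mean -
#' background)` per compound well, background being the cell line's
#' cell-free mean (0 if absent).  The selectivity statistics operate on
#' Z-scores, not on this table.
#'
#' @inheritParams plate_qc
#' @return data.frame `compound_id`, `cell_line`, `percent_viability`
#'   (replicate wells averaged).
#' @export
percent_viability <- function(wells) {
  check_wells(wells)
  qc <- plate_qc(wells)
  cw <- wells[wells$role == "compound", ]
  assert_that(all(qc$n_controls[qc$plate %in% cw$plate] >= 1L),
              "every treatment plate needs at least one DMSO control")
  bg <- vapply(unique(cw$cell_line), function(l) {
    cf <- wells$intensity[wells$role == "cellfree" & wells$cell_line == l]
    if (length(cf)) mean(cf) else 0
  }, numeric(1))
  dmso <- setNames(qc$dmso_mean, qc$plate)
  denom <- dmso[cw$plate] - bg[cw$cell_line]
  if (any(denom <= 0, na.rm = TRUE))
    stopf("plate DMSO mean not above background (assay failure) on plate %s",
          cw$plate[which(denom <= 0)[1L]])
  pv <- 100 * (cw$intensity - bg[cw$cell_line]) / denom
  agg <- aggregate(pv, by = list(compound_id = cw$compound_id,
                                 cell_line = cw$cell_line), FUN = mean)
  names(agg)[3L] <- "percent_viability"
  agg[order(agg$cell_line, agg$compound_id), , drop = FALSE]
}

check_wells <- function(wells) {
  need <- c("plate", "well", "cell_line", "role", "compound_id", "intensity")
  assert_that(is.data.frame(wells) && all(need %in% names(wells)),
              "well table must have columns %s", paste(need, collapse = ", "))
  assert_that(all(wells$role %in% c("compound", "dmso", "cellfree")),
              "role must be compound, dmso or cellfree")
  invisible(TRUE)
}
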