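## Variable-slope four-parameter logistic dose-response model
##
##   y(d) = bottom + (top - bottom) / (1 + 10^(hillslope * (log10 d - logIC50)))
##
## With hillslope > 0 this is the inhibition orientation: y -> top as
## d -> 0 and y -> bottom as d -> infinity, and y(10^logIC50) =
## (top + bottom) / 2.  It is the familiar "log(inhibitor) vs response,
## variable slope" model (whose textbook form writes the exponent as
## (logIC50 - X) * slope with a negative fitted slope for inhibitors;
## the two are identical under a sign flip, and fits here are
## canonicalized to top >= bottom).

#' Evaluate the four-parameter logistic curve
#'
#' @param dose strictly positive dose (molar).
#' @param bottom,top lower/upper response asymptotes.
#' @param logIC50 log10 of the half-maximal dose.
#' @param hillslope slope factor; positive = response falls with dose.
#' @return response at `dose`.
#' @export
f4pl <- function(dose, bottom, top, logIC50, hillslope) {
  bottom + (top - bottom) / (1 + 10^(hillslope * (log10(dose) - logIC50)))
}

#' Fit the variable-slope four-parameter logistic model
#'
#' Least squares with multi-start initialization (`nls`, `port`
#' algorithm).  A stalled optimizer never throws: the best candidate is
#' returned with `converged = FALSE`.  The default constraint keeps
#' `bottom >= 0`; fits are canonicalized so `top >= bottom` (flipping the
#' hillslope sign when the equivalent mirrored parameterization was
#' found).
#'
#' @param dose,response numeric vectors (doses strictly positive,
#'   replicates as repeated dose values).
#' @param constrain_bottom enforce `bottom >= 0`.
#' @return object of class `dr_fit`: `coef` (bottom, top, logIC50,
#'   hillslope), `se`, `rss`, `converged`, `identifiable`, `n`.
#' @examples
#' d <- 10^seq(-9, -4, length.out = 8)
#' y <- f4pl(d, 0, 100, -6, 1)
#' fit_4pl(d, y)$coef
#' @export
fit_4pl <- function(dose, response, constrain_bottom = TRUE) {
  assert_that(is.numeric(dose) && is.numeric(response) &&
                length(dose) == length(response),
              "dose and response must be numeric vectors of equal length")
  assert_that(all(dose > 0), "doses must be strictly positive")
  assert_that(all(is.finite(response)), "responses must be finite")
  nd <- length(unique(dose))
  assert_that(nd >= 4L, "need >= 4 distinct doses for 4 free parameters (got %d)", nd)
  ld <- log10(dose)
  df <- data.frame(ld = ld, y = response)

  ## degenerate: flat data -> bottom = top, logIC50 unidentifiable
  if (sd(response) == 0) {
    cf <- c(bottom = response[1L], top = response[1L],
            logIC50 = NA_real_, hillslope = NA_real_)
    return(structure(list(coef = cf, se = cf * NA, rss = 0,
                          converged = TRUE, identifiable = FALSE,
                          n = length(dose)),
                     class = "dr_fit"))
  }

  lo <- if (constrain_bottom) c(bottom = 0, top = -Inf,
                                logIC50 = -Inf, hillslope = -20) else
    c(bottom = -Inf, top = -Inf, logIC50 = -Inf, hillslope = -20)
  hi <- c(bottom = Inf, top = Inf, logIC50 = Inf, hillslope = 20)

  ## multi-start grid: asymptotes from the data range, logIC50 over the
  ## observed dose span, both slope orientations
  b0 <- max(min(response), if (constrain_bottom) 0 else -Inf)
  t0 <- max(response)
  starts <- expand.grid(logIC50 = quantile(ld, c(0.25, 0.5, 0.75),
                                           names = FALSE),
                        hillslope = c(-1, 0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(bottom = b0, top = t0,
               logIC50 = starts$logIC50[i], hillslope = starts$hillslope[i])
    fit <- tryCatch(
      nls(y ~ bottom + (top - bottom) / (1 + 10^(hillslope * (ld - logIC50))),
          data = df, start = st, algorithm = "port",
          lower = lo, upper = hi,
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    cf <- c(bottom = min(response), top = max(response),
            logIC50 = median(ld), hillslope = 1)
    return(structure(list(coef = cf, se = cf * NA, rss = NA_real_,
                          converged = FALSE, identifiable = FALSE,
                          n = length(dose)),
                     class = "dr_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) cf * NA)
  ## canonical orientation: top >= bottom (mirror parameterization is the
  ## same curve with the hillslope sign flipped)
  if (cf[["top"]] < cf[["bottom"]]) {
    cf <- c(bottom = cf[["top"]], top = cf[["bottom"]],
            logIC50 = cf[["logIC50"]], hillslope = -cf[["hillslope"]])
    se <- se[c("top", "bottom", "logIC50", "hillslope")]
    names(se) <- c("bottom", "top", "logIC50", "hillslope")
  }
  structure(list(coef = cf[c("bottom", "top", "logIC50", "hillslope")],
                 se = se, rss = best$rss,
                 converged = isTRUE(best$fit$convInfo$isConv),
                 identifiable = TRUE, n = length(dose)),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("4PL fit (variable slope)\n")
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  cat(sprintf("RSS %.4g on n = %d; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' @export
predict.dr_fit <- function(object, dose, ...) {
  cf <- object$coef
  if (!object$identifiable) return(rep(cf[["bottom"]], length(dose)))
  f4pl(dose, cf[["bottom"]], cf[["top"]], cf[["logIC50"]], cf[["hillslope"]])
}

#' Per-dose two-group comparison with BH correction
#'
#' Runs a two-sided unpaired t-test (pooled variance by default, Welch by
#' flag) at every dose, then adjusts the p-values across doses with
#' Benjamini-Hochberg.  A dose at which the pooled standard deviation is
#' zero yields an undefined test, reported as NA.
#'
#' @param data data.frame with columns `group`, `dose`, `response`; the
#'   two levels of `group` are compared.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data.frame per dose: `dose`, `n1`, `n2`, `t`, `df`, `p`, `q`.
#' @export
per_dose_group_test <- function(data, var_equal = TRUE) {
  assert_that(all(c("group", "dose", "response") %in% names(data)),
              "data needs columns group, dose, response")
  gl <- unique(data$group)
  assert_that(length(gl) == 2L, "exactly two groups required (got %d)", length(gl))
  doses <- sort(unique(data$dose))
  rows <- lapply(doses, function(d) {
    x <- data$response[data$dose == d & data$group == gl[1L]]
    y <- data$response[data$dose == d & data$group == gl[2L]]
    assert_that(length(x) >= 2L && length(y) >= 2L,
                "need >= 2 replicates per group at dose %g", d)
    tt <- student_t2(x, y, var_equal = var_equal)
    data.frame(dose = d, n1 = length(x), n2 = length(y),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

## two-sample t, returning NA when the variance estimate collapses
student_t2 <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
    if (sp2 <= 0) return(list(t = NA_real_, df = df, p = NA_real_))
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- var(x) / n1; v2 <- var(y) / n2
    if (v1 + v2 <= 0) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
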