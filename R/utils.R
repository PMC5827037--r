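## Internal helpers: argument checking, seeded evaluation, TSV io.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.  All generators funnel through this so that identical seeds
## give byte-identical outputs.
with_seed <- function(seed, expr) {
  assert_that(is_count(seed + 1), "seed must be a single non-negative integer")
  withr::with_seed(as.integer(seed), expr)
}

## Lognormal multiplier with mean exactly 1 and coefficient of variation cv.
## cv = 0 degenerates to the constant 1 (and consumes no random numbers
## unequally: we still draw n deviates so seeds line up across cv settings).
rlnorm_cv <- function(n, cv) {
  z <- rnorm(n)
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(z * sdlog - sdlog^2 / 2)
}

## Deterministic TSV writers/readers.  All on-disk tables in this package
## are plain tab-separated text with a header line and no quoting, so a
## fixed input and seed reproduces byte-identical files.
write_tsv <- function(x, path) {
  write.table(x, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

## Well labels for a 96-well plate in row-major order: A01 ... H12.
well_labels <- function(n_rows = 8L, n_cols = 12L) {
  rows <- LETTERS[seq_len(n_rows)]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(n_cols)), paste0)))
}
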