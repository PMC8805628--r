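# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

abort_bad_arg <- function(msg, class = "speechtrf_error") {
  rlang::abort(msg, class = c(class, "speechtrf_error"))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort_bad_arg(sprintf(
      "`%s` must be a single finite number %s %s.",
      name, if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) + sum(as.double(offs) * 48271)) %% 2147483629
  as.integer(s) + 1L
}

# Run `expr` under `seed` when given, otherwise with the ambient RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Column-wise Pearson correlation of two conformable matrices; returns one
# r per column pair. Constant columns give NA.
pearson_cols <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

# z-score the rows of a matrix; rows with (near-)zero SD become all zeros.
zscore_rows <- function(m, center = NULL, scale = NULL) {
  ctr <- center %||% rowMeans(m)
  scl <- scale %||% apply(m, 1L, stats::sd)
  out <- (m - ctr) / ifelse(scl > 1e-12, scl, 1)
  out[scl <= 1e-12, ] <- 0
  out
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol
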