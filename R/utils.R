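#' Geometric mean with zero handling
#'
#' Geometric mean of nonnegative counts. Zeros would annihilate the product,
#' so values below `zero_floor` are lifted to `zero_floor` before the log;
#' for integer counts this only affects zeros, and zero-free inputs are
#' returned as the exact geometric mean.
#'
#' @param x numeric vector of nonnegative values.
#' @param zero_floor replacement for zero counts (default 0.5).
#' @return scalar geometric mean.
#' @export
#' @examples
#' geo_mean(c(4, 9)) # 6
geo_mean <- function(x, zero_floor = 0.5) {
  if (length(x) == 0L) stop("geo_mean: empty input")
  if (any(x < 0)) stop("geo_mean: negative values")
  exp(mean(log(pmax(x, zero_floor))))
}

# internal: stop with a prefixed message
.fail <- function(...) stop(paste0(...), call. = FALSE)

# internal: coerce to base dense matrix
.dense <- function(x) as.matrix(x)

# internal: column sums that work for both dense and Matrix classes
.colsums <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colSums(x) else colSums(x)
}
.rowsums <- function(x) {
  if (inherits(x, "Matrix")) Matrix::rowSums(x) else rowSums(x)
}
.rowmeans <- function(x) {
  if (inherits(x, "Matrix")) Matrix::rowMeans(x) else rowMeans(x)
}
.colmeans <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colMeans(x) else colMeans(x)
}

# internal: per-gene variance across cells (rows = genes), dense or sparse
.rowvars <- function(x) {
  m <- .rowmeans(x)
  if (inherits(x, "Matrix")) {
    ex2 <- Matrix::rowMeans(x^2)
  } else {
    ex2 <- rowMeans(x^2)
  }
  n <- ncol(x)
  pmax(0, (ex2 - m^2) * n / (n - 1))
}

#' Adjusted Rand index between two labelings
#'
#' Convenience wrapper used by recovery diagnostics; agreement between a
#' clustering and a reference partition, corrected for chance.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[-1, 1\], 1 for identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) .fail("adjusted_rand: length mismatch")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
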