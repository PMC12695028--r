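#' Discrete cosine transform of an open outline
#'
#' Applies the orthonormal type-II discrete cosine transform to the x(t) and
#' y(t) coordinate series of an open outline. Open crown outlines are well
#' represented by a cosine basis because, unlike the complex-exponential
#' basis of elliptic Fourier analysis, it does not assume a closed curve.
#' A "harmonic" is one non-DC coefficient per coordinate stream; the DC
#' (mean) terms are stored separately and excluded from shape distances,
#' since centering already removes translation.
#'
#' @param outline A centered, size-normalized outline.
#' @param harmonics Number of non-DC coefficients to retain per stream
#'   (24 in the standard pipeline; at most \code{n - 1}).
#' @return An object of class \code{"dct_coefs"}: list with \code{coef}
#'   (harmonics x 2 matrix, streams x and y), \code{dc} (length-2), and
#'   \code{n} (source point count).
#' @export
dct_outline <- function(outline, harmonics = 24L) {
  p <- unclass(as_outline(outline))
  n <- nrow(p)
  if (harmonics < 1L) stop("harmonics must be >= 1")
  if (harmonics > n - 1L) stop("harmonics cannot exceed n - 1")
  cf <- cbind(dct2(p[, 1L], harmonics), dct2(p[, 2L], harmonics))
  dc <- c(sum(p[, 1L]) / sqrt(n), sum(p[, 2L]) / sqrt(n))
  structure(list(coef = cf, dc = dc, n = n),
            class = "dct_coefs")
}

# Orthonormal DCT-II, coefficients k = 1..K (DC handled separately).
dct2 <- function(v, K) {
  n <- length(v)
  k <- seq_len(K)
  t0 <- seq_len(n) - 0.5
  basis <- cos(pi * outer(t0, k) / n)   # n x K
  as.numeric(crossprod(basis, v)) * sqrt(2 / n)
}

#' Inverse discrete cosine transform
#'
#' Reconstructs an outline from cosine coefficients by evaluating the
#' truncated orthonormal DCT-III expansion at \code{n} equally spaced
#' parameter values. With full-rank coefficients and \code{n} equal to the
#' source point count the reconstruction is exact.
#'
#' @param coefs A \code{"dct_coefs"} object.
#' @param n Number of output points.
#' @return An outline.
#' @export
inverse_dct <- function(coefs, n = coefs$n) {
  stopifnot(inherits(coefs, "dct_coefs"))
  K <- nrow(coefs$coef)
  n0 <- coefs$n
  u <- (seq_len(n) - 0.5) / n            # parameter in (0, 1)
  basis <- cos(pi * outer(u, seq_len(K)))  # n x K
  x <- coefs$dc[1L] / sqrt(n0) + sqrt(2 / n0) * as.numeric(basis %*% coefs$coef[, 1L])
  y <- coefs$dc[2L] / sqrt(n0) + sqrt(2 / n0) * as.numeric(basis %*% coefs$coef[, 2L])
  as_outline(cbind(x, y))
}

#' Mean shape of a set of outlines
#'
#' Averages full-rank cosine coefficients across outlines and reconstructs
#' the mean tooth shape by inverse transform. All outlines are resampled to
#' a common point count first.
#'
#' @param outlines Non-empty list of outlines (normalized comparably).
#' @param n Common point count used for the average (default: the smallest
#'   point count in the set).
#' @return An outline: the mean shape.
#' @export
mean_shape <- function(outlines, n = NULL) {
  if (length(outlines) == 0L) stop("cannot average an empty set of outlines")
  outlines <- lapply(outlines, as_outline)
  if (is.null(n)) n <- min(vapply(outlines, nrow, 1L))
  cfs <- lapply(outlines, function(o) {
    if (nrow(o) != n) o <- resample_outline(o, n)
    dct_outline(o, harmonics = n - 1L)
  })
  avg <- cfs[[1L]]
  avg$coef <- Reduce(`+`, lapply(cfs, `[[`, "coef")) / length(cfs)
  avg$dc <- Reduce(`+`, lapply(cfs, `[[`, "dc")) / length(cfs)
  inverse_dct(avg, n)
}
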