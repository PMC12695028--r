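#' Construct a tooth outline
#'
#' An outline is an open, ordered 2D point sequence tracing the upper crown
#' boundary of a tooth from the mesial to the distal baseline terminus. The
#' first and last points define the crown baseline; the crown apex lies
#' between them.
#'
#' @param x Two-column numeric matrix (or object coercible to one) of
#'   (x, y) coordinates, ordered along the curve.
#' @return A numeric matrix of class \code{"outline"} with columns
#'   \code{x}, \code{y}.
#' @export
as_outline <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 2L) stop("an outline needs exactly two coordinate columns")
  if (nrow(m) < 3L) stop("an outline needs at least 3 points")
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("outline coordinates contain NA")
  d <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  if (any(d == 0)) stop("outline contains identical consecutive points")
  colnames(m) <- c("x", "y")
  class(m) <- c("outline", "matrix", "array")
  m
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline: %d points, length %.4g>\n", nrow(x), outline_length(x)))
  invisible(x)
}

#' Polyline length of an outline
#'
#' @param outline An outline matrix.
#' @return Total length of the open polyline (the baseline closure is not
#'   included).
#' @export
outline_length <- function(outline) {
  p <- unclass(outline)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Signed area of the baseline-closed crown polygon
#'
#' The crown is closed by the straight segment joining its first and last
#' points, and the shoelace formula is applied.
#'
#' @param outline An outline matrix.
#' @return Signed area (positive for counter-clockwise orientation).
#' @export
crown_area <- function(outline) {
  p <- unclass(outline)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Resample an outline to equally spaced points
#'
#' Interpolates the polyline at \code{n} positions equally spaced in arc
#' length. Endpoints are preserved exactly; teeth are compared at a common
#' point count (1000 in the standard pipeline).
#'
#' @param outline An outline matrix.
#' @param n Number of output points (>= 3).
#' @return A resampled outline.
#' @export
resample_outline <- function(outline, n = 1000L) {
  if (n < 3L) stop("n must be >= 3")
  p <- unclass(as_outline(outline))
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate zero-length outline")
  t_out <- seq(0, L, length.out = n)
  out <- cbind(stats::approx(s, p[, 1L], xout = t_out, ties = "ordered")$y,
               stats::approx(s, p[, 2L], xout = t_out, ties = "ordered")$y)
  out[1L, ] <- p[1L, ]
  out[n, ] <- p[nrow(p), ]
  as_outline(out)
}

#' Center an outline and normalize its size
#'
#' Centers the outline on its point centroid (the arithmetic mean of the
#' resampled points) and rescales so that either the total outline length or
#' the baseline-closed crown area equals 1.
#'
#' @param outline An outline matrix.
#' @param mode \code{"length"} or \code{"area"}.
#' @return The centered, size-normalized outline.
#' @export
center_and_scale <- function(outline, mode = c("length", "area")) {
  mode <- match.arg(mode)
  p <- unclass(as_outline(outline))
  ctr <- colMeans(p)
  p <- sweep(p, 2L, ctr)
  if (mode == "length") {
    s <- outline_length(p)
    if (s <= 0) stop("degenerate zero-length outline")
  } else {
    if (baseline_self_intersects(p))
      stop("baseline closure self-intersects the outline; area normalization undefined")
    a <- abs(crown_area(p))
    if (a <= .Machine$double.eps) stop("degenerate zero-area crown")
    s <- sqrt(a)
  }
  out <- p / s
  as_outline(out)
}

# TRUE when the straight closing segment (last -> first point) crosses the
# interior of any non-adjacent outline edge.
baseline_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p[n, ]; b <- p[1L, ]
  cross <- function(o, u, v) (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
  for (i in seq_len(n - 1L)) {
    if (i == 1L || i == n - 1L) next  # edges sharing a closure endpoint
    c1 <- cross(a, b, p[i, ]); c2 <- cross(a, b, p[i + 1L, ])
    d1 <- cross(p[i, ], p[i + 1L, ], a); d2 <- cross(p[i, ], p[i + 1L, ], b)
    if (((c1 > 0 && c2 < 0) || (c1 < 0 && c2 > 0)) &&
        ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0))) return(TRUE)
  }
  FALSE
}

#' Extract the upper crown from a full tooth outline
#'
#' The functional crown is the upper part of the tooth silhouette; the basal
#' region shows little morphological fine-tuning and is cut away before any
#' comparison. Three rules are applied in order of preference: (1) annotated
#' baseline termini, when the digitization supplies them; (2) on each lateral
#' side, the lowest concave point of the smoothed outline, when an inflection
#' is detectable; (3) otherwise the most distant pair of points within the
#' lower half of the shape.
#'
#' @param full_outline An outline (open or closed full-tooth boundary).
#' @param termini Optional integer vector of length 2: annotated indices of
#'   the baseline termini (rule 1).
#' @return The open crown outline running from one terminus to the other
#'   through the apex (the point farthest from the cut chord).
#' @export
segment_crown <- function(full_outline, termini = NULL) {
  p <- unclass(as_outline(full_outline))
  n <- nrow(p)
  if (!is.null(termini)) {
    termini <- as.integer(termini)
    if (length(termini) != 2L || any(termini < 1L | termini > n))
      stop("termini must be two valid point indices")
    return(crown_between(p, termini[1L], termini[2L]))
  }
  idx <- detect_concave_termini(p)
  if (is.null(idx)) idx <- distant_lower_pair(p)
  if (is.null(idx))
    stop("no crown base detectable; annotate baseline termini manually")
  crown_between(p, idx[1L], idx[2L])
}

# Open sub-outline between two indices, taking the arc containing the apex.
# Under the declared coordinate convention (y basal -> apical) the apex is
# the global y-maximum; if it coincides with a terminus, the arc reaching
# farther from the cut chord is taken instead.
crown_between <- function(p, i, j) {
  n <- nrow(p)
  if (i == j) stop("termini must differ")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  arc1 <- p[i:j, , drop = FALSE]
  arc2 <- p[c(j:n, if (i > 1L) 1:i else 1L), , drop = FALSE]
  if (i == 1L && j == n) return(as_outline(dedup_consecutive(arc1)))
  apex <- which.max(p[, 2L])
  arc <- if (apex > i && apex < j) {
    arc1
  } else if (apex < i || apex > j) {
    arc2
  } else {
    chord_dist <- function(q) {
      v <- p[j, ] - p[i, ]
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(0)
      max(abs((q[, 1L] - p[i, 1L]) * v[2L] - (q[, 2L] - p[i, 2L]) * v[1L]) / nv)
    }
    if (chord_dist(arc1) >= chord_dist(arc2)) arc1 else arc2
  }
  as_outline(dedup_consecutive(arc))
}

dedup_consecutive <- function(p) {
  keep <- c(TRUE, rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2) > 0)
  p[keep, , drop = FALSE]
}

# Rule (2): lowest concave point per lateral side of the smoothed outline.
# Concavity at a vertex is a cross-product of successive edge vectors whose
# sign opposes the dominant orientation of the curve.
detect_concave_termini <- function(p) {
  n <- nrow(p)
  if (n < 9L) return(NULL)
  # treat the full-tooth outline as a closed loop: pad cyclically so that
  # concavities spanning the traversal start are seen as well
  k <- 5L
  if (all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  n <- nrow(p)
  idx <- c((n - k + 1L):n, 1:n, 1:k)
  q <- p[idx, , drop = FALSE]
  sm <- cbind(movavg5(q[, 1L]), movavg5(q[, 2L]))
  m <- nrow(sm)
  e1 <- sm[2:(m - 1L), , drop = FALSE] - sm[1:(m - 2L), , drop = FALSE]
  e2 <- sm[3:m, , drop = FALSE] - sm[2:(m - 1L), , drop = FALSE]
  cr <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  core <- cr[k:(k + n - 1L)]   # curvature sign at original vertices 1..n
  orient <- sign(sum(core))
  if (orient == 0) return(NULL)
  concave <- which(core * orient < -1e-12)
  if (length(concave) < 2L) return(NULL)
  cx <- mean(p[, 1L])
  left <- concave[p[concave, 1L] < cx]
  right <- concave[p[concave, 1L] >= cx]
  if (length(left) == 0L || length(right) == 0L) return(NULL)
  c(left[which.min(p[left, 2L])], right[which.min(p[right, 2L])])
}

# Rule (3): brute-force most distant pair among lower-half points.
distant_lower_pair <- function(p) {
  low <- which(p[, 2L] < mean(p[, 2L]))
  if (length(low) < 2L) return(NULL)
  q <- p[low, , drop = FALSE]
  d <- as.matrix(stats::dist(q))
  ij <- arrayInd(which.max(d), dim(d))
  sort(c(low[ij[1L]], low[ij[2L]]))
}

movavg5 <- function(v) {
  n <- length(v)
  out <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  out <- as.numeric(out)
  # shrink the window at the ends instead of dropping points
  out[1L] <- mean(v[1:3]); out[2L] <- mean(v[1:4])
  out[n - 1L] <- mean(v[(n - 3L):n]); out[n] <- mean(v[(n - 2L):n])
  out
}
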