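#' Euclidean mean distance (EMD) between two outlines
#'
#' For each point of one outline, the distance to the physically closest
#' point of the other is taken, irrespective of relative position; the two
#' directed means (A to B and B to A) are summed. No homology between points
#' is assumed.
#'
#' @param a,b Outlines with equal point counts (as produced by the standard
#'   resampling), already aligned/normalized as required.
#' @return Non-negative distance.
#' @export
dist_emd <- function(a, b) {
  a <- unclass(as_outline(a)); b <- unclass(as_outline(b))
  if (nrow(a) != nrow(b)) stop("EMD requires equal point counts")
  cpp_emd(a, b)
}

#' Homologous Euclidean outline distance (HED)
#'
#' Compares points at identical relative positions along the two outlines
#' (pseudo-homology, akin to semi-landmarks). With equal point counts this
#' reduces to twice the mean positionwise distance; with unequal counts
#' each point i of one outline is matched to the point j of the other
#' minimizing |i/ni - j/nj|.
#'
#' @param a,b Outlines.
#' @return Non-negative distance.
#' @export
dist_hed <- function(a, b) {
  a <- unclass(as_outline(a)); b <- unclass(as_outline(b))
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(cpp_hed_equal(a, b))
  k <- match_relative(na, nb)   # for each i in a, index in b
  l <- match_relative(nb, na)
  d1 <- sqrt(rowSums((a - b[k, , drop = FALSE])^2))
  d2 <- sqrt(rowSums((b - a[l, , drop = FALSE])^2))
  mean(d1) + mean(d2)
}

# For each i = 1..ni, the j in 1..nj minimizing |i/ni - j/nj| (ties: lowest j).
match_relative <- function(ni, nj) {
  vapply(seq_len(ni), function(i) which.min(abs(i / ni - seq_len(nj) / nj)), 1L)
}

#' Superimposed area overlap (SAO) between two crowns
#'
#' Both crowns are closed by the straight baseline segment and rasterized on
#' a common grid; the similarity is 2|A intersect B| / (|A| + |B|) over the
#' pixel sets (1 = identical, 0 = disjoint). The grid discretizes each axis
#' of the joint bounding box into \code{units} cells and is fixed before any
#' alignment, so pixel size does not change under the superimposition search.
#'
#' @param a,b Outlines.
#' @param units Cells per axis across the joint bounding box (default 100).
#' @param grid Optional precomputed grid from \code{\link{sao_grid}}.
#' @return Similarity in [0, 1]. The pipeline stores 1 - SAO so that all six
#'   measures are distances.
#' @export
sao_overlap <- function(a, b, units = 100L, grid = NULL) {
  a <- unclass(as_outline(a)); b <- unclass(as_outline(b))
  if (is.null(grid)) grid <- sao_grid(a, b, units)
  cpp_sao(a, b, grid$x0, grid$y0, grid$cx, grid$cy, grid$nx, grid$ny)
}

#' Rasterization grid for SAO
#'
#' Cell sizes come from the maximal x and y extents of the two outlines
#' divided into \code{units}; the covered region is padded so that shapes
#' remain on-grid throughout the superimposition search bounds.
#'
#' @param a,b Outlines (centered).
#' @param units Cells per axis over the unpadded extent.
#' @param pad Fractional padding per side.
#' @return List with grid origin, cell sizes and cell counts.
#' @export
sao_grid <- function(a, b, units = 100L, pad = 0.4) {
  xr <- range(a[, 1L], b[, 1L]); yr <- range(a[, 2L], b[, 2L])
  wx <- max(diff(xr), .Machine$double.eps)
  wy <- max(diff(yr), .Machine$double.eps)
  cx <- wx / units; cy <- wy / units
  x0 <- xr[1L] - pad * wx; y0 <- yr[1L] - pad * wy
  nx <- as.integer(ceiling(wx * (1 + 2 * pad) / cx))
  ny <- as.integer(ceiling(wy * (1 + 2 * pad) / cy))
  list(x0 = x0, y0 = y0, cx = cx, cy = cy, nx = nx, ny = ny)
}

#' Discrete cosine Fourier distance (DFD)
#'
#' Euclidean distance between the cosine coefficients of two outlines over
#' the first \code{harmonics} harmonics of both coordinate streams. Computed
#' on centered, size-normalized outlines without any superimposition search.
#'
#' @param a,b Outlines (normalized), or \code{"dct_coefs"} objects.
#' @param harmonics Number of harmonics (default 24).
#' @return Non-negative distance.
#' @export
dist_dfd <- function(a, b, harmonics = 24L) {
  ca <- if (inherits(a, "dct_coefs")) a else dct_outline(a, harmonics)
  cb <- if (inherits(b, "dct_coefs")) b else dct_outline(b, harmonics)
  if (nrow(ca$coef) != nrow(cb$coef)) stop("mismatched harmonic counts")
  sqrt(sum((ca$coef - cb$coef)^2))
}

#' Cumulative surface-angle function of an outline
#'
#' The outline is resampled to \code{n} equidistant points (point reduction
#' suppresses digitization noise); at each interior point the angle of the
#' local point triplet is taken (pi for a locally straight outline) and the
#' angles are accumulated from a common anchor of 0.
#'
#' @param outline An outline.
#' @param n Number of equidistant points (default 100).
#' @return Object of class \code{"angle_function"}: numeric vector af of
#'   length n - 2 (interior points 2..n-1) with attribute \code{angles}.
#' @export
angle_function <- function(outline, n = 100L) {
  p <- unclass(resample_outline(outline, n))
  ang <- interior_angles(p)
  structure(cumsum(ang), angles = ang, class = "angle_function")
}

# Interior angle in [0, pi] at each interior vertex of a polyline.
interior_angles <- function(p) {
  n <- nrow(p)
  u <- p[1:(n - 2L), , drop = FALSE] - p[2:(n - 1L), , drop = FALSE]
  v <- p[3:n, , drop = FALSE] - p[2:(n - 1L), , drop = FALSE]
  dot <- rowSums(u * v)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  acos(pmin(1, pmax(-1, dot / (nu * nv))))
}

#' Outline angle sum distance (OAD)
#'
#' The cumulative surface-angle functions of the two outlines are overlaid
#' starting from the same value and the area between them is accumulated
#' (unit step per point).
#'
#' @param a,b Outlines, or \code{"angle_function"} objects.
#' @param n Equidistant points for the angle functions (default 100).
#' @return Non-negative distance.
#' @export
dist_oad <- function(a, b, n = 100L) {
  fa <- if (inherits(a, "angle_function")) a else angle_function(a, n)
  fb <- if (inherits(b, "angle_function")) b else angle_function(b, n)
  if (length(fa) != length(fb)) stop("angle functions of unequal length")
  sum(abs(unclass(fa) - unclass(fb)))
}

#' Angle function discrete cosine Fourier distance (ADD)
#'
#' The cumulative surface-angle functions are cosine-transformed and the
#' Euclidean distance between coefficients over the first \code{harmonics}
#' harmonics is returned (DC excluded, consistent with the common-anchor
#' overlay of the angle functions).
#'
#' @param a,b Outlines, or \code{"angle_function"} objects.
#' @param harmonics Number of harmonics (default 24).
#' @param n Equidistant points for the angle functions (default 100).
#' @return Non-negative distance.
#' @export
dist_add <- function(a, b, harmonics = 24L, n = 100L) {
  fa <- if (inherits(a, "angle_function")) a else angle_function(a, n)
  fb <- if (inherits(b, "angle_function")) b else angle_function(b, n)
  if (length(fa) != length(fb)) stop("angle functions of unequal length")
  ca <- dct2(unclass(fa), harmonics)
  cb <- dct2(unclass(fb), harmonics)
  sqrt(sum((ca - cb)^2))
}

#' The six registered distance measures
#'
#' EMD, HED and SAO receive the partial Procrustes superimposition search;
#' DFD, OAD and ADD are computed directly on centered, size-normalized
#' outlines. SAO enters distance tables as 1 - overlap.
#'
#' @return Character vector of measure identifiers.
#' @export
distance_measures <- function() c("EMD", "HED", "SAO", "DFD", "OAD", "ADD")

#' Pairwise tooth distances under the six measures
#'
#' Computes the distance tensor d(toothA, toothB, measure) for a set of
#' teeth. Outlines are resampled to a common point count; EMD/HED/SAO are
#' minimized over the bounded superimposition search (both size modes, lower
#' kept), DFD/OAD/ADD are evaluated on length-normalized centered outlines.
#'
#' @param teeth A tooth table (see \code{\link{tooth_table}}), a dentition,
#'   or list of dentitions.
#' @param measures Subset of \code{\link{distance_measures}()}.
#' @param search Superimposition grid spec from \code{\link{align_grid_spec}}.
#' @param n_points Common resampling count (the full pipeline uses 1000;
#'   smaller counts trade accuracy for speed).
#' @param harmonics Harmonics for DFD/ADD.
#' @param angle_points Equidistant points for the angle functions.
#' @return Object of class \code{"distance_tensor"}: list with \code{d}
#'   (named list of symmetric matrices, one per measure) and \code{teeth}
#'   (data.frame species/jaw/position).
#' @export
pairwise_distances <- function(teeth, measures = distance_measures(),
                               search = align_grid_spec(),
                               n_points = 200L, harmonics = 24L,
                               angle_points = 100L) {
  if (inherits(teeth, "dentition") || (is.list(teeth) && !is.data.frame(teeth)))
    teeth <- tooth_table(teeth)
  measures <- match.arg(measures, distance_measures(), several.ok = TRUE)
  nt <- nrow(teeth)
  ids <- sprintf("%s_%s_%d", teeth$species, teeth$jaw, teeth$position)
  prepped <- lapply(teeth$outline, function(o)
    center_and_scale(resample_outline(o, n_points), "length"))
  prep_area <- lapply(teeth$outline, function(o)
    tryCatch(center_and_scale(resample_outline(o, n_points), "area"),
             error = function(e) NULL))
  cfs <- if (any(c("DFD") %in% measures))
    lapply(prepped, dct_outline, harmonics = harmonics) else NULL
  afs <- if (any(c("OAD", "ADD") %in% measures))
    lapply(prepped, angle_function, n = angle_points) else NULL
  d <- lapply(measures, function(m) {
    mat <- matrix(0, nt, nt, dimnames = list(ids, ids))
    mat
  })
  names(d) <- measures
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (j <= i) next
      for (m in measures) {
        val <- tryCatch(
          switch(m,
            EMD = align_pair(prepped[[i]], prepped[[j]], "EMD", search,
                             b_area = prep_area[[j]], a_area = prep_area[[i]])$distance,
            HED = align_pair(prepped[[i]], prepped[[j]], "HED", search,
                             b_area = prep_area[[j]], a_area = prep_area[[i]])$distance,
            SAO = align_pair(prepped[[i]], prepped[[j]], "SAO", search,
                             b_area = prep_area[[j]], a_area = prep_area[[i]])$distance,
            DFD = dist_dfd(cfs[[i]], cfs[[j]]),
            OAD = dist_oad(afs[[i]], afs[[j]]),
            ADD = dist_add(afs[[i]], afs[[j]], harmonics = harmonics)),
          error = function(e)
            stop(sprintf("distance %s failed for pair (%s, %s): %s",
                         m, ids[i], ids[j], conditionMessage(e)), call. = FALSE))
        d[[m]][i, j] <- d[[m]][j, i] <- val
      }
    }
  }
  structure(list(d = d, teeth = teeth[, c("species", "jaw", "position")]),
            class = "distance_tensor")
}

#' @export
print.distance_tensor <- function(x, ...) {
  cat(sprintf("<distance_tensor: %d teeth, measures: %s>\n",
              nrow(x$teeth), paste(names(x$d), collapse = ", ")))
  invisible(x)
}

#' Serialize a distance tensor to long-format TSV
#'
#' @param tensor A \code{"distance_tensor"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_tensor <- function(tensor, path) {
  rows <- list()
  ids <- rownames(tensor$d[[1L]])
  for (m in names(tensor$d)) {
    mat <- tensor$d[[m]]
    idx <- which(upper.tri(mat), arr.ind = TRUE)
    rows[[m]] <- data.frame(toothA = ids[idx[, 1L]], toothB = ids[idx[, 2L]],
                            measure = m, value = mat[idx])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
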