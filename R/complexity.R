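#' Resolution ladder for angle-based measures
#'
#' Angle-based complexity is averaged over six successively coarser
#' resamplings of the outline, n_R = n / (5 * 2^(R-1)) for R = 1..6, rounded
#' half-up (200, 100, 50, 25, 13, 6 points at the standard n = 1000).
#' Resolutions with fewer than 3 points are dropped with a warning.
#'
#' @param n Base point count.
#' @param levels Number of resolutions.
#' @return Strictly decreasing integer vector of point counts.
#' @export
resolution_ladder <- function(n = 1000L, levels = 6L) {
  r <- floor(n / (5 * 2^(seq_len(levels) - 1L)) + 0.5)
  keep <- r >= 3
  if (!all(keep))
    warning("dropping resolutions with fewer than 3 points: ",
            paste(r[!keep], collapse = ", "))
  as.integer(r[keep])
}

# Distance of each outline point from the baseline (the line through the
# first and last points), positive toward the apex side.
baseline_distance <- function(p) {
  a <- p[1L, ]; b <- p[nrow(p), ]
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(sqrt(rowSums(sweep(p, 2L, a)^2)))
  d <- ((p[, 1L] - a[1L]) * v[2L] - (p[, 2L] - a[2L]) * v[1L]) / nv
  if (sum(d) < 0) d <- -d   # orient positive toward the crown
  d
}

#' Count major cusps and minor cusplets
#'
#' Cusp apices are local maxima of the distance to the crown baseline. The
#' prominence of a cusp is its apex height minus the higher of its two
#' flanking cols (saddles); a cusp is major if that prominence reaches
#' \code{threshold} times the total outline length, minor otherwise. The
#' largest cusp is always counted as major. A flat crown has no cusps.
#'
#' @param outline A crown outline.
#' @param threshold Prominence threshold as a fraction of outline length
#'   (default 0.02).
#' @return Named integer vector \code{c(major, minor)}.
#' @export
count_cusps <- function(outline, threshold = 0.02) {
  p <- unclass(as_outline(outline))
  h <- baseline_distance(p)
  L <- outline_length(p)
  if (max(h) - min(h) < 1e-9 * max(L, 1)) return(c(major = 0L, minor = 0L))
  n <- length(h)
  # local maxima; plateaus contribute a single peak (their first point)
  peaks <- which(h[2:(n - 1L)] > h[1:(n - 2L)] & h[2:(n - 1L)] >= h[3:n]) + 1L
  if (length(peaks) > 1L) {
    keep <- c(TRUE, vapply(2:length(peaks), function(k) {
      between <- h[(peaks[k - 1L] + 1L):peaks[k]]
      any(between < h[peaks[k]] - 1e-12) || any(between < h[peaks[k - 1L]] - 1e-12)
    }, TRUE))
    peaks <- peaks[keep]
  }
  peaks <- peaks[h[peaks] > 0]
  if (length(peaks) == 0L) peaks <- which.max(h)
  prom <- vapply(peaks, function(pk) peak_prominence(h, pk), 0.0)
  major <- prom >= threshold * L
  major[which.max(h[peaks])] <- TRUE   # the largest cusp is always major
  c(major = sum(major), minor = sum(!major))
}

# Prominence of peak at index pk: height minus the higher of the two cols
# reached before climbing to strictly higher terrain (or the profile end).
peak_prominence <- function(h, pk) {
  n <- length(h)
  left <- h[pk]
  if (pk > 1L) {
    i <- pk - 1L; m <- h[pk]
    while (i >= 1L && h[i] <= h[pk]) { m <- min(m, h[i]); i <- i - 1L }
    left <- if (i >= 1L) m else min(h[1:pk])
  } else left <- h[pk]
  right <- h[pk]
  if (pk < n) {
    i <- pk + 1L; m <- h[pk]
    while (i <= n && h[i] <= h[pk]) { m <- min(m, h[i]); i <- i + 1L }
    right <- if (i <= n) m else min(h[pk:n])
  } else right <- h[pk]
  h[pk] - max(left, right)
}

#' Outline-to-area ratio (OAR)
#'
#' Total crown outline length divided by the area of the baseline-closed
#' crown polygon. Scales as 1/size; the pipeline evaluates it on
#' size-normalized outlines.
#'
#' @param outline A crown outline.
#' @return Positive ratio.
#' @export
oar <- function(outline) {
  o <- as_outline(outline)
  a <- abs(crown_area(o))
  if (a <= .Machine$double.eps) stop("zero crown area; OAR undefined")
  outline_length(o) / a
}

#' Outline-to-centroid-size ratio (OCR)
#'
#' Outline length divided by the square root of the summed point-to-centroid
#' distances. The denominator grows with the sampling density, so OCR is
#' only comparable at a fixed point count (1000 in the standard pipeline).
#'
#' @param outline A crown outline (resampled to the standard point count).
#' @return Positive ratio.
#' @export
ocr <- function(outline) {
  p <- unclass(as_outline(outline))
  ctr <- colMeans(p)
  cs <- sqrt(sum(sqrt(rowSums(sweep(p, 2L, ctr)^2))))
  if (cs <= 0) stop("degenerate outline; OCR undefined")
  outline_length(p) / cs
}

#' Escribed-to-inscribed circle area ratio (OIR)
#'
#' Ratio of the area of the smallest circle enclosing the crown to the area
#' of the largest circle inscribed in the baseline-closed crown polygon,
#' capped at 25 to keep extreme slivers from dominating downstream sums.
#' An eccentricity measure: 1 for a disc, large for elongated shapes.
#'
#' @param outline A crown outline.
#' @param cap Upper cutoff (default 25).
#' @param grid Grid resolution of the inscribed-circle search.
#' @return Ratio in [1, cap].
#' @export
oir <- function(outline, cap = 25, grid = 256L) {
  p <- unclass(as_outline(outline))
  R <- enclosing_circle_radius(p)
  r <- cpp_inradius(p, as.integer(grid), 3L)
  if (!is.finite(r) || r <= 0) return(cap)
  min(cap, max(1, (R / r)^2))
}

# Smallest enclosing circle radius: randomized incremental (Welzl-style)
# over the convex hull vertices; deterministic via a fixed permutation seed.
enclosing_circle_radius <- function(p) {
  hull <- grDevices::chull(p)
  H <- p[hull, , drop = FALSE]
  n <- nrow(H)
  if (n == 1L) return(0)
  if (n == 2L) return(sqrt(sum((H[1L, ] - H[2L, ])^2)) / 2)
  H <- H[local_seed(7L, sample.int(n)), , drop = FALSE]
  inC <- function(c, q) sqrt(sum((q - c[1:2])^2)) <= c[3L] * (1 + 1e-12)
  circ2 <- function(a, b) c((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c3) {
    d <- 2 * (a[1L] * (b[2L] - c3[2L]) + b[1L] * (c3[2L] - a[2L]) +
                c3[1L] * (a[2L] - b[2L]))
    if (abs(d) < 1e-300) return(c(0, 0, Inf))
    ux <- (sum(a^2) * (b[2L] - c3[2L]) + sum(b^2) * (c3[2L] - a[2L]) +
             sum(c3^2) * (a[2L] - b[2L])) / d
    uy <- (sum(a^2) * (c3[1L] - b[1L]) + sum(b^2) * (a[1L] - c3[1L]) +
             sum(c3^2) * (b[1L] - a[1L])) / d
    c(ux, uy, sqrt((a[1L] - ux)^2 + (a[2L] - uy)^2))
  }
  cc <- circ2(H[1L, ], H[2L, ])
  for (i in 3:n) {
    if (inC(cc, H[i, ])) next
    cc <- circ2(H[1L, ], H[i, ])
    for (j in 2:(i - 1L)) {
      if (inC(cc, H[j, ])) next
      cc <- circ2(H[j, ], H[i, ])
      for (k in seq_len(j - 1L)) {
        if (inC(cc, H[k, ])) next
        cc <- circ3(H[k, ], H[j, ], H[i, ])
      }
    }
  }
  cc[3L]
}

#' Discrete cosine Fourier coefficient sum (DFS)
#'
#' Sum of absolute cosine coefficients over the first \code{harmonics}
#' harmonics of both coordinate streams: a proxy for the information needed
#' to describe the shape, i.e. single-tooth Fourier complexity.
#'
#' @param outline A normalized crown outline (or \code{"dct_coefs"}).
#' @param harmonics Number of harmonics (default 24).
#' @return Non-negative sum.
#' @export
dfs <- function(outline, harmonics = 24L) {
  cf <- if (inherits(outline, "dct_coefs")) outline else
    dct_outline(outline, harmonics)
  sum(abs(cf$coef))
}

#' Angle-based complexity measures (ANS, ASC, AND)
#'
#' At each ladder resolution the outline is resampled and interior surface
#' angles computed. ANS is the mean over resolutions of the summed angular
#' deviations from a straight outline, sum |angle - pi|. ASC is the mean
#' signed difference of that sum between successive resolutions (repetitive
#' fine structure produces large drops toward coarse resolutions). AND is
#' the mean over resolutions of the mean absolute difference between all
#' pairs of interior angles (angle diversity).
#'
#' @param outline A crown outline.
#' @param ladder Point counts from \code{\link{resolution_ladder}}.
#' @param asc_absolute Take |differences| in ASC instead of signed values.
#' @return Named list with \code{ANS}, \code{ASC}, \code{AND} and the
#'   per-resolution sums \code{A}.
#' @export
angle_complexity <- function(outline, ladder = resolution_ladder(1000L),
                             asc_absolute = FALSE) {
  A <- numeric(length(ladder))
  AND_r <- numeric(length(ladder))
  for (r in seq_along(ladder)) {
    p <- unclass(resample_outline(outline, ladder[r]))
    ang <- interior_angles(p)
    A[r] <- sum(abs(ang - pi))
    AND_r[r] <- mean(abs(outer(ang, ang, "-")))
  }
  dA <- diff(A)
  if (asc_absolute) dA <- abs(dA)
  list(ANS = mean(A), ASC = if (length(dA)) mean(dA) else 0,
       AND = mean(AND_r), A = A)
}

#' Orientation patch count (OPC), outline variant
#'
#' Each inter-point vector is assigned to a circular direction sector; a
#' patch is a maximal run of consecutive vectors in the same sector. The
#' count is averaged over sector partitions (2, 4, 8 by default), coordinate
#' rotations (none and half a sector per partition, plus a quarter sector
#' for the coarsest partition) and the ladder resolutions. A straight line
#' scores 1 in every configuration.
#'
#' @param outline A crown outline.
#' @param partitions Sector counts.
#' @param ladder Resolutions from \code{\link{resolution_ladder}}.
#' @return Mean patch count (>= 1).
#' @export
opc <- function(outline, partitions = c(2L, 4L, 8L),
                ladder = resolution_ladder(1000L)) {
  counts <- numeric(0)
  for (nr in ladder) {
    p <- unclass(resample_outline(outline, nr))
    v <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    theta <- atan2(v[, 2L], v[, 1L]) %% (2 * pi)
    for (np in partitions) {
      w <- 2 * pi / np
      offs <- c(0, w / 2)
      if (np == min(partitions)) offs <- c(offs, w / 4)
      for (off in offs) {
        sec <- floor(((theta + off) %% (2 * pi)) / w)
        counts <- c(counts, length(rle(sec)$lengths))
      }
    }
  }
  mean(counts)
}

#' All ten complexity measures for one tooth
#'
#' Resamples the outline to \code{n_points}, length-normalizes it, and
#' evaluates cuspidity (CUSP1, CUSP2), eccentricity ratios (OAR, OCR, OIR),
#' Fourier complexity (DFS) and angle complexity (ANS, ASC, AND, OPC).
#'
#' @param outline A crown outline.
#' @param n_points Standard resampling count (default 1000).
#' @param harmonics Harmonics for DFS.
#' @param asc_absolute Passed to \code{\link{angle_complexity}}.
#' @return One-row data.frame with the ten raw measures.
#' @export
tooth_complexity <- function(outline, n_points = 1000L, harmonics = 24L,
                             asc_absolute = FALSE) {
  o <- center_and_scale(resample_outline(outline, n_points), "length")
  ladder <- resolution_ladder(n_points)
  cusp <- count_cusps(o)
  angm <- angle_complexity(o, ladder, asc_absolute)
  data.frame(CUSP1 = cusp[["major"]], CUSP2 = cusp[["minor"]],
             OAR = oar(o), OCR = ocr(o), OIR = oir(o),
             DFS = dfs(o, harmonics),
             ANS = angm$ANS, ASC = angm$ASC, AND = angm$AND,
             OPC = opc(o, ladder = ladder))
}

complexity_measure_names <- function() {
  c("CUSP1", "CUSP2", "OAR", "OCR", "OIR", "DFS", "ANS", "ASC", "AND", "OPC")
}

#' Species-level complexity table
#'
#' Averages per-tooth complexity over all teeth of both jaws per species,
#' then adds globally min-max normalized columns (suffix \code{.norm}), the
#' pooled groups Cx_exc (OCR + OAR + OIR), Cx_ang (ANS + ASC + AND + OPC)
#' and Cx_four (DFS) on normalized values, the combined sum Cx_combined of
#' all ten normalized measures, and the cusp ratio CUSP2/CUSP1 (0 when
#' CUSP1 = 0) on raw counts.
#'
#' @param dents List of dentitions (or a single dentition).
#' @param n_points,harmonics,asc_absolute Passed to
#'   \code{\link{tooth_complexity}}.
#' @return Data.frame, one row per species.
#' @export
species_complexity <- function(dents, n_points = 1000L, harmonics = 24L,
                               asc_absolute = FALSE) {
  if (inherits(dents, "dentition")) dents <- list(dents)
  if (length(dents) == 0L) stop("no dentitions supplied")
  rows <- lapply(dents, function(d) {
    tt <- tooth_table(d)
    if (nrow(tt) == 0L) stop("empty dentition: ", d$species)
    per_tooth <- do.call(rbind, lapply(tt$outline, tooth_complexity,
                                       n_points = n_points,
                                       harmonics = harmonics,
                                       asc_absolute = asc_absolute))
    cbind(data.frame(species = d$species), as.data.frame(t(colMeans(per_tooth))))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  mm <- complexity_measure_names()
  normed <- lapply(mm, function(m) minmax_norm(tab[[m]]))
  names(normed) <- paste0(mm, ".norm")
  tab <- cbind(tab, as.data.frame(normed))
  tab$Cx_exc <- tab$OCR.norm + tab$OAR.norm + tab$OIR.norm
  tab$Cx_ang <- tab$ANS.norm + tab$ASC.norm + tab$AND.norm + tab$OPC.norm
  tab$Cx_four <- tab$DFS.norm
  tab$Cx_combined <- rowSums(tab[paste0(mm, ".norm")])
  tab$cusp_ratio <- ifelse(tab$CUSP1 == 0, 0, tab$CUSP2 / tab$CUSP1)
  tab
}

# Global min-max normalization to [0, 1]; constant columns map to 0.
minmax_norm <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(rep(0, length(v)))
  (v - r[1L]) / diff(r)
}
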