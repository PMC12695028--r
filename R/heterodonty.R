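#' Sequential monognathic heterodonty (HMS)
#'
#' Mean shape difference between neighboring teeth along one jaw:
#' sum over teeth of the distances to their mesial and distal neighbors,
#' divided by 2n. Terms for missing neighbors at the row ends are skipped
#' while the printed denominator 2n is retained, so HMS equals the mean
#' sequential distance times (n-1)/n; \code{boundary = "mean"} divides by
#' the number of existing terms instead.
#'
#' @param d Symmetric distance matrix of the jaw's teeth in positional order.
#' @param boundary \code{"as_printed"} (denominator 2n) or \code{"mean"}.
#' @return Non-negative statistic.
#' @export
hms <- function(d, boundary = c("as_printed", "mean")) {
  boundary <- match.arg(boundary)
  n <- check_row_matrix(d)
  seqd <- d[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  total <- 2 * sum(seqd)          # each neighbor distance appears twice
  if (boundary == "as_printed") total / (2 * n) else total / (2 * (n - 1L))
}

#' Total monognathic heterodonty (HMT)
#'
#' Mean shape difference between all ordered pairs of teeth within one jaw,
#' sum d(i, j) / n^2, with the zero diagonal included as printed.
#'
#' @param d Symmetric distance matrix of the jaw's teeth.
#' @return Non-negative statistic.
#' @export
hmt <- function(d) {
  n <- check_row_matrix(d)
  sum(d) / n^2
}

#' Maximal monognathic heterodonty (HMX)
#'
#' Largest shape difference between any two teeth of one jaw.
#'
#' @param d Symmetric distance matrix of the jaw's teeth.
#' @return Non-negative statistic.
#' @export
hmx <- function(d) {
  check_row_matrix(d)
  max(d)
}

check_row_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 2L) stop("a tooth row needs at least 2 teeth")
  nrow(d)
}

#' Dignathic heterodonty (HDG)
#'
#' Shape difference between teeth at approximately opposite positions of the
#' upper and lower jaw. Each tooth is matched to the tooth of the opposing
#' jaw at the nearest relative position (k minimizing |i/ni - j/nj|, so one
#' tooth may be matched repeatedly when counts differ); the two directed
#' mean distances are summed.
#'
#' @param d_cross Matrix of distances, rows = upper jaw teeth in positional
#'   order, columns = lower jaw teeth.
#' @return Non-negative statistic.
#' @export
hdg <- function(d_cross) {
  if (!is.matrix(d_cross)) stop("d_cross must be a matrix")
  ni <- nrow(d_cross); nj <- ncol(d_cross)
  if (ni == 0L || nj == 0L) stop("both jaws must be non-empty")
  k <- match_relative(ni, nj)
  l <- match_relative(nj, ni)
  mean(d_cross[cbind(seq_len(ni), k)]) + mean(d_cross[cbind(l, seq_len(nj))])
}

#' Total phenotypic distance between two species (DP)
#'
#' Position-matched tooth comparison between two species, applied within
#' matching jaws (upper with upper, lower with lower) in the same directed
#' relative-position manner as dignathic heterodonty, then averaged over the
#' two jaws.
#'
#' @param d_upper Matrix of distances between the two species' upper teeth
#'   (rows = species A, columns = species B, positional order).
#' @param d_lower Same for the lower jaws.
#' @return Non-negative statistic.
#' @export
phenotypic_distance <- function(d_upper, d_lower) {
  (hdg(d_upper) + hdg(d_lower)) / 2
}

# Slice helper: distance sub-matrix for one species/jaw (positional order).
tensor_slice <- function(tensor, measure, species_a, jaw_a,
                         species_b = species_a, jaw_b = jaw_a) {
  t1 <- which(tensor$teeth$species == species_a & tensor$teeth$jaw == jaw_a)
  t2 <- which(tensor$teeth$species == species_b & tensor$teeth$jaw == jaw_b)
  t1 <- t1[order(tensor$teeth$position[t1])]
  t2 <- t2[order(tensor$teeth$position[t2])]
  tensor$d[[measure]][t1, t2, drop = FALSE]
}

#' Per-species heterodonty statistics under each distance measure
#'
#' Computes HMS, HMT and HMX per jaw (averaged over the jaws present), and
#' HDG from the cross-jaw block, for every species and distance measure in
#' the tensor.
#'
#' @param tensor A \code{"distance_tensor"} over all teeth of the species
#'   set (see \code{\link{pairwise_distances}}).
#' @param boundary Passed to \code{\link{hms}}.
#' @return Long data.frame: species, measure, HMS, HMT, HDG, HMX.
#' @export
heterodonty_records <- function(tensor, boundary = "as_printed") {
  stopifnot(inherits(tensor, "distance_tensor"))
  species <- unique(tensor$teeth$species)
  out <- list()
  for (sp in species) {
    jaws <- unique(tensor$teeth$jaw[tensor$teeth$species == sp])
    for (m in names(tensor$d)) {
      vals <- lapply(jaws, function(j) {
        dm <- tensor_slice(tensor, m, sp, j)
        if (nrow(dm) < 2L) return(c(NA_real_, NA_real_, NA_real_))
        c(hms(dm, boundary), hmt(dm), hmx(dm))
      })
      vals <- do.call(rbind, vals)
      hdg_v <- if (all(c("upper", "lower") %in% jaws))
        hdg(tensor_slice(tensor, m, sp, "upper", sp, "lower")) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        species = sp, measure = m,
        HMS = mean(vals[, 1L], na.rm = TRUE),
        HMT = mean(vals[, 2L], na.rm = TRUE),
        HDG = hdg_v,
        HMX = mean(vals[, 3L], na.rm = TRUE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

heterodonty_stat_names <- function() c("HMS", "HMT", "HDG", "HMX")

#' Aggregate heterodonty records into a species measure table
#'
#' Because the six distance measures live on incommensurable scales, each
#' statistic is first min-max normalized per distance measure across species
#' and the six normalized values are then averaged (columns HMS, HMT, HDG,
#' HMX). Raw per-measure values are kept (e.g. \code{HMS_EMD}). Derived
#' ratios are computed on unnormalized per-measure values and averaged over
#' measures: graduality (HMX/HMS) and hdg_hmt_ratio (HDG/HMT); the
#' outline-vs-angle ratios compare normalized heterodonty under the
#' outline-based measures (EMD, HED, SAO) to the angle-based ones (OAD,
#' ADD).
#'
#' @param records Output of \code{\link{heterodonty_records}}.
#' @return Wide data.frame, one row per species (a species measure table).
#' @export
heterodonty_table <- function(records) {
  species <- unique(records$species)
  if (length(species) < 2L)
    stop("global min-max normalization needs at least 2 species")
  measures <- unique(records$measure)
  stats <- heterodonty_stat_names()
  tab <- data.frame(species = species)
  raw <- norm <- list()
  for (st in stats) {
    for (m in measures) {
      v <- records[records$measure == m, ][match(species, records$species[records$measure == m]), st]
      raw[[paste0(st, "_", m)]] <- v
      norm[[paste0(st, "_", m, ".norm")]] <- minmax_norm(v)
    }
  }
  tab <- cbind(tab, as.data.frame(raw), as.data.frame(norm))
  for (st in stats) {
    cols <- paste0(st, "_", measures, ".norm")
    tab[[st]] <- rowMeans(tab[cols], na.rm = TRUE)
  }
  safe_ratio <- function(num, den) ifelse(den == 0, ifelse(num == 0, 0, NA), num / den)
  grad <- sapply(measures, function(m)
    safe_ratio(tab[[paste0("HMX_", m)]], tab[[paste0("HMS_", m)]]))
  hh <- sapply(measures, function(m)
    safe_ratio(tab[[paste0("HDG_", m)]], tab[[paste0("HMT_", m)]]))
  tab$graduality <- rowMeans(as.matrix(grad), na.rm = TRUE)
  tab$hdg_hmt_ratio <- rowMeans(as.matrix(hh), na.rm = TRUE)
  outl <- intersect(c("EMD", "HED", "SAO"), measures)
  angl <- intersect(c("OAD", "ADD"), measures)
  if (length(outl) && length(angl)) {
    for (st in stats) {
      num <- rowMeans(tab[paste0(st, "_", outl, ".norm")], na.rm = TRUE)
      den <- rowMeans(tab[paste0(st, "_", angl, ".norm")], na.rm = TRUE)
      tab[[paste0(st, "_outl_ang")]] <- safe_ratio(num, den)
    }
  }
  tab
}

#' Phenotypic distance table over all species pairs
#'
#' Applies \code{\link{phenotypic_distance}} to every species pair in a
#' cross-species tooth distance tensor, averaging the per-measure values
#' after min-max normalization per measure over pairs.
#'
#' @param tensor Cross-species \code{"distance_tensor"}.
#' @return Data.frame: species_a, species_b, one column per measure
#'   (\code{DP_<measure>}) and an aggregated column \code{DP}.
#' @export
phenotypic_distance_table <- function(tensor) {
  species <- unique(tensor$teeth$species)
  prs <- utils::combn(species, 2L)
  out <- data.frame(species_a = prs[1L, ], species_b = prs[2L, ])
  for (m in names(tensor$d)) {
    out[[paste0("DP_", m)]] <- apply(prs, 2L, function(pr) {
      phenotypic_distance(
        tensor_slice(tensor, m, pr[1L], "upper", pr[2L], "upper"),
        tensor_slice(tensor, m, pr[1L], "lower", pr[2L], "lower"))
    })
  }
  normed <- vapply(names(tensor$d), function(m)
    minmax_norm(out[[paste0("DP_", m)]]), numeric(nrow(out)))
  out$DP <- rowMeans(as.matrix(normed))
  out
}
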