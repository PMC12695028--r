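#' Kimura two-parameter distance matrix
#'
#' For each sequence pair, transitions (P) and transversions (Q) are counted
#' over pairwise-complete sites (positions with a gap or ambiguity in either
#' sequence are excluded for that pair) and the K2P distance
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) is returned.
#'
#' @param aln Named character vector of equal-length aligned sequences over
#'   A, C, G, T, -, N (case-insensitive), or a character matrix (rows =
#'   species).
#' @param saturation \code{"error"} (default) to fail when the log argument
#'   is non-positive (saturated pair), or \code{"na"} to flag the entry as
#'   \code{NA}.
#' @return Symmetric matrix of K2P distances with zero diagonal.
#' @export
k2p_matrix <- function(aln, saturation = c("error", "na")) {
  saturation <- match.arg(saturation)
  M <- alignment_matrix(aln)
  n <- nrow(M)
  if (n < 2L) stop("alignment needs at least 2 sequences")
  purine <- M == "A" | M == "G"
  valid <- M == "A" | M == "C" | M == "G" | M == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      L <- sum(ok)
      if (L < 1L) stop(sprintf("sequences %d and %d share no ungapped site", i, j))
      diffs <- ok & (M[i, ] != M[j, ])
      ts <- sum(diffs & (purine[i, ] == purine[j, ]))
      tv <- sum(diffs) - ts
      P <- ts / L; Q <- tv / L
      arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0) {
        if (saturation == "error")
          stop(sprintf("K2P distance undefined (saturation) for pair %s, %s",
                       rownames(M)[i], rownames(M)[j]))
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(arg1 * sqrt(arg2))
      }
    }
  }
  d
}

#' K2P distance from transition and transversion proportions
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return K2P distance.
#' @export
k2p_from_pq <- function(P, Q) {
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (any(arg <= 0)) stop("K2P distance undefined (saturation)")
  -0.5 * log(arg)
}

alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    M <- toupper(aln)
  } else {
    if (length(unique(nchar(aln))) != 1L)
      stop("alignment sequences have unequal lengths")
    M <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
    rownames(M) <- names(aln)
  }
  M
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}). Negative branch
#' lengths, an occasional artifact of NJ on noisy distances, are clamped to
#' zero with the deficit transferred to the sister branch so that path
#' lengths through the affected node are preserved.
#'
#' @param d Symmetric distance matrix (zero diagonal, n >= 3) or
#'   \code{dist}.
#' @return An unrooted \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    node <- tr$edge[e, 2L]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1L] == tr$edge[e, 1L] & seq_along(tr$edge[, 1L]) != e)
    if (length(sib)) tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
  }
  tr
}

#' Patristic distances of a tree
#'
#' Sums of branch lengths along the tree path between every pair of leaves.
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @return Symmetric matrix of patristic distances.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}

#' Normalized genetic distance table (dG)
#'
#' Patristic distances between all species pairs, min-max normalized over
#' the dataset so the closest pair scores 0 and the most distant pair 1.
#'
#' @param tree A \code{phylo} tree with branch lengths (e.g. from
#'   \code{\link{nj_tree}}, or externally supplied Newick).
#' @return Data.frame: species_a, species_b, patristic, dG.
#' @export
dg_table <- function(tree) {
  pm <- patristic_matrix(tree)
  sp <- rownames(pm)
  if (length(sp) < 2L) stop("dG needs at least 2 leaves")
  prs <- utils::combn(sp, 2L)
  pat <- pm[t(prs)]
  rng <- range(pat)
  if (diff(rng) == 0)
    stop("all species pairs equidistant; dG normalization undefined")
  data.frame(species_a = prs[1L, ], species_b = prs[2L, ],
             patristic = pat, dG = (pat - rng[1L]) / diff(rng))
}
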