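#' Build the species-pair scan table
#'
#' Joins per-species trait values with pairwise genetic distances into one
#' row per unordered species pair, carrying the absolute per-trait
#' difference, the pair's dG, and (optionally) its taxonomic relation. Rows
#' are sorted by ascending dG; ties break by lexicographic pair name so the
#' order is deterministic.
#'
#' @param measures Data.frame with a \code{species} column and numeric
#'   trait columns (e.g. a heterodonty or complexity species table).
#' @param dg Data.frame from \code{\link{dg_table}} (species_a, species_b,
#'   dG).
#' @param taxonomy Optional data.frame with columns \code{species},
#'   \code{family}, \code{order}, \code{superorder}.
#' @param traits Trait columns to difference (default: all numeric columns
#'   of \code{measures}).
#' @return Data.frame of class \code{"pair_scan_table"}: species_a,
#'   species_b, dG, one \code{diff_<trait>} column per trait, and
#'   \code{relation} when taxonomy is given.
#' @export
build_pair_table <- function(measures, dg, taxonomy = NULL, traits = NULL) {
  if (is.null(measures$species)) stop("measures must have a species column")
  sp_m <- measures$species
  sp_d <- union(dg$species_a, dg$species_b)
  if (!setequal(sp_m, sp_d)) {
    off <- c(setdiff(sp_m, sp_d), setdiff(sp_d, sp_m))
    stop("species sets differ between measures and dG table: ",
         paste(off, collapse = ", "))
  }
  if (is.null(traits))
    traits <- names(measures)[vapply(measures, is.numeric, TRUE)]
  tab <- dg[, c("species_a", "species_b", "dG")]
  ia <- match(tab$species_a, measures$species)
  ib <- match(tab$species_b, measures$species)
  for (tr in traits)
    tab[[paste0("diff_", tr)]] <- abs(measures[[tr]][ia] - measures[[tr]][ib])
  if (!is.null(taxonomy)) {
    need <- c("species", "family", "order", "superorder")
    if (!all(need %in% names(taxonomy)))
      stop("taxonomy needs columns: ", paste(need, collapse = ", "))
    missing <- setdiff(sp_m, taxonomy$species)
    if (length(missing))
      stop("species without taxonomy labels: ", paste(missing, collapse = ", "))
    ta <- taxonomy[match(tab$species_a, taxonomy$species), ]
    tb <- taxonomy[match(tab$species_b, taxonomy$species), ]
    tab$relation <- ifelse(ta$family == tb$family, "same_family",
                    ifelse(ta$order == tb$order, "same_order",
                    ifelse(ta$superorder == tb$superorder, "same_superorder",
                           "different_superorders")))
  }
  key <- paste(pmin(tab$species_a, tab$species_b),
               pmax(tab$species_a, tab$species_b))
  tab <- tab[order(tab$dG, key), ]
  rownames(tab) <- NULL
  class(tab) <- c("pair_scan_table", "data.frame")
  tab
}

#' Sliding-window divergence-versus-relatedness scan
#'
#' Species pairs (sorted by dG) are scanned with two windows of
#' \code{window} pairs, the upper window starting \code{offset} ranks after
#' the lower one ends. For each start rank n the one-sided two-sample
#' Wilcoxon rank-sum (Mann-Whitney) test asks whether trait differences in
#' the genetically more distant window are stochastically greater (normal
#' approximation with tie correction).
#'
#' @param table A \code{\link{build_pair_table}} result (or any data.frame
#'   sorted ascending by \code{dG}).
#' @param trait Name of a \code{diff_*} column (or any numeric column).
#' @param window Pairs per window (default 100).
#' @param offset Rank gap between the windows (default 0; the study also
#'   uses 200).
#' @return Data.frame of class \code{"scan_result"}: n, dG_anchor (dG of
#'   the highest-ranked pair in the lower window), dG_start, trait, p.
#' @export
sliding_scan <- function(table, trait, window = 100L, offset = 0L) {
  if (!trait %in% names(table)) stop("no such trait column: ", trait)
  v <- table[[trait]]
  N <- length(v)
  if (N < 2L * window + offset)
    stop(sprintf("need at least 2*window + offset = %d pairs, have %d",
                 2L * window + offset, N))
  starts <- seq_len(N - 2L * window - offset + 1L)
  p <- vapply(starts, function(n) {
    lower <- v[n:(n + window - 1L)]
    upper <- v[(n + window + offset):(n + 2L * window + offset - 1L)]
    stats::wilcox.test(upper, lower, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  }, 0.0)
  res <- data.frame(n = starts,
                    dG_anchor = table$dG[starts + window - 1L],
                    dG_start = table$dG[starts],
                    trait = trait, p = p)
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Taxonomic composition of the sliding windows
#'
#' For each window start over the dG-ordered pair table, the fraction of
#' pairs at each taxonomic relation level (same family, same order, same
#' superorder, different superorders). Fractions sum to 1 per window.
#'
#' @param table A \code{\link{build_pair_table}} result with a
#'   \code{relation} column.
#' @param window Pairs per window.
#' @return Data.frame: n, dG_anchor, and one fraction column per relation
#'   level.
#' @export
composition_annotation <- function(table, window = 100L) {
  if (is.null(table$relation))
    stop("pair table has no relation column; supply taxonomy to build_pair_table")
  levels_ <- c("same_family", "same_order", "same_superorder",
               "different_superorders")
  N <- nrow(table)
  if (N < window) stop("fewer pairs than the window size")
  starts <- seq_len(N - window + 1L)
  fr <- t(vapply(starts, function(n) {
    rel <- table$relation[n:(n + window - 1L)]
    vapply(levels_, function(lv) mean(rel == lv), 0.0)
  }, numeric(length(levels_))))
  out <- data.frame(n = starts, dG_anchor = table$dG[starts + window - 1L])
  out[levels_] <- fr
  out
}
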