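#' Parametric tooth template
#'
#' Parameter set for the synthetic crown generator. A crown is modeled as a
#' baseline segment of unit width carrying raised-cosine cusp bumps: the
#' major cusps are tall bumps spread across the crown, minor cusplets are
#' small bumps superimposed on the flanks (serration-like when their
#' prominence falls below the 2% col threshold used by the cusp counter).
#'
#' @param n_major_cusps Number of major cusps (>= 1).
#' @param n_minor_cusps Number of minor cusplets (>= 0).
#' @param cusp_height Major cusp height as a fraction of crown width, in
#'   (0, 1].
#' @param minor_cusp_height Cusplet height as a fraction of crown width, in
#'   [0, 1).
#' @param asymmetry Apex shift along the baseline in [-1, 1] (0 =
#'   symmetric).
#' @param elongation Overall height/width scaling (> 0).
#' @param smoothness Non-negative corner-rounding bandwidth (Gaussian
#'   smoothing of the height profile, as a fraction of crown width).
#' @return List of class \code{"tooth_params"}.
#' @export
tooth_params <- function(n_major_cusps = 1L, n_minor_cusps = 0L,
                         cusp_height = 0.5, minor_cusp_height = 0.05,
                         asymmetry = 0, elongation = 1, smoothness = 0.01) {
  p <- list(n_major_cusps = as.integer(n_major_cusps),
            n_minor_cusps = as.integer(n_minor_cusps),
            cusp_height = cusp_height, minor_cusp_height = minor_cusp_height,
            asymmetry = asymmetry, elongation = elongation,
            smoothness = smoothness)
  validate_tooth_params(p)
  structure(p, class = "tooth_params")
}

validate_tooth_params <- function(p) {
  if (p$n_major_cusps < 1L) stop("n_major_cusps must be >= 1")
  if (p$n_minor_cusps < 0L) stop("n_minor_cusps must be >= 0")
  if (!(p$cusp_height > 0 && p$cusp_height <= 1))
    stop("cusp_height must be in (0, 1]")
  if (!(p$minor_cusp_height >= 0 && p$minor_cusp_height < 1))
    stop("minor_cusp_height must be in [0, 1)")
  if (abs(p$asymmetry) > 1) stop("asymmetry must be in [-1, 1]")
  if (p$elongation <= 0) stop("elongation must be positive")
  if (p$smoothness < 0) stop("smoothness must be non-negative")
  invisible(p)
}

#' Generate a synthetic crown outline
#'
#' Deterministically builds an open crown outline of exactly \code{n_points}
#' points from a \code{\link{tooth_params}} template. The crown is a height
#' profile y(x) over the unit baseline x in [0, 1]: raised-cosine bumps at
#' evenly spread centers (shifted by \code{asymmetry}) for the major cusps,
#' smaller bumps interleaved on the flanks for the cusplets, optional
#' Gaussian rounding, and a final arc-length resampling.
#'
#' @param params A \code{\link{tooth_params}} object.
#' @param n_points Output point count (>= 32).
#' @return An outline from (0, 0) to (1, 0) with the apex in between.
#' @export
make_tooth <- function(params, n_points = 1000L) {
  validate_tooth_params(params)
  if (n_points < 32L) stop("n_points must be >= 32")
  dense <- max(4L * n_points, 2048L)
  x <- seq(0, 1, length.out = dense)
  k <- params$n_major_cusps
  centers <- (seq_len(k) - 0.5) / k
  centers <- centers + params$asymmetry * 0.3 * (1 - abs(2 * centers - 1))
  width <- 0.5 / k
  y <- rep(0, dense)
  for (c0 in centers) y <- y + raised_cosine(x, c0, width, params$cusp_height)
  # corner rounding applies to the major-cusp profile only; cusplets are
  # superimposed afterwards so that fine serration-like structure survives
  if (params$smoothness > 0) {
    bw <- params$smoothness
    kern_halfw <- max(1L, as.integer(ceiling(3 * bw * dense)))
    u <- (-kern_halfw):kern_halfw
    kern <- exp(-0.5 * (u / (bw * dense))^2)
    kern <- kern / sum(kern)
    ypad <- c(rep(0, kern_halfw), y, rep(0, kern_halfw))
    y <- as.numeric(stats::filter(ypad, kern, sides = 2))[kern_halfw + seq_len(dense)]
  }
  if (params$n_minor_cusps > 0L) {
    mcent <- (seq_len(params$n_minor_cusps) - 0.5) / params$n_minor_cusps
    mwidth <- min(0.5 / (3 * params$n_minor_cusps), 0.008)
    for (c0 in mcent)
      y <- y + raised_cosine(x, c0, mwidth, params$minor_cusp_height)
  }
  y <- y * params$elongation
  y[1L] <- 0; y[dense] <- 0
  resample_outline(as_outline(cbind(x, y)), n_points)
}

raised_cosine <- function(x, center, width, height) {
  z <- rep(0, length(x))
  in_w <- abs(x - center) <= width
  z[in_w] <- height / 2 * (1 + cos(pi * (x[in_w] - center) / width))
  z
}

#' Parameters of a synthetic dentition
#'
#' A dentition is generated from a base tooth template, a monognathic
#' gradient (per-parameter deltas applied in proportion to the tooth's
#' relative position along the row, emulating gradual within-jaw shape
#' change), a dignathic offset (deltas applied to every lower-jaw tooth),
#' and seeded parameter noise. Zero gradient, offset and noise give perfect
#' homodonty.
#'
#' @param n_teeth_upper,n_teeth_lower Teeth per jaw (>= 1).
#' @param base A \code{\link{tooth_params}} template.
#' @param monognathic_gradient Named list of numeric deltas added as
#'   \code{delta * position_fraction} (position fraction 0 at the mesial
#'   end, 1 at the distal end).
#' @param dignathic_offset Named list of deltas added to lower-jaw teeth.
#' @param noise_sd Standard deviation of Gaussian noise on the numeric
#'   shape parameters (applied per tooth).
#' @param seed Integer seed for the noise.
#' @return List of class \code{"dentition_params"}.
#' @export
dentition_params <- function(n_teeth_upper = 12L, n_teeth_lower = 12L,
                             base = tooth_params(),
                             monognathic_gradient = list(),
                             dignathic_offset = list(),
                             noise_sd = 0, seed = 1L) {
  if (n_teeth_upper < 1L || n_teeth_lower < 1L)
    stop("each jaw needs at least one tooth")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_teeth_upper = as.integer(n_teeth_upper),
                 n_teeth_lower = as.integer(n_teeth_lower),
                 base = base, monognathic_gradient = monognathic_gradient,
                 dignathic_offset = dignathic_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dentition_params")
}

numeric_tooth_fields <- function() {
  c("cusp_height", "minor_cusp_height", "asymmetry", "elongation", "smoothness")
}

# Apply additive deltas to a tooth_params object, clamping into the valid
# parameter ranges so perturbed teeth stay physical.
perturb_params <- function(base, deltas) {
  p <- unclass(base)
  for (f in names(deltas)) {
    if (!f %in% names(p)) stop("unknown tooth parameter: ", f)
    p[[f]] <- p[[f]] + deltas[[f]]
  }
  p$n_major_cusps <- max(1L, as.integer(round(p$n_major_cusps)))
  p$n_minor_cusps <- max(0L, as.integer(round(p$n_minor_cusps)))
  p$cusp_height <- min(1, max(1e-3, p$cusp_height))
  p$minor_cusp_height <- min(1 - 1e-9, max(0, p$minor_cusp_height))
  p$asymmetry <- min(1, max(-1, p$asymmetry))
  p$elongation <- max(1e-3, p$elongation)
  p$smoothness <- max(0, p$smoothness)
  class(p) <- "tooth_params"
  p
}

#' Generate a synthetic dentition
#'
#' @param params A \code{\link{dentition_params}} object.
#' @param species Species identifier.
#' @param n_points Points per tooth outline.
#' @return A \code{\link{dentition}} with positions 1..n per jaw.
#' @export
make_dentition <- function(params, species = "synthetic", n_points = 200L) {
  stopifnot(inherits(params, "dentition_params"))
  local_seed(params$seed, {
    rows <- list()
    for (jaw in c("upper", "lower")) {
      n <- if (jaw == "upper") params$n_teeth_upper else params$n_teeth_lower
      teeth <- vector("list", n)
      for (i in seq_len(n)) {
        frac <- if (n == 1L) 0 else (i - 1L) / (n - 1L)
        deltas <- lapply(params$monognathic_gradient, function(g) g * frac)
        if (jaw == "lower" && length(params$dignathic_offset)) {
          for (f in names(params$dignathic_offset)) {
            deltas[[f]] <- (if (is.null(deltas[[f]])) 0 else deltas[[f]]) +
              params$dignathic_offset[[f]]
          }
        }
        if (params$noise_sd > 0) {
          for (f in numeric_tooth_fields()) {
            deltas[[f]] <- (if (is.null(deltas[[f]])) 0 else deltas[[f]]) +
              stats::rnorm(1L, 0, params$noise_sd)
          }
        }
        teeth[[i]] <- make_tooth(perturb_params(params$base, deltas), n_points)
      }
      rows[[jaw]] <- teeth
    }
    dentition(species, upper = rows$upper, lower = rows$lower)
  })
}

#' Simulate sequence evolution under the Kimura two-parameter model
#'
#' Evolves nucleotide sequences down a tree with branch lengths in expected
#' substitutions per site, using the closed-form K2P substitution
#' probabilities. \code{kappa} is the instantaneous expected
#' transition/transversion count ratio (the empirical ts/tv ratio between
#' closely related sequences converges to it).
#'
#' @param tree An \code{ape} \code{phylo} tree with branch lengths.
#' @param seq_length Number of sites (>= 1).
#' @param kappa Expected transition/transversion ratio (> 0).
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences, one per leaf.
#' @export
simulate_k2p_sequences <- function(tree, seq_length, kappa = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (seq_length < 1L) stop("seq_length must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  local_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample(bases, seq_length, replace = TRUE)
    # parent-before-child edge ordering
    ord <- reorder(tree, "cladewise")$edge
    el <- tree$edge.length[match(paste(ord[, 1L], ord[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
    for (e in seq_len(nrow(ord))) {
      parent <- ord[e, 1L]; child <- ord[e, 2L]
      d <- el[e]
      # a = transition branch fraction, b = per-type transversion fraction
      b <- d / (2 * (kappa + 1))
      a <- 2 * kappa * b
      p_ts <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
      p_tv <- 0.25 - 0.25 * exp(-4 * b)   # each of the two transversions
      s <- seqs[[parent]]
      u <- stats::runif(seq_length)
      out <- s
      is_ts <- u < p_ts
      is_tv1 <- !is_ts & u < p_ts + p_tv
      is_tv2 <- !is_ts & !is_tv1 & u < p_ts + 2 * p_tv
      out[is_ts] <- transition[s[is_ts]]
      tv1 <- c(A = "C", G = "C", C = "A", T = "A")
      tv2 <- c(A = "T", G = "T", C = "G", T = "G")
      out[is_tv1] <- tv1[s[is_tv1]]
      out[is_tv2] <- tv2[s[is_tv2]]
      seqs[[child]] <- out
    }
    res <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
    names(res) <- tree$tip.label
    res
  })
}

#' Write aligned sequences as FASTA
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase aligned sequences.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  id <- cumsum(hdr)
  nm <- sub("^>", "", trimws(lines[hdr]))
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  names(seqs) <- nm
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment sequences have unequal lengths")
  seqs
}

#' Synthetic trait differences for species pairs
#'
#' Attaches a per-pair trait difference column to a pair table with known
#' ground truth: \code{"independent"} draws differences i.i.d. (half-normal),
#' \code{"increasing"} makes the expected difference strictly increasing in
#' the pair's genetic distance dG.
#'
#' @param pairs_dg Data.frame with a \code{dG} column (one row per species
#'   pair).
#' @param relation \code{"independent"} or \code{"increasing"}.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return The input data.frame with an added \code{trait_diff} column.
#' @export
make_trait_table <- function(pairs_dg, relation = c("independent", "increasing"),
                             noise_sd = 0.1, seed = 1L) {
  relation <- match.arg(relation)
  if (is.null(pairs_dg$dG)) stop("pairs_dg must contain a dG column")
  n <- nrow(pairs_dg)
  local_seed(seed, {
    diff <- if (relation == "independent") {
      abs(stats::rnorm(n, 0, max(noise_sd, 1e-12)))
    } else {
      pairs_dg$dG + stats::rnorm(n, 0, noise_sd)
    }
    pairs_dg$trait_diff <- diff
    pairs_dg
  })
}
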