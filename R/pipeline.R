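#' Read a flat key = value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Values
#' are parsed as numbers where possible, \code{true}/\code{false} as
#' logical, comma-separated lists as vectors.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
      else parts
  }
  out
}

#' Default pipeline configuration
#'
#' Defaults follow the standard analysis parameters: 1000 outline points,
#' 100 angle-function points, 24 harmonics, OIR cap 25, scan window 100
#' with offsets 0 and 200, and superimposition bounds of pi/8 rotation,
#' 10% shift and 25% scale.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(n_points = 1000, angle_points = 100, harmonics = 24, oir_cap = 25,
       window = 100, offsets = c(0, 200),
       align.rot_steps = 17, align.shift_steps = 9, align.scale_steps = 11,
       align.refine = TRUE, seed = 1)
}

#' Run the full morphometric pipeline
#'
#' Orchestrates outlines to distances to heterodonty and complexity tables,
#' optionally genetic distances and the divergence scan, writing TSV output
#' tables plus a JSON run manifest. Reruns with identical inputs and config
#' produce identical tables.
#'
#' @param dentitions List of \code{\link{dentition}} objects, or a directory
#'   containing dentition CSV files (one per species).
#' @param out_dir Output directory (created if absent).
#' @param tree Optional \code{phylo} tree (or path to a Newick file) as the
#'   genetic distance source; alternatively \code{alignment} (named
#'   character vector or FASTA path) from which a K2P + NJ tree is built.
#' @param alignment See \code{tree}.
#' @param taxonomy Optional taxonomy data.frame (see
#'   \code{\link{build_pair_table}}).
#' @param config Named list overriding \code{\link{default_config}} entries.
#' @return Invisibly, a list with the computed tables and the manifest.
#' @export
run_pipeline <- function(dentitions, out_dir, tree = NULL, alignment = NULL,
                         taxonomy = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(dentitions)) {
    files <- sort(list.files(dentitions, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) stop("no dentition CSV files in ", dentitions)
    dentitions <- lapply(files, read_dentition, dialect = "csv")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  search <- align_grid_spec(rot_steps = cfg$align.rot_steps,
                            shift_steps = cfg$align.shift_steps,
                            scale_steps = cfg$align.scale_steps,
                            refine = cfg$align.refine)
  teeth <- stage("read", tooth_table(dentitions))
  tensor <- stage("distances",
    pairwise_distances(teeth, search = search, n_points = cfg$n_points,
                       harmonics = cfg$harmonics,
                       angle_points = cfg$angle_points))
  het <- stage("heterodonty", heterodonty_table(heterodonty_records(tensor)))
  cx <- stage("complexity",
    species_complexity(dentitions, n_points = cfg$n_points,
                       harmonics = cfg$harmonics))
  dp <- stage("phenotypic_distance", phenotypic_distance_table(tensor))
  write_distance_tensor(tensor, file.path(out_dir, "distance_tensor.tsv"))
  write_tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  write_tsv(het, "heterodonty.tsv")
  write_tsv(cx, "complexity.tsv")
  write_tsv(dp, "phenotypic_distance.tsv")
  out <- list(tensor = tensor, heterodonty = het, complexity = cx,
              phenotypic_distance = dp)
  if (is.null(tree) && !is.null(alignment)) {
    if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
      alignment <- read_alignment(alignment)
    tree <- stage("phylo", nj_tree(k2p_matrix(alignment)))
  } else if (is.character(tree)) {
    tree <- ape::read.tree(tree)
  }
  if (!is.null(tree)) {
    dg <- stage("dg", dg_table(tree))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_tsv(dg, "dg.tsv")
    pairs <- stage("pair_table",
      build_pair_table(merge(het[, c("species", heterodonty_stat_names())],
                             cx[, c("species", "Cx_combined", "Cx_four")],
                             by = "species"),
                       dg, taxonomy = taxonomy))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pairs$diff_DP <- dp$DP[match(key(pairs$species_a, pairs$species_b),
                                 key(dp$species_a, dp$species_b))]
    out$pairs <- pairs
    write_tsv(pairs, "pairs.tsv")
    scans <- list()
    traits <- grep("^diff_", names(pairs), value = TRUE)
    for (off in cfg$offsets) {
      if (nrow(pairs) >= 2 * cfg$window + off) {
        for (tr in traits) {
          scans[[length(scans) + 1L]] <-
            cbind(offset = off,
                  stage("scan", sliding_scan(pairs, tr, cfg$window, off)))
        }
      }
    }
    if (length(scans)) {
      out$scan <- do.call(rbind, scans)
      write_tsv(out$scan, "scan.tsv")
    }
    if (!is.null(taxonomy) && nrow(pairs) >= cfg$window) {
      out$composition <- stage("composition",
                               composition_annotation(pairs, cfg$window))
      write_tsv(out$composition, "composition.tsv")
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("heterodont")),
    n_species = length(unique(teeth$species)),
    n_teeth = nrow(teeth),
    n_pairs_computed = nrow(teeth) * (nrow(teeth) - 1L) / 2L,
    config = cfg,
    config_hash = config_hash(cfg),
    tables = list.files(out_dir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
             sep = "=", collapse = ";")
  # small deterministic FNV-1a style hash over the serialized config
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- bitwAnd(bitwXor(h, b) * 16777619, 0xFFFFFFF)
  sprintf("%07x", h)
}

#' Correlations between dental measures and ecological traits
#'
#' Pairwise correlation of every numeric dental measure column with every
#' numeric trait column across the shared species, with standard two-sided
#' p-values and no multiple-testing correction.
#'
#' @param measures Data.frame with \code{species} and numeric measure
#'   columns.
#' @param traits Data.frame with \code{species} and numeric trait columns
#'   (or path to a TSV).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Data.frame: measure, trait, r, p (NA for constant columns).
#' @export
correlation_summary <- function(measures, traits, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.character(traits)) traits <- utils::read.delim(traits)
  shared <- intersect(measures$species, traits$species)
  if (length(shared) < 3L) stop("need at least 3 shared species")
  m <- measures[match(shared, measures$species), ]
  t <- traits[match(shared, traits$species), ]
  mc <- names(m)[vapply(m, is.numeric, TRUE)]
  tc <- names(t)[vapply(t, is.numeric, TRUE)]
  out <- expand.grid(measure = mc, trait = tc, stringsAsFactors = FALSE)
  res <- t(apply(out, 1L, function(row) {
    x <- m[[row[["measure"]]]]; y <- t[[row[["trait"]]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    c(unname(ct$estimate), ct$p.value)
  }))
  out$r <- res[, 1L]
  out$p <- res[, 2L]
  out
}
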