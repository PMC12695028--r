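#' Construct a dentition
#'
#' A dentition holds one jaw hemisphere of a species: two ordered tooth rows
#' (upper and lower), each tooth an outline indexed by its 1-based position
#' from the mesial/anterior end.
#'
#' @param species Species identifier.
#' @param upper,lower Lists of outlines, ordered mesial to distal. Either may
#'   be empty, but not both.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class \code{"dentition"}.
#' @export
dentition <- function(species, upper = list(), lower = list(), metadata = list()) {
  stopifnot(is.character(species), length(species) == 1L)
  upper <- lapply(upper, as_outline)
  lower <- lapply(lower, as_outline)
  if (length(upper) + length(lower) == 0L) stop("dentition has no teeth")
  structure(list(species = species,
                 rows = list(upper = upper, lower = lower),
                 metadata = metadata),
            class = "dentition")
}

#' @export
print.dentition <- function(x, ...) {
  cat(sprintf("<dentition: %s, %d upper + %d lower teeth>\n", x$species,
              length(x$rows$upper), length(x$rows$lower)))
  invisible(x)
}

#' Number of teeth in a dentition
#' @param dent A dentition.
#' @return Named integer vector (upper, lower).
#' @export
n_teeth <- function(dent) {
  vapply(dent$rows, length, integer(1))
}

#' Flatten dentitions into a tooth table
#'
#' @param dents A dentition or list of dentitions.
#' @return A data.frame with columns \code{species}, \code{jaw},
#'   \code{position} and a list-column \code{outline}.
#' @export
tooth_table <- function(dents) {
  if (inherits(dents, "dentition")) dents <- list(dents)
  rows <- list()
  for (d in dents) {
    for (jaw in c("upper", "lower")) {
      teeth <- d$rows[[jaw]]
      for (i in seq_along(teeth)) {
        rows[[length(rows) + 1L]] <- list(species = d$species, jaw = jaw,
                                          position = i, outline = teeth[[i]])
      }
    }
  }
  data.frame(species = vapply(rows, `[[`, "", "species"),
             jaw = vapply(rows, `[[`, "", "jaw"),
             position = vapply(rows, function(r) as.integer(r$position), 1L),
             outline = I(lapply(rows, `[[`, "outline")),
             stringsAsFactors = FALSE)
}

#' Write a dentition to disk
#'
#' CSV dialect: one file per dentition with mandatory header
#' \code{species,jaw,position,point_index,x,y}; x increases mesial to distal,
#' y basal to apical. TPS dialect: one specimen per tooth with
#' \code{ID=species_jaw_position}.
#'
#' @param dent A dentition.
#' @param path Output file path.
#' @param dialect \code{"csv"} or \code{"tps"}.
#' @return \code{path}, invisibly.
#' @export
write_dentition <- function(dent, path, dialect = c("csv", "tps")) {
  dialect <- match.arg(dialect)
  tt <- tooth_table(dent)
  if (dialect == "csv") {
    recs <- lapply(seq_len(nrow(tt)), function(i) {
      o <- tt$outline[[i]]
      data.frame(species = tt$species[i], jaw = tt$jaw[i],
                 position = tt$position[i], point_index = seq_len(nrow(o)),
                 x = o[, 1L], y = o[, 2L])
    })
    utils::write.csv(do.call(rbind, recs), path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(tt))) {
      o <- tt$outline[[i]]
      writeLines(sprintf("LM=%d", nrow(o)), con)
      writeLines(sprintf("%.10g %.10g", o[, 1L], o[, 2L]), con)
      writeLines(sprintf("ID=%s_%s_%d", tt$species[i], tt$jaw[i], tt$position[i]), con)
    }
  }
  invisible(path)
}

#' Read a dentition from disk
#'
#' @param path File written by \code{\link{write_dentition}} (or conforming
#'   to either dialect).
#' @param dialect \code{"csv"} or \code{"tps"}.
#' @param reverse If \code{TRUE}, outlines are stored distal-to-mesial and
#'   point order is reversed on read.
#' @return A \code{\link{dentition}}.
#' @export
read_dentition <- function(path, dialect = c("csv", "tps"), reverse = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("species", "jaw", "position", "point_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("CSV dentition file must have columns: ", paste(need, collapse = ", "))
    teeth <- split(df, list(df$jaw, df$position), drop = TRUE)
    recs <- lapply(teeth, function(g) {
      g <- g[order(g$point_index), ]
      if (anyDuplicated(g$point_index))
        stop(sprintf("duplicate (jaw, position): %s %d", g$jaw[1], g$position[1]))
      if (nrow(g) < 3L)
        stop(sprintf("tooth %s position %d has fewer than 3 points", g$jaw[1], g$position[1]))
      list(species = g$species[1], jaw = g$jaw[1], position = g$position[1],
           outline = as_outline(cbind(g$x, g$y)))
    })
  } else {
    lines <- readLines(path)
    recs <- list(); i <- 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (!grepl("^LM=", ln)) stop("malformed TPS: expected LM= at line ", i)
      k <- as.integer(sub("^LM=", "", ln))
      pts <- do.call(rbind, lapply(lines[(i + 1L):(i + k)], function(s) {
        as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
      }))
      idl <- trimws(lines[i + k + 1L])
      if (!grepl("^ID=", idl)) stop("malformed TPS: expected ID= after landmarks")
      id <- sub("^ID=", "", idl)
      parts <- strsplit(id, "_")[[1]]
      np <- length(parts)
      if (np < 3L) stop("TPS ID must be species_jaw_position: ", id)
      recs[[length(recs) + 1L]] <- list(
        species = paste(parts[1:(np - 2L)], collapse = "_"),
        jaw = parts[np - 1L], position = as.integer(parts[np]),
        outline = as_outline(pts))
      i <- i + k + 2L
    }
  }
  sp <- unique(vapply(recs, `[[`, "", "species"))
  if (length(sp) != 1L) stop("file mixes species: ", paste(sp, collapse = ", "))
  rows <- list(upper = list(), lower = list())
  for (jaw in c("upper", "lower")) {
    jr <- Filter(function(r) r$jaw == jaw, recs)
    if (length(jr) == 0L) next
    pos <- vapply(jr, function(r) r$position, 1L)
    if (anyDuplicated(pos))
      stop(sprintf("duplicate (jaw, position): %s %d", jaw, pos[duplicated(pos)][1]))
    if (!setequal(pos, seq_len(max(pos)))) {
      missing <- setdiff(seq_len(max(pos)), pos)
      stop(sprintf("%s jaw positions are not consecutive; missing position(s) %s",
                   jaw, paste(missing, collapse = ", ")))
    }
    ord <- order(pos)
    rows[[jaw]] <- lapply(jr[ord], function(r) {
      o <- r$outline
      if (reverse) as_outline(o[rev(seq_len(nrow(o))), , drop = FALSE]) else o
    })
  }
  dentition(sp, upper = rows$upper, lower = rows$lower)
}
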