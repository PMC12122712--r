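#' Occurrence point set
#'
#' A thin data.frame subclass holding presence records
#' (`species`, `lon`, `lat`, `source`) plus a processing-stage tag
#' (`"raw"`, `"deduplicated"`, `"clipped"`, `"thinned"`).
#'
#' @param species character vector of species ids.
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @param source provenance tag per record.
#' @param stage processing stage of the set.
#' @return data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, source = "unknown",
                           stage = "raw") {
  stopifnot(is.numeric(lon), is.numeric(lat), all(is.finite(lon)),
            all(is.finite(lat)))
  out <- data.frame(species = as.character(species), lon = lon, lat = lat,
                    source = rep_len(as.character(source), length(lon)),
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- stage
  class(out) <- c("occurrence_set", "data.frame")
  out
}

occ_stage <- function(occ) attr(occ, "stage") %||% "raw"

set_stage <- function(occ, stage) {
  attr(occ, "stage") <- stage
  occ
}

#' Read occurrence records from CSV
#'
#' Expects columns `species`, `lon`, `lat` (a `source` column is optional).
#' Rows with non-numeric or non-finite coordinates are dropped with a
#' warning that reports how many were rejected.
#'
#' @param path CSV file path.
#' @return an [occurrence_set()] at stage `"raw"`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "lon", "lat")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("occurrence file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  ok <- is.finite(lon) & is.finite(lat) & nzchar(df$species)
  if (any(!ok)) {
    warning(sprintf("%d malformed occurrence row(s) skipped in %s",
                    sum(!ok), basename(path)), call. = FALSE)
  }
  src <- if ("source" %in% names(df)) df$source else "csv"
  occurrence_set(df$species[ok], lon[ok], lat[ok],
                 source = if (length(src) > 1) src[ok] else src,
                 stage = "raw")
}

#' Write occurrence records to CSV
#'
#' @param occ an [occurrence_set()].
#' @param path output CSV path (header `species,lon,lat,source`).
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("species", "lon", "lat", "source")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove exact duplicate records
#'
#' Duplicates are exact matches on `(species, lon, lat)`; the first
#' occurrence is kept, preserving input order.
#'
#' @param occ an [occurrence_set()].
#' @return the deduplicated set (stage `"deduplicated"`).
#' @export
deduplicate <- function(occ) {
  keep <- !duplicated(occ[, c("species", "lon", "lat")])
  set_stage(occ[keep, , drop = FALSE], "deduplicated")
}

#' Clip records to a study extent
#'
#' Retains records inside the grid extent under the half-open convention:
#' a point exactly on the maximum longitude or latitude edge is excluded,
#' matching the cell-coverage rule of [make_grid()].
#'
#' @param occ an [occurrence_set()].
#' @param grid a [make_grid()] object defining the extent.
#' @return the clipped set (stage `"clipped"`).
#' @export
clip_to_extent <- function(occ, grid) {
  keep <- occ$lon >= grid$lon_min & occ$lon < grid$lon_max &
          occ$lat >= grid$lat_min & occ$lat < grid$lat_max
  set_stage(occ[keep, , drop = FALSE], "clipped")
}

#' Spatially thin records: one per species per grid cell
#'
#' For each species and each occupied thinning cell, exactly one record is
#' retained, chosen uniformly at random under the given seed. The thinning
#' grid is anchored at the study-extent lower-left corner:
#' `cell = (floor((lon - lon_min)/size), floor((lat - lat_min)/size))`.
#' This reduces the spatial clustering that uneven record density induces.
#'
#' @param occ an [occurrence_set()] (typically clipped first).
#' @param grid a [make_grid()] supplying the extent origin.
#' @param thin_cell_size thinning cell edge in degrees (default 0.25).
#' @param seed integer seed for the per-cell random choice.
#' @return the thinned set (stage `"thinned"`), in input order.
#' @export
thin_per_cell <- function(occ, grid, thin_cell_size = 0.25, seed = 1) {
  stopifnot(thin_cell_size > 0)
  if (nrow(occ) == 0) return(set_stage(occ, "thinned"))
  ci <- floor((occ$lon - grid$lon_min) / thin_cell_size)
  cj <- floor((occ$lat - grid$lat_min) / thin_cell_size)
  key <- paste(occ$species, ci, cj, sep = "|")
  keep <- with_seed(seed, {
    idx <- split(seq_len(nrow(occ)), key)
    # deterministic order over cells, then one uniform draw per cell
    idx <- idx[order(names(idx))]
    vapply(idx, function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)],
           integer(1))
  })
  set_stage(occ[sort(keep), , drop = FALSE], "thinned")
}

#' Thinning report: record counts before and after, per species
#'
#' @param before,after [occurrence_set()]s from the same pipeline stage pair.
#' @return data.frame with columns `species`, `n_before`, `n_after`.
#' @export
thinning_report <- function(before, after) {
  sp <- sort(unique(c(before$species, after$species)))
  data.frame(
    species = sp,
    n_before = as.integer(table(factor(before$species, levels = sp))),
    n_after = as.integer(table(factor(after$species, levels = sp)))
  )
}

#' Sample background (pseudoabsence) points from a predictor stack
#'
#' Samples `n` cells uniformly over the stack's valid cells — without
#' replacement while `n` does not exceed the number of valid cells, with
#' replacement otherwise — and places each point at its cell center, where
#' predictor values are defined.
#'
#' @param stack a [climate_stack()].
#' @param n number of background points (default 10000).
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat` of class `background_set`.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  valid <- which(stack$mask)
  if (length(valid) == 0) {
    stop("stack has no valid cells to sample background from", call. = FALSE)
  }
  g <- stack$grid
  flat <- with_seed(seed, {
    if (n <= length(valid)) valid[sample.int(length(valid), n)]
    else valid[sample.int(length(valid), n, replace = TRUE)]
  })
  row <- ((flat - 1L) %% g$n_rows) + 1L
  col <- ((flat - 1L) %/% g$n_rows) + 1L
  ctr <- cell_center(g, row, col)
  out <- data.frame(lon = ctr$lon, lat = ctr$lat)
  class(out) <- c("background_set", "data.frame")
  out
}
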