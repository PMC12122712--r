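#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' from north to south. `NA` cells are written as the grid's nodata value.
#'
#' @param values numeric matrix (row 1 = southern edge, package convention).
#' @param grid the [make_grid()] it lives on.
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(values, grid, path) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$lon_min),
    sprintf("yllcorner %.10g", grid$lat_min),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata_value)), con)
  vals <- values
  vals[is.na(vals)] <- grid$nodata_value
  for (i in rev(seq_len(grid$n_rows))) {  # north to south
    writeLines(paste(formatC(vals[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return list with `grid` (a [make_grid()]) and `values` (matrix, nodata
#'   as `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  grid <- make_grid(hdr$xllcorner, hdr$yllcorner,
                    hdr$xllcorner + nc * hdr$cellsize,
                    hdr$yllcorner + nr * hdr$cellsize,
                    hdr$cellsize, nodata_value = hdr$nodata_value)
  vals <- matrix(NA_real_, nr, nc)
  for (k in seq_len(nr)) {
    vals[nr - k + 1L, ] <- as.numeric(strsplit(trimws(lines[6 + k]),
                                               "\\s+")[[1]])
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  list(grid = grid, values = vals)
}

#' Write / read a climate stack as a directory of ASCII grids
#'
#' Each layer goes to `<dir>/<layer>.asc`; the layer order is recorded in
#' `<dir>/layers.txt`.
#'
#' @param stack a [climate_stack()].
#' @param dir directory to create/populate.
#' @return the directory path (write) or a `climate_stack` (read).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in layer_names(stack)) {
    write_ascii_grid(stack$layers[[l]], stack$grid,
                     file.path(dir, paste0(l, ".asc")))
  }
  writeLines(layer_names(stack), file.path(dir, "layers.txt"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  nm <- readLines(file.path(dir, "layers.txt"))
  first <- read_ascii_grid(file.path(dir, paste0(nm[1], ".asc")))
  layers <- list()
  layers[[nm[1]]] <- first$values
  for (l in nm[-1]) {
    layers[[l]] <- read_ascii_grid(file.path(dir, paste0(l, ".asc")))$values
  }
  climate_stack(first$grid, layers)
}

# FNV-1a 32-bit hash over the byte serialization of an R object; used for
# manifest checksums and stage-seed derivation (no cryptographic intent).
fnv1a32 <- function(x) {
  bytes <- if (is.raw(x)) x else {
    if (is.character(x) && length(x) == 1) charToRaw(x)
    else serialize(x, NULL, version = 2)
  }
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # XOR with a byte only touches the low 8 bits; keep h a double since it
    # exceeds the 32-bit signed range bitwXor accepts
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so every intermediate stays exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  h
}
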