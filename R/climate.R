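#' Named stack of climate predictor layers on a common grid
#'
#' A `climate_stack` bundles one or more raster layers (matrices of
#' `n_rows x n_cols`, row 1 = southern edge) with the shared [make_grid()]
#' georeference and a logical validity mask. Masked-out cells are `NA` in
#' every layer; the nodata sentinel only appears on disk.
#'
#' @param grid a [make_grid()] object.
#' @param layers named list of numeric matrices, one per predictor
#'   (e.g. `bio1` ... `bio19`, or a derived `host_suitability` layer).
#' @param mask optional logical matrix of valid cells; defaults to cells that
#'   are non-`NA` in every layer.
#' @return an object of class `climate_stack` with fields `grid`, `layers`,
#'   `mask`.
#' @export
climate_stack <- function(grid, layers, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layers must be uniquely named", call. = FALSE)
  }
  for (l in nm) {
    m <- layers[[l]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols) {
      stop(sprintf("layer '%s' is not a %d x %d matrix",
                   l, grid$n_rows, grid$n_cols), call. = FALSE)
    }
  }
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  }
  stopifnot(is.logical(mask), nrow(mask) == grid$n_rows,
            ncol(mask) == grid$n_cols)
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d layer(s) on %d x %d grid, %d valid cells\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              sum(x$mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname climate_stack
#' @param stack a `climate_stack`.
#' @export
layer_names <- function(stack) names(stack$layers)

#' @rdname climate_stack
#' @export
n_valid_cells <- function(stack) sum(stack$mask)

#' Extract layer values at point locations
#'
#' Looks up the cell containing each point and returns the layer values
#' there. Points outside the extent or on masked cells yield `NA` rows.
#'
#' @param stack a [climate_stack()].
#' @param lon,lat point coordinates in decimal degrees.
#' @param layers character vector of layer names (default: all).
#' @return a data.frame with one column per requested layer.
#' @export
extract_values <- function(stack, lon, lat, layers = NULL) {
  if (is.null(layers)) layers <- layer_names(stack)
  missing <- setdiff(layers, layer_names(stack))
  if (length(missing)) {
    stop("layers not in stack: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- cell_index(stack$grid, lon, lat)
  flat <- ifelse(is.na(idx$row), NA_integer_,
                 (idx$col - 1L) * stack$grid$n_rows + idx$row)
  out <- lapply(stack$layers[layers], function(m) m[flat])
  as.data.frame(out, optional = TRUE)
}

#' Add or replace a layer in a stack
#'
#' The new layer is masked to the stack's validity mask; the mask itself is
#' never changed.
#'
#' @param stack a [climate_stack()].
#' @param name layer name.
#' @param values numeric matrix on the stack's grid.
#' @return the updated `climate_stack`.
#' @export
set_layer <- function(stack, name, values) {
  stopifnot(is.matrix(values),
            nrow(values) == stack$grid$n_rows,
            ncol(values) == stack$grid$n_cols)
  values[!stack$mask] <- NA_real_
  stack$layers[[name]] <- values
  stack
}

#' Per-cell data.frame of a stack's valid cells
#'
#' Flattens the valid cells of a stack into a data.frame (one row per valid
#' cell) with the cell-center coordinates, for model fitting and prediction.
#'
#' @param stack a [climate_stack()].
#' @param layers layer names (default all).
#' @return data.frame with columns `row`, `col`, `lon`, `lat`, then layers.
#' @export
stack_table <- function(stack, layers = NULL) {
  if (is.null(layers)) layers <- layer_names(stack)
  keep <- which(stack$mask)
  g <- stack$grid
  row <- ((keep - 1L) %% g$n_rows) + 1L
  col <- ((keep - 1L) %/% g$n_rows) + 1L
  ctr <- cell_center(g, row, col)
  out <- data.frame(row = row, col = col, lon = ctr$lon, lat = ctr$lat)
  for (l in layers) out[[l]] <- stack$layers[[l]][keep]
  out
}
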