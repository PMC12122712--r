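#' @importFrom stats plogis rnorm runif sd cor quantile optimize rbinom
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that a
# seed argument implies bit-reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Simulate spatially autocorrelated climate layers
#'
#' Each layer is a Gaussian random field: white noise convolved (on a torus,
#' via FFT) with an isotropic Gaussian kernel whose standard deviation is
#' `smoothness` cells, then standardized to mean 0 / sd 1 over valid cells.
#' `smoothness = 0` gives pure white noise. Deterministic for a fixed seed.
#'
#' @param grid a [make_grid()] object.
#' @param layer_names character vector of layer names (at least one).
#' @param smoothness correlation length in cells (kernel sd), `>= 0`.
#' @param seed integer seed.
#' @param mask optional logical matrix of valid cells (default: all valid).
#' @return a [climate_stack()].
#' @export
simulate_climate <- function(grid, layer_names, smoothness = 3, seed = 1,
                             mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(layer_names) < 1) {
    stop("at least one layer name is required", call. = FALSE)
  }
  stopifnot(smoothness >= 0)
  nr <- grid$n_rows; nc <- grid$n_cols
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  kern_fft <- NULL
  if (smoothness > 0) {
    # torus distances; kernel normalized to sum 1
    dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
    dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
    kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * smoothness^2))
    kern <- kern / sum(kern)
    kern_fft <- stats::fft(kern)
  }
  layers <- with_seed(seed, {
    out <- list()
    for (l in layer_names) {
      z <- matrix(rnorm(nr * nc), nr, nc)
      if (!is.null(kern_fft)) {
        z <- Re(stats::fft(stats::fft(z) * kern_fft, inverse = TRUE)) /
          (nr * nc)
      }
      v <- z[mask]
      z <- (z - mean(v)) / sd(v)
      out[[l]] <- z
    }
    out
  })
  climate_stack(grid, layers, mask = mask)
}

#' Ground-truth logistic niche definition
#'
#' Defines a known niche as a logistic function of climate layers (linear and
#' optional quadratic terms) plus, for a parasite, a host-suitability term.
#' This is the generating truth that model-recovery tests compare against;
#' the host model itself must have `host_coefficient = 0`.
#'
#' @param intercept scalar intercept of the linear predictor.
#' @param coefficients named numeric vector of linear coefficients
#'   (names = layer names).
#' @param quadratic optional named numeric vector of quadratic coefficients.
#' @param host_coefficient coefficient on the host-suitability layer
#'   (0 for a host niche).
#' @return an object of class `niche_truth`.
#' @export
niche_truth <- function(intercept = 0, coefficients = numeric(),
                        quadratic = NULL, host_coefficient = 0) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("coefficients must be named by layer", call. = FALSE)
  }
  if (!is.null(quadratic) && length(quadratic) && is.null(names(quadratic))) {
    stop("quadratic coefficients must be named by layer", call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 quadratic = quadratic %||% numeric(),
                 host_coefficient = host_coefficient),
            class = "niche_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True suitability raster from a niche definition
#'
#' Evaluates `plogis(intercept + sum coef * layer [+ quad * layer^2]
#' [+ host_coefficient * host_layer])` cell-wise; `NA` (masked) cells
#' propagate.
#'
#' @param stack a [climate_stack()].
#' @param truth a [niche_truth()].
#' @param host_layer name of the host-suitability layer in `stack`
#'   (required when `host_coefficient != 0`).
#' @return numeric matrix of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(stack, truth, host_layer = NULL) {
  need <- union(names(truth$coefficients), names(truth$quadratic))
  missing <- setdiff(need, layer_names(stack))
  if (length(missing)) {
    stop("niche references layers absent from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- matrix(truth$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (l in names(truth$coefficients)) {
    lp <- lp + truth$coefficients[[l]] * stack$layers[[l]]
  }
  for (l in names(truth$quadratic)) {
    lp <- lp + truth$quadratic[[l]] * stack$layers[[l]]^2
  }
  if (truth$host_coefficient != 0) {
    if (is.null(host_layer) || !host_layer %in% layer_names(stack)) {
      stop("host_coefficient != 0 requires a host layer present in the stack",
           call. = FALSE)
    }
    lp <- lp + truth$host_coefficient * stack$layers[[host_layer]]
  }
  out <- plogis(lp)
  out[!stack$mask] <- NA_real_
  out
}

#' Sample presence-only occurrence points from a suitability surface
#'
#' Cells are drawn with probability proportional to `suitability * bias`
#' (with replacement), and each point is then placed uniformly at random
#' within its cell, exercising downstream point-to-cell assignment. This
#' emulates presence-only archive data whose density varies across regions.
#'
#' @param suitability numeric matrix on `grid` (values in `[0, 1]`).
#' @param grid the [make_grid()] the matrix lives on.
#' @param n_points number of points to draw (`>= 1`).
#' @param bias optional non-negative weight matrix (e.g. a collection-effort
#'   hotspot); default uniform.
#' @param seed integer seed.
#' @param species species id recorded on each point.
#' @return an [occurrence_set()] with `source = "synthetic"`.
#' @export
sample_occurrences <- function(suitability, grid, n_points, bias = NULL,
                               seed = 1, species = "species") {
  stopifnot(n_points >= 1)
  w <- suitability
  if (!is.null(bias)) w <- w * bias
  w[is.na(w)] <- 0
  if (all(w <= 0)) {
    stop("all sampling weights are zero: degenerate suitability/bias input",
         call. = FALSE)
  }
  nr <- grid$n_rows
  with_seed(seed, {
    flat <- sample.int(length(w), n_points, replace = TRUE, prob = as.vector(w))
    row <- ((flat - 1L) %% nr) + 1L
    col <- ((flat - 1L) %/% nr) + 1L
    lon <- grid$lon_min + (col - 1L + runif(n_points)) * grid$cell_size
    lat <- grid$lat_min + (row - 1L + runif(n_points)) * grid$cell_size
    occurrence_set(species = rep(species, n_points), lon = lon, lat = lat,
                   source = "synthetic", stage = "raw")
  })
}

#' Default collection-bias surface: one over-sampled hotspot
#'
#' Returns a weight raster equal to 1 everywhere and `factor` inside a
#' rectangular hotspot region (default: the south-west quarter of the grid),
#' emulating the uneven record density that motivates spatial thinning.
#'
#' @param grid a [make_grid()] object.
#' @param factor over-sampling multiplier for the hotspot (default 5).
#' @param rows,cols integer ranges of the hotspot (defaults: lower-left
#'   quarter).
#' @return numeric weight matrix.
#' @export
bias_hotspot <- function(grid, factor = 5, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(max(1L, grid$n_rows %/% 2L))
  if (is.null(cols)) cols <- seq_len(max(1L, grid$n_cols %/% 2L))
  w <- matrix(1, grid$n_rows, grid$n_cols)
  w[rows, cols] <- factor
  w
}

#' Additive climate shift for one scenario x GCM x timeline
#'
#' @param scenario scenario id, e.g. `"SSP126"`.
#' @param gcm GCM id, e.g. `"GCM1"`.
#' @param timeline timeline id, e.g. `"2041-2060"`.
#' @param offsets named list of per-layer offsets; each entry is a scalar or
#'   a matrix on the target grid.
#' @return an object of class `scenario_shift`.
#' @export
scenario_shift <- function(scenario, gcm, timeline, offsets) {
  stopifnot(is.list(offsets), !is.null(names(offsets)))
  structure(list(scenario = scenario, gcm = gcm, timeline = timeline,
                 offsets = offsets),
            class = "scenario_shift")
}

#' Apply an additive scenario shift to a climate stack
#'
#' Offsets are added on valid cells of the named layers; the grid, the mask
#' and all unnamed layers are unchanged.
#'
#' @param stack a [climate_stack()].
#' @param shift a [scenario_shift()].
#' @return a new `climate_stack`.
#' @export
apply_scenario <- function(stack, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  missing <- setdiff(names(shift$offsets), layer_names(stack))
  if (length(missing)) {
    stop("shift references layers absent from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (l in names(shift$offsets)) {
    off <- shift$offsets[[l]]
    if (is.matrix(off)) {
      if (nrow(off) != stack$grid$n_rows || ncol(off) != stack$grid$n_cols) {
        stop(sprintf("offset for layer '%s' is not on the stack grid", l),
             call. = FALSE)
      }
    } else {
      stopifnot(is.numeric(off), length(off) == 1)
    }
    stack$layers[[l]] <- stack$layers[[l]] + off
    stack$layers[[l]][!stack$mask] <- NA_real_
  }
  stack
}
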