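#' Project a fitted model onto a future climate stack
#'
#' Predicts suitability under a scenario stack with training-range clamping.
#' When the model uses the host-suitability biotic predictor, the host layer
#' must be present in the stack or supplied via `host_future` (e.g. the host
#' model re-projected under the same scenario, or the current host layer if
#' the host is held static).
#'
#' @param model a [maxent_sdm()] model.
#' @param future_stack a [climate_stack()] for the scenario.
#' @param host_future optional host-suitability matrix to insert as the
#'   `host_layer` before predicting.
#' @param host_layer name of the host predictor (default
#'   `"host_suitability"`).
#' @return numeric suitability matrix.
#' @export
project_model <- function(model, future_stack, host_future = NULL,
                          host_layer = "host_suitability") {
  if (!is.null(host_future)) {
    future_stack <- set_layer(future_stack, host_layer, host_future)
  }
  if (host_layer %in% model$variables &&
      !host_layer %in% layer_names(future_stack)) {
    stop("model uses the host-suitability predictor but no host layer is ",
         "present for this scenario", call. = FALSE)
  }
  predict_suitability(model, future_stack)
}

#' Cellwise arithmetic mean of suitability rasters
#'
#' Averages per-GCM suitability rasters into an ensemble mean; a cell that is
#' nodata in any member is nodata in the mean (strict propagation, so the
#' average is never taken over differing supports).
#'
#' @param rasters list of numeric matrices on a common grid.
#' @return numeric matrix.
#' @export
ensemble_mean <- function(rasters) {
  stopifnot(is.list(rasters), length(rasters) >= 1)
  dims <- dim(rasters[[1]])
  for (r in rasters) {
    if (!identical(dim(r), dims)) {
      stop("ensemble members are not on a common grid", call. = FALSE)
    }
  }
  Reduce(`+`, rasters) / length(rasters)
}

#' Per-scenario suitability ensemble
#'
#' Bundles the per-GCM suitability rasters of one SSP x timeline with their
#' ensemble mean.
#'
#' @param ssp SSP id (e.g. `"SSP126"`).
#' @param timeline timeline id (e.g. `"2041-2060"`).
#' @param gcm_rasters named list of per-GCM suitability matrices.
#' @return an object of class `scenario_grid` with the cellwise `mean`.
#' @export
scenario_grid <- function(ssp, timeline, gcm_rasters) {
  structure(list(ssp = ssp, timeline = timeline, gcm_rasters = gcm_rasters,
                 mean = ensemble_mean(gcm_rasters)),
            class = "scenario_grid")
}
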