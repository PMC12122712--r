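#' Stage seed derived from a master seed
#'
#' Each pipeline stage consumes a seed that is a deterministic hash of the
#' master seed and the stage name, so adding or reordering stages never
#' perturbs the randomness of existing ones.
#'
#' @param master_seed integer master seed.
#' @param stage stage name (character).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((master_seed + fnv1a32(stage)) %% 2147483645 + 1)
}

#' Pipeline run configuration
#'
#' Collects every parameter of the two-species analysis: the study extent
#' and grid, the synthetic world (climate smoothness, niche truths, sampling
#' sizes, scenario shift table), and the modelling protocol (thinning cell,
#' background size, split fraction, collinearity threshold, host handling).
#' All stage seeds derive from `master_seed` via [stage_seed()].
#'
#' @param extent `c(lon_min, lat_min, lon_max, lat_max)` in degrees.
#' @param cell_size grid cell size in degrees.
#' @param climate_layers names of the climate predictor layers.
#' @param smoothness correlation length (cells) of the synthetic climate.
#' @param gradient_layer layer tied to latitude (the "temperature" proxy
#'   that warming shifts); `NULL` for none.
#' @param host_truth,parasite_truth [niche_truth()] definitions.
#' @param n_host_points,n_parasite_points raw occurrence counts to sample.
#' @param bias_factor over-sampling factor of the collection hotspot.
#' @param ssps named numeric vector: warming offset (in layer sd units) per
#'   SSP for the later timeline.
#' @param gcm_factors named numeric vector: per-GCM multiplier on the SSP
#'   offset (inter-model spread).
#' @param timeline_factors named numeric vector: multiplier per timeline.
#' @param latitude_graded extra shift fraction at the northern edge (0 =
#'   spatially uniform shift).
#' @param thin_cell_size thinning cell (degrees, default 0.25).
#' @param background_n background points per model (default 10000).
#' @param split_fraction training fraction (default 0.8).
#' @param cor_threshold collinearity cutoff (default 0.7).
#' @param screen_host screen the host model's variables too? Default FALSE
#'   (the host uses all candidates; only the parasite set is screened).
#' @param host_mode `"reprojected"` (host model re-projected under each
#'   scenario feeds the parasite) or `"static"` (current host suitability
#'   reused).
#' @param master_seed integer master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(extent = c(-10, 33, 45, 72),
                       cell_size = 0.25,
                       climate_layers = paste0("bio", 1:5),
                       smoothness = 4,
                       gradient_layer = "bio1",
                       host_truth = niche_truth(
                         intercept = 0.5,
                         coefficients = c(bio1 = 1.6, bio2 = 1.2),
                         quadratic = c(bio1 = -1)),
                       parasite_truth = niche_truth(
                         intercept = -2,
                         coefficients = c(bio2 = 1.0),
                         host_coefficient = 4),
                       n_host_points = 1200,
                       n_parasite_points = 600,
                       bias_factor = 5,
                       ssps = c(SSP126 = 0.5, SSP245 = 0.8,
                                SSP370 = 1.1, SSP585 = 1.4),
                       gcm_factors = c(GCM1 = 0.85, GCM2 = 0.95,
                                       GCM3 = 1.05, GCM4 = 1.15),
                       timeline_factors = c(`2041-2060` = 0.6,
                                            `2061-2080` = 1.0),
                       latitude_graded = 0.5,
                       thin_cell_size = 0.25,
                       background_n = 10000,
                       split_fraction = 0.8,
                       cor_threshold = 0.7,
                       screen_host = FALSE,
                       host_mode = c("reprojected", "static"),
                       master_seed = 1) {
  host_mode <- match.arg(host_mode)
  structure(as.list(environment()), class = "run_config")
}

#' Small demo-world configuration
#'
#' A 60 x 60 grid (15 x 15 degrees at 0.25 degrees) with five climate
#' layers, a warm-optimum host niche tied to the latitude-linked temperature
#' proxy, a host-dependent parasite, and a reduced background size so the
#' full pipeline runs end-to-end in minutes.
#'
#' @param master_seed integer master seed.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
demo_config <- function(master_seed = 1, ...) {
  run_config(extent = c(0, 40, 15, 55), cell_size = 0.25,
             n_host_points = 1000, n_parasite_points = 500,
             background_n = 3000, master_seed = master_seed, ...)
}

#' Generate the synthetic world a configuration describes
#'
#' Simulates the current climate stack (tying `gradient_layer` to latitude
#' so warming produces a poleward signal), evaluates the true host and
#' parasite suitabilities, samples biased occurrence records for both
#' species, and builds the SSP x GCM x timeline scenario shift table.
#'
#' @param config a [run_config()].
#' @return a list of class `world`: `grid`, `stack`, `bias`, truths, true
#'   suitability rasters, `host_occ` / `parasite_occ` (raw), and
#'   `shifts` (named list of [scenario_shift()]s, keys
#'   `<SSP>.<timeline>.<GCM>`).
#' @export
build_world <- function(config) {
  e <- config$extent
  grid <- make_grid(e[1], e[2], e[3], e[4], config$cell_size)
  stack <- simulate_climate(grid, config$climate_layers,
                            smoothness = config$smoothness,
                            seed = stage_seed(config$master_seed, "climate"))
  if (!is.null(config$gradient_layer)) {
    # tie the temperature proxy to latitude: colder toward the north
    lat <- latitude_matrix(grid)
    lat_std <- (lat - mean(lat)) / sd(lat)
    mixed <- 0.6 * stack$layers[[config$gradient_layer]] - lat_std
    stack$layers[[config$gradient_layer]] <-
      (mixed - mean(mixed[stack$mask])) / sd(mixed[stack$mask])
  }
  host_suit <- true_suitability(stack, config$host_truth)
  stack_h <- set_layer(stack, "host_suitability", host_suit)
  parasite_suit <- true_suitability(stack_h, config$parasite_truth,
                                    host_layer = "host_suitability")
  bias <- bias_hotspot(grid, factor = config$bias_factor)
  host_occ <- sample_occurrences(
    host_suit, grid, config$n_host_points, bias = bias,
    seed = stage_seed(config$master_seed, "host_occ"), species = "host")
  parasite_occ <- sample_occurrences(
    parasite_suit, grid, config$n_parasite_points, bias = bias,
    seed = stage_seed(config$master_seed, "parasite_occ"),
    species = "parasite")

  lat_unit <- (latitude_matrix(grid) - grid$lat_min) /
    (grid$lat_max - grid$lat_min)
  shifts <- list()
  for (ssp in names(config$ssps)) {
    for (tl in names(config$timeline_factors)) {
      for (gcm in names(config$gcm_factors)) {
        base <- config$ssps[[ssp]] * config$timeline_factors[[tl]] *
          config$gcm_factors[[gcm]]
        offsets <- list()
        if (!is.null(config$gradient_layer)) {
          offsets[[config$gradient_layer]] <-
            base * (1 + config$latitude_graded * lat_unit)
        } else {
          offsets[[config$climate_layers[1]]] <- base
        }
        shifts[[paste(ssp, tl, gcm, sep = ".")]] <-
          scenario_shift(ssp, gcm, tl, offsets)
      }
    }
  }
  structure(list(grid = grid, stack = stack, bias = bias,
                 host_truth = config$host_truth,
                 parasite_truth = config$parasite_truth,
                 host_suitability_true = host_suit,
                 parasite_suitability_true = parasite_suit,
                 host_occ = host_occ, parasite_occ = parasite_occ,
                 shifts = shifts),
            class = "world")
}

# Shared occurrence preparation: dedup -> clip -> thin -> split, plus
# background sampling and value extraction for one species.
prepare_species <- function(occ, stack, config, stage) {
  grid <- stack$grid
  occ <- deduplicate(occ)
  occ <- clip_to_extent(occ, grid)
  thinned <- thin_per_cell(occ, grid, config$thin_cell_size,
                           seed = stage_seed(config$master_seed,
                                             paste0(stage, "_thin")))
  # drop presences on nodata cells (logged)
  vals <- extract_values(stack, thinned$lon, thinned$lat,
                         layers = layer_names(stack)[1])
  on_valid <- !is.na(vals[[1]])
  if (any(!on_valid)) {
    message(sprintf("%s: %d presence(s) on nodata cells dropped",
                    stage, sum(!on_valid)))
    thinned <- thinned[on_valid, , drop = FALSE]
  }
  split <- split_train_validation(
    thinned, fraction = config$split_fraction,
    seed = stage_seed(config$master_seed, paste0(stage, "_split")))
  background <- sample_background(
    stack, n = config$background_n,
    seed = stage_seed(config$master_seed, paste0(stage, "_background")))
  list(clipped = occ, thinned = thinned, train = split$train,
       validation = split$validation, background = background)
}

# Fit + evaluate one species' model on the given predictor variables.
fit_species_model <- function(prep, stack, variables, config) {
  train_vals <- extract_values(stack, prep$train$lon, prep$train$lat,
                               layers = variables)
  bg_vals <- extract_values(stack, prep$background$lon, prep$background$lat,
                            layers = variables)
  model <- maxent_sdm(train_vals, bg_vals)
  val_vals <- extract_values(stack, prep$validation$lon,
                             prep$validation$lat, layers = variables)
  eval <- max_sens_spec_threshold(predict(model, val_vals),
                                  predict(model, bg_vals))
  list(model = model, eval = eval)
}

#' Fit and project the host model
#'
#' Fits the host niche model on the configured candidate variables (all of
#' them by default; screening optional), evaluates it on the held-out
#' split, predicts the current host suitability raster, and — when
#' `host_mode = "reprojected"` — projects it under every scenario so the
#' parasite model can consume scenario-consistent host suitability.
#'
#' @param config a [run_config()].
#' @param world a [build_world()] result (built from `config` if omitted).
#' @return list: `model`, `eval`, `prep` (occurrence stages),
#'   `current_suitability`, `current_binary`, `future_suitability` (named
#'   list keyed `<SSP>.<timeline>.<GCM>`; empty when `host_mode =
#'   "static"`), `variables`.
#' @export
run_host_model <- function(config, world = NULL) {
  if (is.null(world)) world <- build_world(config)
  stack <- world$stack
  variables <- config$climate_layers
  if (isTRUE(config$screen_host)) {
    rep <- correlation_matrix(stack)
    variables <- eliminate_collinear(rep, config$cor_threshold)$retained
  }
  prep <- prepare_species(world$host_occ, stack, config, "host")
  fitted <- fit_species_model(prep, stack, variables, config)
  current <- predict_suitability(fitted$model, stack)
  future <- list()
  if (config$host_mode == "reprojected") {
    for (key in names(world$shifts)) {
      future[[key]] <- predict_suitability(
        fitted$model, apply_scenario(stack, world$shifts[[key]]))
    }
  }
  list(model = fitted$model, eval = fitted$eval, prep = prep,
       current_suitability = current,
       current_binary = binarize(current, stack$grid,
                                 fitted$eval$threshold),
       future_suitability = future, variables = variables)
}

#' Fit, evaluate and project the host-conditioned parasite model
#'
#' Appends the host model's current suitability to the predictor stack as
#' the layer `host_suitability`, screens the climate layers for
#' collinearity (the host layer is always retained), fits and evaluates the
#' parasite model, computes permutation percent contributions, projects
#' under every SSP x GCM x timeline (substituting the scenario's host
#' suitability when `host_mode = "reprojected"`), averages GCMs within each
#' SSP x timeline, thresholds, and encodes range change against the current
#' parasite range.
#'
#' @param config a [run_config()].
#' @param world a [build_world()] result.
#' @param host a [run_host_model()] result.
#' @return list: `model`, `eval`, `prep`, `contribution`, `retained`
#'   (screened climate variables), `current_suitability`, `current_binary`,
#'   `ensembles` (list of [scenario_grid()]s keyed `<SSP>_<timeline>`),
#'   `change_maps`, `summaries`, `report` (long-format change table).
#' @export
run_parasite_model <- function(config, world, host) {
  stack <- set_layer(world$stack, "host_suitability",
                     host$current_suitability)
  rep <- correlation_matrix(
    climate_stack(stack$grid, stack$layers[config$climate_layers],
                  mask = stack$mask))
  retained <- eliminate_collinear(rep, config$cor_threshold)$retained
  variables <- c(retained, "host_suitability")
  prep <- prepare_species(world$parasite_occ, stack, config, "parasite")
  fitted <- fit_species_model(prep, stack, variables, config)
  current <- predict_suitability(fitted$model, stack)
  current_bin <- binarize(current, stack$grid, fitted$eval$threshold)

  contrib <- percent_contribution(
    fitted$model,
    extract_values(stack, prep$train$lon, prep$train$lat, variables),
    extract_values(stack, prep$background$lon, prep$background$lat,
                   variables),
    seed = stage_seed(config$master_seed, "parasite_contribution"))

  ensembles <- list(); change_maps <- list(); summaries <- list()
  for (ssp in names(config$ssps)) {
    for (tl in names(config$timeline_factors)) {
      per_gcm <- list()
      for (gcm in names(config$gcm_factors)) {
        key <- paste(ssp, tl, gcm, sep = ".")
        fut_stack <- apply_scenario(world$stack, world$shifts[[key]])
        host_fut <- if (config$host_mode == "reprojected") {
          host$future_suitability[[key]]
        } else {
          host$current_suitability
        }
        per_gcm[[gcm]] <- project_model(fitted$model, fut_stack,
                                        host_future = host_fut)
      }
      skey <- paste(ssp, tl, sep = "_")
      ensembles[[skey]] <- scenario_grid(ssp, tl, per_gcm)
      fut_bin <- binarize(ensembles[[skey]]$mean, stack$grid,
                          fitted$eval$threshold)
      change_maps[[skey]] <- encode_change(current_bin, fut_bin)
      summaries[[skey]] <- list(ssp = ssp, timeline = tl,
                                summary = summarize_change(change_maps[[skey]]))
    }
  }
  list(model = fitted$model, eval = fitted$eval, prep = prep,
       contribution = contrib, retained = retained,
       current_suitability = current, current_binary = current_bin,
       ensembles = ensembles, change_maps = change_maps,
       summaries = summaries, report = change_report(summaries))
}

#' Run the full two-species analysis
#'
#' World generation, occurrence preparation, collinearity screening, host
#' model, host-conditioned parasite model, scenario ensembles, and range
#' change accounting, returning a manifest of stage checksums for
#' reproducibility audits. When `output_dir` is given, rasters (ASCII
#' grids), occurrence CSVs, the change report CSV, and the manifest JSON
#' are written under it.
#'
#' @param config a [run_config()].
#' @param output_dir optional output directory.
#' @return list of class `run_result`: `world`, `host`, `parasite`,
#'   `report`, `manifest`.
#' @export
run_all <- function(config, output_dir = NULL) {
  world <- build_world(config)
  host <- run_host_model(config, world)
  parasite <- run_parasite_model(config, world, host)
  manifest <- list(
    package_version = as.character(utils::packageVersion("parashift")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = config$master_seed,
    checksums = list(
      climate = fnv1a32(lapply(world$stack$layers, round, digits = 10)),
      host_occ = fnv1a32(world$host_occ),
      parasite_occ = fnv1a32(world$parasite_occ),
      host_beta = fnv1a32(round(host$model$fit$beta, 10)),
      parasite_beta = fnv1a32(round(parasite$model$fit$beta, 10)),
      change_report = fnv1a32(parasite$report)
    ),
    parameters = list(
      extent = config$extent, cell_size = config$cell_size,
      thin_cell_size = config$thin_cell_size,
      background_n = config$background_n,
      split_fraction = config$split_fraction,
      cor_threshold = config$cor_threshold,
      host_mode = config$host_mode,
      retained_climate = parasite$retained
    )
  )
  if (!is.null(output_dir)) {
    dir.create(file.path(output_dir, "rasters"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(output_dir, "reports"), showWarnings = FALSE)
    write_occurrences(host$prep$thinned,
                      file.path(output_dir, "host_thinned.csv"))
    write_occurrences(parasite$prep$thinned,
                      file.path(output_dir, "parasite_thinned.csv"))
    write_ascii_grid(host$current_suitability, world$grid,
                     file.path(output_dir, "rasters", "host_current.asc"))
    write_ascii_grid(parasite$current_suitability, world$grid,
                     file.path(output_dir, "rasters",
                               "parasite_current.asc"))
    for (skey in names(parasite$ensembles)) {
      write_ascii_grid(parasite$ensembles[[skey]]$mean, world$grid,
                       file.path(output_dir, "rasters",
                                 paste0(skey, "_mean.asc")))
      write_ascii_grid(parasite$change_maps[[skey]]$codes + 0, world$grid,
                       file.path(output_dir, "rasters",
                                 paste0(skey, "_change.asc")))
    }
    utils::write.csv(parasite$report,
                     file.path(output_dir, "reports", "change_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(output_dir, "reports", "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(world = world, host = host, parasite = parasite,
                 report = parasite$report, manifest = manifest),
            class = "run_result")
}

#' Serialize a run configuration to YAML (and back)
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  # named vectors serialize as YAML mappings (as.list keeps length-1 names)
  for (f in c("ssps", "gcm_factors", "timeline_factors")) {
    x[[f]] <- as.list(x[[f]])
  }
  for (f in c("host_truth", "parasite_truth")) {
    t <- unclass(x[[f]])
    t$coefficients <- as.list(t$coefficients)
    t$quadratic <- as.list(t$quadratic)
    x[[f]] <- t
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("host_truth", "parasite_truth")) {
    t <- x[[f]]
    x[[f]] <- niche_truth(intercept = t$intercept,
                          coefficients = unlist(t$coefficients),
                          quadratic = if (length(t$quadratic))
                            unlist(t$quadratic) else NULL,
                          host_coefficient = t$host_coefficient)
  }
  for (f in c("ssps", "gcm_factors", "timeline_factors")) {
    x[[f]] <- unlist(x[[f]])
  }
  x$extent <- unlist(x$extent)
  x$climate_layers <- unlist(x$climate_layers)
  structure(x, class = "run_config")
}
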