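# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

small_grid <- function(n = 10, cell = 1) {
  make_grid(0, 40, n * cell, 40 + n * cell, cell)
}

small_stack <- function(n = 10, layers = c("a", "b"), smoothness = 0,
                        seed = 1) {
  simulate_climate(small_grid(n), layers, smoothness = smoothness,
                   seed = seed)
}

# Stack with layers set to explicit matrices on a small grid.
manual_stack <- function(...) {
  layers <- list(...)
  n <- nrow(layers[[1]])
  climate_stack(small_grid(n), layers)
}

# One-cell binary range maps for the range-change encoding cases.
one_cell_map <- function(suitable) {
  g <- make_grid(0, 0, 1, 1, 1)
  binarize(matrix(if (suitable) 0.9 else 0.1, 1, 1), g, 0.5)
}

# Lag-1 neighbor correlation (rook moves), computed by direct looping --
# the independent spatial-autocorrelation oracle.
neighbor_correlation <- function(m) {
  x <- c(); y <- c()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m) - 1)) {
    x <- c(x, m[i, j]); y <- c(y, m[i, j + 1])
  }
  for (i in seq_len(nrow(m) - 1)) for (j in seq_len(ncol(m))) {
    x <- c(x, m[i, j]); y <- c(y, m[i + 1, j])
  }
  cor(x, y)
}

# The niche-recovery harness: a specialist niche (two informative layers,
# three noise layers) on a 60x60 quarter-degree window. Returns the fitted
# model's held-out AUC and its Spearman correlation with the generating
# truth over all valid cells.
recovery_run <- function(seed, n_presence = 500, n_background = 10000) {
  st <- simulate_climate(make_grid(0, 40, 15, 55, 0.25), paste0("bio", 1:5),
                         smoothness = 4, seed = seed)
  tr <- niche_truth(-6, c(bio1 = 5, bio2 = -4))
  suit <- true_suitability(st, tr)
  occ <- sample_occurrences(suit, st$grid, n_presence, seed = seed + 100)
  sp <- split_train_validation(occ, 0.8, seed = seed + 300)
  bg <- sample_background(st, n_background, seed = seed + 200)
  m <- maxent_sdm(extract_values(st, sp$train$lon, sp$train$lat),
                  extract_values(st, bg$lon, bg$lat))
  pred <- predict_suitability(m, st)
  list(model = m, stack = st, truth = suit,
       auc = auc(predict(m, extract_values(st, sp$validation$lon,
                                           sp$validation$lat)),
                 predict(m, extract_values(st, bg$lon, bg$lat))),
       spearman = cor(pred[st$mask], suit[st$mask], method = "spearman"))
}

# Reduced two-species pipeline configuration for range-shift property runs:
# weakest and strongest scenario, later timeline, two GCMs.
shift_config <- function(seed) {
  run_config(extent = c(0, 40, 10, 50), cell_size = 0.25,
             n_host_points = 800, n_parasite_points = 450,
             background_n = 2000,
             ssps = c(SSP126 = 0.5, SSP585 = 1.4),
             gcm_factors = c(GCM1 = 0.9, GCM2 = 1.1),
             timeline_factors = c(`2061-2080` = 1.0),
             master_seed = seed)
}
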