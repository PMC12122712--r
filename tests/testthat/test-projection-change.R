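test_that("ensemble mean matches an explicit elementwise loop", {
  set.seed(20)
  rs <- lapply(1:4, function(i) matrix(runif(36), 6, 6))
  em <- ensemble_mean(rs)
  manual <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    manual[i, j] <- (rs[[1]][i, j] + rs[[2]][i, j] + rs[[3]][i, j] +
                       rs[[4]][i, j]) / 4
  }
  expect_equal(em, manual, tolerance = 1e-12)
  # within member envelope; permutation invariant; identity on equal inputs
  expect_true(all(em >= pmin(rs[[1]], rs[[2]], rs[[3]], rs[[4]]) - 1e-12))
  expect_true(all(em <= pmax(rs[[1]], rs[[2]], rs[[3]], rs[[4]]) + 1e-12))
  expect_equal(ensemble_mean(rev(rs)), em)
  expect_equal(ensemble_mean(list(rs[[1]], rs[[1]])), rs[[1]])
  expect_equal(ensemble_mean(list(matrix(0, 1, 1), matrix(1, 1, 1),
                                  matrix(1, 1, 1), matrix(0, 1, 1)))[1, 1],
               0.5)
  # nodata in any member propagates
  rs[[2]][3, 3] <- NA
  expect_true(is.na(ensemble_mean(rs)[3, 3]))
  expect_error(ensemble_mean(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "common grid")
})

test_that("projection under the identity scenario reproduces current", {
  r <- recovery_run(2, n_presence = 200, n_background = 800)
  cur <- predict_suitability(r$model, r$stack)
  proj <- project_model(r$model, r$stack)
  expect_identical(proj, cur)
  # clamping: pushing a layer far beyond the training range predicts like
  # the training-range boundary
  big <- apply_scenario(r$stack,
                        scenario_shift("S", "G", "T", list(bio1 = 100)))
  very_big <- apply_scenario(r$stack,
                             scenario_shift("S", "G", "T",
                                            list(bio1 = 1000)))
  expect_equal(project_model(r$model, big), project_model(r$model, very_big))
})

test_that("host-conditioned models refuse scenarios without a host layer", {
  st <- small_stack(12, layers = c("bio1", "bio2"), smoothness = 2,
                    seed = 30)
  host_suit <- true_suitability(st, niche_truth(0, c(bio1 = 2)))
  st_h <- set_layer(st, "host_suitability", host_suit)
  suit <- true_suitability(st_h, niche_truth(-1, c(bio2 = 1),
                                             host_coefficient = 3),
                           host_layer = "host_suitability")
  occ <- sample_occurrences(suit, st$grid, 120, seed = 31)
  bg <- sample_background(st_h, 144, seed = 32)
  vars <- c("bio1", "bio2", "host_suitability")
  m <- maxent_sdm(extract_values(st_h, occ$lon, occ$lat, vars),
                  extract_values(st_h, bg$lon, bg$lat, vars))
  expect_error(project_model(m, st), "host")
  ok <- project_model(m, st, host_future = host_suit)
  expect_equal(ok, predict_suitability(m, st_h))
})

test_that("range-change encoding reproduces the four codes", {
  expect_equal(encode_change(one_cell_map(FALSE),
                             one_cell_map(FALSE))$codes[1, 1], 0L)
  expect_equal(encode_change(one_cell_map(FALSE),
                             one_cell_map(TRUE))$codes[1, 1], -2L)
  expect_equal(encode_change(one_cell_map(TRUE),
                             one_cell_map(FALSE))$codes[1, 1], 1L)
  expect_equal(encode_change(one_cell_map(TRUE),
                             one_cell_map(TRUE))$codes[1, 1], -1L)
})

test_that("encode/decode round-trips and conserves range identities", {
  g <- small_grid(8)
  set.seed(33)
  for (rep in 1:5) {
    cur_s <- matrix(runif(64), 8, 8); fut_s <- matrix(runif(64), 8, 8)
    cur_s[1, 1] <- NA; fut_s[1, 1] <- NA
    cur <- binarize(cur_s, g, 0.5); fut <- binarize(fut_s, g, 0.5)
    rcm <- encode_change(cur, fut)
    # decoding recovers both maps: future = (current - code)/2
    cur_back <- rcm$codes %in% c(1L, -1L) & !is.na(rcm$codes)
    fut_back <- (as.integer(cur$suitable) - rcm$codes) / 2
    expect_equal(matrix(cur_back, 8, 8)[!is.na(rcm$codes)],
                 cur$suitable[!is.na(rcm$codes)])
    expect_equal(fut_back[!is.na(rcm$codes)],
                 as.numeric(fut$suitable[!is.na(rcm$codes)]))
    expect_true(is.na(rcm$codes[1, 1]))

    s <- summarize_change(rcm)
    expect_equal(s$n_contraction + s$n_persistence,
                 sum(cur$suitable, na.rm = TRUE))
    expect_equal(s$n_expansion + s$n_persistence,
                 sum(fut$suitable, na.rm = TRUE))
    expect_equal(s$n_still_unsuitable + s$n_expansion + s$n_contraction +
                   s$n_persistence, sum(!is.na(rcm$codes)))
  }
})

test_that("change summaries use current-range percentages", {
  g <- make_grid(0, 0, 2, 2, 1)
  # one cell of each code
  cur <- binarize(matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2), g, 0.5)
  fut <- binarize(matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2), g, 0.5)
  s <- summarize_change(encode_change(cur, fut))
  expect_equal(s$current_range, 2)
  expect_equal(s$expansion_pct, 50)
  expect_equal(s$contraction_pct, 50)

  # identity: no expansion, no contraction
  s2 <- summarize_change(encode_change(cur, cur))
  expect_equal(s2$expansion_pct, 0)
  expect_equal(s2$contraction_pct, 0)
  expect_equal(s2$n_persistence, s2$current_range)

  # empty current range: counts valid, percentages undefined
  none <- binarize(matrix(0.1, 2, 2), g, 0.5)
  some <- binarize(matrix(c(0.9, 0.1, 0.1, 0.1), 2, 2), g, 0.5)
  s3 <- summarize_change(encode_change(none, some))
  expect_equal(s3$n_expansion, 1)
  expect_true(is.na(s3$expansion_pct))

  # latitude weighting multiplies counts by cos(latitude of cell center)
  s4 <- summarize_change(encode_change(cur, fut), latitude_weighted = TRUE)
  # the expansion cell is in row 1, center latitude 0.5 degrees
  expect_equal(s4$n_expansion, cos(0.5 * pi / 180), tolerance = 1e-12)
})

test_that("change reports are long-format and CSV round-trip clean", {
  g <- make_grid(0, 0, 2, 2, 1)
  cur <- binarize(matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2), g, 0.5)
  fut <- binarize(matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2), g, 0.5)
  s <- summarize_change(encode_change(cur, fut))
  keys <- as.vector(outer(c("SSP126", "SSP245", "SSP370", "SSP585"),
                          c("2041-2060", "2061-2080"), paste, sep = "_"))
  summaries <- setNames(rep(list(s), 8), keys)
  rep8 <- change_report(summaries)
  expect_equal(sum(rep8$metric == "expansion_pct"), 8)
  expect_equal(nrow(rep8), 8 * 6)
  expect_setequal(unique(rep8$ssp),
                  c("SSP126", "SSP245", "SSP370", "SSP585"))

  expect_equal(nrow(change_report(list())), 0)

  path <- tempfile(fileext = ".csv")
  utils::write.csv(rep8, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$value, rep8$value)
  expect_equal(back$metric, rep8$metric)
})
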