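test_that("simulated climate is standardized, seeded, and autocorrelated", {
  st <- small_stack(10, smoothness = 0, seed = 3)
  for (l in layer_names(st)) {
    v <- st$layers[[l]][st$mask]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_true(sd(v) > 0.9 && sd(v) < 1.1)
  }
  expect_identical(small_stack(10, smoothness = 0, seed = 3)$layers,
                   st$layers)
  expect_error(simulate_climate(small_grid(5), character(0)), "layer")

  # smoothing raises lag-1 neighbor correlation (independent loop oracle)
  wins <- vapply(1:20, function(s) {
    smooth <- simulate_climate(small_grid(15), "a", smoothness = 5,
                               seed = s)$layers$a
    rough <- simulate_climate(small_grid(15), "a", smoothness = 0,
                              seed = s)$layers$a
    neighbor_correlation(smooth) > neighbor_correlation(rough)
  }, logical(1))
  expect_true(all(wins))
})

test_that("true suitability is the logistic of the configured niche", {
  st <- small_stack(5, layers = c("a", "b"))
  flat <- true_suitability(st, niche_truth(0))
  expect_true(all(flat[st$mask] == 0.5))
  # large intercept drives suitability toward 1
  expect_true(all(true_suitability(st, niche_truth(30))[st$mask] > 0.999))
  # explicit value: one layer, coef 1, cell value 2 -> logistic(2)
  st2 <- manual_stack(a = matrix(2, 3, 3))
  expect_equal(true_suitability(st2, niche_truth(0, c(a = 1)))[1, 1],
               1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(true_suitability(st, niche_truth(0, c(zz = 1))), "absent")
  expect_error(true_suitability(st, niche_truth(0, c(a = 1),
                                                host_coefficient = 2)),
               "host")
})

test_that("occurrence sampling follows suitability x bias and the seed", {
  g <- small_grid(4)
  suit <- matrix(0, 4, 4); suit[2, 3] <- 1
  occ <- sample_occurrences(suit, g, 25, seed = 5)
  idx <- cell_index(g, occ$lon, occ$lat)
  expect_true(all(idx$row == 2 & idx$col == 3))

  expect_error(sample_occurrences(matrix(0, 4, 4), g, 5), "degenerate")
  expect_identical(sample_occurrences(suit, g, 10, seed = 7),
                   sample_occurrences(suit, g, 10, seed = 7))

  # uniform suitability, 10x bias on the left half: expected left share
  # 10/11, binomial sd sqrt(p(1-p)/n)
  g2 <- small_grid(10)
  bias <- matrix(1, 10, 10); bias[, 1:5] <- 10
  occ2 <- sample_occurrences(matrix(0.5, 10, 10), g2, 10000, bias = bias,
                             seed = 11)
  share <- mean(cell_index(g2, occ2$lon, occ2$lat)$col <= 5)
  p <- 10 / 11
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("scenario shifts are additive, composable and mask-preserving", {
  st <- small_stack(6, layers = c("bio1", "bio2"), seed = 2)
  zero <- apply_scenario(st, scenario_shift("S", "G", "T", list(bio1 = 0)))
  expect_identical(zero$layers, st$layers)

  plus1 <- apply_scenario(st, scenario_shift("S", "G", "T", list(bio1 = 1)))
  expect_equal(plus1$layers$bio1, st$layers$bio1 + 1)
  expect_identical(plus1$layers$bio2, st$layers$bio2)
  expect_identical(plus1$mask, st$mask)

  a_b <- apply_scenario(plus1, scenario_shift("S", "G", "T",
                                              list(bio1 = 0.5)))
  ab <- apply_scenario(st, scenario_shift("S", "G", "T", list(bio1 = 1.5)))
  expect_equal(a_b$layers$bio1, ab$layers$bio1)

  expect_error(apply_scenario(st, scenario_shift("S", "G", "T",
                                                 list(zz = 1))),
               "absent")
  expect_error(apply_scenario(st, scenario_shift("S", "G", "T",
                                                 list(bio1 = matrix(1, 2, 2)))),
               "grid")
})

test_that("matrix offsets and masked stacks keep nodata cells nodata", {
  g <- small_grid(4)
  mask <- matrix(TRUE, 4, 4); mask[4, 4] <- FALSE
  st <- simulate_climate(g, "bio1", smoothness = 1, seed = 4, mask = mask)
  shifted <- apply_scenario(st, scenario_shift("S", "G", "T",
                                               list(bio1 = matrix(2, 4, 4))))
  expect_true(is.na(shifted$layers$bio1[4, 4]))
  expect_equal(shifted$layers$bio1[mask], st$layers$bio1[mask] + 2)
})
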