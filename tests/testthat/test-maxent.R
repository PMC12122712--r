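test_that("feature expansion has the expected structure and counts", {
  x <- data.frame(a = runif(30), b = runif(30), c = runif(30))
  # linear-only on one variable equals the scaled variable
  f1 <- build_features(x["a"], feature_spec(classes = "linear"))
  s <- (x$a - min(x$a)) / (max(x$a) - min(x$a))
  expect_equal(unname(f1$features[, "a"]), s)

  # combinatorial count: linear + quadratic + product = 2v + v(v-1)/2
  f2 <- build_features(x, feature_spec(classes = c("linear", "quadratic",
                                                   "product")))
  v <- 3
  expect_equal(ncol(f2$features), 2 * v + v * (v - 1) / 2)

  # forward hinge is zero at its own knot
  f3 <- build_features(x["a"], feature_spec(classes = "hinge",
                                            n_knots = 5))
  k <- 0.25  # second knot of seq(0, 1, length.out = 5)
  at_knot <- pmax(0, (s - k) / (1 - k))
  expect_equal(unname(f3$features[, sprintf("h(%s>%.4f)", "a", k)]),
               at_knot)

  # constant variables are excluded with a warning
  x$d <- 1
  expect_warning(f4 <- build_features(x, feature_spec(classes = "linear")),
                 "constant")
  expect_false("d" %in% colnames(f4$features))
})

test_that("stored scaling clamps new data into the training range", {
  x <- data.frame(a = seq(0, 1, length.out = 20))
  fx <- build_features(x, feature_spec(classes = "linear"))
  beyond <- build_features(data.frame(a = c(-5, 2)), feature_spec("linear"),
                           scaling = fx$scaling)
  expect_equal(unname(beyond$features[, "a"]), c(0, 1))
})

test_that("fitted raw distribution sums to 1 over the training background", {
  set.seed(1)
  st <- small_stack(20, layers = c("a", "b"), smoothness = 3, seed = 8)
  suit <- true_suitability(st, niche_truth(-1, c(a = 2)))
  occ <- sample_occurrences(suit, st$grid, 150, seed = 2)
  bg <- sample_background(st, 400, seed = 3)
  m <- maxent_sdm(extract_values(st, occ$lon, occ$lat),
                  extract_values(st, bg$lon, bg$lat))
  raw <- predict(m, extract_values(st, bg$lon, bg$lat), type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-6)
  logi <- predict(m, extract_values(st, bg$lon, bg$lat))
  expect_true(all(logi > 0 & logi < 1))
  # prediction is deterministic across calls
  expect_identical(predict_suitability(m, st), predict_suitability(m, st))
})

test_that("binary-feature fit matches the closed-form maxent solution", {
  # presences all at feature = 1; background split 50/50.
  # Penalized solution maximizes beta - log((exp(beta) + 1)/2) - lam*|beta|,
  # giving raw ratio exp(beta) = (1 - lam)/lam; cross-checked by direct 1-D
  # optimization.
  Fp <- matrix(1, 50, 1); Fb <- matrix(rep(c(0, 1), 100), ncol = 1)
  colnames(Fp) <- colnames(Fb) <- "f"
  for (lam in c(0.05, 0.2)) {
    fit <- fit_maxent(Fp, Fb, lambda = lam, tol = 1e-10)
    expect_equal(unname(fit$beta["f"]), log((1 - lam) / lam),
                 tolerance = 1e-6)
    brute <- optimize(function(b) b - log((exp(b) + 1) / 2) - lam * abs(b),
                      c(-20, 20), maximum = TRUE)$maximum
    expect_equal(unname(fit$beta["f"]), brute, tolerance = 1e-4)
  }
})

test_that("coefficients match the glmnet infinite-weight reference", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  worst <- 0
  for (rep in 1:20) {
    m <- 50 + 5 * rep; nb <- 300; p <- 3 + rep %% 3
    X <- matrix(runif((m + nb) * p), ncol = p)
    colnames(X) <- paste0("v", seq_len(p))
    X[1:m, 1] <- X[1:m, 1]^0.4
    X[1:m, 2] <- X[1:m, 2]^2
    Fp <- X[1:m, , drop = FALSE]; Fb <- X[-(1:m), , drop = FALSE]
    lam <- runif(p, 0.005, 0.05)
    fit <- fit_maxent(Fp, Fb, lambda = lam, tol = 1e-8)
    W <- 1e5
    y <- c(rep(1, m), rep(0, nb)); w <- c(rep(1, m), rep(W, nb))
    lg <- mean(lam) * m / (m + W * nb)
    g <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                        standardize = FALSE,
                        penalty.factor = lam / mean(lam),
                        lambda = lg * c(8, 4, 2, 1), thresh = 1e-14,
                        maxit = 1e6)
    ref <- as.numeric(coef(g, s = lg))[-1]
    worst <- max(worst, max(abs(ref - fit$beta)))
  }
  expect_lt(worst, 1e-3)
})

test_that("null data yields a near-uniform fitted distribution", {
  st <- simulate_climate(make_grid(-10, 33, 45, 72, 0.25),
                         paste0("bio", 1:5), smoothness = 8, seed = 11)
  bg1 <- sample_background(st, 5000, seed = 101)
  bg2 <- sample_background(st, 5000, seed = 201)
  pv <- extract_values(st, bg1$lon, bg1$lat)
  bv <- extract_values(st, bg2$lon, bg2$lat)
  m <- maxent_sdm(pv, bv,
                  spec = feature_spec(classes = c("linear", "quadratic")))
  raw <- predict(m, bv, type = "raw")
  # linear predictor nearly constant and no background cell far from the
  # uniform density 1/n
  expect_lt(sd(log(raw)), 0.15)
  expect_lt(max(raw) * length(raw), 2)
})

test_that("stronger regularization never adds active coefficients", {
  set.seed(3)
  st <- small_stack(15, layers = c("a", "b", "c"), smoothness = 2, seed = 4)
  suit <- true_suitability(st, niche_truth(-1, c(a = 2, b = -1)))
  occ <- sample_occurrences(suit, st$grid, 120, seed = 5)
  bg <- sample_background(st, 225, seed = 6)
  pv <- extract_values(st, occ$lon, occ$lat)
  bv <- extract_values(st, bg$lon, bg$lat)
  counts <- vapply(c(0.5, 1, 2, 4), function(mult) {
    sum(maxent_sdm(pv, bv, reg_multiplier = mult)$fit$beta != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("percent contributions are normalized and rank signal over noise", {
  r <- recovery_run(1, n_presence = 300, n_background = 1000)
  st <- r$stack
  occ <- sample_occurrences(r$truth, st$grid, 300, seed = 101)
  bg <- sample_background(st, 1000, seed = 201)
  ct <- percent_contribution(r$model,
                             extract_values(st, occ$lon, occ$lat),
                             extract_values(st, bg$lon, bg$lat),
                             n_permutations = 3, seed = 5)
  expect_equal(sum(ct$contribution), 100, tolerance = 0.1)
  expect_true(all(ct$contribution >= 0))
  signal <- ct$contribution[ct$variable %in% c("bio1", "bio2")]
  noise <- ct$contribution[ct$variable %in% c("bio3", "bio4", "bio5")]
  expect_true(min(signal) > max(noise))
  expect_true(all(noise < 10))
})
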