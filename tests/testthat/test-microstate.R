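test_that("gfp follows the population spatial-SD formula", {
  expect_equal(gfp(c(5, 5, 5)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(2, 0, -2)), sqrt(8 / 3))
  expect_error(gfp(3), "channels")
  # matrix form: one value per sample
  m <- cbind(c(1, -1), c(2, 0))
  expect_equal(gfp(m), c(1, 1))
})

test_that("spatial correlation is strength-independent and polarity-aware", {
  u <- rnorm(20)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -3 * u), 1)
  expect_equal(spatial_correlation(u, -3 * u, polarity_invariant = FALSE), -1)
  expect_equal(spatial_correlation(c(1, 0, -1), c(0, 1, -1)), 0.5)
  expect_error(spatial_correlation(c(1, 1, 1), u[1:3]), "zero-norm")
})

test_that("the peak map is the latest local GFP maximum, with max fallback", {
  mon <- small_montage(8)
  n <- 60
  # construct a GFP series with local maxima at offsets -31 and -12 ms
  # (the last pre-stimulus sample is at -1 ms)
  g <- rep(0.2, n)
  g[n - 30] <- 1.0
  g[n - 11] <- 0.8
  v <- rnorm(8); v <- (v - mean(v)) / gfp(v)
  ep <- one_trial_epochs(outer(v, g), onset = n)
  pk <- find_prestim_peak_map(ep, 1, window_ms = 50)
  expect_equal(pk$time_offset_ms, -12)
  # strictly increasing GFP: fallback to the final pre-stimulus sample
  ep2 <- one_trial_epochs(outer(v, seq_len(n)), onset = n)
  pk2 <- find_prestim_peak_map(ep2, 1, window_ms = 50)
  expect_equal(pk2$time_offset_ms, -1)
})

test_that("noiseless single-state trials yield peak maps identical to the template", {
  mon <- small_montage(24)
  tpl <- make_templates(mon, 1, seed = 9)
  p <- sim_params(n_trials_per_condition = 3, noise_sd = 0,
                  alpha = list(amplitude = 0), seed = 1)
  sim <- simulate_epochs(tpl, mon, p)
  pm <- peak_maps(sim$epochs, 50)
  for (i in seq_len(nrow(pm$maps)))
    expect_equal(spatial_correlation(pm$maps[i, ], tpl[, 1]), 1,
                 tolerance = 1e-9)
})

test_that("clustering recovers planted orthogonal templates and degenerate k=1", {
  set.seed(4)
  C <- 16
  t1 <- rnorm(C); t1 <- t1 - mean(t1); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- rnorm(C); t2 <- t2 - mean(t2)
  t2 <- t2 - sum(t2 * t1) * t1; t2 <- t2 / sqrt(sum(t2^2))
  X <- rbind(t(sapply(runif(20, 0.5, 2) * sample(c(-1, 1), 20, TRUE),
                      function(a) a * t1)),
             t(sapply(runif(20, 0.5, 2) * sample(c(-1, 1), 20, TRUE),
                      function(a) a * t2)))
  scan <- cluster_microstates(X, k_range = 1:3, restarts = 10, seed = 2)
  m2 <- get_model(scan, 2)
  expect_equal(m2$gev_total, 1, tolerance = 1e-9)
  match_C <- abs(crossprod(cbind(t1, t2), m2$templates))
  expect_true(all(apply(match_C, 1, max) >= 0.999))
  # +/- multiples of one template: k = 1 explains everything
  X1 <- t(sapply(runif(12, 0.5, 2) * sample(c(-1, 1), 12, TRUE),
                 function(a) a * t1))
  m1 <- get_model(cluster_microstates(X1, k_range = 1, restarts = 3,
                                      seed = 1), 1)
  expect_equal(m1$gev_total, 1, tolerance = 1e-9)
})

test_that("explained variance matches exhaustive sign-free assignment search", {
  set.seed(31)
  for (i in 1:8) {
    X <- matrix(rnorm(8 * 4), 8, 4)
    scan <- cluster_microstates(X, k_range = 2, restarts = 40, seed = i)
    expect_equal(get_model(scan, 2)$gev_total, brute_force_ev_k2(X),
                 tolerance = 1e-8)
  }
})

test_that("cv criterion applies the predictive-variance penalty", {
  m <- structure(list(k = 3, sigma2 = 0, templates = matrix(0, 30, 3)),
                 class = "microstate_model")
  expect_equal(cv_criterion(m, 30), 0)
  sig <- 1.7
  cvs <- sapply(1:10, function(k) {
    mk <- structure(list(k = k, sigma2 = sig, templates = matrix(0, 30, k)),
                    class = "microstate_model")
    cv_criterion(mk, 30)
  })
  expect_true(all(diff(cvs) > 0))
  expect_equal(cvs[2], sig * (29 / 27)^2)
  mbad <- structure(list(k = 29, sigma2 = 1, templates = matrix(0, 30, 29)),
                    class = "microstate_model")
  expect_error(cv_criterion(mbad, 30), "n_channels")
})

test_that("clustering output is invariant to polarity flips of the input", {
  set.seed(12)
  X <- matrix(rnorm(30 * 12), 30, 12)
  flips <- sample(c(-1, 1), 30, replace = TRUE)
  s1 <- cluster_microstates(X, k_range = 2:3, restarts = 8, seed = 5)
  s2 <- cluster_microstates(X * flips, k_range = 2:3, restarts = 8, seed = 5)
  for (i in 1:2) {
    m1 <- s1$models[[i]]; m2 <- s2$models[[i]]
    expect_equal(m1$sigma2, m2$sigma2, tolerance = 1e-10)
    expect_equal(m1$gev_total, m2$gev_total, tolerance = 1e-10)
    expect_equal(m1$cv, m2$cv, tolerance = 1e-10)
    # each template reproduced up to polarity
    for (j in seq_len(m1$k))
      expect_lt(min(sqrt(sum((m1$templates[, j] - m2$templates[, j])^2)),
                    sqrt(sum((m1$templates[, j] + m2$templates[, j])^2))),
                1e-6)
    expect_identical(m1$assignments, m2$assignments)
  }
})

test_that("gev_total is non-decreasing in k on the same data", {
  set.seed(3)
  X <- matrix(rnorm(40 * 10), 40, 10)
  scan <- cluster_microstates(X, k_range = 1:6, restarts = 10, seed = 7)
  gevs <- vapply(scan$models, `[[`, 0, "gev_total")
  expect_true(all(diff(gevs) >= -1e-10))
})

test_that("model objects expose the usual S3 surface", {
  set.seed(2)
  X <- matrix(rnorm(30 * 12), 30, 12)
  scan <- cluster_microstates(X, k_range = 1:3, restarts = 5, seed = 1)
  expect_s3_class(scan, "microstate_scan")
  expect_true(select_k(scan) %in% 1:3)
  m <- get_model(scan)
  expect_identical(coef(m), m$templates)
  lab <- predict(m, X)
  expect_s3_class(lab, "ms_labeling")
  expect_equal(nrow(lab$table), 30)
  df <- summary(scan)
  expect_identical(df$k, 1:3)
  expect_output(print(scan), "CV-selected")
})
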