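test_that("reference transforms satisfy their defining identities", {
  ep <- noise_epochs(n_trials = 3, montage = make_montage(32, 1),
                     n_samples = 40)
  avg <- rereference(ep, "average")
  expect_lt(max(abs(apply(avg$data, c(1, 3), sum))), 1e-9)
  cz <- rereference(ep, "Cz")
  czi <- match("Cz", ep$montage$names)
  expect_lt(max(abs(cz$data[, czi, ])), 1e-12)
  mst <- rereference(ep, "mastoids")
  mi <- match(c("M1", "M2"), ep$montage$names)
  expect_lt(max(abs((mst$data[, mi[1], ] + mst$data[, mi[2], ]) / 2)), 1e-12)
})

test_that("reference transforms are idempotent and compose linearly", {
  ep <- noise_epochs(n_trials = 2, montage = make_montage(32, 1),
                     n_samples = 30)
  a1 <- rereference(ep, "average")
  expect_equal(rereference(a1, "average")$data, a1$data, tolerance = 1e-12)
  # avg -> Cz -> avg equals avg directly (reference algebra)
  back <- rereference(rereference(a1, "Cz"), "average")
  expect_equal(back$data, a1$data, tolerance = 1e-9)
  expect_error(rereference(ep, "NoSuchChannel"), "unknown electrode")
})

test_that("band-pass is zero-phase with the specified in/out-of-band gains", {
  fs <- 1000
  n <- 6000              # long tone so the 1 Hz high-pass transient settles
  t <- (seq_len(n) - 1) / fs
  mon <- small_montage(4)
  mid <- 2500:3500
  # 10 Hz tone: two-pass squared Butterworth magnitude at 10 Hz
  x <- sin(2 * pi * 10 * t)
  ep <- one_trial_epochs(rbind(x, x, x, x), fs = fs, montage = mon)
  y <- bandpass_filter(ep, filter_spec(1, 30))$data[1, 1, ]
  gain <- max(abs(y[mid])) / max(abs(x[mid]))
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.0001)
  # DC killed by > 40 dB
  ep_dc <- one_trial_epochs(matrix(1, 4, n), fs = fs, montage = mon)
  ydc <- bandpass_filter(ep_dc, filter_spec(1, 30))$data[1, 1, ]
  expect_lt(max(abs(ydc[mid])), 10^(-40 / 20))
  # symmetric Gaussian pulse keeps its peak sample (zero phase)
  g <- exp(-((seq_len(n) - 3000)^2) / (2 * 20^2))
  epg <- one_trial_epochs(rbind(g, g, g, g), fs = fs, montage = mon)
  yg <- bandpass_filter(epg, filter_spec(1, 30))$data[1, 1, ]
  expect_equal(which.max(yg), 3000)
  expect_error(bandpass_filter(ep, filter_spec(1, 600)), "cutoffs")
})

test_that("filtering and re-referencing commute", {
  ep <- noise_epochs(n_trials = 2, montage = small_montage(12),
                     n_samples = 300)
  a <- rereference(bandpass_filter(ep, filter_spec(1, 30)), "average")
  b <- bandpass_filter(rereference(ep, "average"), filter_spec(1, 30))
  expect_equal(a$data, b$data, tolerance = 1e-9)
})

test_that("spherical-spline interpolation reconstructs a degree-1 harmonic", {
  mon <- make_montage(64, seed = 3)
  # degree-1 spherical harmonic: linear field v = a . r
  a <- c(0.4, -1, 0.6)
  v <- as.numeric(mon$positions %*% a)
  ep <- one_trial_epochs(cbind(v, v), montage = mon, onset = 2)
  bad <- mon$names[10]
  out <- interpolate_channels(ep, bad)
  err <- abs(out$data[1, 10, 1] - v[10]) / diff(range(v))
  expect_lt(err, 0.02)
  # good channels untouched
  expect_identical(out$data[1, -10, ], ep$data[1, -10, ])
  # all-zero field interpolates to zero; empty bad list is a no-op
  ep0 <- one_trial_epochs(matrix(0, 64, 2), montage = mon, onset = 2)
  expect_lt(max(abs(interpolate_channels(ep0, bad)$data)), 1e-9)
  expect_identical(interpolate_channels(ep, character(0))$data, ep$data)
  expect_error(interpolate_channels(ep, mon$names[1:62]), "too many")
})

test_that("pre-stimulus extraction counts samples and range-checks", {
  ep <- noise_epochs(n_trials = 2, n_samples = 300, onset = 250)
  expect_equal(dim(extract_prestim(ep, 50)$data)[3], 50)
  e200 <- extract_prestim(ep, 200)
  expect_equal(dim(e200$data)[3], 200)
  expect_equal(e200$onset, 200L)
  # the window is the data immediately before onset
  expect_equal(e200$data[1, 1, 200], ep$data[1, 1, 250])
  expect_error(extract_prestim(ep, 300), "exceeds")
})

test_that("amplitude-threshold rejection removes exactly the planted artifacts", {
  mon <- small_montage(16)
  tpl <- make_templates(mon, 2, seed = 1)
  p <- sim_params(n_trials_per_condition = 15, noise_sd = 1,
                  artifacts = list(n_trials = 5, amplitude = 300), seed = 3)
  sim <- simulate_epochs(tpl, mon, p)
  res <- reject_artifacts(sim$epochs, 100)
  expect_identical(res$rejected, sim$truth$artifact_trials)
  expect_equal(dim(res$epochs$data)[1], 25)
  expect_identical(reject_artifacts(sim$epochs, Inf)$rejected, integer(0))
  one_big <- sim$epochs
  one_big$data[] <- 0
  one_big$data[3, 2, 10] <- 150
  expect_identical(reject_artifacts(one_big, 100)$rejected, 3L)
})
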