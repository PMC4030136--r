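test_that("DFT bins, on-bin phase, and the zero-signal flag behave as specified", {
  fs <- 1000
  mon <- small_montage(4)
  n <- 250
  phi <- 0.7
  t_onset <- (seq_len(n) - 250 - 1) / fs       # sample 251 would be t = 0
  x <- cos(2 * pi * 10 * t_onset + phi)
  ep <- one_trial_epochs(rbind(x, x, 2 * x, 0), fs = fs, onset = 250,
                         montage = mon)
  sp <- spectral_estimate(ep, 200)
  expect_equal(sp$freqs[2] - sp$freqs[1], 5)
  # 10 Hz on bin index 2 (third bin)
  expect_equal(sp$freqs[3], 10)
  # phase equals the directly-summed windowed-DFT oracle...
  seg <- x[51:250]
  expect_equal(sp$phase[1, 1, 3], Arg(direct_windowed_dft(seg, 2)),
               tolerance = 1e-9)
  # ...which equals the planted onset phase up to Blackman leakage (~1e-4)
  expect_equal(sp$phase[1, 1, 3], phi, tolerance = 1e-3)
  # power scales with squared amplitude
  expect_equal(sp$power[1, 3, 3] / sp$power[1, 1, 3], 4, tolerance = 1e-9)
  # zero signal: zero power, undefined phase
  expect_equal(sp$power[1, 4, 3], 0)
  expect_true(is.na(sp$phase[1, 4, 3]))
  # off-bin requests are refused
  expect_error(prestim:::spectral_bin(sp, 12), "not on a DFT bin")
})

test_that("power is invariant to a time-constant offset; phase respects references", {
  ep <- noise_epochs(n_trials = 2, montage = small_montage(6),
                     n_samples = 220, onset = 210)
  sp1 <- spectral_estimate(ep, 200)
  ep2 <- ep
  ep2$data <- ep2$data + 17.3                   # constant across time
  sp2 <- spectral_estimate(ep2, 200)
  expect_equal(sp2$power[, , 3], sp1$power[, , 3], tolerance = 1e-9)
  # phase under reference R equals phase of the time-domain difference signal
  reref <- rereference(ep, ep$montage$names[5])
  spr <- spectral_estimate(reref, 200)
  diffsig <- ep
  for (ch in 1:6) diffsig$data[, ch, ] <- ep$data[, ch, ] - ep$data[, 5, ]
  spd <- spectral_estimate(diffsig, 200)
  expect_equal(spr$phase[, -5, 3], spd$phase[, -5, 3], tolerance = 1e-9)
})

test_that("circular means and the Watson-Williams statistic match hand values", {
  cm <- circular_mean(c(0, pi / 2))
  expect_equal(cm$mean, pi / 4)
  expect_equal(cm$R, sqrt(2) / 2)
  expect_equal(circular_mean(1.3)$R, 1)
  expect_true(is.na(circular_mean(c(0, pi))$mean))
  # angles shifted by 2*pi give the same mean and lags
  a <- rvonmises(50, 0.5, 3)
  expect_equal(circular_mean(a)$mean, circular_mean(a + 2 * pi)$mean,
               tolerance = 1e-9)
  # frozen oracle: hand-computed resultants R1 = R2 = 1 + 2 cos(10 deg)
  ww <- watson_williams(c(-10, 0, 10) * pi / 180, c(80, 90, 100) * pi / 180)
  expect_equal(ww$statistic, 115.3685, tolerance = 1e-4)
  expect_lt(ww$p, 0.001)
  expect_equal(ww$df2, 4)
  # identical samples: F = 0, p = 1
  x <- rvonmises(10, 0, 2)
  ww0 <- suppressWarnings(watson_williams(x, x))
  expect_equal(ww0$statistic, 0, tolerance = 1e-9)
  expect_equal(ww0$p, 1, tolerance = 1e-9)
  expect_error(watson_williams(rep(1, 3), rep(1, 3)), "degenerate")
})

test_that("a planted phase offset is flagged at alpha-carrying electrodes", {
  mon <- make_montage(64, seed = 2)
  tpl <- make_templates(mon, 2, seed = 1)
  p <- sim_params(n_trials_per_condition = 30, epoch_ms = 210, onset_ms = 200,
                  alpha = list(amplitude = 3, phase_concentration = 4,
                               condition_phase_offset = pi),
                  noise_sd = 1, seed = 0)
  cohort <- simulate_cohort(8, tpl, mon, p, seed = 21)
  pl <- phase_lag_analysis(cohort, references = list("average"), freq = 10)
  df <- pl[["average"]]
  prof <- occipital_profile(mon)
  strong <- which(abs(prof - mean(prof)) > 0.3)
  expect_gt(sum(df$flagged[strong]), length(strong) * 0.5)
  expect_true(all(abs(df$lag_deg[df$flagged]) > 170))
  # under an electrode reference, that electrode is undefined
  plOz <- phase_lag_analysis(cohort, references = list("Oz"), freq = 10)
  ozi <- match("Oz", mon$names)
  expect_true(is.na(plOz[["Oz"]]$lag_deg[ozi]))
})

test_that("a planted occipital power boost survives FDR in the power contrast", {
  mon <- make_montage(64, seed = 2)
  tpl <- make_templates(mon, 2, seed = 1)
  prof <- occipital_profile(mon)
  occ_ch <- which(prof > 0.5)
  p <- sim_params(n_trials_per_condition = 30, epoch_ms = 210, onset_ms = 200,
                  alpha = list(amplitude = c(CA = 2, CU = 3),
                               phase_concentration = 2,
                               condition_phase_offset = 0),
                  noise_sd = 1, seed = 0)
  hits <- sapply(1:4, function(r) {
    cohort <- simulate_cohort(8, tpl, mon, p, seed = 30 + r)
    tab <- alpha_power_contrast(cohort, freq = 10)
    any(tab$significant[occ_ch] & tab$t[occ_ch] < 0)
  })
  expect_gte(sum(hits), 3)
  # identical condition data: all t = 0
  ep <- noise_epochs(n_trials = 4, montage = small_montage(6),
                     n_samples = 210, onset = 200, seed = 3,
                     conditions = c("CA", "CU", "CA", "CU"))
  ep$data[2, , ] <- ep$data[1, , ]
  ep$data[4, , ] <- ep$data[3, , ]
  tab0 <- alpha_power_contrast(list(ep, ep, ep), freq = 10)
  expect_true(all(abs(tab0$t) < 1e-9))
})
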