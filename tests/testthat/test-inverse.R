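test_that("the 3-shell forward solution degenerates to the homogeneous sphere", {
  mon <- make_montage(64, seed = 3)
  h_eq <- head_model(conductivities = c(scalp = 1, skull = 1, brain = 1))
  pos <- c(0.2, -0.3, 0.35)
  mom <- c(1, -0.5, 0.25)
  v <- dipole_field(mon, h_eq, pos, mom, n_terms = 80)
  # homogeneous-sphere oracle: free-medium series with the (2n+1)/n boundary
  # factor, assembled independently of the package implementation
  b <- sqrt(sum(pos^2)); rhat0 <- pos / b
  x <- pmin(1, pmax(-1, as.numeric(mon$positions %*% rhat0)))
  nt <- 80
  P <- matrix(0, nt, 64); dP <- matrix(0, nt, 64)
  pp <- rep(1, 64); pc <- x; dp <- rep(0, 64); dc <- rep(1, 64)
  P[1, ] <- pc; dP[1, ] <- dc
  for (n in 2:nt) {
    pn <- ((2 * n - 1) * x * pc - (n - 1) * pp) / n
    dn <- dp + (2 * n - 1) * pc
    P[n, ] <- pn; dP[n, ] <- dn
    pp <- pc; pc <- pn; dp <- dc; dc <- dn
  }
  nn <- seq_len(nt)
  wn <- ((2 * nn + 1) / nn) * b^(nn - 1) / (4 * pi)
  m_r <- sum(mom * rhat0)
  vo <- m_r * as.numeric(crossprod(P, wn * nn)) +
    (as.numeric(mon$positions %*% mom) - x * m_r) * as.numeric(crossprod(dP, wn))
  vo <- vo - mean(vo)
  expect_lt(max(abs(v - vo)) / max(abs(vo)), 1e-3)
})

test_that("a central dipole produces a cosine field and depth reduces GFP", {
  mon <- make_montage(128, seed = 1)
  h <- head_model()
  v <- dipole_field(mon, h, c(0, 0, 1e-5), c(0, 0, 1))
  ct <- mon$positions[, 3]
  expect_gt(cor(v, ct - mean(ct)), 1 - 1e-9)
  g1 <- gfp(dipole_field(mon, h, c(0, 0, 0.8), c(1, 0, 0)))
  g2 <- gfp(dipole_field(mon, h, c(0, 0, 0.4), c(1, 0, 0)))
  expect_gt(g1, g2)
  expect_error(dipole_field(mon, h, c(0, 0, 0.9), c(1, 0, 0)), "outside")
})

test_that("lead-field columns are average-referenced and geometry-checked", {
  mon <- make_montage(32, seed = 2)
  h <- head_model()
  src <- source_space(h, spacing = 0.35)
  lf <- compute_leadfield(mon, h, src, n_terms = 40)
  expect_equal(dim(lf$gain), c(32, 3 * src$n_points))
  expect_lt(max(abs(colMeans(lf$gain))), 1e-12)
  bad <- src
  bad$points[1, ] <- c(0, 0, 0.95)
  expect_error(compute_leadfield(mon, h, bad, 40), "outside")
})

test_that("the inverse is linear and reference-invariant", {
  mon <- make_montage(32, seed = 2)
  h <- head_model()
  src <- source_space(h, spacing = 0.3)
  lf <- compute_leadfield(mon, h, src, n_terms = 40)
  op <- build_laura_operator(lf)
  expect_equal(max(estimate_source_magnitudes(rep(0, 32), op)), 0)
  set.seed(5)
  v <- rnorm(32); v <- v - mean(v)
  m1 <- estimate_source_magnitudes(v, op)
  expect_equal(estimate_source_magnitudes(3 * v, op), 3 * m1,
               tolerance = 1e-9)
  # adding a constant to all channels changes nothing
  expect_equal(estimate_source_magnitudes(v + 11, op), m1, tolerance = 1e-9)
})

test_that("lambda shrinks the unstandardized solution monotonically", {
  mon <- make_montage(32, seed = 2)
  h <- head_model()
  src <- source_space(h, spacing = 0.3)
  lf <- compute_leadfield(mon, h, src, n_terms = 40)
  set.seed(2)
  v <- rnorm(32); v <- v - mean(v)
  norms <- sapply(c(0.01, 0.1, 1, 10), function(lr) {
    op <- build_laura_operator(lf, lambda_rel = lr, standardize = FALSE)
    sqrt(sum((op$M %*% v)^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("the resolution matrix concentrates on the diagonal as lambda shrinks", {
  mon <- make_montage(48, seed = 2)
  h <- head_model()
  src <- source_space(h, spacing = 0.3)
  lf <- compute_leadfield(mon, h, src, n_terms = 40)
  # three well-separated points
  set.seed(1)
  far <- c(which.max(src$points[, 2]), which.min(src$points[, 2]),
           which.max(src$points[, 3]))
  dom <- sapply(c(1e-3, 1), function(lr) {
    op <- build_laura_operator(lf, lambda_rel = lr, standardize = FALSE)
    mean(sapply(far, function(j) {
      v <- lf$gain[, 3 * (j - 1) + 1:3] %*% c(0.5, 0.5, 0.7)
      mag <- estimate_source_magnitudes(as.numeric(v), op)
      mag[j] / max(mag)
    }))
  })
  expect_gt(dom[1], dom[2] - 1e-9)
})

test_that("the point-wise contrast handles identical inputs and flags a plant", {
  src <- source_space(head_model(), spacing = 0.3)
  n <- src$n_points
  set.seed(3)
  m <- matrix(abs(rnorm(8 * n)), 8, n)
  spm0 <- spm_contrast(m, m, src)
  expect_true(all(spm0$table$t == 0))
  expect_equal(sum(spm0$table$significant), 0)
  # a strong planted difference at one point is the peak and significant
  m2 <- m
  m2[, 17] <- m2[, 17] + 5
  spm1 <- spm_contrast(m2, m, src)
  expect_equal(spm1$peak, 17)
  expect_true(spm1$table$significant[17])
  expect_gt(spm1$table$t[17], 0)
  expect_error(spm_contrast(m[1, , drop = FALSE], m[1, , drop = FALSE]),
               "subjects")
})
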