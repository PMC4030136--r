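# shared small fixtures and independent oracles

small_montage <- function(n = 32, seed = 1) make_montage(n, seed)

# epochs holding a prescribed channels x samples matrix as a single trial
one_trial_epochs <- function(mat, fs = 1000, onset = ncol(mat),
                             montage = NULL, condition = "CA") {
  if (is.null(montage)) montage <- make_montage(nrow(mat), seed = 1)
  ms_epochs(array(mat, c(1, nrow(mat), ncol(mat))), fs = fs, onset = onset,
            conditions = condition, montage = montage)
}

# exhaustive polarity-invariant 2-means: every sign-free assignment of n maps
# into 2 clusters, templates as dominant eigenvectors, maximal explained
# variance. Independent of the package's clustering path.
brute_force_ev_k2 <- function(X) {
  Xc <- X - rowMeans(X)
  ssq <- sum(Xc^2)
  n <- nrow(Xc)
  best <- -Inf
  expl_one <- function(rows) {
    if (!length(rows)) return(0)
    M <- crossprod(Xc[rows, , drop = FALSE])
    max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  for (code in 0:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n)]
    e <- expl_one(which(lab == 0)) + expl_one(which(lab == 1))
    if (e > best) best <- e
  }
  best / ssq
}

# directly summed Blackman-windowed DFT coefficient at one bin (oracle,
# independent of fft-based code paths)
direct_windowed_dft <- function(x, bin) {
  n <- length(x)
  i <- seq_len(n) - 1
  w <- 0.42 - 0.5 * cos(2 * pi * i / (n - 1)) + 0.08 * cos(4 * pi * i / (n - 1))
  sum(w * x * exp(-2i * pi * bin * i / n))
}

# quick epochs filled with white noise
noise_epochs <- function(n_trials = 4, montage = small_montage(), fs = 1000,
                         n_samples = 250, onset = n_samples, sd = 1, seed = 1,
                         conditions = NULL) {
  set.seed(seed)
  if (is.null(conditions))
    conditions <- rep(c("CA", "CU"), length.out = n_trials)
  ms_epochs(array(rnorm(n_trials * montage$n_channels * n_samples, sd = sd),
                  c(n_trials, montage$n_channels, n_samples)),
            fs = fs, onset = onset, conditions = conditions, montage = montage)
}
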