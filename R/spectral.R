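#' Blackman window
#'
#' \eqn{w[n] = 0.42 - 0.5 \cos(2\pi n/(N-1)) + 0.08 \cos(4\pi n/(N-1))},
#' n = 0..N-1 (symmetric form).
#'
#' @param n window length.
#' @export
blackman_window <- function(n) {
  i <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * i / (n - 1)) + 0.08 * cos(4 * pi * i / (n - 1))
}

#' Blackman-windowed DFT of the pre-stimulus window
#'
#' Per trial and channel: the last \code{window_ms} of pre-stimulus data is
#' demeaned over the window (so static electrode offsets cannot leak through
#' the window's DC lobe into low-frequency bins), multiplied by a Blackman
#' window and transformed with a plain DFT (no zero-padding, so the bin
#' spacing is 1/window length). Power is
#' \eqn{|X_k|^2} and phase \eqn{\arg X_k}; with the default 200 ms window at
#' 1000 Hz the bin spacing is 5 Hz and 10 Hz falls exactly on bin index 2.
#' The phase convention makes the phase of an on-bin cosine equal its phase
#' at stimulus onset whenever the window length is an integer number of
#' cycles.
#'
#' @param epochs an \code{ms_epochs}.
#' @param window_ms analysis window before onset (default 200).
#' @return object of class \code{ms_spectrum}: \code{power} and \code{phase}
#'   arrays (trial x channel x bin), \code{freqs} (Hz), conditions, window
#'   name. Phase is NA where power is numerically zero.
#' @export
spectral_estimate <- function(epochs, window_ms = 200) {
  w <- round(window_ms * epochs$fs / 1000)
  if (w > epochs$onset)
    stop("window exceeds available pre-stimulus data")
  idx <- seq.int(epochs$onset - w + 1, epochs$onset)
  win <- blackman_window(w)
  nb <- floor(w / 2) + 1
  d <- dim(epochs$data)
  power <- array(0, c(d[1], d[2], nb))
  phase <- array(0, c(d[1], d[2], nb))
  for (tr in seq_len(d[1])) {
    seg <- t(epochs$data[tr, , idx, drop = TRUE])         # samples x channels
    seg <- sweep(seg, 2, colMeans(seg)) * win
    X <- stats::mvfft(seg)[seq_len(nb), , drop = FALSE]
    power[tr, , ] <- t(Mod(X)^2)
    phase[tr, , ] <- t(Arg(X))
  }
  phase[power < 1e-20] <- NA
  structure(list(power = power, phase = phase,
                 freqs = (seq_len(nb) - 1) * epochs$fs / w,
                 window = "blackman", fs = epochs$fs,
                 conditions = epochs$conditions,
                 channel_names = epochs$montage$names),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> ", dim(x$power)[1], " trials x ", dim(x$power)[2],
      " channels; bins ", x$freqs[1], "..", x$freqs[length(x$freqs)],
      " Hz, spacing ", x$freqs[2] - x$freqs[1], " Hz (", x$window,
      " window)\n", sep = "")
  invisible(x)
}

# bin index of an exact DFT frequency; no interpolation by design
spectral_bin <- function(spec, freq) {
  i <- which(abs(spec$freqs - freq) < 1e-9)
  if (!length(i))
    stop(freq, " Hz is not on a DFT bin (spacing ",
         spec$freqs[2] - spec$freqs[1], " Hz); no interpolation is done")
  i
}

#' Circular mean direction and resultant length
#'
#' @param angles radians.
#' @return list: \code{mean} (radians in (-pi, pi], NA when the resultant
#'   vanishes), \code{R} (mean resultant length in [0, 1]).
#' @export
circular_mean <- function(angles) {
  if (!length(angles)) stop("need >= 1 angle")
  z <- mean(exp(1i * angles))
  R <- Mod(z)
  list(mean = if (R < 1e-12) NA_real_ else Arg(z), R = R)
}

# maximum-likelihood von Mises concentration from a resultant length
# (Fisher/Best approximations, as in the CircStat toolbox)
circ_kappa <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analogue of the two-sample test:
#' \eqn{F = K (N-2)(R_1 + R_2 - R) / (N - R_1 - R_2)} with
#' \eqn{K = 1 + 3/(8\hat\kappa)}, where \eqn{R_1, R_2, R} are the within-
#' sample and pooled resultant lengths and \eqn{\hat\kappa} is estimated
#' from the weighted mean within-sample resultant. p from F(1, N-2). A
#' warning is issued when the mean resultant is below 0.45 (the
#' concentration assumptions of the test are then doubtful).
#'
#' @param angles_a,angles_b samples of angles (radians), each of size >= 2.
#' @return list of class \code{ms_test}: statistic (F), df1, df2, p.
#' @export
watson_williams <- function(angles_a, angles_b) {
  n1 <- length(angles_a); n2 <- length(angles_b)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 angles")
  N <- n1 + n2
  R1 <- n1 * circular_mean(angles_a)$R
  R2 <- n2 * circular_mean(angles_b)$R
  R <- N * circular_mean(c(angles_a, angles_b))$R
  rw <- (R1 + R2) / N
  if (rw < 0.45)
    warning("mean resultant length ", sprintf("%.3f", rw),
            " < 0.45: Watson-Williams assumptions doubtful")
  denom <- N - (R1 + R2)
  if (denom < 1e-12)
    stop("degenerate samples (no within-sample dispersion)")
  kk <- circ_kappa(rw)
  K <- 1 + 3 / (8 * kk)
  Fstat <- K * ((N - 2) * (R1 + R2 - R)) / denom
  structure(list(statistic = Fstat, df1 = 1, df2 = N - 2,
                 p = stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)),
            class = "ms_test")
}

# circular difference a - b wrapped to (-pi, pi]
circ_diff <- function(a, b) wrap_angle(a - b)

# per-subject, per-channel, per-condition mean phase at one frequency
subject_mean_phases <- function(epochs, freq, window_ms) {
  sp <- spectral_estimate(epochs, window_ms)
  bin <- spectral_bin(sp, freq)
  ph <- sp$phase[, , bin, drop = TRUE]
  if (n_trials(epochs) == 1) ph <- matrix(ph, nrow = 1)
  sapply(c("CA", "CU"), function(cond) {
    rows <- which(epochs$conditions == cond)
    apply(ph[rows, , drop = FALSE], 2, function(a) {
      a <- a[!is.na(a)]
      if (!length(a)) return(NA_real_)
      circular_mean(a)$mean
    })
  })
}

#' Per-electrode phase-lag analysis under multiple references
#'
#' For each reference scheme: re-reference, extract Blackman-DFT phase at
#' \code{freq}, compute each subject's mean phase angle per condition and
#' electrode, then test CA vs CU mean directions per electrode with a
#' Watson-Williams test across subjects. The lag is the circular difference
#' of the group mean phases (CA - CU, degrees); electrodes with a
#' significant test and |lag| above \code{flag_deg} are flagged as
#' near-inversion.
#'
#' @param cohort list of \code{ms_epochs} (or of \code{list(epochs = ...)}).
#' @param references list of \code{\link{reference_scheme}}s or kind/label
#'   strings (default the five standard references).
#' @param freq analysis frequency (must be on-bin; default 10 Hz).
#' @param window_ms spectral window (default 200).
#' @param flag_deg near-inversion threshold in degrees (default 170).
#' @param alpha per-electrode significance level (default 0.05).
#' @param fdr apply BH correction across electrodes (default FALSE,
#'   matching electrode-count reporting on raw p values).
#' @return named list (one entry per reference) of data.frames: channel,
#'   mean_CA, mean_CU (radians), lag_deg, F, p, significant, flagged.
#' @export
phase_lag_analysis <- function(cohort,
                               references = list("average", "mastoids",
                                                 "Fpz", "Cz", "Oz"),
                               freq = 10, window_ms = 200, flag_deg = 170,
                               alpha = 0.05, fdr = FALSE) {
  cohort <- lapply(cohort, function(s) if (inherits(s, "ms_epochs")) s
                                       else s$epochs)
  ref_name <- vapply(references, function(r)
    if (is.character(r)) r else paste(r$kind, r$electrode), "")
  out <- lapply(references, function(ref) {
    per_subj <- lapply(cohort, function(ep)
      subject_mean_phases(rereference(ep, ref), freq, window_ms))
    C <- nrow(per_subj[[1]])
    ca <- sapply(per_subj, function(m) m[, "CA"])   # channels x subjects
    cu <- sapply(per_subj, function(m) m[, "CU"])
    res <- lapply(seq_len(C), function(ch) {
      a <- ca[ch, ]; b <- cu[ch, ]
      if (anyNA(a) || anyNA(b))
        return(data.frame(mean_CA = NA, mean_CU = NA, lag_deg = NA,
                          F = NA, p = NA))
      ww <- suppressWarnings(watson_williams(a, b))
      mA <- circular_mean(a)$mean
      mB <- circular_mean(b)$mean
      data.frame(mean_CA = mA, mean_CU = mB,
                 lag_deg = circ_diff(mA, mB) * 180 / pi,
                 F = ww$statistic, p = ww$p)
    })
    df <- cbind(channel = cohort[[1]]$montage$names, do.call(rbind, res))
    df$significant <- if (fdr) bh_fdr(df$p, alpha)$significant
                      else !is.na(df$p) & df$p < alpha
    df$flagged <- df$significant & !is.na(df$lag_deg) &
      abs(df$lag_deg) > flag_deg
    df
  })
  names(out) <- ref_name
  out
}

#' Per-channel condition contrast of alpha power
#'
#' Per-subject mean power at \code{freq} per condition and channel, paired
#' t tests across subjects per channel, BH-FDR across channels. Positive t
#' means more power in the CA condition.
#'
#' @param cohort list of \code{ms_epochs} (or of \code{list(epochs = ...)}).
#' @param trial_subset optional list (per subject) of trial indices entering
#'   the contrast (e.g., trials labeled with specific microstate maps).
#' @param freq analysis frequency (default 10 Hz).
#' @param window_ms spectral window (default 200).
#' @param q FDR level (default 0.05).
#' @param reference reference applied before the spectral estimate
#'   (default average).
#' @return data.frame: channel, t, p, p_adj, significant.
#' @export
alpha_power_contrast <- function(cohort, trial_subset = NULL, freq = 10,
                                 window_ms = 200, q = 0.05,
                                 reference = "average") {
  cohort <- lapply(cohort, function(s) if (inherits(s, "ms_epochs")) s
                                       else s$epochs)
  per_subj <- lapply(seq_along(cohort), function(s) {
    ep <- rereference(cohort[[s]], reference)
    sp <- spectral_estimate(ep, window_ms)
    bin <- spectral_bin(sp, freq)
    pw <- sp$power[, , bin, drop = TRUE]
    if (n_trials(ep) == 1) pw <- matrix(pw, nrow = 1)
    keep <- if (is.null(trial_subset)) seq_len(nrow(pw)) else trial_subset[[s]]
    conds <- ep$conditions[keep]
    if (!all(c("CA", "CU") %in% conds))
      stop("both conditions must be present in the trial subset (subject ",
           s, ")")
    pw <- pw[keep, , drop = FALSE]
    rbind(CA = colMeans(pw[conds == "CA", , drop = FALSE]),
          CU = colMeans(pw[conds == "CU", , drop = FALSE]))
  })
  ca <- t(sapply(per_subj, function(m) m["CA", ]))   # subjects x channels
  cu <- t(sapply(per_subj, function(m) m["CU", ]))
  ns <- nrow(ca)
  if (ns < 2) stop("need >= 2 subjects")
  d <- ca - cu
  mu <- colMeans(d)
  sdv <- sqrt(colSums(sweep(d, 2, mu)^2) / (ns - 1))
  tt <- mu / (sdv / sqrt(ns))
  tt[sdv == 0 & mu == 0] <- 0
  p <- p_from_t(tt, ns - 1)
  fdr <- bh_fdr(p, q)
  data.frame(channel = cohort[[1]]$montage$names, t = tt, p = p,
             p_adj = fdr$p_adjusted, significant = fdr$significant)
}
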