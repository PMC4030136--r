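#' Reference scheme
#'
#' @param kind one of \code{"average"}, \code{"mastoids"}, \code{"electrode"}.
#' @param electrode electrode label (for \code{kind = "electrode"}).
#' @param mastoids pair of labels; defaults to the montage designation at
#'   application time.
#' @export
reference_scheme <- function(kind = c("average", "mastoids", "electrode"),
                             electrode = NULL, mastoids = NULL) {
  kind <- match.arg(kind)
  if (kind == "electrode" && is.null(electrode))
    stop("electrode reference needs an electrode label")
  structure(list(kind = kind, electrode = electrode, mastoids = mastoids),
            class = "ms_reference")
}

#' Re-reference epochs
#'
#' Linear, per-sample reference transform: common average (per-sample channel
#' mean subtracted), averaged mastoids, or a single electrode.
#'
#' @param epochs an \code{ms_epochs}.
#' @param scheme an \code{\link{reference_scheme}} or one of its kind strings.
#' @return re-referenced \code{ms_epochs}.
#' @export
rereference <- function(epochs, scheme = "average") {
  if (is.character(scheme)) {
    scheme <- if (scheme %in% c("average", "mastoids"))
      reference_scheme(scheme) else reference_scheme("electrode", scheme)
  }
  x <- epochs$data
  ref <- switch(
    scheme$kind,
    average = apply(x, c(1, 3), mean),
    mastoids = {
      mast <- scheme$mastoids
      if (is.null(mast)) mast <- epochs$montage$mastoids
      if (is.null(mast) || length(mast) != 2)
        stop("no mastoid pair designated for this montage")
      idx <- match_channel(epochs$montage, mast)
      (x[, idx[1], , drop = FALSE][, 1, ] + x[, idx[2], , drop = FALSE][, 1, ]) / 2
    },
    electrode = {
      idx <- match_channel(epochs$montage, scheme$electrode)
      x[, idx, , drop = FALSE][, 1, ]
    })
  if (n_trials(epochs) == 1) ref <- matrix(ref, nrow = 1)
  for (ch in seq_len(dim(x)[2])) x[, ch, ] <- x[, ch, ] - ref
  epochs$data <- x
  epochs
}

#' Band-pass filter specification
#'
#' Butterworth band-pass applied in two passes (forward and backward) for
#' zero phase; the default order 2 gives a -12 dB/octave roll-off per pass.
#'
#' @param low_hz,high_hz cutoff frequencies.
#' @param order filter order (default 2).
#' @export
filter_spec <- function(low_hz = 1, high_hz = 30, order = 2) {
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "ms_filter")
}

# two-pass (zero-phase) filtering of one signal with reflect padding
# of 3 x the filter length per pass
filtfilt_reflect <- function(b, a, x) {
  np <- min(3 * (max(length(a), length(b)) - 1), length(x) - 1)
  as.numeric(iir_filtfilt_mat(b, a, matrix(x, ncol = 1), np))
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Each channel of each trial is filtered forward and backward with the same
#' Butterworth band-pass, eliminating phase shifts; epoch edges are handled
#' by reflect padding. Apply before window extraction so the short analysis
#' windows are not edge-dominated.
#'
#' @param epochs an \code{ms_epochs}.
#' @param spec a \code{\link{filter_spec}}.
#' @return filtered \code{ms_epochs}.
#' @export
bandpass_filter <- function(epochs, spec = filter_spec()) {
  fs <- epochs$fs
  if (!(spec$low_hz > 0 && spec$low_hz < spec$high_hz && spec$high_hz < fs / 2))
    stop("cutoffs must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  x <- epochs$data
  d <- dim(x)
  np <- min(3 * (max(length(bf$a), length(bf$b)) - 1), d[3] - 1)
  for (tr in seq_len(d[1]))
    x[tr, , ] <- t(iir_filtfilt_mat(bf$b, bf$a, t(x[tr, , , drop = TRUE]), np))
  epochs$data <- x
  epochs
}

# Perrin g function values for a vector of cos(angle), order m, n_terms terms
spline_g <- function(cosang, m = 4, n_terms = 50) {
  # Legendre P_n(x) by recurrence, accumulate (2n+1)/(n(n+1))^m P_n(x)
  x <- cosang
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur
    p_cur <- p_new
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Bad channels are replaced, per sample, by Perrin spherical-spline
#' estimates computed from the good channels. The spline system is solved
#' with a small ridge term for numerical stability.
#'
#' @param epochs an \code{ms_epochs}.
#' @param bad character vector of bad-channel labels (or integer indices).
#' @param m spline order (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @param lambda_reg ridge term added to the spline system (default 1e-5).
#' @return \code{ms_epochs} with bad channels replaced; good channels
#'   untouched.
#' @export
interpolate_channels <- function(epochs, bad, m = 4, n_terms = 50,
                                 lambda_reg = 1e-5) {
  if (length(bad) == 0) return(epochs)
  bad_idx <- if (is.character(bad)) match_channel(epochs$montage, bad)
             else as.integer(bad)
  C <- epochs$montage$n_channels
  if (length(bad_idx) >= C - 3)
    stop("too many bad channels to interpolate")
  good <- setdiff(seq_len(C), bad_idx)
  P <- epochs$montage$positions
  Ggg <- spline_g(tcrossprod(P[good, , drop = FALSE]), m, n_terms)
  Gbg <- spline_g(P[bad_idx, , drop = FALSE] %*% t(P[good, , drop = FALSE]),
                  m, n_terms)
  ng <- length(good)
  # [G + lambda I, 1; 1', 0] [c; c0] = [v; 0]
  A <- rbind(cbind(Ggg + diag(lambda_reg, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  x <- epochs$data
  d <- dim(x)
  for (tr in seq_len(d[1])) {
    # solve all samples at once: rhs columns are per-sample good-channel fields
    sol <- solve(A, rbind(matrix(x[tr, good, ], ng, d[3]), 0))
    cc <- sol[seq_len(ng), , drop = FALSE]
    c0 <- sol[ng + 1, ]
    x[tr, bad_idx, ] <- Gbg %*% cc + rep(c0, each = length(bad_idx))
  }
  epochs$data <- x
  epochs
}

#' Extract the pre-stimulus window
#'
#' Restricts the data to the half-open window of \code{window_ms} immediately
#' preceding stimulus onset.
#'
#' @param epochs an \code{ms_epochs}.
#' @param window_ms window length in milliseconds.
#' @return \code{ms_epochs} containing only the pre-stimulus window; the
#'   stored onset becomes the window end.
#' @export
extract_prestim <- function(epochs, window_ms) {
  w <- round(window_ms * epochs$fs / 1000)
  if (w > epochs$onset)
    stop("window (", window_ms, " ms) exceeds available pre-stimulus data (",
         round(epochs$onset / epochs$fs * 1000), " ms)")
  idx <- seq.int(epochs$onset - w + 1, epochs$onset)
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$onset <- w
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Removes trials whose absolute voltage exceeds the threshold on any
#' channel at any sample.
#'
#' @param epochs an \code{ms_epochs}.
#' @param abs_threshold_uv rejection threshold in microvolts (default 100).
#' @return list with \code{epochs} (retained trials), \code{rejected}
#'   (indices of removed trials) and \code{retained_per_condition}.
#' @export
reject_artifacts <- function(epochs, abs_threshold_uv = 100) {
  if (abs_threshold_uv <= 0) stop("threshold must be > 0")
  mx <- apply(abs(epochs$data), 1, max)
  rej <- which(mx > abs_threshold_uv)
  if (length(rej) == n_trials(epochs))
    stop("all trials rejected at threshold ", abs_threshold_uv, " uV")
  if (length(rej)) {
    epochs$data <- epochs$data[-rej, , , drop = FALSE]
    epochs$conditions <- epochs$conditions[-rej]
  }
  list(epochs = epochs, rejected = rej,
       retained_per_condition = table(epochs$conditions))
}
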