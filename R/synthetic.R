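#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used for planted trial phases and for
#' between-subject phase spread; \code{kappa = 0} gives the circular uniform,
#' \code{kappa = Inf} a point mass at \code{mu}.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(wrap_angle(rep(mu, n)))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5)[ok] * acos(pmin(1, pmax(-1, f[ok])))
    take <- min(length(theta), n - got)
    if (take > 0) out[got + seq_len(take)] <- theta[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + mu)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Occipitally weighted spatial profile
#'
#' Gaussian (in angular distance) scalp profile centred on the occipital
#' pole, used as the default alpha-band topography of the generator.
#'
#' @param montage an \code{ms_montage}.
#' @param centre unit vector of the profile centre (default: occipital pole).
#' @param width angular SD in radians.
#' @return per-channel weights in [0, 1], max 1.
#' @export
occipital_profile <- function(montage, centre = c(0, -0.9239, 0.3827),
                              width = 0.5) {
  centre <- centre / sqrt(sum(centre^2))
  ang <- acos(pmin(1, pmax(-1, montage$positions %*% centre)))
  as.numeric(exp(-ang^2 / (2 * width^2)))
}

#' Planted microstate template maps
#'
#' Templates are average-referenced, unit-norm forward fields of randomly
#' placed intracranial dipoles, so that planted topographies are physically
#' plausible scalp fields. Templates are re-drawn until all pairwise absolute
#' spatial correlations are at or below \code{max_abs_corr}.
#'
#' @param montage an \code{ms_montage}.
#' @param k number of templates (>= 1).
#' @param leadfield optional \code{ms_leadfield} whose source points are used
#'   as candidate dipole locations; when \code{NULL}, dipoles are placed at
#'   random interior locations and their fields computed analytically.
#' @param seed integer seed.
#' @param head head model for the analytic fields (default
#'   \code{head_model()}).
#' @param max_abs_corr distinctness ceiling on pairwise |spatial correlation|.
#' @param retries resampling attempts before giving up.
#' @return channels x k matrix; each column zero-mean, unit L2 norm.
#' @export
make_templates <- function(montage, k, leadfield = NULL, seed = 1,
                           head = head_model(), max_abs_corr = 0.7,
                           retries = 200) {
  if (k < 1) stop("k must be >= 1")
  set.seed(as.integer(seed))
  draw_one <- function() {
    if (!is.null(leadfield)) {
      if (nrow(leadfield$gain) != montage$n_channels)
        stop("leadfield channels do not match montage")
      j <- sample.int(leadfield$n_points, 1)
      m <- stats::rnorm(3)
      v <- leadfield$gain[, 3 * (j - 1) + 1:3] %*% (m / sqrt(sum(m^2)))
    } else {
      rmax <- 0.8 * min(head$radii)
      repeat {
        p <- stats::runif(3, -rmax, rmax)
        if (sum(p^2) < rmax^2 && sum(p^2) > 0.01) break
      }
      m <- stats::rnorm(3)
      v <- dipole_field(montage, head, p, m / sqrt(sum(m^2)))
    }
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) return(NULL)
    as.numeric(v / nv)
  }
  tpl <- matrix(0, montage$n_channels, k)
  for (j in seq_len(k)) {
    ok <- FALSE
    for (a in seq_len(retries)) {
      v <- draw_one()
      if (is.null(v)) next
      if (j == 1 ||
          max(abs(crossprod(tpl[, seq_len(j - 1), drop = FALSE], v))) <= max_abs_corr) {
        tpl[, j] <- v
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not satisfy template distinctness after ", retries,
                  " retries")
  }
  colnames(tpl) <- paste0("T", seq_len(k))
  tpl
}

#' Default generator parameters
#'
#' Study conditions emulated by the generator: 204-channel average-referenced
#' epochs at 1000 Hz, at least 200 ms of pre-stimulus data, quasi-stable
#' topographic states of 80-120 ms, a 10 Hz component with condition-dependent
#' phase, and a condition-dependent occipital source amplitude.
#'
#' \code{state_amplitude} is the planted peak GFP (microvolts) of the
#' microstate component; \code{noise_sd} is the per-channel SD of white
#' sensor noise, default 0.3 x state amplitude.
#'
#' @param ... overrides merged into the defaults (nested lists merged one
#'   level deep for \code{alpha}, \code{diff_source}, \code{artifacts}).
#' @export
sim_params <- function(...) {
  p <- list(
    n_trials_per_condition = 150,
    fs = 1000,
    epoch_ms = 300,
    onset_ms = 250,
    duration_range = c(80, 120),
    state_amplitude = 5,
    envelope_freq = 10,
    state_prob = NULL,
    alpha = list(freq = 10, amplitude = 2, phase_concentration = 2,
                 condition_phase_offset = pi, mean_phase = 0,
                 spatial_profile = NULL),
    diff_source = list(location = "occipital", amplitude_CA = 0,
                       amplitude_CU = 0, freq = 6),
    noise_sd = 1.5,
    artifacts = list(n_trials = 0, amplitude = 200),
    seed = 1)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("alpha", "diff_source", "artifacts") && is.list(ov[[nm]])) {
      p[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else p[[nm]] <- ov[[nm]]
  }
  p
}

# condition-specific value from a scalar or c(CA=,CU=) parameter
cond_value <- function(x, cond) {
  if (length(x) == 1) return(unname(x))
  if (!all(c("CA", "CU") %in% names(x)))
    stop("per-condition parameters need names CA and CU")
  unname(x[[cond]])
}

#' Simulate epoched EEG with planted ground truth
#'
#' Each trial is the sum of (a) a piecewise-constant sequence of planted
#' template maps, each scaled by a rectified-sinusoid strength envelope so
#' that GFP shows clear local maxima, (b) an alpha-band sinusoid whose phase
#' at stimulus onset is von Mises across trials with a condition-dependent
#' mean direction, projected through a spatial profile, (c) the forward field
#' of a designated differential source scaled per condition, and (d) white
#' Gaussian sensor noise. Fully deterministic given \code{params$seed}.
#'
#' @param templates channels x k matrix of planted maps
#'   (\code{\link{make_templates}}).
#' @param montage an \code{ms_montage}.
#' @param params list from \code{\link{sim_params}}.
#' @param leadfield optional \code{ms_leadfield}; required when
#'   \code{params$diff_source} amplitudes are nonzero and its location is a
#'   source-point index or \code{"occipital"}.
#' @param subject_id stored in the result.
#' @return list with \code{epochs} (an \code{ms_epochs}) and \code{truth}
#'   (state sequence per trial x sample, planted templates, onset phases,
#'   per-condition source amplitudes, artifact trials, seed).
#' @export
simulate_epochs <- function(templates, montage, params = sim_params(),
                            leadfield = NULL, subject_id = "S01") {
  if (nrow(templates) != montage$n_channels)
    stop("templates and montage disagree on channel count")
  p <- params
  if (p$onset_ms < 200) stop("at least 200 ms of pre-stimulus data required")
  if (p$n_trials_per_condition < 1) stop("need >= 1 trial per condition")
  set.seed(as.integer(p$seed))
  fs <- p$fs
  S <- round(p$epoch_ms * fs / 1000)
  onset <- round(p$onset_ms * fs / 1000)
  k <- ncol(templates)
  C <- montage$n_channels
  ntr <- 2 * p$n_trials_per_condition
  conditions <- rep(c("CA", "CU"), each = p$n_trials_per_condition)

  # alpha setup; phase convention: planted phase is the cosine phase at onset
  prof <- p$alpha$spatial_profile
  if (is.null(prof)) prof <- occipital_profile(montage)
  tvec <- (seq_len(S) - onset - 1) / fs           # sample onset+1 is t = 0
  mu_CA <- p$alpha$mean_phase
  mu_by_cond <- c(CA = mu_CA, CU = mu_CA + p$alpha$condition_phase_offset)

  # differential source field (unit map; scaled per condition)
  diff_amp <- c(CA = p$diff_source$amplitude_CA, CU = p$diff_source$amplitude_CU)
  diff_map <- NULL
  if (any(diff_amp != 0)) {
    diff_map <- resolve_diff_field(p$diff_source, montage, leadfield)
  }

  dur_smp <- round(p$duration_range / 1000 * fs)
  amp_scale <- p$state_amplitude * sqrt(C)

  data <- array(0, dim = c(ntr, C, S))
  state_seq <- matrix(0L, ntr, S)
  phases <- numeric(ntr)
  for (tr in seq_len(ntr)) {
    cond <- conditions[tr]
    prob <- if (is.null(p$state_prob)) rep(1 / k, k) else {
      pr <- if (is.list(p$state_prob)) p$state_prob[[cond]] else p$state_prob
      pr / sum(pr)
    }
    # piecewise-constant state sequence, no immediate repetitions, built
    # backward from the epoch end so the state covering stimulus onset is
    # drawn from the configured occurrence probabilities (only the first,
    # epoch-initial segment is truncated)
    seq_i <- integer(S)
    pos <- S
    nxt <- 0L
    while (pos >= 1L) {
      d <- sample(seq.int(dur_smp[1], dur_smp[2]), 1)
      pr2 <- prob
      if (k > 1 && nxt > 0L) { pr2[nxt] <- 0; pr2 <- pr2 / sum(pr2) }
      st <- sample.int(k, 1, prob = pr2)
      seq_i[max(1L, pos - d + 1L):pos] <- st
      nxt <- st
      pos <- pos - d
    }
    state_seq[tr, ] <- seq_i
    env <- abs(sin(2 * pi * p$envelope_freq * (seq_len(S) - 1) / fs +
                     stats::runif(1, 0, pi)))
    sig <- templates[, seq_i, drop = FALSE] *
      rep(amp_scale * env, each = C)

    phi <- rvonmises(1, mu_by_cond[[cond]], p$alpha$phase_concentration)
    phases[tr] <- phi
    a_amp <- cond_value(p$alpha$amplitude, cond)
    if (a_amp != 0)
      sig <- sig + outer(prof * a_amp, cos(2 * pi * p$alpha$freq * tvec + phi))
    if (!is.null(diff_map) && diff_amp[[cond]] != 0)
      sig <- sig + outer(diff_map * diff_amp[[cond]],
                         cos(2 * pi * p$diff_source$freq * tvec +
                               stats::runif(1, 0, 2 * pi)))
    if (p$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(C * S, sd = p$noise_sd), C, S)
    data[tr, , ] <- sig
  }

  artifact_trials <- integer(0)
  if (p$artifacts$n_trials > 0) {
    artifact_trials <- sort(sample.int(ntr, p$artifacts$n_trials))
    for (tr in artifact_trials) {
      ch <- sample.int(C, 1)
      at <- sample.int(S - 30, 1)
      data[tr, ch, at:(at + 29)] <- data[tr, ch, at:(at + 29)] +
        p$artifacts$amplitude * sin(pi * (0:29) / 29)
    }
  }

  epochs <- ms_epochs(data, fs = fs, onset = onset, conditions = conditions,
                      montage = montage, subject_id = subject_id)
  truth <- list(state_sequence = state_seq, templates = templates,
                alpha_phase_at_onset = phases,
                alpha_mean_phase = mu_by_cond,
                source_amplitudes = diff_amp,
                diff_field = diff_map,
                diff_source_point = attr(diff_map, "point"),
                artifact_trials = artifact_trials,
                conditions = conditions, seed = p$seed)
  list(epochs = epochs, truth = truth)
}

# unit-norm scalp field of the configured differential source
resolve_diff_field <- function(ds, montage, leadfield) {
  loc <- ds$location
  if (is.character(loc) && identical(loc, "occipital")) {
    if (is.null(leadfield))
      stop("diff_source location 'occipital' needs a leadfield")
    occ <- which(leadfield$sources$occipital)
    if (!length(occ)) stop("source space has no occipital points")
    # a point well inside the occipital region, towards the posterior pole
    target <- c(0, -0.75 * leadfield$sources$rmax, 0)
    loc <- occ[which.min(rowSums(sweep(
      leadfield$sources$points[occ, , drop = FALSE], 2, target)^2))]
  }
  j <- NA_integer_
  if (length(loc) == 1) {
    if (is.null(leadfield)) stop("point-index diff_source needs a leadfield")
    j <- as.integer(loc)
    rhat <- leadfield$sources$points[j, ]
    rhat <- rhat / sqrt(sum(rhat^2))
    v <- leadfield$gain[, 3 * (j - 1) + 1:3] %*% rhat
  } else {
    v <- dipole_field(montage, head_model(), loc, loc / sqrt(sum(loc^2)))
  }
  v <- v - mean(v)
  structure(as.numeric(v / sqrt(sum(v^2))), point = j)
}

#' Simulate a multi-subject cohort
#'
#' Subjects share the planted templates and condition structure; each
#' subject's baseline alpha phase is drawn from a von Mises around zero with
#' concentration \code{between_subject_kappa}, and each subject gets an
#' independent derived seed.
#'
#' @param n_subjects number of subjects (default 11).
#' @param templates planted template matrix.
#' @param montage an \code{ms_montage}.
#' @param params generator parameters (\code{\link{sim_params}}).
#' @param leadfield optional leadfield passed through.
#' @param between_subject_kappa concentration of subject baseline phases.
#' @param seed master seed.
#' @return list of per-subject \code{list(epochs, truth)}.
#' @export
simulate_cohort <- function(n_subjects = 11, templates, montage,
                            params = sim_params(), leadfield = NULL,
                            between_subject_kappa = 8, seed = 1) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  base_phase <- rvonmises(n_subjects, 0, between_subject_kappa)
  lapply(seq_len(n_subjects), function(s) {
    ps <- params
    ps$seed <- seeds[s]
    ps$alpha$mean_phase <- base_phase[s]
    simulate_epochs(templates, montage, ps, leadfield = leadfield,
                    subject_id = sprintf("S%02d", s))
  })
}

#' Simulate a behavioral trial log
#'
#' Metacontrast-masking style log: per trial a target (square/diamond), a
#' response, an awareness report and a reaction time, with accuracy and
#' awareness rates depending on the target-mask ISI and a planted RT
#' difference between correct-aware and correct-unaware trials.
#'
#' @param n_trials total trials (spread evenly over ISIs).
#' @param isi_ms ISI levels.
#' @param p_correct accuracy per ISI.
#' @param p_aware_correct probability of an aware report on correct trials.
#' @param rt_ca,rt_cu mean RT (ms) for correct-aware / correct-unaware.
#' @param rt_sd trial RT standard deviation.
#' @param seed integer seed.
#' @return data.frame: trial, ISI_ms, truth, response, aware, RT_ms.
#' @export
simulate_behavior_log <- function(n_trials = 784,
                                  isi_ms = c(39, 52, 65, 104),
                                  p_correct = c(0.73, 0.76, 0.80, 0.95),
                                  p_aware_correct = c(0.5, 0.62, 0.72, 0.95),
                                  rt_ca = 665, rt_cu = 819, rt_sd = 150,
                                  seed = 1) {
  set.seed(as.integer(seed))
  isi <- sample(rep(isi_ms, length.out = n_trials))
  ii <- match(isi, isi_ms)
  truth <- sample(c("square", "diamond"), n_trials, replace = TRUE)
  correct <- stats::runif(n_trials) < p_correct[ii]
  response <- ifelse(correct, truth,
                     ifelse(truth == "square", "diamond", "square"))
  aware <- ifelse(correct,
                  stats::runif(n_trials) < p_aware_correct[ii],
                  stats::runif(n_trials) < 0.25)
  rt <- ifelse(correct & aware, rt_ca,
               ifelse(correct & !aware, rt_cu, (rt_ca + rt_cu) / 2)) +
    stats::rnorm(n_trials, 0, rt_sd)
  data.frame(trial = seq_len(n_trials), ISI_ms = isi, truth = truth,
             response = response, aware = aware, RT_ms = pmax(150, rt))
}
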