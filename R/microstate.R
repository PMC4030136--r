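#' Global field power
#'
#' Spatial standard deviation of the potential field at one time point,
#' population (divide-by-N) convention:
#' \eqn{GFP = \sqrt{\sum_i (u_i - \bar u)^2 / N}}.
#'
#' @param x channel vector, or a channels x samples matrix (one GFP value
#'   per column).
#' @return scalar (vector input) or per-sample vector (matrix input), in the
#'   units of \code{x}.
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("need >= 2 channels")
    xc <- sweep(x, 2, colMeans(x))
    return(sqrt(colSums(xc^2) / nrow(x)))
  }
  if (length(x) < 2) stop("need >= 2 channels")
  sqrt(sum((x - mean(x))^2) / length(x))
}

#' Strength-independent spatial correlation between two maps
#'
#' Pearson-type correlation of the mean-removed channel vectors; with
#' \code{polarity_invariant = TRUE} the absolute value is returned, since
#' spontaneous-EEG topographies are defined up to polarity.
#'
#' @param u,v channel vectors of equal length.
#' @param polarity_invariant return |C| (default TRUE).
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) stop("maps must have equal channel counts")
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-15 || nv < 1e-15)
    stop("zero-norm map: spatial correlation undefined")
  C <- sum(u * v) / (nu * nv)
  if (polarity_invariant) abs(C) else C
}

#' Single-trial pre-stimulus peak map
#'
#' Returns the topographic map at the GFP local maximum closest to (i.e.,
#' latest before) stimulus onset within the pre-stimulus window. A local
#' maximum is strict (\code{g[i-1] < g[i] > g[i+1]}, window-interior); if
#' the window contains none, the sample of maximal GFP is used (boundary
#' allowed, latest such sample on ties).
#'
#' @param epochs an \code{ms_epochs}.
#' @param trial trial index.
#' @param window_ms search window before onset (default 50).
#' @return list: \code{values} (channel vector), \code{time_offset_ms}
#'   (negative, relative to onset), \code{gfp}, \code{trial},
#'   \code{condition}.
#' @export
find_prestim_peak_map <- function(epochs, trial, window_ms = 50) {
  w <- round(window_ms * epochs$fs / 1000)
  if (w > epochs$onset) stop("window exceeds pre-stimulus data")
  idx <- seq.int(epochs$onset - w + 1, epochs$onset)
  seg <- epochs$data[trial, , idx, drop = TRUE]
  g <- gfp(seg)
  # strict interior local maxima of the GFP series
  peaks <- which(g[2:(w - 1)] > g[1:(w - 2)] & g[2:(w - 1)] > g[3:w]) + 1
  i <- if (length(peaks)) max(peaks) else max(which(g == max(g)))
  list(values = seg[, i], time_offset_ms = (i - w - 1) * 1000 / epochs$fs,
       gfp = g[i], trial = trial, condition = epochs$conditions[trial])
}

#' Peak maps for all trials of one subject
#'
#' @param epochs an \code{ms_epochs}.
#' @param window_ms search window before onset (default 50).
#' @return object of class \code{ms_peakmaps}: \code{maps} (trials x
#'   channels matrix) and \code{info} (trial, subject, condition, gfp,
#'   time_offset_ms).
#' @export
peak_maps <- function(epochs, window_ms = 50) {
  nt <- n_trials(epochs)
  res <- lapply(seq_len(nt), find_prestim_peak_map, epochs = epochs,
                window_ms = window_ms)
  maps <- do.call(rbind, lapply(res, `[[`, "values"))
  info <- data.frame(trial = seq_len(nt), subject = epochs$subject_id,
                     condition = epochs$conditions,
                     gfp = vapply(res, `[[`, 0, "gfp"),
                     time_offset_ms = vapply(res, `[[`, 0, "time_offset_ms"))
  structure(list(maps = maps, info = info), class = "ms_peakmaps")
}

#' Pool peak maps across subjects
#' @param ... \code{ms_peakmaps} objects (or a single list of them).
#' @export
pool_peak_maps <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "ms_peakmaps")) xs <- xs[[1]]
  structure(list(maps = do.call(rbind, lapply(xs, `[[`, "maps")),
                 info = do.call(rbind, lapply(xs, `[[`, "info"))),
            class = "ms_peakmaps")
}

#' @export
print.ms_peakmaps <- function(x, ...) {
  cat("<ms_peakmaps> ", nrow(x$maps), " maps x ", ncol(x$maps),
      " channels from ", length(unique(x$info$subject)), " subject(s)\n",
      sep = "")
  invisible(x)
}

as_map_matrix <- function(maps) {
  if (inherits(maps, "ms_peakmaps")) return(maps$maps)
  if (is.matrix(maps)) return(maps)
  stop("maps must be a matrix or an ms_peakmaps object")
}

#' Cross-validation criterion for a microstate model
#'
#' Predictive residual variance
#' \eqn{CV = \sigma^2 ((N-1)/(N-1-k))^2} with N the channel count and
#' \eqn{\sigma^2} the mean per-sample residual variance of the
#' polarity-invariant fit. Its minimum over k selects the number of
#' microstate classes.
#'
#' @param model a \code{microstate_model}, or a residual variance scalar.
#' @param n_channels channel count (required when \code{model} is a scalar).
#' @export
cv_criterion <- function(model, n_channels = NULL) {
  if (inherits(model, "microstate_model")) {
    sigma2 <- model$sigma2; k <- model$k
    if (is.null(n_channels)) n_channels <- nrow(model$templates)
  } else {
    sigma2 <- model
    k <- attr(model, "k")
    if (is.null(k)) stop("scalar form needs attr(model, 'k')")
  }
  if (n_channels - 1 - k <= 0)
    stop("cv criterion needs n_channels > k + 1")
  sigma2 * ((n_channels - 1) / (n_channels - 1 - k))^2
}

#' Polarity-invariant spatial k-means over a range of cluster counts
#'
#' For each k the assignment step maximizes the squared spatial projection
#' onto the templates (so a map and its polarity reversal are treated
#' identically) and the template update is the dominant eigenvector of the
#' sum of outer products of the assigned mean-removed maps. The best of
#' \code{restarts} random initializations (k distinct maps drawn from the
#' data) is kept; convergence is a relative change in explained variance
#' below \code{tol}.
#'
#' @param maps trials x channels matrix or an \code{ms_peakmaps}.
#' @param k_range candidate cluster counts (default 1:20).
#' @param restarts random initializations per k (default 100).
#' @param max_iter iteration cap per restart.
#' @param tol relative explained-variance convergence tolerance.
#' @param seed integer seed for the initializations.
#' @return object of class \code{microstate_scan}: per-k
#'   \code{microstate_model}s (templates, assignments, residual variance
#'   \code{sigma2}, \code{cv}, \code{gev_total}), the CV curve, and the
#'   selected k.
#' @export
cluster_microstates <- function(maps, k_range = 1:20, restarts = 100,
                                max_iter = 1000, tol = 1e-6, seed = 1) {
  pm <- if (inherits(maps, "ms_peakmaps")) maps else NULL
  X <- as_map_matrix(maps)
  n <- nrow(X); C <- ncol(X)
  if (max(k_range) > n) stop("k exceeds the number of maps")
  if (max(k_range) >= C - 1)
    stop("k_range exceeds what the CV criterion admits for ", C, " channels")
  Xc <- X - rowMeans(X)
  set.seed(as.integer(seed))
  models <- lapply(k_range, function(k) {
    inits <- t(vapply(seq_len(restarts), function(r) sample.int(n, k),
                      integer(k)))
    fit <- ms_kmeans_core(Xc, k, inits, max_iter, tol)
    templates <- fit$templates
    colnames(templates) <- paste0("M", seq_len(k))
    m <- structure(list(k = k, templates = templates,
                        assignments = as.integer(fit$assignments),
                        sigma2 = fit$sigma2, gev_total = fit$ev,
                        n_maps = n),
                   class = "microstate_model")
    m$cv <- cv_criterion(m, C)
    m
  })
  cv <- vapply(models, `[[`, 0, "cv")
  structure(list(models = models, k_range = k_range, cv = cv,
                 k_selected = k_range[which.min(cv)],
                 n_maps = n, n_channels = C, info = pm$info),
            class = "microstate_scan")
}

#' Selected number of microstate classes (argmin of the CV criterion)
#' @param scan a \code{microstate_scan}.
#' @export
select_k <- function(scan) scan$k_selected

#' Model for a given k from a scan
#' @param scan a \code{microstate_scan}.
#' @param k cluster count (default: the CV-selected k).
#' @export
get_model <- function(scan, k = select_k(scan)) {
  i <- match(k, scan$k_range)
  if (is.na(i)) stop("k = ", k, " was not scanned")
  scan$models[[i]]
}

#' @export
print.microstate_scan <- function(x, ...) {
  cat("<microstate_scan> ", x$n_maps, " maps x ", x$n_channels,
      " channels; k in ", min(x$k_range), "..", max(x$k_range), "\n", sep = "")
  cat("  CV-selected k = ", x$k_selected, " (gev_total = ",
      sprintf("%.4f", get_model(x)$gev_total), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.microstate_scan <- function(object, ...) {
  df <- data.frame(k = object$k_range,
                   sigma2 = vapply(object$models, `[[`, 0, "sigma2"),
                   cv = object$cv,
                   gev_total = vapply(object$models, `[[`, 0, "gev_total"))
  df$selected <- df$k == object$k_selected
  df
}

#' @export
plot.microstate_scan <- function(x, ...) {
  graphics::plot(x$k_range, x$cv, type = "b", xlab = "number of clusters k",
                 ylab = "cross-validation criterion", ...)
  graphics::abline(v = x$k_selected, lty = 2)
  invisible(x)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("<microstate_model> k = ", x$k, ", gev_total = ",
      sprintf("%.4f", x$gev_total), ", sigma2 = ",
      sprintf("%.4g", x$sigma2), "\n", sep = "")
  invisible(x)
}

#' @export
coef.microstate_model <- function(object, ...) object$templates

#' @export
predict.microstate_model <- function(object, newdata, ...) {
  label_trials(newdata, object$templates)
}
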