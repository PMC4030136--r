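#' Three-shell spherical head model
#'
#' Concentric homogeneous spheres: scalp, skull, brain. Radii are normalized
#' to a unit head radius; conductivities are relative (skull about 1/80 of
#' soft tissue).
#'
#' @param radii scalp/skull/brain shell radii, strictly decreasing.
#' @param conductivities relative conductivities of scalp/skull/brain.
#' @export
head_model <- function(radii = c(scalp = 1.0, skull = 0.92, brain = 0.87),
                       conductivities = c(scalp = 1, skull = 0.0125, brain = 1)) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  structure(list(radii = radii, conductivities = conductivities),
            class = "ms_head")
}

# surface amplification factors g_n for a dipole harmonic of degree n:
# solve the 5x5 boundary system of the 3-shell model per degree. With the
# free-medium dipole coefficient normalized to 1, the scalp-surface
# potential coefficient is g_n (equals (2n+1)/n for equal conductivities).
shell_factors <- function(head, n_terms) {
  rb <- head$radii[["brain"]]; rs <- head$radii[["skull"]]
  R <- head$radii[["scalp"]]
  s1 <- head$conductivities[["brain"]]
  s2 <- head$conductivities[["skull"]]
  s3 <- head$conductivities[["scalp"]]
  vapply(seq_len(n_terms), function(n) {
    # unknowns: A1, A2, B2, A3, B3 (layer fields A r^n + B r^-(n+1);
    # layer 1 adds the particular term r^-(n+1))
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    # potential continuity at brain/skull
    A[1, ] <- c(rb^n, -rb^n, -rb^(-(n + 1)), 0, 0)
    b[1] <- -rb^(-(n + 1))
    # flux continuity at brain/skull
    A[2, ] <- c(s1 * n * rb^(n - 1), -s2 * n * rb^(n - 1),
                s2 * (n + 1) * rb^(-(n + 2)), 0, 0)
    b[2] <- s1 * (n + 1) * rb^(-(n + 2))
    # potential continuity at skull/scalp
    A[3, ] <- c(0, rs^n, rs^(-(n + 1)), -rs^n, -rs^(-(n + 1)))
    # flux continuity at skull/scalp
    A[4, ] <- c(0, s2 * n * rs^(n - 1), -s2 * (n + 1) * rs^(-(n + 2)),
                -s3 * n * rs^(n - 1), s3 * (n + 1) * rs^(-(n + 2)))
    # insulating outer boundary
    A[5, ] <- c(0, 0, 0, n * R^(n - 1), -(n + 1) * R^(-(n + 2)))
    x <- solve(A, b)
    x[4] * R^n + x[5] * R^(-(n + 1))
  }, 0)
}

# Legendre P_n(x) and P'_n(x) tables, n = 1..n_terms, vectorized over x.
legendre_tables <- function(x, n_terms) {
  E <- length(x)
  P <- matrix(0, n_terms, E)
  dP <- matrix(0, n_terms, E)
  p_prev <- rep(1, E); p_cur <- x
  d_prev <- rep(0, E); d_cur <- rep(1, E)
  P[1, ] <- p_cur; dP[1, ] <- d_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    d_new <- d_prev + (2 * n - 1) * p_cur
    P[n, ] <- p_new; dP[n, ] <- d_new
    p_prev <- p_cur; p_cur <- p_new
    d_prev <- d_cur; d_cur <- d_new
  }
  list(P = P, dP = dP)
}

#' Scalp field of a single current dipole in the 3-shell sphere
#'
#' Truncated Legendre-series solution of the forward problem for one dipole,
#' evaluated at the electrode positions (unit sphere) and average-referenced.
#'
#' @param montage an \code{ms_montage}.
#' @param head a \code{\link{head_model}}.
#' @param pos dipole position (3-vector, inside the brain shell).
#' @param moment dipole moment (3-vector).
#' @param n_terms series truncation (default 60).
#' @return per-channel potential vector (zero mean).
#' @export
dipole_field <- function(montage, head, pos, moment, n_terms = 60) {
  b <- sqrt(sum(pos^2))
  if (b >= head$radii[["brain"]])
    stop("dipole lies outside the brain shell")
  s1 <- head$conductivities[["brain"]]
  g <- shell_factors(head, n_terms)
  rhat0 <- if (b > 1e-9) pos / b else moment / sqrt(sum(moment^2))
  re <- montage$positions
  x <- as.numeric(re %*% rhat0)
  x <- pmin(1, pmax(-1, x))
  lt <- legendre_tables(x, n_terms)
  nn <- seq_len(n_terms)
  wn <- g * b^(nn - 1) / (4 * pi * s1)
  m_r <- sum(moment * rhat0)
  S1 <- as.numeric(crossprod(lt$P, wn * nn))    # radial series
  S2 <- as.numeric(crossprod(lt$dP, wn))        # tangential series
  mt_e <- as.numeric(re %*% moment) - x * m_r   # m . (r_e - x r0hat)
  v <- m_r * S1 + mt_e * S2
  v - mean(v)
}

#' Quasi-regular source space inside the brain shell
#'
#' Cubic grid (offset by half a spacing so the origin is excluded) clipped
#' to a sphere at 92% of the brain-shell radius; points in the posterior
#' third (y < -0.5 in source-space-normalized coordinates, i.e. y below
#' half the source-space radius towards the back of the head) are flagged
#' occipital.
#'
#' @param head a \code{\link{head_model}}.
#' @param spacing grid spacing in head-radius units (default 0.13, about
#'   1000 points).
#' @return object of class \code{ms_sources}: \code{points} (n x 3),
#'   \code{n_points}, \code{spacing}, \code{occipital} (logical).
#' @export
source_space <- function(head, spacing = 0.13) {
  rmax <- 0.92 * head$radii[["brain"]]
  m <- ceiling(rmax / spacing)
  g <- (seq(-m, m - 1) + 0.5) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= rmax^2, , drop = FALSE]
  structure(list(points = pts, n_points = nrow(pts), spacing = spacing,
                 rmax = rmax, occipital = pts[, "y"] < -0.5 * rmax),
            class = "ms_sources")
}

#' @export
print.ms_sources <- function(x, ...) {
  cat("<ms_sources> ", x$n_points, " points, spacing ", x$spacing,
      ", ", sum(x$occipital), " occipital\n", sep = "")
  invisible(x)
}

#' Lead field of the 3-shell spherical head
#'
#' Channels x (3 n_points) gain matrix mapping free-orientation dipole
#' moments to average-referenced scalp potentials, via the analytic
#' Legendre-series forward solution.
#'
#' @param montage an \code{ms_montage}.
#' @param head a \code{\link{head_model}}.
#' @param sources an \code{\link{source_space}}.
#' @param n_terms series truncation (default 60).
#' @return object of class \code{ms_leadfield}: \code{gain}, \code{sources},
#'   \code{head}, \code{n_points}.
#' @export
compute_leadfield <- function(montage, head, sources, n_terms = 60) {
  if (any(rowSums(sources$points^2) >= head$radii[["brain"]]^2))
    stop("source point outside the brain shell")
  E <- montage$n_channels
  n <- sources$n_points
  g <- shell_factors(head, n_terms)
  s1 <- head$conductivities[["brain"]]
  nn <- seq_len(n_terms)
  re <- montage$positions
  gain <- matrix(0, E, 3 * n)
  for (j in seq_len(n)) {
    p <- sources$points[j, ]
    b <- sqrt(sum(p^2))
    rhat0 <- p / b
    x <- pmin(1, pmax(-1, as.numeric(re %*% rhat0)))
    lt <- legendre_tables(x, n_terms)
    wn <- g * b^(nn - 1) / (4 * pi * s1)
    S1 <- as.numeric(crossprod(lt$P, wn * nn))
    S2 <- as.numeric(crossprod(lt$dP, wn))
    # unit moments along the coordinate axes
    for (i in 1:3) {
      v <- rhat0[i] * S1 + (re[, i] - x * rhat0[i]) * S2
      gain[, 3 * (j - 1) + i] <- v - mean(v)
    }
  }
  structure(list(gain = gain, sources = sources, head = head,
                 n_points = n, montage = montage),
            class = "ms_leadfield")
}

#' @export
print.ms_leadfield <- function(x, ...) {
  cat("<ms_leadfield> ", nrow(x$gain), " channels x ", x$n_points,
      " source points (free orientation)\n", sep = "")
  invisible(x)
}

#' LAURA-style regularized distributed inverse operator
#'
#' Linear inverse \eqn{J = M v} with
#' \eqn{M = R A^T (A R A^T + \lambda I)^{-1}}. The prior covariance R
#' combines (a) a local autoregressive smoothness term: each point's moment
#' is driven toward the inverse-squared-distance weighted average of its
#' neighbors within \code{neighbor_radius}, and (b) a depth weighting that
#' counteracts the superficial bias of unweighted minimum-norm solutions.
#' \eqn{\lambda} is \code{lambda_rel} times the mean eigenvalue of
#' \eqn{A R A^T}.
#'
#' @param leadfield an \code{ms_leadfield}.
#' @param lambda_rel relative regularization weight (default 0.1).
#' @param neighbor_radius neighborhood radius; default 1.6 x grid spacing
#'   (face and edge neighbors of the cubic grid).
#' @param depth_exponent exponent of the per-point gain-norm depth
#'   compensation (default 2: full column normalization).
#' @param prior_ridge ridge added to the autoregressive precision so the
#'   prior is proper (relative to its mean diagonal; default 0.02).
#' @param standardize apply resolution-based standardization (default TRUE):
#'   each point's rows of M are whitened by the inverse square root of its
#'   3 x 3 resolution block \eqn{(M A)_{jj}}, which removes the residual
#'   localization bias of depth-weighted minimum-norm magnitudes.
#' @return object of class \code{ms_inverse} with the (3 n_points) x
#'   channels matrix \code{M}.
#' @export
build_laura_operator <- function(leadfield, lambda_rel = 0.1,
                                 neighbor_radius = NULL,
                                 depth_exponent = 2, prior_ridge = 0.02,
                                 standardize = TRUE) {
  src <- leadfield$sources
  n <- src$n_points
  if (is.null(neighbor_radius)) neighbor_radius <- 1.6 * src$spacing
  D2 <- as.matrix(stats::dist(src$points))^2
  Bw <- ifelse(D2 > 0 & D2 <= neighbor_radius^2, 1 / D2, 0)
  deg <- rowSums(Bw)
  if (any(deg == 0))
    stop("isolated source point(s): increase neighbor_radius")
  B <- Bw / deg
  IB <- diag(n) - B
  Wp <- crossprod(IB)
  Wp <- Wp + diag(prior_ridge * mean(diag(Wp)), n)
  W3 <- Matrix::Matrix(kronecker(Wp, diag(3)), sparse = TRUE)
  # depth weighting: scale each point's 3 columns by 1/|A_j|^depth_exponent
  colnorm <- sqrt(colSums(matrix(colSums(leadfield$gain^2), 3), na.rm = TRUE))
  w <- 1 / pmax(colnorm, 1e-12)^depth_exponent
  sw3 <- rep(sqrt(w), each = 3)
  At <- t(leadfield$gain) * sw3                 # (3n) x E, scaled
  X <- as.matrix(Matrix::solve(W3, At))         # R^(1/2)-space solve
  K <- crossprod(At, X)                         # A R A^T, E x E
  lambda <- lambda_rel * mean(diag(K))
  G <- X * sw3                                  # R A^T
  M <- G %*% solve(K + diag(lambda, nrow(K)))
  if (standardize) {
    # whiten each point's rows by its 3x3 posterior-covariance block
    # (R A^T (A R A^T + lambda I)^-1 A R)_jj = M_j G_j^T
    for (j in seq_len(n)) {
      rows <- 3 * (j - 1) + 1:3
      S <- M[rows, ] %*% t(G[rows, ])
      S <- (S + t(S)) / 2
      e <- eigen(S, symmetric = TRUE)
      ev <- pmax(e$values, max(e$values, 1e-30) * 1e-8)
      Sinv_half <- e$vectors %*% (t(e$vectors) / sqrt(ev))
      M[rows, ] <- Sinv_half %*% M[rows, ]
    }
  }
  structure(list(M = M, lambda = lambda, lambda_rel = lambda_rel,
                 neighbor_radius = neighbor_radius,
                 depth_exponent = depth_exponent, standardize = standardize,
                 sources = src), class = "ms_inverse")
}

#' @export
print.ms_inverse <- function(x, ...) {
  cat("<ms_inverse> ", nrow(x$M) / 3, " source points x ", ncol(x$M),
      " channels; lambda = ", sprintf("%.4g", x$lambda), "\n", sep = "")
  invisible(x)
}

#' Source magnitudes of scalp maps under a linear inverse
#'
#' Applies the inverse operator and returns the Euclidean norm of the 3D
#' moment at each solution point.
#'
#' @param maps channel vector, trials x channels matrix, or
#'   \code{ms_peakmaps}.
#' @param op an \code{ms_inverse}.
#' @return n_points x n_maps matrix of current magnitudes.
#' @export
estimate_source_magnitudes <- function(maps, op) {
  X <- if (is.matrix(maps) || inherits(maps, "ms_peakmaps"))
    as_map_matrix(maps) else matrix(maps, nrow = 1)
  if (ncol(X) != ncol(op$M)) stop("channel count mismatch with the inverse")
  J <- op$M %*% t(X)                            # 3n x n_maps
  n <- nrow(J) / 3
  idx <- rep(seq_len(n), each = 3)
  mag2 <- rowsum(J^2, idx)
  sqrt(mag2)
}

#' Solution-point-wise condition contrast of source magnitudes
#'
#' Paired two-tailed t test across subjects at each solution point on the
#' per-subject mean current magnitudes, with Benjamini-Hochberg FDR over
#' points. Positive t means larger magnitude in the CA condition.
#'
#' @param mag_CA,mag_CU subjects x points matrices of per-subject mean
#'   magnitudes.
#' @param sources optional \code{ms_sources} for coordinates/region flags.
#' @param q FDR level (default 0.05).
#' @return object of class \code{ms_spm}: per-point table (t, p, p_adj,
#'   significant), index/coordinates of the maximal-|t| point.
#' @export
spm_contrast <- function(mag_CA, mag_CU, sources = NULL, q = 0.05) {
  if (!all(dim(mag_CA) == dim(mag_CU)))
    stop("condition magnitude matrices must have equal shape")
  ns <- nrow(mag_CA)
  if (ns < 2) stop("need >= 2 subjects")
  d <- mag_CA - mag_CU
  mu <- colMeans(d)
  sdv <- sqrt(colSums(sweep(d, 2, mu)^2) / (ns - 1))
  tt <- mu / (sdv / sqrt(ns))
  tt[sdv == 0 & mu == 0] <- 0
  p <- p_from_t(tt, ns - 1)
  fdr <- bh_fdr(p, q)
  peak <- which.max(abs(tt))
  tab <- data.frame(point = seq_along(tt), t = tt, p = p,
                    p_adj = fdr$p_adjusted, significant = fdr$significant)
  if (!is.null(sources)) {
    tab <- cbind(tab, sources$points)
    tab$occipital <- sources$occipital
  }
  structure(list(table = tab, peak = peak, n_subjects = ns, q = q,
                 peak_point = if (!is.null(sources)) sources$points[peak, ]
                              else NULL),
            class = "ms_spm")
}

#' @export
print.ms_spm <- function(x, ...) {
  pk <- x$table[x$peak, ]
  cat("<ms_spm> ", nrow(x$table), " solution points, ",
      sum(x$table$significant), " FDR-significant at q = ", x$q, "\n",
      sep = "")
  cat(sprintf("  peak |t|: point %d, t = %.3f, p = %.4g\n",
              x$peak, pk$t, pk$p))
  invisible(x)
}
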