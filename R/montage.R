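#' Electrode montage on the unit sphere
#'
#' Builds a quasi-uniform electrode layout covering the upper portion of a
#' unit sphere (scalp coverage down to roughly 20 degrees below the equator),
#' using a Fibonacci spiral with a seed-controlled azimuthal rotation.
#' Channels closest to canonical 10-20 landmarks are relabelled
#' \code{Cz}, \code{Fpz}, \code{Oz}, and two inferior-lateral channels are
#' designated mastoids \code{M1}/\code{M2} (montages with at least 16
#' channels only; smaller montages keep plain \code{E...} labels).
#'
#' Head coordinates: x points to the right ear, y to the nasion (anterior),
#' z to the vertex; head radius is normalized to 1.
#'
#' @param n_channels number of electrodes (>= 4); default 204.
#' @param seed integer seed controlling the spiral rotation.
#' @return An object of class \code{ms_montage}: list with \code{names}
#'   (character), \code{positions} (n x 3 matrix of unit vectors),
#'   \code{n_channels}, and \code{mastoids} (labels or NULL).
#' @examples
#' mon <- make_montage(32, seed = 1)
#' range(sqrt(rowSums(mon$positions^2)))
#' @export
make_montage <- function(n_channels = 204, seed = 1) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 4)
    stop("n_channels must be a single number >= 4")
  n_channels <- as.integer(n_channels)
  rot <- local({
    rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
    set.seed(as.integer(seed))
    stats::runif(1, 0, 2 * pi)
  })
  # Fibonacci spiral over z in (zmin, zmax): quasi-uniform area coverage
  zmin <- -1 / 3
  zmax <- 1
  i <- seq_len(n_channels)
  z <- zmax - (i - 0.5) / n_channels * (zmax - zmin)
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i + rot
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  nm <- sprintf("E%03d", i)
  mastoids <- NULL
  if (n_channels >= 16) {
    landmarks <- rbind(
      Cz  = c(0, 0, 1),
      Fpz = c(0, 0.9239, 0.3827),
      Oz  = c(0, -0.9239, 0.3827),
      M1  = c(-0.88, -0.40, -0.26),
      M2  = c(0.88, -0.40, -0.26))
    landmarks <- landmarks / sqrt(rowSums(landmarks^2))
    taken <- integer(0)
    for (j in seq_len(nrow(landmarks))) {
      d <- pos %*% landmarks[j, ]
      d[taken] <- -Inf
      idx <- which.max(d)
      nm[idx] <- rownames(landmarks)[j]
      taken <- c(taken, idx)
    }
    mastoids <- c("M1", "M2")
  }
  structure(list(names = nm, positions = pos, n_channels = n_channels,
                 mastoids = mastoids),
            class = "ms_montage")
}

#' @export
print.ms_montage <- function(x, ...) {
  cat("<ms_montage> ", x$n_channels, " channels on the unit sphere\n", sep = "")
  if (!is.null(x$mastoids))
    cat("  landmarks: Cz, Fpz, Oz; mastoids:", paste(x$mastoids, collapse = ", "), "\n")
  invisible(x)
}

# index of a channel label, with a clear error for unknown labels
match_channel <- function(montage, label) {
  idx <- match(label, montage$names)
  if (anyNA(idx))
    stop("unknown electrode label(s): ", paste(label[is.na(idx)], collapse = ", "))
  idx
}
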