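#' Epoched multichannel EEG container
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param onset number of pre-stimulus samples: samples \code{1..onset} are
#'   pre-stimulus, sample \code{onset + 1} is the first post-stimulus sample.
#' @param conditions character/factor of per-trial condition labels
#'   (\code{"CA"} = correct aware, \code{"CU"} = correct unaware).
#' @param montage an \code{\link{make_montage}} object matching the channel
#'   dimension.
#' @param subject_id identifier stored with the object.
#' @return An object of class \code{ms_epochs}.
#' @export
ms_epochs <- function(data, fs, onset, conditions, montage, subject_id = "S01") {
  if (length(dim(data)) != 3)
    stop("data must be a trials x channels x samples array")
  if (dim(data)[2] != montage$n_channels)
    stop("channel dimension (", dim(data)[2], ") does not match montage (",
         montage$n_channels, ")")
  if (length(conditions) != dim(data)[1])
    stop("length(conditions) must equal the number of trials")
  if (anyNA(data)) stop("data contains NAs")
  onset <- as.integer(onset)
  if (onset < 1 || onset > dim(data)[3])
    stop("onset must lie within the sample range")
  structure(list(data = data, fs = fs, onset = onset,
                 conditions = as.character(conditions), montage = montage,
                 subject_id = subject_id),
            class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<ms_epochs> subject ", x$subject_id, ": ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  pre-stimulus: ", x$onset, " samples (",
      round(x$onset / x$fs * 1000), " ms); conditions: ",
      paste(sprintf("%s=%d", names(table(x$conditions)), table(x$conditions)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]
n_samples <- function(epochs) dim(epochs$data)[3]

#' Write epochs to an on-disk container
#'
#' The container is a directory holding the voltage array as raw
#' little-endian float32 (\code{data.f32}, trial-major, then channel, then
#' sample), a JSON sidecar with shape, sampling rate, onset, channel names
#' and condition labels, and an events TSV (trial, condition, onset sample).
#'
#' @param epochs an \code{ms_epochs} object.
#' @param dir output directory (created if needed).
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  con <- file(file.path(dir, "data.f32"), "wb")
  on.exit(close(con))
  # aperm so the file is laid out trial-major
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4, endian = "little")
  meta <- list(shape = d, fs = epochs$fs, onset = epochs$onset,
               channel_names = epochs$montage$names,
               mastoids = epochs$montage$mastoids,
               positions = unname(apply(epochs$montage$positions, 1, c,
                                        simplify = FALSE)),
               conditions = epochs$conditions,
               subject_id = epochs$subject_id)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  ev <- data.frame(trial = seq_len(d[1]), condition = epochs$conditions,
                   onset_sample = epochs$onset)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read epochs from an on-disk container written by \code{\link{write_epochs}}
#' @param dir container directory.
#' @return an \code{ms_epochs} object.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  con <- file(file.path(dir, "data.f32"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = prod(d), size = 4,
                 endian = "little")
  data <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  pos <- if (is.matrix(meta$positions)) meta$positions
         else do.call(rbind, meta$positions)
  colnames(pos) <- c("x", "y", "z")
  montage <- structure(list(names = meta$channel_names, positions = pos,
                            n_channels = d[2],
                            mastoids = meta$mastoids),
                       class = "ms_montage")
  ms_epochs(data, fs = meta$fs, onset = meta$onset,
            conditions = meta$conditions, montage = montage,
            subject_id = meta$subject_id)
}
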