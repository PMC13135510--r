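#' Multichannel recording container
#'
#' Bundles a channels-by-samples data matrix with its sampling rate, channel
#' labels and roles, a per-sample bad mask, and subject/condition labels.
#' This is the common currency passed between the simulator, preprocessing,
#' state inference and spectral estimation.
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one per row of `data`.
#' @param channel_roles Character vector of `"cortical"` or `"lfp"`.
#' @param bad_mask Logical vector (TRUE = bad sample); defaults to all good.
#' @param subject Subject identifier.
#' @param condition Condition label, conventionally `"off"` or `"on"`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, channel_roles = NULL,
                      bad_mask = NULL, subject = "s1", condition = "off") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (is.null(channel_labels))
    channel_labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  if (is.null(channel_roles)) channel_roles <- rep("cortical", nrow(data))
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, ncol(data))
  rec <- structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         channel_roles = channel_roles, bad_mask = bad_mask,
         subject = subject, condition = condition),
    class = "recording")
  validate_recording(rec)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$data), all(is.finite(rec$data)), rec$fs > 0)
  if (length(rec$channel_labels) != nrow(rec$data))
    stop("channel_labels must match the number of rows")
  if (length(rec$channel_roles) != nrow(rec$data))
    stop("channel_roles must match the number of rows")
  if (!all(rec$channel_roles %in% c("cortical", "lfp")))
    stop("channel roles must be 'cortical' or 'lfp'")
  if (length(rec$bad_mask) != ncol(rec$data))
    stop("bad_mask length must equal the number of samples")
  if (anyDuplicated(rec$channel_labels)) stop("duplicate channel labels")
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject=%s condition=%s: %d channels x %d samples @ %g Hz\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$fs))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s(%s)", x$channel_labels, substr(x$channel_roles, 1, 1)),
                    collapse = " ")))
  cat(sprintf("  bad samples: %d (%.1f%%)\n", sum(x$bad_mask),
              100 * mean(x$bad_mask)))
  invisible(x)
}

#' @rdname recording
#' @param rec A `recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

# indices of channels with a given role
channels_with_role <- function(rec, role) which(rec$channel_roles == role)

# row index for a channel label, with a clear error
channel_index <- function(rec, label) {
  i <- match(label, rec$channel_labels)
  if (is.na(i)) stop(sprintf("channel '%s' not present in recording", label))
  i
}

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The data matrix is stored as a tab-separated channels-by-samples file and
#' metadata (sampling rate, labels, roles, bad mask, subject, condition) in a
#' JSON sidecar named `<path>.json`.
#'
#' @param rec A `recording`.
#' @param path Path of the data file (e.g. `"sub1_off.tsv"`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `recording`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               channel_roles = rec$channel_roles,
               bad_samples = which(rec$bad_mask),
               n_samples = ncol(rec$data),
               subject = rec$subject, condition = rec$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  bad <- rep(FALSE, meta$n_samples)
  bad[meta$bad_samples] <- TRUE
  recording(dat, fs = meta$fs, channel_labels = meta$channel_labels,
            channel_roles = meta$channel_roles, bad_mask = bad,
            subject = meta$subject, condition = meta$condition)
}
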