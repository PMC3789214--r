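#' Construct a multichannel EEG recording
#'
#' The `eeg_recording` object is the unit of biomarker extraction: a
#' channel-by-sample matrix (microvolts) with sampling rate, 10-20 channel
#' labels, and subject/visit/group metadata.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_labels character vector of 10-20 electrode names, one per row.
#' @param subject_id subject identifier.
#' @param visit visit index, 1 or 2.
#' @param group group label: `"MCI-stable"`, `"AD-converter"` or `"unknown"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          subject_id = NA_character_, visit = 1L,
                          group = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal the number of data rows")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  if (!visit %in% c(1L, 2L)) stop("visit must be 1 or 2")
  group <- match.arg(group, c("MCI-stable", "AD-converter", "unknown"))
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = channel_labels,
         subject_id = as.character(subject_id), visit = as.integer(visit),
         group = group),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(sprintf("  subject %s, visit %d, group %s\n",
              x$subject_id, x$visit, x$group))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param x an `eeg_recording`.
#' @return integer count.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname n_channels
#' @export
n_samples <- function(x) ncol(x$data)

#' Duration of a recording in seconds
#' @param x an `eeg_recording`.
#' @return seconds.
#' @export
recording_duration <- function(x) ncol(x$data) / x$sampling_rate

#' Write a recording to the plain-text repository container format
#'
#' The container is self-describing text: a first line
#' `#eegdx-recording<TAB><JSON header>` carrying sampling rate, labels and
#' metadata, followed by one tab-separated row of samples per channel,
#' serialized at full double precision so that a write/read round trip is
#' bit-identical.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  header <- jsonlite::toJSON(
    list(format = "eegdx-recording", version = 1L,
         sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, visit = rec$visit, group = rec$group),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#eegdx-recording\t", as.character(header)), con)
  # %.17g preserves doubles exactly
  apply(rec$data, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  invisible(path)
}

#' Read a recording from the repository container format
#'
#' @param path file written by [write_recording()].
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#eegdx-recording\t"))
    stop("parse error: missing '#eegdx-recording' header in ", path)
  header <- jsonlite::fromJSON(sub("^#eegdx-recording\t", "", lines[1L]))
  needed <- c("sampling_rate", "channel_labels")
  missing <- setdiff(needed, names(header))
  if (length(missing))
    stop("parse error: header lacks field(s): ", paste(missing, collapse = ", "))
  rows <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  if (length(unique(lengths(rows))) != 1L)
    stop("parse error: ragged sample rows")
  data <- do.call(rbind, rows)
  if (nrow(data) != length(header$channel_labels))
    stop("parse error: channel_labels count does not match data rows")
  if (!all(is.finite(data)))
    stop("parse error: non-finite samples in data")
  eeg_recording(data, header$sampling_rate, header$channel_labels,
                subject_id = if (!is.null(header$subject_id)) header$subject_id else NA_character_,
                visit = if (!is.null(header$visit)) as.integer(header$visit) else 1L,
                group = if (!is.null(header$group)) header$group else "unknown")
}
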