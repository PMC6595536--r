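# Recording / annotation containers and text-format I/O.

#' Construct an EEG recording
#'
#' @param channels Named list of equal-length numeric vectors; names are
#'   channel labels (e.g. `"C3-A2"`, `"C4-A1"`).
#' @param sampling_rate Samples per second (> 0).
#' @return An `eeg_recording` object.
#' @export
new_recording <- function(channels, sampling_rate) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of numeric vectors", call. = FALSE)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 channels = lapply(channels, as.numeric),
                 n_samples = unname(lens[1])),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "], ",
      x$n_samples, " samples @ ", x$sampling_rate, " Hz (",
      round(x$n_samples / x$sampling_rate, 1), " s)\n", sep = "")
  invisible(x)
}

#' Average two EEG channels sample-wise
#'
#' The method extracts features from the time-domain average of the two
#' symmetric channels, which attenuates uncorrelated channel noise.
#'
#' @param recording An `eeg_recording`.
#' @param labels Two channel labels; both must exist.
#' @return Numeric vector, the element-wise mean.
#' @export
average_channels <- function(recording, labels = c("C3-A2", "C4-A1")) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(labels) != 2L) stop("exactly two channel labels required", call. = FALSE)
  miss <- setdiff(labels, names(recording$channels))
  if (length(miss))
    stop("channel(s) not found in recording: ",
         paste(miss, collapse = ", "), call. = FALSE)
  (recording$channels[[labels[1]]] + recording$channels[[labels[2]]]) / 2
}

#' Read an EEG recording from disk
#'
#' Supports 16-bit EDF and delimited text (one column per channel, header
#' row of channel labels). For delimited text a `sampling_rate` must be
#' supplied; EDF carries its own.
#'
#' @param path File path.
#' @param format `"edf"`, `"delimited"`, or `"auto"` (by file extension).
#' @param sampling_rate Required for delimited files.
#' @param sep Field separator for delimited files (default tab).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           sampling_rate = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf"
      else if (ext %in% c("csv", "tsv", "txt", "dat")) "delimited"
      else stop("cannot infer format from extension '", ext,
                "'; pass `format`", call. = FALSE)
  }
  if (format == "edf") return(read_edf(path))
  if (is.null(sampling_rate))
    stop("a sampling_rate must be supplied for delimited recordings", call. = FALSE)
  if (tolower(tools::file_ext(path)) == "csv" && sep == "\t") sep <- ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (ncol(tab) < 1L) stop("no channels in delimited file", call. = FALSE)
  chans <- as.list(tab)
  if (is.null(names(chans)) || any(names(chans) == ""))
    names(chans) <- paste0("ch", seq_along(chans))
  new_recording(chans, sampling_rate)
}

#' Write a recording as delimited text
#'
#' One column per channel with a header row of labels — the dependency-free
#' interchange path. The sampling rate is not stored; keep it alongside.
#'
#' @param recording An `eeg_recording`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_recording_delim <- function(recording, path, sep = "\t") {
  stopifnot(inherits(recording, "eeg_recording"))
  tab <- as.data.frame(recording$channels, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' Events are sorted by onset; labels are lower-cased. Overlapping events
#' with the same label are merged into their union (the method only needs
#' apnea / non-apnea intervals).
#'
#' @param onset,duration Numeric vectors, seconds; durations > 0.
#' @param label Character vector of event labels.
#' @return An `apnea_annotations` data frame with columns
#'   `onset`, `duration`, `label`.
#' @export
new_annotations <- function(onset = numeric(0), duration = numeric(0),
                            label = character(0)) {
  if (length(onset) != length(duration) || length(onset) != length(label))
    stop("onset, duration and label must have equal length", call. = FALSE)
  if (any(duration <= 0)) stop("durations must be > 0", call. = FALSE)
  if (any(onset < 0)) stop("onsets must be >= 0", call. = FALSE)
  df <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   label = tolower(as.character(label)), stringsAsFactors = FALSE)
  df <- df[order(df$onset, df$duration), , drop = FALSE]
  df <- merge_same_label(df)
  rownames(df) <- NULL
  class(df) <- c("apnea_annotations", "data.frame")
  df
}

# union-merge overlapping events that share a label
merge_same_label <- function(df) {
  if (nrow(df) < 2L) return(df)
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    same <- df$label[i] == out$label[j]
    if (same && df$onset[i] < out$onset[j] + out$duration[j]) {
      end <- max(out$onset[j] + out$duration[j], df$onset[i] + df$duration[i])
      out$duration[j] <- end - out$onset[j]
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Read / write an apnea annotation file
#'
#' Plain text, one event per line: `onset_s<TAB>duration_s<TAB>label`
#' (any whitespace separates fields on read). Onsets are seconds from
#' recording start; intervals are half-open `[onset, onset + duration)`.
#'
#' @param path File path.
#' @return `read_annotations` returns an `apnea_annotations` object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(new_annotations())
  parts <- strsplit(trimws(lines), "[ \t]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("annotation line ", i, ": expected 'onset duration label'", call. = FALSE)
    on <- suppressWarnings(as.numeric(p[1]))
    du <- suppressWarnings(as.numeric(p[2]))
    if (is.na(on) || is.na(du))
      stop("annotation line ", i, ": non-numeric onset or duration", call. = FALSE)
    if (du <= 0)
      stop("annotation line ", i, ": duration must be > 0", call. = FALSE)
    if (on < 0)
      stop("annotation line ", i, ": onset must be >= 0", call. = FALSE)
  }
  new_annotations(
    onset = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    duration = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    label = vapply(parts, function(p) paste(p[-(1:2)], collapse = " "), character(1))
  )
}

#' @rdname read_annotations
#' @param ann An `apnea_annotations` object.
#' @export
write_annotations <- function(ann, path) {
  df <- as.data.frame(ann)
  lines <- sprintf("%s\t%s\t%s", format(df$onset, trim = TRUE, scientific = FALSE),
                   format(df$duration, trim = TRUE, scientific = FALSE), df$label)
  writeLines(lines, path)
  invisible(path)
}

#' Merged apnea intervals of an annotation set
#'
#' Events whose label matches any of `patterns` (case-insensitive substring,
#' default `"apnea"` — which also matches "hypopnea" variants spelled
#' "...apnea" — and `"hypopnea"`) count as apnea; overlapping or adjacent
#' matching events are merged into disjoint intervals.
#'
#' @param ann An `apnea_annotations` object.
#' @param patterns Character vector of label substrings.
#' @return Two-column matrix `(start, end)` in seconds, possibly 0 rows.
#' @export
apnea_intervals <- function(ann, patterns = c("apnea", "hypopnea")) {
  df <- as.data.frame(ann)
  if (!nrow(df)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, df$label, ignore.case = TRUE)))
  df <- df[hit, , drop = FALSE]
  if (!nrow(df)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  df <- df[order(df$onset), , drop = FALSE]
  s <- df$onset; e <- df$onset + df$duration
  ks <- s[1]; ke <- e[1]; out <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ke) ke <- max(ke, e[i])
    else { out <- rbind(out, c(ks, ke)); ks <- s[i]; ke <- e[i] }
  }
  out <- rbind(out, c(ks, ke))
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}
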