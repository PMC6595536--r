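# Frame segmentation, apnea/non-apnea labelling, class balancing and
# per-frame preprocessing.

#' Cut a signal into fixed-length non-overlapping frames
#'
#' Frames are anchored to t = 0 and a trailing remainder shorter than one
#' frame is dropped. At the defaults (128 samples/s, 10 s) each frame holds
#' N = 1280 samples. An `overlap` fraction is available for reproducing
#' overlapped-framing comparisons but defaults to 0 (the method itself uses
#' disjoint frames).
#'
#' @param signal Numeric vector (typically the two-channel average).
#' @param sampling_rate Samples per second.
#' @param frame_duration Frame length in seconds (default 10).
#' @param overlap Fraction in `[0, 1)` of frame overlap between successive
#'   frames (0 = disjoint).
#' @return A `frame_set`: list with `samples` (frames-by-N matrix), `start`
#'   (seconds), `labels` (`NULL` until [label_frames()]), `frame_duration`,
#'   `sampling_rate`.
#' @export
segment <- function(signal, sampling_rate, frame_duration = 10, overlap = 0) {
  n_frame <- frame_duration * sampling_rate
  if (abs(n_frame - round(n_frame)) > 1e-9)
    stop("frame_duration * sampling_rate must be an integer sample count", call. = FALSE)
  n_frame <- as.integer(round(n_frame))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (length(signal) < n_frame)
    stop("signal shorter than one frame (", length(signal), " < ", n_frame,
         " samples)", call. = FALSE)
  hop <- max(1L, as.integer(round(n_frame * (1 - overlap))))
  starts_idx <- seq(1L, length(signal) - n_frame + 1L, by = hop)
  samples <- matrix(0, length(starts_idx), n_frame)
  for (i in seq_along(starts_idx))
    samples[i, ] <- signal[starts_idx[i]:(starts_idx[i] + n_frame - 1L)]
  structure(list(samples = samples,
                 start = (starts_idx - 1L) / sampling_rate,
                 labels = NULL,
                 frame_duration = frame_duration,
                 sampling_rate = sampling_rate),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> ", nrow(x$samples), " frame(s) x ", ncol(x$samples),
      " samples (", x$frame_duration, " s @ ", x$sampling_rate, " Hz)\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Label frames apnea / non-apnea from annotations
#'
#' A frame is `apnea` iff its interval lies entirely inside one annotated
#' apnea interval, and `non_apnea` iff it is at least `guard` seconds away
#' from every apnea interval. All other frames (boundary-straddling or
#' inside the guard zone) are dropped, so every retained frame holds a
#' single breathing condition.
#'
#' @param frames An unlabelled `frame_set`.
#' @param annotations An `apnea_annotations` object.
#' @param guard Minimum distance (s) of a non-apnea frame from any event
#'   (default 30).
#' @param patterns Label substrings that count as apnea, see
#'   [apnea_intervals()].
#' @return The `frame_set` restricted to labelled frames, with `labels` set.
#' @export
label_frames <- function(frames, annotations, guard = 30,
                         patterns = c("apnea", "hypopnea")) {
  stopifnot(inherits(frames, "frame_set"))
  iv <- apnea_intervals(annotations, patterns)
  a <- frames$start
  b <- frames$start + frames$frame_duration
  n <- length(a)
  lab <- rep(NA_character_, n)
  if (nrow(iv) == 0L) {
    lab[] <- "non_apnea"
  } else {
    for (i in seq_len(n)) {
      inside <- any(iv[, "start"] <= a[i] & b[i] <= iv[, "end"])
      if (inside) { lab[i] <- "apnea"; next }
      gap <- pmax(iv[, "start"] - b[i], a[i] - iv[, "end"])
      if (all(gap >= guard)) lab[i] <- "non_apnea"
    }
  }
  keep <- !is.na(lab)
  structure(list(samples = frames$samples[keep, , drop = FALSE],
                 start = frames$start[keep],
                 labels = lab[keep],
                 frame_duration = frames$frame_duration,
                 sampling_rate = frames$sampling_rate),
            class = "frame_set")
}

#' Balance apnea and non-apnea frame counts
#'
#' Keeps every apnea frame and subsamples the non-apnea frames uniformly
#' without replacement down to the apnea count, seeded. The evaluation
#' protocol uses all apnea frames plus an equal number of non-apnea frames.
#'
#' @param frames A labelled `frame_set`.
#' @param seed Integer seed for the subsample.
#' @return A `frame_set` with equal class counts, in original time order.
#' @export
balance_frames <- function(frames, seed = 1L) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(frames$labels)) stop("frames must be labelled first", call. = FALSE)
  n_a <- sum(frames$labels == "apnea")
  n_n <- sum(frames$labels == "non_apnea")
  if (n_a == 0L) {
    warning("no apnea frames: balanced set is empty")
    keep <- logical(length(frames$labels))
  } else {
    if (n_n < n_a)
      stop("only ", n_n, " non-apnea frames for ", n_a,
           " apnea frames; try a smaller guard distance", call. = FALSE)
    pick <- with_seed(seed, sample(which(frames$labels == "non_apnea"), n_a))
    keep <- frames$labels == "apnea"
    keep[pick] <- TRUE
  }
  structure(list(samples = frames$samples[keep, , drop = FALSE],
                 start = frames$start[keep],
                 labels = frames$labels[keep],
                 frame_duration = frames$frame_duration,
                 sampling_rate = frames$sampling_rate),
            class = "frame_set")
}

#' Per-frame preprocessing: DC removal and amplitude normalisation
#'
#' Subtracts the frame mean, then divides by the maximum absolute value of
#' the mean-removed frame, so the output has mean 0 and max |value| 1.
#' This makes all downstream energy-ratio features invariant to per-frame
#' gain and offset. Idempotent.
#'
#' @param frame Numeric vector.
#' @return Preprocessed frame.
#' @export
#' @examples
#' preprocess_frame(c(2, 4, 6))   # -1 0 1
preprocess_frame <- function(frame) {
  if (!length(frame)) stop("empty frame", call. = FALSE)
  x <- frame - mean(frame)
  m <- max(abs(x))
  if (m == 0) stop("flat frame: zero amplitude after mean removal", call. = FALSE)
  x / m
}

# run a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
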