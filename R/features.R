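# Band energies and inter-band energy-ratio feature vectors.

#' Energy of a band-limited signal
#'
#' Sum of squared samples over the frame, \eqn{E_p = \sum_n x_p[n]^2}.
#'
#' @param band_signal Real vector.
#' @return Non-negative scalar.
#' @export
band_energy <- function(band_signal) {
  if (length(band_signal) == 0L) stop("empty band signal", call. = FALSE)
  sum(band_signal^2)
}

#' Inter-band energy ratio
#'
#' \eqn{R_{pq} = E_p / E_q}. A zero denominator signals a degenerate
#' (empty) band rather than being clamped.
#'
#' @param e_p,e_q Band energies.
#' @param band_q Name used in the error message for a zero denominator.
#' @return `e_p / e_q`.
#' @export
energy_ratio <- function(e_p, e_q, band_q = "denominator") {
  if (e_q <= 0)
    stop("degenerate band: zero energy in band '", band_q,
         "' (flat or broken frame?)", call. = FALSE)
  e_p / e_q
}

# (p, q) band-index pairs in the fixed published order; reduced = first 5.
ratio_pairs <- function(feature_set = c("full", "reduced")) {
  feature_set <- match.arg(feature_set)
  p <- cbind(p = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
             q = c(2, 3, 4, 5, 3, 4, 5, 4, 5, 5))
  if (feature_set == "reduced") p[1:5, , drop = FALSE] else p
}

#' Ratio labels of a feature set
#'
#' Full order: delta_theta, delta_alpha, delta_sigma, delta_beta,
#' theta_alpha, theta_sigma, theta_beta, alpha_sigma, alpha_beta,
#' sigma_beta. The reduced set is the first five (the low-to-high band
#' ratios that carry most of the apnea energy-shift signal).
#'
#' @param feature_set `"full"` (10 ratios) or `"reduced"` (5).
#' @param bands Band table; only `name` is used.
#' @return Character vector of ratio names.
#' @export
feature_names <- function(feature_set = c("full", "reduced"), bands = eeg_bands()) {
  pr <- ratio_pairs(feature_set)
  paste(bands$name[pr[, "p"]], bands$name[pr[, "q"]], sep = "_")
}

#' Energy-ratio feature vector of one frame
#'
#' Band-decomposes the frame, computes the five band energies and returns
#' the inter-band ratios in the fixed order of [feature_names()]. Ratios are
#' lower-band-first (`delta_theta` is \eqn{E_\delta/E_\theta}), raw
#' (no log transform), and scale-invariant in the input frame.
#'
#' @param frame Real-valued preprocessed frame.
#' @param sampling_rate Samples per second.
#' @param bands Band table as from [eeg_bands()].
#' @param feature_set `"full"` or `"reduced"`.
#' @param floor_zero If `TRUE`, a zero band energy is floored at
#'   `1e-12 * sum(frame^2)` instead of raising, for batch robustness.
#' @param edge_rule See [fft_band_filter()].
#' @return Named numeric vector of ratios.
#' @export
#' @examples
#' fr <- sin(2 * pi * 2 * (0:1279) / 128) + 0.1 * sin(2 * pi * 20 * (0:1279) / 128)
#' featurize(fr, 128)[["delta_beta"]]  # delta-dominant frame: ratio >> 1
featurize <- function(frame, sampling_rate, bands = eeg_bands(),
                      feature_set = c("full", "reduced"),
                      floor_zero = FALSE,
                      edge_rule = c("halfopen", "nearest")) {
  feature_set <- match.arg(feature_set)
  bs <- extract_bands(frame, sampling_rate, bands, edge_rule)
  e <- vapply(bs, band_energy, numeric(1))
  if (floor_zero) {
    eps <- 1e-12 * sum(frame^2)
    e <- pmax(e, eps)
  }
  pr <- ratio_pairs(feature_set)
  vals <- vapply(seq_len(nrow(pr)), function(i) {
    energy_ratio(e[[pr[i, "p"]]], e[[pr[i, "q"]]], bands$name[pr[i, "q"]])
  }, numeric(1))
  names(vals) <- feature_names(feature_set, bands)
  vals
}

#' Feature matrix of a labelled frame set
#'
#' Preprocesses each frame (DC removal, max-abs normalisation) and computes
#' its energy-ratio vector. This is the interchange surface between the
#' framing and classification stages.
#'
#' @param frames A labelled `frame_set` (see [label_frames()]).
#' @param bands,feature_set,floor_zero,edge_rule Passed to [featurize()].
#' @param subject_id Identifier stored in the `subject_id` column.
#' @param preprocess Apply [preprocess_frame()] first (default `TRUE`).
#' @return Data frame with columns `subject_id`, `frame_start_s`, `label`
#'   and one column per ratio.
#' @export
featurize_frames <- function(frames, bands = eeg_bands(),
                             feature_set = c("full", "reduced"),
                             floor_zero = FALSE,
                             edge_rule = c("halfopen", "nearest"),
                             subject_id = "subject", preprocess = TRUE) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(frames$labels))
    stop("frames must be labelled first (label_frames)", call. = FALSE)
  n <- nrow(frames$samples)
  fn <- feature_names(feature_set, bands)
  mat <- matrix(NA_real_, n, length(fn), dimnames = list(NULL, fn))
  for (i in seq_len(n)) {
    fr <- frames$samples[i, ]
    if (preprocess) fr <- preprocess_frame(fr)
    mat[i, ] <- tryCatch(
      featurize(fr, frames$sampling_rate, bands, feature_set, floor_zero, edge_rule),
      error = function(e) stop("frame at t=", frames$start[i], " s: ",
                               conditionMessage(e), call. = FALSE))
  }
  cbind(
    data.frame(subject_id = subject_id, frame_start_s = frames$start,
               label = frames$labels, stringsAsFactors = FALSE),
    as.data.frame(mat)
  )
}

#' Write / read a feature matrix as tab-separated text
#'
#' @param x Feature data frame as from [featurize_frames()].
#' @param path File path.
#' @return `read_feature_matrix` returns the data frame.
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "frame_start_s", "label")
  if (!all(need %in% names(x)))
    stop("feature matrix lacks required columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  x
}

# numeric feature columns of a feature data frame, as a matrix
feature_values <- function(x) {
  meta <- c("subject_id", "frame_start_s", "label")
  as.matrix(x[, setdiff(names(x), meta), drop = FALSE])
}
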