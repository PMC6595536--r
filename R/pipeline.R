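# End-to-end wiring: recording + annotations -> balanced labelled feature
# matrix, and cohort-level convenience runners.

#' Full feature-extraction pipeline for one subject
#'
#' average channels -> segment -> label -> balance -> preprocess ->
#' featurize, in that order.
#'
#' @param recording An `eeg_recording`.
#' @param annotations An `apnea_annotations`.
#' @param channels Two channel labels to average.
#' @param frame_duration Frame length in seconds.
#' @param guard Non-apnea guard distance in seconds.
#' @param balance_seed Seed for the non-apnea subsample.
#' @param feature_set `"full"` or `"reduced"`.
#' @param bands Band table.
#' @param subject_id Stored in the output.
#' @param patterns Apnea label substrings.
#' @return Feature data frame as from [featurize_frames()].
#' @export
extract_subject_features <- function(recording, annotations,
                                     channels = c("C3-A2", "C4-A1"),
                                     frame_duration = 10, guard = 30,
                                     balance_seed = 1L,
                                     feature_set = c("full", "reduced"),
                                     bands = eeg_bands(),
                                     subject_id = "subject",
                                     patterns = c("apnea", "hypopnea")) {
  feature_set <- match.arg(feature_set)
  avg <- average_channels(recording, channels)
  fr <- segment(avg, recording$sampling_rate, frame_duration)
  fr <- label_frames(fr, annotations, guard, patterns)
  fr <- balance_frames(fr, balance_seed)
  featurize_frames(fr, bands, feature_set, subject_id = subject_id)
}

#' Simulate a cohort of synthetic subjects and extract their features
#'
#' Each subject gets an independent seed derived from `seed`; all other
#' generator settings come from `config`.
#'
#' @param n_subjects Number of subjects.
#' @param config A [synth_config()] template (its `seed` is overridden).
#' @param seed Master seed.
#' @param feature_set,guard,frame_duration Passed through.
#' @return Named list of feature data frames (`S1`, `S2`, ...).
#' @export
simulate_cohort_features <- function(n_subjects = 5, config = synth_config(),
                                     seed = 1L,
                                     feature_set = c("full", "reduced"),
                                     guard = 30, frame_duration = 10) {
  feature_set <- match.arg(feature_set)
  out <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1009L + s * 7919L) %% .Machine$integer.max)
    gen <- generate_recording(cfg)
    out[[paste0("S", s)]] <- extract_subject_features(
      gen$recording, gen$annotations, frame_duration = frame_duration,
      guard = guard, balance_seed = cfg$seed, feature_set = feature_set,
      subject_id = paste0("S", s))
  }
  out
}

#' Bundled reference confusion matrices (five UCDDB subjects)
#'
#' Per-subject leave-one-out confusion matrices of the energy-ratio
#' detector on five PhysioNet UCDDB subjects, transcribed from the
#' published benchmark and shipped as plain text. Used as a fixed input for
#' metric-computation regression: feeding them through
#' [classification_metrics()] and [aggregate_metrics()] must reproduce the
#' published percentage tables.
#'
#' @return Data frame with columns `subject`, `tp`, `fn`, `fp`, `tn`.
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "ucddb_loo_confusion.tsv", package = "apneaband")
  if (path == "") stop("bundled confusion table not found", call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Metrics and aggregates from stored confusion matrices
#'
#' @param cm_table Data frame with columns `subject`, `tp`, `fn`, `fp`,
#'   `tn` (default: [reference_confusion()]).
#' @return List with `per_subject` (metrics per row) and `aggregates`
#'   (mean / sd / iqr rows).
#' @export
metrics_from_confusion <- function(cm_table = reference_confusion()) {
  per <- do.call(rbind, lapply(seq_len(nrow(cm_table)), function(i) {
    m <- classification_metrics(as.list(cm_table[i, c("tp", "fn", "fp", "tn")]))
    data.frame(subject = cm_table$subject[i],
               n_frames = sum(unlist(cm_table[i, c("tp", "fn", "fp", "tn")])),
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               accuracy = m[["accuracy"]], stringsAsFactors = FALSE)
  }))
  list(per_subject = per,
       aggregates = aggregate_metrics(per[, c("sensitivity", "specificity",
                                              "accuracy")]))
}
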