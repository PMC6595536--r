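# Seeded synthetic two-channel EEG with a controllable apnea band-energy
# shift, plus the matching annotation schedule. Synthesis uses the same FFT
# brick-wall filters as the analysis path, so the generated band structure
# is exactly what the feature extractor measures.

#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the structure the detector exploits: outside
#' events the averaged EEG concentrates its energy in the low bands
#' (delta-dominant sound sleep); inside annotated events energy shifts
#' toward the high bands (sigma/beta arousal activity). Both channels share
#' the band-structured component and receive independent additive Gaussian
#' noise, so two-channel averaging is measurably beneficial.
#'
#' @param sampling_rate Samples per second (default 128).
#' @param duration Recording length in seconds (integer).
#' @param band_weights_non_apnea,band_weights_apnea Named fractions of frame
#'   energy per band (`delta`, `theta`, `alpha`, `sigma`, `beta`); each must
#'   be non-negative and sum to 1. Defaults: non-apnea
#'   (0.70, 0.15, 0.08, 0.04, 0.03), apnea (0.25, 0.15, 0.15, 0.20, 0.25).
#' @param n_events Number of apnea events.
#' @param event_duration_range Min/max event duration in seconds
#'   (default `c(10, 25)`, the range reported for clinical events); the
#'   minimum must be at least one downstream frame so every event can
#'   contain a fully-enclosed frame.
#' @param inter_event_gap_min Minimum gap between events in seconds.
#' @param channel_noise_sd Per-channel noise SD relative to the unit-RMS
#'   band component (default 0.3).
#' @param amplitude Physical scale in microvolts applied to the unit-RMS
#'   signal (default 30, a typical sleep-EEG RMS).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(sampling_rate = 128,
                         duration = 600,
                         band_weights_non_apnea = c(delta = 0.70, theta = 0.15,
                                                    alpha = 0.08, sigma = 0.04,
                                                    beta = 0.03),
                         band_weights_apnea = c(delta = 0.25, theta = 0.15,
                                                alpha = 0.15, sigma = 0.20,
                                                beta = 0.25),
                         n_events = 5,
                         event_duration_range = c(10, 25),
                         inter_event_gap_min = 30,
                         channel_noise_sd = 0.3,
                         amplitude = 30,
                         seed = 1L) {
  check_weights <- function(w, what) {
    if (is.null(names(w)) || !setequal(names(w), eeg_bands()$name))
      stop(what, " must be named with the five band names", call. = FALSE)
    w <- w[eeg_bands()$name]
    if (any(w < 0)) stop(what, " must be non-negative", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-9) stop(what, " must sum to 1", call. = FALSE)
    w
  }
  cfg <- list(
    sampling_rate = sampling_rate,
    duration = as.integer(round(duration)),
    band_weights_non_apnea = check_weights(band_weights_non_apnea,
                                           "band_weights_non_apnea"),
    band_weights_apnea = check_weights(band_weights_apnea, "band_weights_apnea"),
    n_events = as.integer(n_events),
    event_duration_range = as.numeric(event_duration_range),
    inter_event_gap_min = as.numeric(inter_event_gap_min),
    channel_noise_sd = as.numeric(channel_noise_sd),
    amplitude = as.numeric(amplitude),
    seed = as.integer(seed)
  )
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (cfg$duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (cfg$n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  if (length(cfg$event_duration_range) != 2 ||
      cfg$event_duration_range[1] > cfg$event_duration_range[2] ||
      cfg$event_duration_range[1] <= 0)
    stop("event_duration_range must be (min, max) with 0 < min <= max", call. = FALSE)
  if (cfg$channel_noise_sd < 0) stop("channel_noise_sd must be >= 0", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' Band-limited Gaussian noise with an exact target energy
#'
#' White Gaussian noise passed through the analysis brick-wall filter for
#' the band and rescaled so its sum of squares equals `target_energy`
#' exactly. Spectral content is therefore confined to `[lo, hi)` by
#' construction.
#'
#' @param lo,hi Band edges in Hz, `lo < hi <= sampling_rate / 2`.
#' @param n_samples Number of samples (> 0).
#' @param sampling_rate Samples per second.
#' @param target_energy Desired sum of squares (>= 0; 0 gives all zeros).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_band_noise <- function(lo, hi, n_samples, sampling_rate,
                                target_energy = 1, seed = NULL) {
  if (!(lo < hi)) stop("invalid band edges: need lo < hi", call. = FALSE)
  if (hi > sampling_rate / 2)
    stop("invalid band edges: hi exceeds the Nyquist frequency", call. = FALSE)
  if (n_samples <= 0) stop("n_samples must be > 0", call. = FALSE)
  if (target_energy < 0) stop("target_energy must be >= 0", call. = FALSE)
  if (target_energy == 0) return(numeric(n_samples))
  gen <- function() {
    y <- fft_band_filter(stats::rnorm(n_samples), sampling_rate, lo, hi)
    e <- sum(y^2)
    if (e == 0)
      stop("band [", lo, ", ", hi, ") Hz contains no DFT bin at n=",
           n_samples, ", fs=", sampling_rate, call. = FALSE)
    y * sqrt(target_energy / e)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Uniform draw of a feasible, ordered, non-overlapping event schedule:
# sorted uniforms over the slack plus cumulative durations and minimum
# gaps. Equivalent to rejection-sampling independent onsets conditioned on
# feasibility, but O(n) and never stalls at high event density.
sample_schedule <- function(duration, n_events, dur_range, gap_min) {
  if (n_events == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0)))
  durs <- if (dur_range[1] == dur_range[2]) rep(dur_range[1], n_events)
          else sample(seq(dur_range[1], dur_range[2]), n_events, replace = TRUE)
  slack <- duration - sum(durs) - (n_events - 1) * gap_min
  if (slack < 0)
    stop("infeasible schedule: ", n_events, " events of up to ",
         dur_range[2], " s with ", gap_min, " s gaps do not fit in ",
         duration, " s", call. = FALSE)
  u <- sort(floor(stats::runif(n_events, 0, slack + 1)))
  u <- pmin(u, slack)
  onsets <- u + c(0, cumsum(durs[-n_events])) + (seq_len(n_events) - 1) * gap_min
  data.frame(onset = onsets, duration = durs)
}

#' Generate a synthetic two-channel EEG recording with apnea annotations
#'
#' Draws an event schedule (integer-second onsets and durations, uniform
#' over feasible placements), then synthesises one stationary band-limited
#' Gaussian noise process per EEG band (brick-wall filtered white noise,
#' normalised to unit per-sample energy over the recording) and mixes them
#' with time-varying gains `sqrt(w_band(t))`, where the weights switch to
#' `band_weights_apnea` inside annotated events. Both channels, `C3-A2`
#' and `C4-A1`, share that component and receive independent Gaussian
#' noise. Transitions are hard splices; boundary frames are excluded
#' downstream anyway. Because the per-band processes are stationary, equal
#' apnea and non-apnea weights make the two classes statistically
#' indistinguishable by construction; per-frame band-energy fractions
#' fluctuate (chi-square) around the configured weights and match them in
#' the mean.
#'
#' @param config A [synth_config()].
#' @return List with elements `recording` (an `eeg_recording`, microvolts)
#'   and `annotations` (an `apnea_annotations`, labels `"apnea"`).
#' @export
#' @examples
#' out <- generate_recording(synth_config(duration = 120, n_events = 2, seed = 42))
#' out$recording
#' out$annotations
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n_total <- as.integer(config$duration * fs)
  bands <- eeg_bands()
  with_seed(config$seed, {
    sched <- sample_schedule(config$duration, config$n_events,
                             config$event_duration_range,
                             config$inter_event_gap_min)
    # per-sample apnea indicator -> contiguous segments
    apnea_flag <- logical(n_total)
    if (nrow(sched)) {
      for (i in seq_len(nrow(sched))) {
        a <- floor(sched$onset[i] * fs) + 1L
        b <- floor((sched$onset[i] + sched$duration[i]) * fs)
        apnea_flag[a:min(b, n_total)] <- TRUE
      }
    }
    base <- numeric(n_total)
    for (bi in seq_len(nrow(bands))) {
      bn <- bands$name[bi]
      w_non <- config$band_weights_non_apnea[[bn]]
      w_apn <- config$band_weights_apnea[[bn]]
      if (w_non == 0 && w_apn == 0) next
      nb <- fft_band_filter(stats::rnorm(n_total), fs, bands$lo[bi], bands$hi[bi])
      nb <- nb / sqrt(sum(nb^2) / n_total)      # unit per-sample energy
      gain <- sqrt(ifelse(apnea_flag, w_apn, w_non))
      base <- base + gain * nb
    }
    ch <- lapply(1:2, function(i)
      config$amplitude * (base + stats::rnorm(n_total, 0, config$channel_noise_sd)))
    names(ch) <- c("C3-A2", "C4-A1")
    list(
      recording = new_recording(ch, fs),
      annotations = if (nrow(sched))
        new_annotations(sched$onset, sched$duration, rep("apnea", nrow(sched)))
      else new_annotations()
    )
  })
}

#' Write a synthetic recording and its annotations to disk
#'
#' Emits the recording as EDF (`<stem>.edf`), as delimited text
#' (`<stem>.tsv`, one column per channel), and the annotations as a
#' 3-column TSV (`<stem>_events.tsv`).
#'
#' @param out Result of [generate_recording()].
#' @param stem Output path stem (directory must exist).
#' @param formats Subset of `c("edf", "delim")`.
#' @return Named character vector of the files written.
#' @export
write_synthetic <- function(out, stem, formats = c("edf", "delim")) {
  files <- c()
  if ("edf" %in% formats) {
    f <- paste0(stem, ".edf"); write_edf(out$recording, f)
    files["edf"] <- f
  }
  if ("delim" %in% formats) {
    f <- paste0(stem, ".tsv"); write_recording_delim(out$recording, f)
    files["signal_tsv"] <- f
  }
  f <- paste0(stem, "_events.tsv"); write_annotations(out$annotations, f)
  files["annotations"] <- f
  files
}
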