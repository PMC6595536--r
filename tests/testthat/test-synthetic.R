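# synthetic_data: band-limited noise and full recordings

test_that("band noise hits its target energy and stays in band", {
  y <- generate_band_noise(8, 12, 1280, 128, target_energy = 1, seed = 51)
  expect_equal(sum(y^2), 1, tolerance = 1e-6)
  bs <- extract_bands(y, 128)
  for (b in c("delta", "theta", "sigma", "beta"))
    expect_lt(band_energy(bs[[b]]), 1e-6)
  expect_equal(band_energy(bs$alpha), 1, tolerance = 1e-6)
})

test_that("band noise edge cases and determinism", {
  expect_equal(generate_band_noise(8, 12, 64, 128, 0), numeric(64))
  y1 <- generate_band_noise(0.25, 4, 256, 128, 2, seed = 9)
  y2 <- generate_band_noise(0.25, 4, 256, 128, 2, seed = 9)
  expect_identical(y1, y2)
  y3 <- generate_band_noise(0.25, 4, 256, 128, 2, seed = 10)
  expect_false(identical(y1, y3))
  expect_error(generate_band_noise(12, 8, 64, 128), "lo < hi")
  expect_error(generate_band_noise(16, 70, 64, 128), "Nyquist")
  expect_error(generate_band_noise(0.25, 4, 0, 128), "n_samples")
  expect_error(generate_band_noise(0.25, 4, 16, 128), "no DFT bin")
})

test_that("config validation enforces the stated invariants", {
  expect_error(synth_config(band_weights_apnea = c(delta = 1)), "band names")
  w <- c(delta = 0.5, theta = 0.2, alpha = 0.1, sigma = 0.1, beta = 0.05)
  expect_error(synth_config(band_weights_apnea = w), "sum to 1")
  expect_error(synth_config(event_duration_range = c(25, 10)), "min <= max")
  expect_error(generate_recording(synth_config(duration = 100, n_events = 10)),
               "infeasible")
})

test_that("recordings honour the schedule and are seed-reproducible", {
  cfg <- synth_config(duration = 600, n_events = 5, seed = 52)
  out <- generate_recording(cfg)
  ann <- out$annotations
  expect_equal(nrow(ann), 5)
  expect_true(all(ann$duration >= 10 & ann$duration <= 25))
  expect_true(all(ann$onset >= 0 & ann$onset + ann$duration <= 600))
  gaps <- ann$onset[-1] - (ann$onset + ann$duration)[-5]
  expect_true(all(gaps >= cfg$inter_event_gap_min))
  expect_equal(names(out$recording$channels), c("C3-A2", "C4-A1"))
  expect_equal(out$recording$n_samples, 600 * 128)

  out2 <- generate_recording(cfg)
  expect_identical(out$recording$channels, out2$recording$channels)
  out3 <- generate_recording(synth_config(duration = 600, n_events = 5, seed = 53))
  expect_false(identical(out$recording$channels[[1]], out3$recording$channels[[1]]))

  out0 <- generate_recording(synth_config(duration = 120, n_events = 0, seed = 1))
  expect_equal(nrow(out0$annotations), 0)
})

test_that("noise-free synthesis realises the configured band fractions", {
  # whole-recording fractions are exact up to inter-band leakage
  cfg <- synth_config(duration = 60, n_events = 0, channel_noise_sd = 0, seed = 54)
  out <- generate_recording(cfg)
  x <- average_channels(out$recording)
  e <- vapply(extract_bands(x, 128), band_energy, numeric(1))
  expect_true(all(abs(e / sum(e) - cfg$band_weights_non_apnea) < 0.02))
  # individual frames fluctuate (chi-square); their mean matches the weights
  cfg2 <- synth_config(duration = 600, n_events = 0, channel_noise_sd = 0, seed = 55)
  out2 <- generate_recording(cfg2)
  fr <- segment(average_channels(out2$recording), 128, 10)
  fracs <- t(apply(fr$samples, 1, function(f) {
    e <- vapply(extract_bands(f, 128), band_energy, numeric(1)); e / sum(e)
  }))
  expect_true(all(abs(colMeans(fracs) - cfg2$band_weights_non_apnea) < 0.02))
})

test_that("apnea frames show the low-to-high energy shift", {
  cfg <- synth_config(duration = 1500, n_events = 12, seed = 56)
  out <- generate_recording(cfg)
  feats <- extract_subject_features(out$recording, out$annotations,
                                    balance_seed = 1, subject_id = "S")
  db <- feats$delta_beta
  expect_lt(mean(db[feats$label == "apnea"]),
            mean(db[feats$label == "non_apnea"]))
  expect_lt(median(db[feats$label == "apnea"]),
            median(db[feats$label == "non_apnea"]))
})

test_that("synthetic writer emits EDF, signal TSV and annotations", {
  dir <- withr::local_tempdir()
  out <- generate_recording(synth_config(duration = 60, n_events = 1,
                                         inter_event_gap_min = 5, seed = 57))
  files <- write_synthetic(out, file.path(dir, "syn"))
  expect_true(all(file.exists(files)))
  r <- read_recording(files[["edf"]])
  expect_equal(r$n_samples, 60 * 128)
  a <- read_annotations(files[["annotations"]])
  expect_equal(nrow(a), 1)
  expect_equal(a$onset, out$annotations$onset)
})
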