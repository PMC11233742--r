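test_that("resampling preserves tones and rejects aliases", {
  x <- sin(2 * pi * 5 * seq_len(5000) / 500)
  expect_identical(resample_channel(x, 500, 500), x)
  y <- resample_channel(x, 500, 128)
  expect_length(y, round(5000 * 128 / 500))
  expect_lt(abs(peak_freq(y, 128) - 5), 128 / length(y) * 2) # one bin
  # 60 Hz tone folded to 40 Hz must be attenuated >= 20 dB vs naive decimation
  z <- sin(2 * pi * 60 * seq_len(5000) / 500)
  dec <- z[seq(1, 5000, by = 5)]
  res <- resample_channel(z, 500, 100)
  p_at <- function(v, fs, f0) {
    s <- stats::spec.pgram(stats::ts(v, frequency = fs), plot = FALSE,
                           taper = 0)
    mean(s$spec[abs(s$freq - f0) < 1])
  }
  expect_gt(10 * log10(p_at(dec, 100, 40) / p_at(res, 100, 40)), 20)
})

test_that("zero-phase bandpass rejects DC, keeps passband, passes unfiltered kinds", {
  fs <- 500
  const <- rep(3, fs * 10)
  out <- bandpass(const, fs, 0.3, 50)
  expect_lt(max(abs(out)), 1e-6 * 3)
  tone <- sin(2 * pi * 10 * seq_len(fs * 10) / fs)
  flt <- bandpass(tone, fs, 0.3, 50)
  mid <- (fs * 2):(fs * 8)
  expect_equal(sd(flt[mid]), sd(tone[mid]), tolerance = 0.05)
  # idempotence in the passband (within 2%)
  flt2 <- bandpass(flt, fs, 0.3, 50)
  expect_equal(sd(flt2[mid]), sd(flt[mid]), tolerance = 0.02)
  expect_identical(bandpass(tone, fs, NA, NA), tone)
  expect_error(bandpass(tone, fs, 0.3, 300), "Nyquist")
})

test_that("stage decomposition keeps only sleep epochs with joint bookkeeping", {
  fs <- 100
  ch <- channel_signal("EEGO1_A2", "EEG", seq_len(fs * 120), fs)
  hyp <- hypnogram(c("N2", "N2", "W", "N2"))
  dec <- decompose_stages(ch, hyp)
  expect_named(dec, "N2")
  expect_length(dec$N2$samples, 9000)
  expect_identical(joint_offsets(dec$N2), 6001L)
  # temporal order and exact sample content
  expect_identical(dec$N2$samples, as.numeric(c(seq_len(6000),
                                                9001:12000)))
  expect_length(decompose_stages(ch, hypnogram(rep("W", 4))), 0L)
  # conservation across all stages
  hyp2 <- hypnogram(c("N1", "N2", "N3", "REM", "W", "N2"))
  ch2 <- channel_signal("EEGO1_A2", "EEG", rnorm(fs * 180), fs)
  dec2 <- decompose_stages(ch2, hyp2)
  tot <- sum(vapply(dec2, function(s) length(s$samples), numeric(1))) / fs
  expect_equal(tot, 5 * 30)
  expect_error(decompose_stages(ch, hypnogram(rep("N2", 10))), "longer")
})

test_that("artifact grid drops overlapping 10-s segments and tails", {
  fs <- 128
  sig <- stage_signal("EEGO1_A2", "EEG", "N2", fs, rnorm(95 * fs),
                      data.frame(src_start_s = 0, dur_s = 95))
  kept <- drop_artifact_segments(sig, artifact_intervals())
  expect_length(kept$samples, 11520) # 9 segments, 5-s tail dropped
  gone <- drop_artifact_segments(sig, artifact_intervals(0, 95, "*"))
  expect_length(gone$samples, 0)
  # one artifact strictly inside segment 3 -> 8 segments survive
  one <- drop_artifact_segments(sig, artifact_intervals(23, 24, "*"))
  expect_length(one$samples, 8 * 10 * fs)
  # artifact for a different channel does not apply
  other <- drop_artifact_segments(sig, artifact_intervals(23, 24, "EMGChin"))
  expect_length(other$samples, 9 * 10 * fs)
})

test_that("preprocess_record produces both analysis streams with conservation", {
  gen <- generate_record(night_spec(duration_min = 6, artifact_per_h = 0),
                         seed = 3)
  pre <- preprocess_record(gen$record)
  expect_setequal(names(pre), names(gen$record$channels))
  eeg <- pre$EEGO1_A2
  st <- names(eeg$feature)[1]
  expect_gt(length(st), 0)
  expect_equal(eeg$feature[[st]]$fs, 128)
  expect_equal(eeg$spectral[[st]]$fs, 500) # EEG fsf
  expect_equal(pre$EMGChin$spectral[[st]]$fs, 200) # EMG fsf
  # conservation: kept + wake == hypnogram span (no artifacts, whole epochs)
  hyp <- gen$record$hypnogram
  kept_s <- sum(vapply(eeg$feature, function(s) length(s$samples) / s$fs,
                       numeric(1)))
  wake_s <- sum(hyp$stages == "W") * hyp$epoch_s
  expect_equal(kept_s + wake_s, hypnogram_span_s(hyp))
  # determinism: same record preprocessed twice is bit-identical
  pre2 <- preprocess_record(gen$record)
  expect_identical(pre, pre2)
})

test_that("unknown channel kind without filter spec errors", {
  rec <- generate_record(night_spec(duration_min = 2), seed = 1)$record
  cfg <- preprocess_config(filters = default_filter_table()[1:2, ])
  expect_error(preprocess_record(rec, cfg), "no filter specification")
})
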