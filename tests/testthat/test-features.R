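test_that("time-domain block matches hand values and degenerate rules", {
  td <- time_domain_features(rep(2, 10))
  expect_equal(td, list(rms = 2, var = 0, sk = 0, kurt = 0, max = 2))
  alt <- time_domain_features(rep(c(1, -1), 10))
  expect_equal(alt$rms, 1); expect_equal(alt$var, 1); expect_equal(alt$sk, 0)
  set.seed(7)
  g <- rnorm(15360)
  tg <- time_domain_features(g)
  expect_lt(abs(tg$sk), 0.06)
  expect_lt(abs(tg$kurt - 3), 0.12)
})

test_that("Shannon entropy counts equal-width amplitude bins in bits", {
  expect_equal(shannon_entropy(rep(1, 100)), 0)
  # samples uniformly filling 16 bins -> 4 bits
  x <- rep(seq(0.5, 15.5, by = 1), each = 10) / 16
  expect_equal(shannon_entropy(x, 16), 4)
  expect_equal(shannon_entropy(rep(c(0, 1), 50), 16), 1)
})

test_that("sample entropy equals the exhaustive oracle and known limits", {
  per <- rep(c(1, 2, 3), length.out = 60)
  expect_equal(sample_entropy(per, 2, 0.2), 0)
  for (s in 1:8) {
    set.seed(s)
    n <- sample(30:200, 1)
    m <- sample(1:3, 1)
    x <- if (s %% 2) rnorm(n) else round(rnorm(n), 1)
    expect_equal(sample_entropy(x, m, 0.2),
                 brute_sampen(x, m, 0.2 * sd(x)),
                 info = paste("seed", s))
  }
  expect_true(is.na(sample_entropy(rep(1, 50))))
  # white noise more entropic than its low-pass filtered version
  wins <- vapply(1:40, function(s) {
    set.seed(s)
    w <- rnorm(800)
    lp <- as.numeric(stats::filter(w, rep(1 / 8, 8), sides = 2))
    lp <- lp[!is.na(lp)]
    sample_entropy(w, 2, 0.2) > sample_entropy(lp, 2, 0.2)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("LZ76 complexity: hand parse, ordered below random, asymptotics", {
  # all samples equal the median -> all-zero binary sequence
  expect_equal(lempel_ziv(seq_len(1024) * 0), 2 * log2(1024) / 1024)
  expect_equal(somnomark:::lz76_cpp(integer(1024)), 2L)
  set.seed(1)
  rnd <- lempel_ziv(rnorm(4096))
  alt <- lempel_ziv(rep(c(0, 1), 2048))
  expect_lt(alt, rnd / 3)
  inside <- vapply(1:40, function(s) {
    set.seed(s)
    v <- lempel_ziv(rnorm(1e4))
    v >= 0.9 && v <= 1.15
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("Higuchi dimension: line 1, white noise 2, sine below noise", {
  line <- seq(0, 5, length.out = 2000)
  expect_equal(as.numeric(higuchi_fd(line)), 1, tolerance = 0.01)
  for (s in 1:10) {
    set.seed(s)
    w <- as.numeric(higuchi_fd(rnorm(15360)))
    expect_equal(w, 2, tolerance = 0.1)
    sine <- as.numeric(higuchi_fd(sin(2 * pi * 5 * seq_len(2000) / 200)))
    expect_lt(sine, w)
  }
  expect_true(is.na(higuchi_fd(rep(1, 200))))
})

test_that("Welch PSD locates tones and conserves unit variance", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq_len(fs * 120) / fs)
  est <- welch_psd(x, fs, 65536)
  expect_equal(est$freqs[which.max(est$psd)], 10, tolerance = fs / 65536 * 2)
  set.seed(3)
  z <- rnorm(fs * 120)
  estz <- welch_psd(z, fs, 65536)
  total <- sum(diff(estz$freqs) *
                 (head(estz$psd, -1) + tail(estz$psd, -1)) / 2)
  expect_equal(total, 1, tolerance = 0.1)
  # flat spectrum for white noise over 1-40 Hz
  bandavg <- vapply(seq(1, 39, by = 2), function(f0)
    mean(estz$psd[estz$freqs >= f0 & estz$freqs < f0 + 2]), numeric(1))
  expect_lt(max(bandavg) / min(bandavg), 3)
  expect_error(welch_psd(z, fs, 1), "nfft")
})

test_that("spectral features: band powers, DF, MF", {
  fs <- 500
  bands <- default_spectral_bands()$EEG
  est <- welch_psd(sin(2 * pi * 10 * seq_len(fs * 120) / fs), fs, 65536)
  sf <- spectral_features(est, bands)
  sub <- unlist(sf[c("delta", "theta", "alpha", "lowBeta", "highBeta",
                     "gamma", "sp")])
  expect_identical(names(which.max(sub)), "alpha")
  expect_equal(sf$DF, 10, tolerance = 0.1)
  expect_equal(sf$MF, 10, tolerance = 0.1)
  expect_gte(sf$beta + 1e-9, sf$lowBeta + sf$highBeta) # 22-23 Hz gap
  # two equal tones straddle the median frequency
  two <- sin(2 * pi * 5 * seq_len(fs * 120) / fs) +
    sin(2 * pi * 20 * seq_len(fs * 120) / fs)
  sf2 <- spectral_features(welch_psd(two, fs, 65536), bands)
  expect_gt(sf2$MF, 5); expect_lt(sf2$MF, 20)
  expect_error(spectral_features(est, data.frame(name = "x", low = 100,
                                                 high = 400)),
               "outside")
})

test_that("window arithmetic follows the 2-min / 50% overlap rule", {
  expect_equal(n_feature_windows(600), 9L)
  expect_equal(n_feature_windows(119), 0L)
  expect_equal(n_feature_windows(120), 1L)
  sig <- stage_signal("EffortTHO", "Effort", "N2", 128, rnorm(128 * 120),
                      data.frame(src_start_s = 0, dur_s = 120))
  sf <- stage_features(sig, NULL)
  expect_equal(sf$n_windows, 1L)
  # single window: stage value equals window value exactly
  w <- sig$samples
  expect_equal(unname(sf$values["rms"]), sqrt(mean(w^2)))
  short <- stage_signal("EffortTHO", "Effort", "N2", 128, rnorm(128 * 119),
                        data.frame(src_start_s = 0, dur_s = 119))
  expect_equal(stage_features(short, NULL)$n_windows, 0L)
})

test_that("offset and scale invariances hold per feature", {
  set.seed(11)
  base <- rnorm(128 * 120)
  sig <- function(x) stage_signal("EEGO1_A2", "EEG", "N2", 128, x,
                                  data.frame(src_start_s = 0, dur_s = 120))
  spc <- function(x) stage_signal("EEGO1_A2", "EEG", "N2", 500,
                                  rep(x, length.out = 500 * 120),
                                  data.frame(src_start_s = 0, dur_s = 120))
  f0 <- stage_features(sig(base), spc(base))$values
  f_off <- stage_features(sig(base + 7), spc(base + 7))$values
  moved <- names(f0)[abs(f0 - f_off) > 1e-6 * pmax(1, abs(f0))]
  # rms = sqrt(mean^2 + var) necessarily follows the offset; everything else
  # except max must be invariant
  expect_identical(sort(moved), c("max", "rms"))
  f_scl <- stage_features(sig(base * 3), spc(base * 3))$values
  expect_equal(unname(f_scl["rms"]), unname(3 * f0["rms"]))
  expect_equal(unname(f_scl["var"]), unname(9 * f0["var"]))
  for (nm in c("sk", "kurt", "ShanEnt", "LempZiv", "HFD", "MF", "DF"))
    expect_equal(unname(f_scl[nm]), unname(f0[nm]), tolerance = 1e-8,
                 info = nm)
})

test_that("extract_psgvar emits the naming grid with spectral eligibility", {
  gen <- generate_record(night_spec(duration_min = 8, artifact_per_h = 0),
                         seed = 21)
  pre <- preprocess_record(gen$record)
  pv <- extract_psgvar(pre, params = nonlinear_params(sampen_decimate = 4),
                       window_s = 60, overlap = 0.5)
  expect_true(all(grepl("^[A-Za-z0-9_]+_(N1|N2|N3|REM)$", pv$feature)))
  stages <- unique(sub(".*_", "", pv$feature))
  # per stage present: EEG channels have 9 + 2 + 9 codes, Effort only 9
  st <- stages[1]
  eeg_codes <- pv$feature[grepl(paste0("^EEGO1_A2_.*_", st, "$"), pv$feature)]
  eff_codes <- pv$feature[grepl(paste0("^EffortTHO_.*_", st, "$"),
                                pv$feature)]
  expect_length(eeg_codes, 9 + 2 + 9) # td+nl, MF/DF, TotalPw + 8 sub-bands
  expect_length(eff_codes, 9)         # no spectral block for Effort
  expect_true(paste0("EEGO1_A2_sk_", st) %in% pv$feature)
})
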