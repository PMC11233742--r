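test_that("EDF round-trip preserves labels, rates and samples to quantization", {
  set.seed(42)
  rec <- psg_record("S042", list(
    channel_signal("EEGO1_A2", "EEG", rnorm(10 * 128, sd = 40), 128),
    channel_signal("SpO2", "SpO2", 90 + runif(10, 0, 8), 1),
    channel_signal("Airflow", "Airflow",
                   sin(2 * pi * 0.25 * seq_len(1000) / 100), 100)))
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  rec2 <- read_edf(p)
  expect_identical(names(rec2$channels), names(rec$channels))
  expect_identical(rec2$subject_id, "S042")
  for (lab in names(rec$channels)) {
    a <- rec$channels[[lab]]; b <- rec2$channels[[lab]]
    expect_equal(b$fs, a$fs)
    expect_length(b$samples, length(a$samples))
    step <- diff(range(a$samples)) / 65535
    expect_lte(max(abs(a$samples - b$samples)), step)
  }
  # 1 Hz channel stored and recovered at 1 Hz: inspect header directly
  con <- file(p, "rb")
  hdr <- readChar(con, 256 + 3 * 256, useBytes = TRUE)
  close(con)
  spr <- substr(hdr, 256 + 3 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 8 + 1,
                256 + 3 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 16)
  expect_match(spr, "1") # second signal, 1 sample per 1-s record
})

test_that("channel lengths follow duration times rate", {
  ch <- channel_signal("EEGO1_A2", "EEG", numeric(1280), 128)
  expect_length(ch$samples, round(10 * 128))
  expect_error(channel_signal("X", "EEG", c(1, NA), 10), "non-finite")
  expect_error(channel_signal("X", "EEG", 1:10, -1), "positive")
})

test_that("write_edf validates its input", {
  expect_error(psg_record("S1", list()), "length")
  rec <- psg_record("S1", list(channel_signal("EEGO1_A2", "EEG",
                                              rnorm(128 * 2), 128)))
  # non-integer number of seconds is rejected
  bad <- psg_record("S1", list(channel_signal("EEGO1_A2", "EEG",
                                              rnorm(192), 128)))
  expect_error(write_edf(bad, tempfile()), "whole number of seconds")
  expect_silent(write_edf(rec, withr::local_tempfile(fileext = ".edf")))
})

test_that("synthetic 9-channel record maps onto the expected kinds", {
  gen <- generate_record(night_spec(duration_min = 2), seed = 5)
  kinds <- sort(vapply(gen$record$channels, function(ch) ch$kind,
                       character(1)))
  expect_identical(unname(table(kinds)[c("EEG")]), 2L)
  expect_setequal(unique(kinds),
                  c("EEG", "EOG", "EMG", "Effort", "Airflow", "SpO2",
                    "ECG", "Snore"))
  expect_length(gen$record$channels, 9L)
  # kind inference from labels agrees with the generator's assignment
  for (ch in gen$record$channels)
    expect_identical(somnomark:::infer_kind(ch$label), ch$kind)
})

test_that("hypnogram TSV round-trips and rejects bad labels", {
  hyp <- hypnogram(rep("N2", 840))
  expect_equal(hypnogram_span_s(hyp), 840 * 30) # 7 h
  p <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(hyp, p)
  hyp2 <- read_hypnogram(p)
  expect_identical(hyp2$stages, hyp$stages)
  writeLines(c("epoch\tstage", "1\tN2", "2\tX1"), p)
  expect_error(read_hypnogram(p), "row\\(s\\) 2")
})

test_that("artifact TSV validates interval order", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("start_s\tend_s\tchannel", "10\t5\t*"), p)
  expect_error(read_artifacts(p), "row\\(s\\) 1")
  writeLines(c("start_s\tend_s\tchannel", "10\t25\tEEGO1_A2"), p)
  a <- read_artifacts(p)
  expect_equal(a$end_s, 25)
  expect_error(artifact_intervals(5, 5), "start_s < end_s")
})
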