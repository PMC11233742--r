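# Independent oracles and small fixture builders used across the suite.

# exhaustive O(N^2) sample-entropy template counter (Richman-Moorman,
# self-matches excluded); the reference the fast implementation must equal
brute_sampen <- function(x, m, r) {
  n <- length(x)
  B <- 0L; A <- 0L
  for (i in seq_len(n - m)) for (j in seq_len(n - m)) {
    if (j <= i) next
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1L
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) NA_real_ else -log(A / B)
}

# constant-rate sine channel helper
sine_channel <- function(label, kind, freq, fs, dur_s, amp = 1) {
  t <- seq_len(dur_s * fs) / fs
  channel_signal(label, kind, amp * sin(2 * pi * freq * t), fs)
}

# dominant frequency of a vector via a plain periodogram (no Welch machinery)
peak_freq <- function(x, fs) {
  s <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                         taper = 0)
  s$freq[which.max(s$spec)]
}

# a tiny complete cohort bundle in feature mode
tiny_cohort <- function(n = 61, miss_psg = 3, miss_bio = 9, seed = 1) {
  generate_cohort(cohort_spec(n, miss_psg, miss_bio, mode = "feature"),
                  seed = seed)
}
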