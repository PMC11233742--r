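#' Non-linear feature parameters
#'
#' Field-conventional defaults for the four complexity measures: sample
#' entropy with embedding dimension \code{m = 2} and tolerance \code{r = 0.2}
#' of the window SD; Shannon entropy over 16 equal-width amplitude bins (in
#' bits); LZ76 complexity after median binarization; Higuchi fractal dimension
#' with \code{kmax = 10}.
#'
#' @param sampen_m embedding dimension (>= 1).
#' @param sampen_r tolerance as a fraction of the window SD (> 0).
#' @param shannon_bins histogram bin count (>= 2).
#' @param hfd_kmax maximum delay for the Higuchi construction (>= 2).
#' @param sampen_decimate optional integer decimation factor applied to the
#'   window before sample entropy only (its cost is quadratic in the window
#'   length); 1 = none. The factor in effect is recorded with the results.
#' @return list of class \code{nonlinear_params}.
#' @export
nonlinear_params <- function(sampen_m = 2L, sampen_r = 0.2,
                             shannon_bins = 16L, hfd_kmax = 10L,
                             sampen_decimate = 1L) {
  stopifnot(sampen_m >= 1, sampen_r > 0, shannon_bins >= 2, hfd_kmax >= 2,
            sampen_decimate >= 1)
  structure(list(sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 shannon_bins = as.integer(shannon_bins),
                 hfd_kmax = as.integer(hfd_kmax),
                 sampen_decimate = as.integer(sampen_decimate)),
            class = "nonlinear_params")
}

#' Spectral band definitions per signal kind
#'
#' EOG/EMG carry only the total 0.5-30 Hz band (plus median and dominant
#' frequency); EEG additionally the classical sub-bands delta 0.5-4, theta
#' 4-7, alpha 8-12, lowBeta 14-22, highBeta 23-30, beta 14-30, gamma 31-40 and
#' the spindle band 12-14 Hz; Airflow uses 0.025-0.05 Hz (respiratory
#' periodicity) and SpO2 0.014-0.033 Hz (desaturation periodicity). MF and DF
#' are computed over each kind's total band.
#'
#' @return named list: per kind, a data.frame(name, low, high) whose first row
#'   is the total band, plus an \code{nfft} attribute per kind.
#' @export
default_spectral_bands <- function() {
  eeg <- data.frame(
    name = c("TotalPw", "delta", "theta", "alpha", "lowBeta", "highBeta",
             "beta", "gamma", "sp"),
    low  = c(0.5, 0.5, 4, 8, 14, 23, 14, 31, 12),
    high = c(30, 4, 7, 12, 22, 30, 30, 40, 14),
    stringsAsFactors = FALSE)
  simple <- function(lo, hi) data.frame(name = "TotalPw", low = lo, high = hi,
                                        stringsAsFactors = FALSE)
  list(EOG = simple(0.5, 30), EEG = eeg, EMG = simple(0.5, 30),
       Airflow = simple(0.025, 0.05), SpO2 = simple(0.014, 0.033))
}

#' Welch FFT lengths per signal kind
#' @return named integer vector (kinds without spectral features omitted).
#' @export
default_nfft <- function() {
  c(EOG = 65536L, EEG = 65536L, EMG = 32768L, Airflow = 16384L, SpO2 = 128L)
}

#' Time-domain amplitude statistics of a window
#'
#' Root mean square, population variance, skewness and kurtosis (standardized
#' 3rd/4th central moments; kurtosis is not excess-corrected, so Gaussian data
#' sit near 3), and the maximum value. A zero-variance window yields
#' skewness = kurtosis = 0 by convention.
#'
#' @param window numeric vector, length >= 4.
#' @return named list \code{rms, var, sk, kurt, max}.
#' @export
time_domain_features <- function(window) {
  stopifnot(length(window) >= 4L)
  m <- mean(window)
  v <- mean((window - m)^2)
  if (v == 0) {
    sk <- 0; kurt <- 0
  } else {
    sk <- mean((window - m)^3) / v^1.5
    kurt <- mean((window - m)^4) / v^2
  }
  list(rms = sqrt(mean(window^2)), var = v, sk = sk, kurt = kurt,
       max = max(window))
}

#' Shannon entropy of the amplitude histogram
#'
#' Entropy (bits) of the equal-width histogram over \code{[min, max]} of the
#' window; empty bins contribute nothing; a constant window has entropy 0.
#'
#' @param window numeric vector.
#' @param bins number of equal-width bins (>= 2).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(window, bins = 16L) {
  stopifnot(bins >= 2L)
  lo <- min(window); hi <- max(window)
  if (lo == hi) return(0)
  idx <- pmin(bins, findInterval(window, seq(lo, hi, length.out = bins + 1),
                                 rightmost.closed = TRUE))
  p <- tabulate(idx, nbins = bins) / length(window)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sample entropy
#'
#' \code{-ln(A/B)} where \code{B} counts template pairs of length \code{m}
#' within Chebyshev distance \code{r} and \code{A} the same at length
#' \code{m + 1}; self-matches excluded (Richman-Moorman). The tolerance is
#' \code{r_frac} times the window SD. Returns \code{NA} when either count is
#' zero or the window is constant.
#'
#' @param window numeric vector of length > \code{m + 1}.
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of the window SD.
#' @return non-negative value, or \code{NA}.
#' @export
sample_entropy <- function(window, m = 2L, r_frac = 0.2) {
  stopifnot(length(window) > m + 1L)
  s <- sd(window)
  if (!is.finite(s) || s == 0) return(NA_real_)
  cnt <- sampen_counts_cpp(as.numeric(window), as.integer(m), r_frac * s)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Lempel-Ziv (LZ76) complexity
#'
#' The window is binarized at its median and parsed into distinct phrases by
#' the LZ76 exhaustive-history scheme; the phrase count \code{c(n)} is
#' normalized by the asymptotic random-sequence rate, giving
#' \code{c(n) * log2(n) / n} (about 1 for random binary sequences).
#'
#' @param window numeric vector of length >= 2.
#' @return normalized complexity.
#' @export
lempel_ziv <- function(window) {
  stopifnot(length(window) >= 2L)
  bits <- as.integer(window > median(window))
  n <- length(bits)
  lz76_cpp(bits) * log2(n) / n
}

#' Higuchi fractal dimension
#'
#' Curve lengths \code{L(k)} are computed for delays \code{k = 1..kmax} per
#' Higuchi's construction and the dimension is the least-squares slope of
#' \code{log L(k)} against \code{log(1/k)}. Smooth curves give 1, white noise
#' approaches 2. The reported value is clipped to \code{[1, 2]} (the raw slope
#' is kept in the \code{"raw"} attribute); a constant window returns \code{NA}.
#'
#' @param window numeric vector, length >= 10 * kmax.
#' @param kmax maximum delay.
#' @return fractal dimension in \code{[1, 2]} with attribute \code{raw}.
#' @export
higuchi_fd <- function(window, kmax = 10L) {
  N <- length(window)
  stopifnot(N >= 10L * kmax)
  if (max(window) == min(window)) return(NA_real_)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, N, by = k)
      nm <- length(idx) - 1L
      if (nm < 1L) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(window[idx]))) * (N - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  fit <- lm(log(Lk) ~ log(1 / seq_len(kmax)))
  raw <- unname(fit$coefficients[2])
  structure(min(2, max(1, raw)), raw = raw)
}

#' Welch power spectral density
#'
#' Hamming-windowed averaged modified periodogram. The window is z-scored
#' first (the spectral features are defined on normalized segments); segments
#' of length \code{min(length, nfft)} with 50\% overlap are tapered,
#' zero-padded to \code{nfft} and averaged; the one-sided density is returned,
#' so that the integral over frequency recovers the (unit) signal variance up
#' to taper leakage.
#'
#' @param window numeric vector, length >= 2.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length (>= 2).
#' @param normalize z-score the window first (default TRUE).
#' @return list of class \code{spectral_estimate}: \code{freqs} (Hz, 0 to
#'   fs/2), \code{psd} (density per Hz), \code{nfft}.
#' @export
welch_psd <- function(window, fs, nfft, normalize = TRUE) {
  if (nfft < 2L) stop("nfft must be >= 2")
  n <- length(window)
  stopifnot(n >= 2L)
  if (normalize) {
    s <- sd(window)
    window <- if (s > 0) (window - mean(window)) / s else window - mean(window)
  }
  seg <- min(n, nfft)
  hop <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = hop)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg) - 1) / (seg - 1))
  U <- fs * sum(ham^2)
  segm <- vapply(starts, function(s0) {
    x <- window[s0:(s0 + seg - 1L)] * ham
    c(x, numeric(nfft - seg))
  }, numeric(nfft))
  P <- abs(stats::mvfft(segm))^2 / U
  pxx <- rowMeans(P)
  half <- nfft %/% 2L + 1L
  pxx <- pxx[seq_len(half)]
  if (nfft %% 2L == 0L) pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
  else pxx[2:half] <- 2 * pxx[2:half]
  structure(list(freqs = (seq_len(half) - 1) * fs / nfft, psd = pxx,
                 nfft = as.integer(nfft)),
            class = "spectral_estimate")
}

#' Band powers, median and dominant frequency of a spectral estimate
#'
#' \code{Pw} of each band is the trapezoidal integral of the density over the
#' frequency-grid points inside \code{[low, high]}; \code{DF} is the frequency
#' of the density maximum within the total band; \code{MF} the smallest grid
#' frequency splitting the total-band power into halves. The first row of
#' \code{bands} is taken as the total band.
#'
#' @param est a \code{\link{welch_psd}} result.
#' @param bands data.frame(name, low, high); first row = total band.
#' @return named list: \code{MF}, \code{DF}, then one power per band row.
#' @export
spectral_features <- function(est, bands) {
  if (any(bands$high > max(est$freqs) + 1e-12) || any(bands$low < 0))
    stop("band outside the frequency grid")
  pw <- function(lo, hi) {
    sel <- which(est$freqs >= lo & est$freqs <= hi)
    if (length(sel) < 2L) stop("band ", lo, "-", hi,
                               " Hz covers fewer than 2 grid points")
    trapz(est$freqs[sel], est$psd[sel])
  }
  tot <- bands[1, ]
  sel <- which(est$freqs >= tot$low & est$freqs <= tot$high)
  f <- est$freqs[sel]; p <- est$psd[sel]
  DF <- f[which.max(p)]
  cumpow <- c(0, cumsum((f[-1] - f[-length(f)]) * (p[-1] + p[-length(p)]) / 2))
  MF <- f[which(cumpow >= cumpow[length(cumpow)] / 2)[1]]
  out <- list(MF = MF, DF = DF)
  for (i in seq_len(nrow(bands))) out[[bands$name[i]]] <- pw(bands$low[i],
                                                            bands$high[i])
  out
}

#' Number of analysis windows in a stage
#' @param T_s stage duration in seconds.
#' @param window_s window length (default 120).
#' @param hop_s hop (default 60, i.e. 50\% overlap).
#' @return window count (0 when the stage is shorter than one window).
#' @export
n_feature_windows <- function(T_s, window_s = 120, hop_s = 60) {
  if (T_s < window_s) return(0L)
  as.integer(floor((T_s - window_s) / hop_s) + 1L)
}

#' Stage-level feature vector for one channel
#'
#' Features are computed in 2-minute windows with 50\% overlap and averaged
#' across windows: time-domain and non-linear measures on the common-rate
#' (128 Hz) stream, spectral measures on the kind's spectral-rate stream (only
#' for EOG/EEG/EMG/Airflow/SpO2 kinds). Stages shorter than one window yield
#' no features (\code{n_windows = 0}).
#'
#' @param sig_feat stage signal at the analysis rate.
#' @param sig_spec stage signal at the spectral rate (may be NULL).
#' @param params a \code{\link{nonlinear_params}}.
#' @param bands output of \code{\link{default_spectral_bands}}.
#' @param nfft named vector of FFT lengths per kind.
#' @param window_s,overlap window length (s) and fractional overlap.
#' @return list(values = named numeric vector, n_windows).
#' @export
stage_features <- function(sig_feat, sig_spec = NULL,
                           params = nonlinear_params(),
                           bands = default_spectral_bands(),
                           nfft = default_nfft(),
                           window_s = 120, overlap = 0.5) {
  hop_s <- window_s * (1 - overlap)
  T_s <- length(sig_feat$samples) / sig_feat$fs
  if (!is.null(sig_spec))
    T_s <- min(T_s, length(sig_spec$samples) / sig_spec$fs)
  nw <- n_feature_windows(T_s, window_s, hop_s)
  spectral <- !is.null(sig_spec) && sig_feat$kind %in% names(bands)
  if (nw == 0L) return(list(values = numeric(), n_windows = 0L))
  per_win <- vector("list", nw)
  for (w in seq_len(nw)) {
    t0 <- (w - 1) * hop_s
    i1 <- round(t0 * sig_feat$fs) + 1L
    x <- sig_feat$samples[i1:(i1 + round(window_s * sig_feat$fs) - 1L)]
    td <- time_domain_features(x)
    x_se <- if (params$sampen_decimate > 1L)
      x[seq(1L, length(x), by = params$sampen_decimate)] else x
    nl <- list(ShanEnt = shannon_entropy(x, params$shannon_bins),
               SampEnt = sample_entropy(x_se, params$sampen_m,
                                        params$sampen_r),
               LempZiv = lempel_ziv(x),
               HFD = as.numeric(higuchi_fd(x, params$hfd_kmax)))
    sp <- list()
    if (spectral) {
      j1 <- round(t0 * sig_spec$fs) + 1L
      y <- sig_spec$samples[j1:(j1 + round(window_s * sig_spec$fs) - 1L)]
      est <- welch_psd(y, sig_spec$fs, nfft[[sig_feat$kind]])
      sp <- spectral_features(est, bands[[sig_feat$kind]])
    }
    per_win[[w]] <- unlist(c(td, nl, sp))
  }
  vals <- colMeans(do.call(rbind, per_win), na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  list(values = vals, n_windows = nw)
}

#' Extract the quantitative PSG feature block for one subject
#'
#' Runs \code{\link{stage_features}} for every channel and every sleep stage
#' present and emits scalars named
#' \code{\{channelLabel\}_\{featureCode\}_\{stage\}} (e.g.
#' \code{"EEGO1_A2_sk_N1"}). Channels whose kind has no spectral definition
#' (Effort, ECG, Snore, Leg, Pulse) contribute time-domain and non-linear
#' codes only.
#'
#' @param pre output of \code{\link{preprocess_record}}.
#' @param params,bands,nfft,window_s,overlap forwarded to
#'   \code{\link{stage_features}}.
#' @return data.frame(feature, value, n_windows).
#' @export
extract_psgvar <- function(pre, params = nonlinear_params(),
                           bands = default_spectral_bands(),
                           nfft = default_nfft(),
                           window_s = 120, overlap = 0.5) {
  rows <- list()
  for (lab in names(pre)) {
    entry <- pre[[lab]]
    for (st in names(entry$feature)) {
      sf <- stage_features(entry$feature[[st]], entry$spectral[[st]],
                           params = params, bands = bands, nfft = nfft,
                           window_s = window_s, overlap = overlap)
      if (sf$n_windows == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = paste(lab, names(sf$values), st, sep = "_"),
        value = unname(sf$values), n_windows = sf$n_windows,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature = character(), value = numeric(),
                      n_windows = integer()))
  do.call(rbind, rows)
}
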