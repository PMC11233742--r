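#' Per-kind resampling and filter settings
#'
#' One row per signal kind: the target rate after harmonization (\code{fst}),
#' the output rate used for spectral analysis (\code{fsf}), and the Butterworth
#' band edges (5th order per pass; \code{NA} band = channel passed unfiltered).
#' The AASM-style defaults: EOG/EEG 500/500 Hz, 0.3-50 Hz; EMG 500/200 Hz,
#' 1-90 Hz; Effort 100/100 Hz unfiltered; Airflow 100/100 Hz, 0.1-15 Hz;
#' Pulse and SpO2 1/1 Hz unfiltered; ECG 500/200 Hz, 0.3-50 Hz; Snore
#' 500/500 Hz, 1-100 Hz. Leg-movement channels are not covered by the AASM
#' montage table; the default treats them like EMG.
#'
#' @return data.frame with columns \code{kind, fst, fsf, low, high, order}.
#' @export
default_filter_table <- function() {
  data.frame(
    kind  = c("EOG", "EEG", "EMG", "Effort", "Airflow", "Pulse", "SpO2",
              "ECG", "Snore", "Leg"),
    fst   = c(500, 500, 500, 100, 100, 1, 1, 500, 500, 500),
    fsf   = c(500, 500, 200, 100, 100, 1, 1, 200, 500, 200),
    low   = c(0.3, 0.3, 1, NA, 0.1, NA, NA, 0.3, 1, 1),
    high  = c(50, 50, 90, NA, 15, NA, NA, 50, 100, 90),
    order = 5L,
    stringsAsFactors = FALSE)
}

#' Preprocessing configuration
#'
#' @param filters filter table, see \code{\link{default_filter_table}}.
#' @param analysis_rate common rate (Hz) of the stream used for time-domain and
#'   non-linear features (default 128).
#' @param segment_s artifact-exclusion grid in seconds (default 10).
#' @param epoch_s scoring epoch length in seconds (default 30).
#' @return list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(filters = default_filter_table(),
                              analysis_rate = 128, segment_s = 10,
                              epoch_s = 30) {
  structure(list(filters = filters, analysis_rate = analysis_rate,
                 segment_s = segment_s, epoch_s = epoch_s),
            class = "preprocess_config")
}

#' Rational-factor resampling with anti-alias filtering
#'
#' Polyphase resampling by the reduced ratio \code{fs_out/fs_in} with a
#' linear-phase windowed-sinc FIR (Hamming, 20 taps per phase), i.e. the
#' classic upsample-filter-downsample scheme. \code{method = "linear"} does
#' plain linear interpolation, appropriate only for slow step-wise channels
#' such as 1 Hz oximetry.
#'
#' @param samples numeric vector.
#' @param fs_in,fs_out rates in Hz (positive; non-integer rates are scaled to a
#'   rational approximation).
#' @param method \code{"poly"} (default) or \code{"linear"}.
#' @return samples at \code{fs_out}, length \code{round(n * fs_out / fs_in)}.
#' @export
resample_channel <- function(samples, fs_in, fs_out,
                             method = c("poly", "linear")) {
  stopifnot(fs_in > 0, fs_out > 0)
  method <- match.arg(method)
  if (fs_in == fs_out) return(samples)
  n_out <- round(length(samples) * fs_out / fs_in)
  if (method == "linear") {
    t_out <- (seq_len(n_out) - 1) / fs_out
    return(approx(x = (seq_along(samples) - 1) / fs_in, y = samples,
                  xout = pmin(t_out, (length(samples) - 1) / fs_in))$y)
  }
  # reduce fs_out/fs_in to p/q
  scale <- 1
  while (any(c(fs_in, fs_out) * scale != round(c(fs_in, fs_out) * scale)) &&
         scale < 1e6) scale <- scale * 10
  a <- round(fs_out * scale); b <- round(fs_in * scale)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(a, b); p <- a / d; q <- b / d
  half <- 10L * max(p, q)
  L <- 2L * half + 1L
  h <- signal::fir1(L - 1L, min(1 / p, 1 / q), type = "low",
                    window = signal::hamming(L)) * p
  resample_fir_cpp(as.numeric(samples), as.integer(p), as.integer(q),
                   as.numeric(h))
}

#' Zero-phase Butterworth bandpass
#'
#' Designs a Butterworth bandpass of the requested order and applies it
#' forward-backward (\code{signal::filtfilt}), so the output is phase-free at
#' the cost of squaring the magnitude response. The signal mean is removed
#' first: with sub-Hz low edges the DC response of the discretized filter is
#' dominated by its slow edge transient, and explicit centering removes the
#' offset exactly. A band of \code{NA} returns the input unchanged
#' (unfiltered channel kinds).
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; both \code{NA} to pass through.
#' @param order filter order per pass (default 5).
#' @return filtered samples, same length.
#' @export
bandpass <- function(samples, fs, low, high, order = 5L) {
  if (is.na(low) && is.na(high)) return(samples)
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2)
    stop("band edge ", high, " Hz is at or above Nyquist (fs = ", fs, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, samples - mean(samples)))
}

#' Same-stage concatenated signal
#'
#' Internal container: samples of one channel restricted to one sleep stage,
#' concatenated in temporal order. \code{runs} maps concatenated time back to
#' source time (one row per contiguous source run), which is what artifact
#' exclusion operates on; \code{joint_offsets} are the sample indices at which
#' non-contiguous source runs were joined.
#'
#' @param label,kind,stage,fs channel metadata.
#' @param samples concatenated samples.
#' @param runs data.frame(src_start_s, dur_s) of contiguous source runs.
#' @return object of class \code{stage_signal}.
#' @export
stage_signal <- function(label, kind, stage, fs, samples, runs) {
  stopifnot(is.data.frame(runs))
  structure(list(label = label, kind = kind, stage = stage, fs = fs,
                 samples = as.numeric(samples), runs = runs),
            class = "stage_signal")
}

#' @export
print.stage_signal <- function(x, ...) {
  cat(sprintf("<stage_signal %s/%s %g Hz: %.0f s in %d run(s)>\n",
              x$label, x$stage, x$fs, length(x$samples) / x$fs, nrow(x$runs)))
  invisible(x)
}

#' @rdname stage_signal
#' @param sig a \code{stage_signal}.
#' @return \code{joint_offsets}: 1-based sample indices where a new
#'   non-contiguous source run begins (excluding the first).
#' @export
joint_offsets <- function(sig) {
  if (nrow(sig$runs) < 2L) return(integer())
  as.integer(round(cumsum(sig$runs$dur_s[-nrow(sig$runs)]) * sig$fs)) + 1L
}

#' Split a channel into per-stage concatenated signals
#'
#' Epochs scored W are discarded; epochs scored N1/N2/N3/REM contribute their
#' samples, in temporal order, to the stage's concatenated signal. Adjacent
#' same-stage epochs are merged into one contiguous source run.
#'
#' @param channel a \code{\link{channel_signal}}.
#' @param hyp a \code{\link{hypnogram}} no longer than the channel.
#' @return named list of \code{\link{stage_signal}} objects (absent stages are
#'   omitted; all-W hypnograms give an empty list).
#' @export
decompose_stages <- function(channel, hyp) {
  if (hypnogram_span_s(hyp) > channel_duration_s(channel) + 1e-9)
    stop("hypnogram is longer than channel ", channel$label)
  eps <- hyp$epoch_s * channel$fs
  if (abs(eps - round(eps)) > 1e-9)
    stop("epoch length times fs must be an integer sample count")
  eps <- as.integer(round(eps))
  out <- list()
  for (st in .sm_sleep_stages) {
    idx <- which(hyp$stages == st)
    if (!length(idx)) next
    sel <- unlist(lapply(idx, function(e) ((e - 1L) * eps + 1L):(e * eps)))
    # merge adjacent epochs into contiguous runs
    brk <- c(TRUE, diff(idx) != 1L)
    run_id <- cumsum(brk)
    starts <- idx[brk]
    durs <- tabulate(run_id) * hyp$epoch_s
    out[[st]] <- stage_signal(channel$label, channel$kind, st, channel$fs,
                              channel$samples[sel],
                              data.frame(src_start_s = (starts - 1) * hyp$epoch_s,
                                         dur_s = durs))
  }
  out
}

# map concatenated time interval [t0, t1) of a stage signal to source intervals
concat_to_source <- function(sig, t0, t1) {
  ends <- cumsum(sig$runs$dur_s)
  begs <- c(0, head(ends, -1))
  out <- NULL
  for (i in seq_len(nrow(sig$runs))) {
    lo <- max(t0, begs[i]); hi <- min(t1, ends[i])
    if (hi > lo)
      out <- rbind(out, c(sig$runs$src_start_s[i] + (lo - begs[i]),
                          sig$runs$src_start_s[i] + (hi - begs[i])))
  }
  out
}

#' Remove artifact-contaminated segments from a stage signal
#'
#' The concatenated signal is partitioned into consecutive fixed-length
#' segments (incomplete tail dropped). A segment is excluded when its source
#' time range overlaps, by any amount, an artifact interval annotated for this
#' channel or for all channels (\code{"*"}). Surviving segments are
#' re-concatenated.
#'
#' @param sig a \code{\link{stage_signal}}.
#' @param artifacts an \code{\link{artifact_intervals}} data frame.
#' @param segment_s segment length in seconds (default 10).
#' @return a \code{\link{stage_signal}} (possibly empty).
#' @export
drop_artifact_segments <- function(sig, artifacts, segment_s = 10) {
  seg_len <- as.integer(round(segment_s * sig$fs))
  n_seg <- length(sig$samples) %/% seg_len
  arts <- artifacts[artifacts$channel == "*" | artifacts$channel == sig$label, ,
                    drop = FALSE]
  keep <- logical(n_seg)
  new_runs <- NULL
  for (s in seq_len(n_seg)) {
    t0 <- (s - 1) * segment_s
    src <- concat_to_source(sig, t0, t0 + segment_s)
    hit <- FALSE
    if (nrow(arts) > 0 && !is.null(src)) {
      for (i in seq_len(nrow(src))) {
        if (any(arts$start_s < src[i, 2] & arts$end_s > src[i, 1])) {
          hit <- TRUE; break
        }
      }
    }
    keep[s] <- !hit
    if (!hit && !is.null(src))
      new_runs <- rbind(new_runs,
                        data.frame(src_start_s = src[, 1],
                                   dur_s = src[, 2] - src[, 1]))
  }
  sel <- unlist(lapply(which(keep), function(s)
    ((s - 1L) * seg_len + 1L):(s * seg_len)))
  if (is.null(new_runs))
    new_runs <- data.frame(src_start_s = numeric(), dur_s = numeric())
  else {
    # merge back-to-back source runs
    merged <- new_runs[1, , drop = FALSE]
    if (nrow(new_runs) > 1) for (i in 2:nrow(new_runs)) {
      last <- nrow(merged)
      if (abs(merged$src_start_s[last] + merged$dur_s[last] -
              new_runs$src_start_s[i]) < 1e-9)
        merged$dur_s[last] <- merged$dur_s[last] + new_runs$dur_s[i]
      else merged <- rbind(merged, new_runs[i, ])
    }
    new_runs <- merged
  }
  stage_signal(sig$label, sig$kind, sig$stage, sig$fs,
               if (is.null(sel)) numeric() else sig$samples[sel], new_runs)
}

#' Preprocess one subject-night
#'
#' Per channel: harmonize the rate to the kind's target rate, apply the
#' zero-phase Butterworth band (if any), derive two analysis streams --- the
#' common \code{analysis_rate} (default 128 Hz) stream feeding time-domain and
#' non-linear features, and the kind's \code{fsf}-rate stream feeding spectral
#' features --- then split both by sleep stage (wake discarded) and drop
#' artifact-contaminated 10-s segments.
#'
#' 1 Hz channels (SpO2, Pulse) are brought to the analysis rate by linear
#' interpolation; all other conversions use polyphase anti-aliased resampling.
#'
#' @param rec a \code{\link{psg_record}} with a hypnogram.
#' @param config a \code{\link{preprocess_config}}.
#' @return list per channel label with elements \code{kind},
#'   \code{feature} (named list of stage signals at the analysis rate) and
#'   \code{spectral} (stage signals at the kind's \code{fsf}).
#' @export
preprocess_record <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "psg_record"))
  if (is.null(rec$hypnogram)) stop("record has no hypnogram")
  ft <- config$filters
  out <- list()
  for (ch in rec$channels) {
    row <- ft[ft$kind == ch$kind, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("no filter specification for channel kind '", ch$kind, "'")
    slow <- ch$kind %in% c("SpO2", "Pulse")
    x <- resample_channel(ch$samples, ch$fs, row$fst,
                          method = if (slow && ch$fs < row$fst) "linear"
                                   else "poly")
    x <- bandpass(x, row$fst, row$low, row$high, row$order)
    streams <- list(
      feature = resample_channel(x, row$fst, config$analysis_rate,
                                 method = if (slow) "linear" else "poly"),
      spectral = resample_channel(x, row$fst, row$fsf, method = "poly"))
    rates <- c(feature = config$analysis_rate, spectral = row$fsf)
    res <- list(kind = ch$kind)
    for (sn in names(streams)) {
      cs <- channel_signal(ch$label, ch$kind, streams[[sn]], rates[[sn]])
      stg <- decompose_stages(cs, rec$hypnogram)
      res[[sn]] <- lapply(stg, drop_artifact_segments,
                          artifacts = rec$artifacts,
                          segment_s = config$segment_s)
    }
    out[[ch$label]] <- res
  }
  out
}
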