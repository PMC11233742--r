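#' A single polysomnography channel
#'
#' Container for one channel of a PSG recording: a label as exported by the
#' acquisition system (e.g. \code{"EEGO1_A2"}, \code{"EffortTHO"}), a signal
#' kind used to look up filter settings and spectral bands, the samples in
#' physical units, and the sampling rate.
#'
#' @param label channel name, unique within a record.
#' @param kind one of \code{"EOG"}, \code{"EEG"}, \code{"EMG"}, \code{"Effort"},
#'   \code{"Airflow"}, \code{"Pulse"}, \code{"SpO2"}, \code{"ECG"},
#'   \code{"Snore"}, \code{"Leg"}.
#' @param samples numeric vector of finite samples.
#' @param fs sampling rate in Hz, > 0.
#' @return an object of class \code{channel_signal}.
#' @export
channel_signal <- function(label, kind, samples, fs) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  kind <- match.arg(kind, .sm_kinds)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (!all(is.finite(samples)))
    stop("channel '", label, "' contains non-finite samples")
  structure(list(label = label, kind = kind,
                 samples = as.numeric(samples), fs = fs),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel %s [%s] %g Hz, %.1f s>\n",
              x$label, x$kind, x$fs, length(x$samples) / x$fs))
  invisible(x)
}

channel_duration_s <- function(ch) length(ch$samples) / ch$fs

#' An epoch-wise sleep-stage sequence
#'
#' @param stages character vector over \code{W, N1, N2, N3, REM}, one entry per
#'   scoring epoch.
#' @param epoch_s epoch length in seconds (30 by AASM convention).
#' @return object of class \code{hypnogram}.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  bad <- which(!stages %in% .sm_stages)
  if (length(bad))
    stop("unknown stage label(s) at epoch row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(stages[bad]), collapse = ", "))
  structure(list(stages = stages, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram: %d x %gs epochs (%.1f min)>\n",
              length(x$stages), x$epoch_s, hypnogram_span_s(x) / 60))
  print(table(factor(x$stages, levels = .sm_stages)))
  invisible(x)
}

#' @rdname hypnogram
#' @param hyp a \code{hypnogram}.
#' @export
hypnogram_span_s <- function(hyp) length(hyp$stages) * hyp$epoch_s

#' Artifact annotation intervals
#'
#' @param start_s,end_s interval bounds in seconds from recording start.
#' @param channel channel label the annotation applies to, or \code{"*"} for
#'   all channels.
#' @return data.frame of class \code{artifact_intervals}.
#' @export
artifact_intervals <- function(start_s = numeric(), end_s = numeric(),
                               channel = character()) {
  if (length(channel) == 0L && length(start_s) > 0L)
    channel <- rep("*", length(start_s))
  if (any(end_s <= start_s) || any(start_s < 0))
    stop("artifact intervals require 0 <= start_s < end_s")
  structure(data.frame(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s),
                       channel = as.character(channel),
                       stringsAsFactors = FALSE),
            class = c("artifact_intervals", "data.frame"))
}

#' One subject-night of polysomnography
#'
#' Bundles channels, the scored hypnogram and artifact annotations. All
#' channels must span the same duration to within one scoring epoch and
#' labels must be unique.
#'
#' @param subject_id subject identifier.
#' @param channels list of \code{\link{channel_signal}} objects.
#' @param hyp optional \code{\link{hypnogram}}.
#' @param artifacts optional \code{\link{artifact_intervals}}.
#' @return object of class \code{psg_record}.
#' @export
psg_record <- function(subject_id, channels, hyp = NULL, artifacts = NULL) {
  stopifnot(length(channels) >= 1L)
  labels <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  durs <- vapply(channels, channel_duration_s, numeric(1))
  ep <- if (is.null(hyp)) 30 else hyp$epoch_s
  if (diff(range(durs)) > ep)
    stop("channel durations differ by more than one epoch")
  if (!is.null(hyp) && hypnogram_span_s(hyp) > max(durs) + 1e-9)
    stop("hypnogram is longer than the recorded signals")
  names(channels) <- labels
  structure(list(subject_id = as.character(subject_id), channels = channels,
                 hypnogram = hyp,
                 artifacts = artifacts %||% artifact_intervals()),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record %s: %d channels, %.1f min>\n", x$subject_id,
              length(x$channels),
              max(vapply(x$channels, channel_duration_s, numeric(1))) / 60))
  invisible(x)
}

#' Default channel-label to signal-kind mapping
#'
#' Regular expressions matched in order against channel labels; covers the
#' montage labels this pipeline reports on (EEG derivations, chin EMG,
#' thoracic/abdominal effort, oronasal airflow, oximetry, ECG, snore
#' microphone, leg EMG). Override by passing your own two-column data frame
#' (\code{pattern}, \code{kind}) to \code{\link{read_edf}}.
#'
#' @return data.frame with columns \code{pattern} and \code{kind}.
#' @export
default_channel_map <- function() {
  data.frame(
    pattern = c("^EEG", "^EOG", "^EMG", "^Effort|^THO|^ABD", "Airflow|Flow",
                "SpO2|SaO2", "^ECG|^EKG", "Snore", "^Leg", "Pulse|Pleth"),
    kind = c("EEG", "EOG", "EMG", "Effort", "Airflow",
             "SpO2", "ECG", "Snore", "Leg", "Pulse"),
    stringsAsFactors = FALSE)
}

infer_kind <- function(label, map = default_channel_map()) {
  for (i in seq_len(nrow(map)))
    if (grepl(map$pattern[i], label, ignore.case = TRUE)) return(map$kind[i])
  stop("cannot infer signal kind for channel label '", label,
       "'; extend the channel map")
}

# ---- EDF ------------------------------------------------------------------
# Minimal EDF (16-bit) writer/reader. Record duration is fixed at 1 s, so
# sampling rates must be whole numbers and the recording an integer number of
# seconds. Physical calibration values are round-tripped through their ASCII
# header representation before quantization so that read(write(x)) is within
# one quantization step of x.

edf_num <- function(x, width = 8L) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) break
  }
  if (nchar(s) > width) stop("cannot format ", x, " into ", width, " chars")
  s
}

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a PSG record to an EDF file
#'
#' Signals are stored as 16-bit integers with per-channel physical calibration
#' covering the sample range; 1-second data records. Sampling rates must be
#' integer Hz and the record an integer number of seconds.
#'
#' @param record a \code{\link{psg_record}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "psg_record"))
  chans <- record$channels
  if (!length(chans)) stop("record has no channels")
  fs <- vapply(chans, function(ch) ch$fs, numeric(1))
  if (any(fs != round(fs)))
    stop("EDF writer requires integer sampling rates (1-s records)")
  durs <- vapply(chans, channel_duration_s, numeric(1))
  n_rec <- max(durs)
  if (abs(n_rec - round(n_rec)) > 1e-9 || any(abs(durs - n_rec) > 1e-9))
    stop("all channels must span the same whole number of seconds")
  n_rec <- as.integer(round(n_rec))
  ns <- length(chans)

  # per-channel calibration, round-tripped through header ASCII
  cal <- lapply(chans, function(ch) {
    if (any(!is.finite(ch$samples))) stop("non-finite samples in ", ch$label)
    pmin <- min(ch$samples); pmax <- max(ch$samples)
    if (pmin == pmax) { pmin <- pmin - 1; pmax <- pmax + 1 }
    pmin_s <- edf_num(pmin); pmax_s <- edf_num(pmax)
    pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
    if (pmax <= pmin) pmax <- pmin + 1  # ASCII rounding collapse guard
    list(pmin = pmin, pmax = pmax, pmin_s = pmin_s, pmax_s = edf_num(pmax))
  })

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(record$subject_id, 80)
  wr("somnomark", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  wrall <- function(f, w) for (ch in chans) wr(f(ch), w)
  wrall(function(ch) ch$label, 16)
  wrall(function(ch) ch$kind, 80)
  wrall(function(ch) "", 8)
  for (cc in cal) wr(cc$pmin_s, 8)
  for (cc in cal) wr(cc$pmax_s, 8)
  wrall(function(ch) "-32768", 8)
  wrall(function(ch) "32767", 8)
  wrall(function(ch) "", 80)
  wrall(function(ch) as.character(as.integer(ch$fs)), 8)
  wrall(function(ch) "", 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    cc <- cal[[i]]
    d <- round((chans[[i]]$samples - cc$pmin) / (cc$pmax - cc$pmin) * 65535 -
                 32768)
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  spr <- as.integer(fs)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a PSG record
#'
#' Parses the EDF header and 16-bit data records, converts samples to physical
#' units, and infers each channel's signal kind from its label. The hypnogram
#' and artifact annotations travel in separate TSV files (see
#' \code{\link{read_hypnogram}}, \code{\link{read_artifacts}}).
#'
#' @param path an EDF/EDF+ file.
#' @param channel_map label-to-kind mapping, see \code{\link{default_channel_map}}.
#' @return a \code{\link{psg_record}} (channels only).
#' @export
read_edf <- function(path, channel_map = default_channel_map()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < w)
      stop("unreadable EDF header in ", path)
    trimws(s)
  }
  rd(8) # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || is.na(n_rec) || is.na(rec_dur))
    stop("unreadable EDF header in ", path)
  if (ns < 1L) stop("EDF file contains zero signals")
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdn(16); rdn(80); rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i]) stop("truncated EDF data in ", path)
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  chans <- lapply(seq_len(ns), function(i) {
    phys <- (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax[i] - pmin[i]) + pmin[i]
    channel_signal(labels[i], infer_kind(labels[i], channel_map),
                   phys, spr[i] / rec_dur)
  })
  psg_record(if (nzchar(patient)) patient else "unknown", chans)
}

# ---- TSV dialects ---------------------------------------------------------

#' Read a hypnogram TSV
#'
#' Expects a header \code{epoch<TAB>stage} and one stage label per epoch row.
#'
#' @param path TSV file.
#' @param epoch_s epoch length in seconds.
#' @return a \code{\link{hypnogram}}.
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"stage" %in% names(d)) stop("hypnogram TSV needs a 'stage' column")
  hypnogram(d$stage, epoch_s = epoch_s)
}

#' Write a hypnogram TSV
#' @param hyp a \code{\link{hypnogram}}.
#' @param path output path.
#' @export
write_hypnogram <- function(hyp, path) {
  write.table(data.frame(epoch = seq_along(hyp$stages), stage = hyp$stages),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read artifact annotations
#'
#' TSV with header \code{start_s<TAB>end_s<TAB>channel}; \code{channel} may be
#' \code{"*"} for annotations applying to every channel.
#'
#' @param path TSV file.
#' @return an \code{\link{artifact_intervals}} data frame.
#' @export
read_artifacts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s")
  if (!all(need %in% names(d))) stop("artifact TSV needs start_s and end_s")
  bad <- which(d$end_s <= d$start_s | d$start_s < 0)
  if (length(bad))
    stop("invalid artifact interval(s) at row(s) ", paste(bad, collapse = ", "))
  artifact_intervals(d$start_s, d$end_s, d$channel %||% rep("*", nrow(d)))
}

#' Write artifact annotations
#' @param artifacts an \code{\link{artifact_intervals}} data frame.
#' @param path output path.
#' @export
write_artifacts <- function(artifacts, path) {
  write.table(as.data.frame(artifacts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read scored respiratory events
#'
#' TSV with header \code{start_s, duration_s, kind, desat, arousal} (tab
#' separated). Kinds: \code{obstructive_apnea}, \code{central_apnea},
#' \code{mixed_apnea}, \code{hypopnea}.
#'
#' @param path TSV file.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  kinds <- c("obstructive_apnea", "central_apnea", "mixed_apnea", "hypopnea")
  bad <- which(!d$kind %in% kinds)
  if (length(bad))
    stop("unknown event kind at row(s) ", paste(bad, collapse = ", "))
  if (any(d$duration_s <= 10))
    stop("respiratory events must last more than 10 s")
  d$desat <- as.logical(d$desat); d$arousal <- as.logical(d$arousal)
  d
}

#' @rdname read_events
#' @param events events data frame.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
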