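#' Conventional sleep parameters from a scored night
#'
#' Derives the standard clinical report quantities: time in bed (TIB, full
#' recording span), total sleep time (TST, non-wake epochs), sleep efficiency
#' (SE = 100 * TST / TIB), arousal index (arousals per hour of sleep), the
#' apnea-hypopnea index (all scored apneas plus hypopneas per hour of TST) and
#' the central/mixed/obstructive sub-indices, the 3\%-desaturation index ODI,
#' CT90 (percentage of sleep time with SpO2 below 90\%), mean and minimum
#' sleep SpO2, per-stage times and percentages of TST, stage latencies (time
#' from recording start to the first epoch of each stage), and the OSA flag
#' (AHI strictly greater than 15 events/h).
#'
#' When TST is zero all per-hour indices and percentages are \code{NA}.
#'
#' @param hyp a \code{\link{hypnogram}}.
#' @param events data.frame of respiratory events (see
#'   \code{\link{read_events}}); may have zero rows.
#' @param arousals data.frame(start_s, end_s) of arousal intervals.
#' @param spo2 a \code{\link{channel_signal}} of kind SpO2, or NULL.
#' @return list of class \code{sleep_parameters} (units: minutes, percent,
#'   events per hour).
#' @export
derive_sleep_parameters <- function(hyp, events = NULL, arousals = NULL,
                                    spo2 = NULL) {
  ep_min <- hyp$epoch_s / 60
  TIB <- length(hyp$stages) * ep_min
  sleep <- hyp$stages != "W"
  TST <- sum(sleep) * ep_min
  tst_h <- TST / 60
  per_h <- function(k) if (TST > 0) k / tst_h else NA_real_
  n_ev <- function(kind) if (is.null(events)) 0L else sum(events$kind == kind)
  n_resp <- if (is.null(events)) 0L else nrow(events)
  n_arous <- if (is.null(arousals)) 0L else nrow(arousals)
  n_desat <- if (is.null(events)) 0L else sum(events$desat)

  stage_min <- vapply(.sm_sleep_stages,
                      function(st) sum(hyp$stages == st) * ep_min, numeric(1))
  stage_pct <- if (TST > 0) 100 * stage_min / TST
               else rep(NA_real_, 4)
  latency <- vapply(.sm_sleep_stages, function(st) {
    i <- which(hyp$stages == st)[1]
    if (is.na(i)) NA_real_ else (i - 1) * ep_min
  }, numeric(1))

  CT90 <- mean_sa <- min_sa <- NA_real_
  if (!is.null(spo2) && TST > 0) {
    ep_at <- pmin(length(hyp$stages),
                  floor((seq_along(spo2$samples) - 1) / spo2$fs /
                          hyp$epoch_s) + 1L)
    asleep <- sleep[ep_at]
    v <- spo2$samples[asleep]
    if (length(v)) {
      CT90 <- 100 * sum(v < 90) / length(v)
      mean_sa <- mean(v); min_sa <- min(v)
    }
  }

  ahi <- per_h(n_resp)
  structure(list(
    TIB = TIB, TST = TST, SE = if (TIB > 0) 100 * TST / TIB else NA_real_,
    AI = per_h(n_arous), AHI = ahi,
    obstructive_apnea_index = per_h(n_ev("obstructive_apnea")),
    central_apnea_index = per_h(n_ev("central_apnea")),
    mixed_apnea_index = per_h(n_ev("mixed_apnea")),
    hypopnea_index = per_h(n_ev("hypopnea")),
    ODI = per_h(n_desat), CT90 = CT90,
    mean_SaO2 = mean_sa, min_SaO2 = min_sa,
    stage_min = stage_min, stage_pct = stage_pct, latency_min = latency,
    n_arousals = n_arous, n_events = n_resp,
    OSA = if (is.na(ahi)) NA else ahi > 15),
    class = "sleep_parameters")
}

#' @export
print.sleep_parameters <- function(x, ...) {
  cat(sprintf("TST %.1f min (SE %.1f%%), AHI %.1f/h, ODI %.1f/h, CT90 %.1f%%\n",
              x$TST, x$SE, x$AHI, x$ODI, x$CT90))
  invisible(x)
}

#' Flatten sleep parameters to one named row
#'
#' The SLEEPVAR representation used by the feature-selection stage.
#'
#' @param sp a \code{sleep_parameters} object.
#' @return named numeric vector.
#' @export
sleep_parameters_row <- function(sp) {
  c(TIB = sp$TIB, TST = sp$TST, SE = sp$SE, AI = sp$AI, AHI = sp$AHI,
    obstructive_apnea_index = sp$obstructive_apnea_index,
    central_apnea_index = sp$central_apnea_index,
    mixed_apnea_index = sp$mixed_apnea_index,
    hypopnea_index = sp$hypopnea_index,
    ODI = sp$ODI, CT90 = sp$CT90, mean_SaO2 = sp$mean_SaO2,
    min_SaO2 = sp$min_SaO2,
    setNames(sp$stage_min, paste0(.sm_sleep_stages, "_min")),
    setNames(sp$stage_pct, paste0(.sm_sleep_stages, "_pct")),
    setNames(sp$latency_min, paste0("latency_", .sm_sleep_stages)),
    n_arousals = sp$n_arousals, n_events = sp$n_events,
    OSA = as.numeric(sp$OSA))
}

#' Score respiratory events from the airflow trace (optional scorer)
#'
#' A deliberately simple automatic scorer for synthetic or exploratory use ---
#' the pipeline itself consumes expert event annotations. Breath amplitude is
#' tracked as a moving RMS (2-s windows); an event is scored when the
#' amplitude drops below a fraction of the local 120-s baseline for more than
#' 10 s: below 10\% = apnea, below 70\% = hypopnea.
#'
#' @param airflow a \code{\link{channel_signal}} of kind Airflow.
#' @return data.frame(start_s, duration_s, kind).
#' @export
detect_respiratory_events <- function(airflow) {
  fs <- airflow$fs
  win <- as.integer(2 * fs)
  x2 <- airflow$samples^2
  k <- rep(1 / win, win)
  amp <- sqrt(pmax(0, as.numeric(stats::filter(x2, k, sides = 2))))
  amp[is.na(amp)] <- amp[!is.na(amp)][1]
  base_w <- as.integer(120 * fs)
  n <- length(amp)
  base <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - base_w %/% 2L); hi <- min(n, i + base_w %/% 2L)
    if (i %% as.integer(fs) == 1L || i == 1L)
      b <- median(amp[lo:hi])
    base[i] <- b
  }
  rel <- amp / pmax(base, .Machine$double.eps)
  lab <- ifelse(rel < 0.10, 2L, ifelse(rel < 0.70, 1L, 0L))
  r <- rle(lab > 0L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- NULL
  for (i in which(r$values)) {
    dur <- r$lengths[i] / fs
    if (dur <= 10) next
    seg <- lab[starts[i]:ends[i]]
    kind <- if (mean(seg == 2L) > 0.5) "obstructive_apnea" else "hypopnea"
    out <- rbind(out, data.frame(start_s = (starts[i] - 1) / fs,
                                 duration_s = dur, kind = kind,
                                 stringsAsFactors = FALSE))
  }
  out %||% data.frame(start_s = numeric(), duration_s = numeric(),
                      kind = character())
}
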