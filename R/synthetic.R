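#' Specification of one synthetic subject-night
#'
#' Encodes the phenomena the pipeline measures: a first-order Markov stage
#' architecture; stage-gated EEG content (slow-wave boost in N3, 12-14 Hz
#' spindle bursts in N2, theta in REM, alpha in wake); chin-EMG tone
#' decreasing from wake to N3 and minimal in REM; ~0.25 Hz respiration on the
#' effort and airflow channels with planted apneas (airflow x0.1) and
#' hypopneas (x0.7) longer than 10 s; SpO2 desaturations of at least 3\%
#' following flagged events; and artifact intervals at a configurable rate.
#' The default event rates mirror a sleep-clinic dementia cohort with highly
#' prevalent sleep apnea (median AHI near 27/h, arousal index near 36/h).
#'
#' @param duration_min recording span in minutes (default 420; tests use
#'   shorter nights).
#' @param epoch_s scoring epoch (30 s).
#' @param transition 5x5 stage transition matrix (rows sum to 1, order
#'   W, N1, N2, N3, REM).
#' @param apnea_per_h,hypopnea_per_h planted event rates per hour of sleep.
#' @param desat_range desaturation depth range in percent SpO2.
#' @param spindle_rate_per_min Poisson spindle rate in N2.
#' @param arousal_per_h arousal rate per hour of sleep.
#' @param artifact_per_h artifact annotation rate per recording hour.
#' @return list of class \code{night_spec}.
#' @export
night_spec <- function(duration_min = 420, epoch_s = 30,
                       transition = default_transition_matrix(),
                       apnea_per_h = 20, hypopnea_per_h = 7,
                       desat_range = c(3, 6), spindle_rate_per_min = 3,
                       arousal_per_h = 36, artifact_per_h = 2) {
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9),
            apnea_per_h >= 0, hypopnea_per_h >= 0)
  structure(as.list(environment()), class = "night_spec")
}

#' Default sleep-stage transition matrix
#'
#' Calibrated to produce fragmented, N2-dominated sleep with moderate
#' efficiency, as seen in elderly cohorts with mild-moderate dementia.
#'
#' @return 5x5 row-stochastic matrix over W, N1, N2, N3, REM.
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    W   = c(0.60, 0.30, 0.08, 0.00, 0.02),
    N1  = c(0.15, 0.35, 0.45, 0.02, 0.03),
    N2  = c(0.08, 0.08, 0.62, 0.15, 0.07),
    N3  = c(0.05, 0.02, 0.25, 0.65, 0.03),
    REM = c(0.10, 0.10, 0.15, 0.00, 0.65))
  colnames(m) <- .sm_stages
  m
}

#' Generate a hypnogram as a first-order Markov chain
#'
#' @param spec a \code{\link{night_spec}}.
#' @param seed integer seed.
#' @return a \code{\link{hypnogram}} starting in W.
#' @export
generate_hypnogram <- function(spec, seed = 1L) {
  n_ep <- as.integer(round(spec$duration_min * 60 / spec$epoch_s))
  P <- spec$transition
  set.seed(derive_seed(seed, "hypnogram"))
  st <- integer(n_ep)
  st[1] <- 1L
  for (i in seq_len(n_ep - 1L))
    st[i + 1L] <- sample.int(5L, 1L, prob = P[st[i], ])
  hypnogram(.sm_stages[st], epoch_s = spec$epoch_s)
}

# 1/f^alpha noise via spectral shaping of white noise
colored_noise <- function(n, alpha = 1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  W <- W / f^(alpha / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

place_events <- function(n_target, dur_range, sleep_mask_s) {
  # sleep_mask_s: logical per second of recording; greedy non-overlapping
  out <- data.frame(start_s = numeric(), duration_s = numeric())
  avail <- which(sleep_mask_s)
  if (!length(avail) || n_target == 0) return(out)
  taken <- rep(FALSE, length(sleep_mask_s))
  tries <- 0L
  while (nrow(out) < n_target && tries < 50L * max(1L, n_target)) {
    tries <- tries + 1L
    dur <- runif(1, dur_range[1], dur_range[2])
    s0 <- sample(avail, 1L)
    span <- s0:min(length(taken), s0 + ceiling(dur))
    if (any(taken[span]) || !all(sleep_mask_s[span])) next
    taken[span] <- TRUE
    out <- rbind(out, data.frame(start_s = s0 - 1, duration_s = dur))
  }
  out
}

#' Generate one synthetic PSG record
#'
#' Synthesizes the nine-channel montage (two EEG derivations, EOG, chin EMG,
#' thoracic effort, airflow, SpO2, ECG, snore) at realistic native rates,
#' gates the signal content by the hypnogram, plants respiratory events and
#' arousals in sleep time, attaches artifact annotations, and returns the
#' planted events as ground truth.
#'
#' @param spec a \code{\link{night_spec}}.
#' @param hyp a \code{\link{hypnogram}} (generated if NULL).
#' @param seed integer seed.
#' @param subject_id id stored in the record.
#' @return list(record, events, arousals, ground_truth).
#' @export
generate_record <- function(spec, hyp = NULL, seed = 1L,
                            subject_id = "synthetic") {
  if (is.null(hyp)) hyp <- generate_hypnogram(spec, seed)
  set.seed(derive_seed(seed, "record"))
  n_ep <- length(hyp$stages)
  ep_s <- hyp$epoch_s
  dur_s <- n_ep * ep_s
  stage_of_s <- rep(hyp$stages, each = ep_s)
  sleep_s <- stage_of_s != "W"
  tst_h <- sum(sleep_s) / 3600

  # ---- respiratory events and arousals (ground truth) ----
  n_ap <- round(spec$apnea_per_h * tst_h)
  n_hyp <- round(spec$hypopnea_per_h * tst_h)
  ev <- place_events(n_ap + n_hyp, c(11, 25), sleep_s)
  events <- if (nrow(ev)) {
    kind <- c(sample(c("obstructive_apnea", "central_apnea", "mixed_apnea"),
                     min(n_ap, nrow(ev)), replace = TRUE,
                     prob = c(0.7, 0.15, 0.15)),
              rep("hypopnea", max(0, nrow(ev) - n_ap)))
    desat <- runif(nrow(ev)) < ifelse(kind == "hypopnea", 0.7, 0.8)
    arous <- runif(nrow(ev)) < 0.5
    arous[kind == "hypopnea" & !desat] <- TRUE # hypopnea needs desat or arousal
    data.frame(start_s = ev$start_s, duration_s = ev$duration_s, kind = kind,
               desat = desat, arousal = arous, stringsAsFactors = FALSE)
  } else data.frame(start_s = numeric(), duration_s = numeric(),
                    kind = character(), desat = logical(), arousal = logical())
  n_arous <- round(spec$arousal_per_h * tst_h)
  ar <- place_events(n_arous, c(3, 10), sleep_s)
  arousals <- data.frame(start_s = ar$start_s,
                         end_s = ar$start_s + ar$duration_s)

  # per-second airflow/effort attenuation from events
  flow_gain <- rep(1, dur_s); eff_gain <- rep(1, dur_s)
  for (i in seq_len(nrow(events))) {
    span <- max(1, floor(events$start_s[i]) + 1):
      min(dur_s, ceiling(events$start_s[i] + events$duration_s[i]))
    k <- events$kind[i]
    flow_gain[span] <- if (k == "hypopnea") 0.7 else 0.1
    eff_gain[span] <- switch(k, obstructive_apnea = 1, central_apnea = 0.1,
                             mixed_apnea = 0.5, hypopnea = 0.7)
  }

  per_epoch <- function(fs, fun) {
    # fun(stage, t_local) -> samples for one epoch at rate fs
    out <- numeric(dur_s * fs)
    tl <- seq_len(ep_s * fs) / fs
    for (e in seq_len(n_ep)) {
      idx <- ((e - 1L) * ep_s * fs + 1L):(e * ep_s * fs)
      out[idx] <- fun(hyp$stages[e], tl)
    }
    out
  }

  eeg_make <- function() {
    fs <- 200
    base <- 10 * colored_noise(dur_s * fs)
    add <- per_epoch(fs, function(st, tl) {
      ph <- runif(1, 0, 2 * pi)
      switch(st,
        W  = 8 * sin(2 * pi * runif(1, 9, 11) * tl + ph),
        N1 = 4 * sin(2 * pi * runif(1, 4, 7) * tl + ph),
        N2 = {
          x <- numeric(length(tl))
          n_sp <- rpois(1, spec$spindle_rate_per_min * ep_s / 60)
          for (s in seq_len(n_sp)) {
            c0 <- runif(1, 1, ep_s - 1)
            env <- exp(-(tl - c0)^2 / (2 * 0.25^2))
            x <- x + 12 * env * sin(2 * pi * runif(1, 12, 14) * tl + ph)
          }
          x + 3 * sin(2 * pi * runif(1, 4, 7) * tl + ph)
        },
        N3 = 30 * sin(2 * pi * runif(1, 0.8, 2) * tl + ph),
        REM = 6 * sin(2 * pi * runif(1, 4, 7) * tl + ph))
    })
    base + add
  }

  resp_f <- runif(1, 0.2, 0.3)
  t100 <- seq_len(dur_s * 100) / 100
  gain_at <- function(g, tt) g[pmin(length(g), floor(tt) + 1L)]
  resp_wave <- sin(2 * pi * resp_f * t100)

  spo2 <- 96 + as.numeric(stats::filter(rnorm(dur_s, 0, 0.2), 0.8,
                                        method = "recursive"))
  for (i in which(events$desat)) {
    depth <- runif(1, spec$desat_range[1], spec$desat_range[2])
    s0 <- floor(events$start_s[i]) + 5L
    s1 <- min(dur_s, s0 + ceiling(events$duration_s[i]))
    rec_end <- min(dur_s, s1 + 15L)
    if (s0 >= dur_s) next
    down <- s0:s1; up <- if (s1 < rec_end) (s1 + 1L):rec_end else integer()
    spo2[down] <- spo2[down] - depth * seq_along(down) / length(down)
    if (length(up)) spo2[up] <- spo2[up] - depth * rev(seq_along(up)) /
        length(up)
  }
  spo2 <- pmin(100, spo2)

  hr <- runif(1, 55, 75) / 60
  beats <- seq(0.5, dur_s, by = 1 / hr)
  t200 <- seq_len(dur_s * 200) / 200
  ecg <- 0.05 * rnorm(length(t200))
  for (b in beats) {
    i0 <- round(b * 200)
    if (i0 > 2 && i0 < length(ecg) - 2) ecg[(i0 - 2):(i0 + 2)] <-
        ecg[(i0 - 2):(i0 + 2)] + c(0.2, 0.6, 1, 0.6, 0.2)
  }

  snore_fs <- 500
  snore <- 0.1 * rnorm(dur_s * snore_fs)
  n_burst <- rpois(1, 2 * dur_s / 60)
  for (b in seq_len(n_burst)) {
    s0 <- runif(1, 0, dur_s - 1)
    idx <- round(s0 * snore_fs):round((s0 + 0.5) * snore_fs)
    idx <- idx[idx >= 1 & idx <= length(snore)]
    snore[idx] <- snore[idx] + 0.8 * rnorm(length(idx))
  }

  emg_amp <- c(W = 12, N1 = 8, N2 = 6, N3 = 4, REM = 1.5)
  channels <- list(
    channel_signal("EEGC3_A2", "EEG", eeg_make(), 200),
    channel_signal("EEGO1_A2", "EEG", eeg_make(), 200),
    channel_signal("EOG", "EOG",
                   8 * colored_noise(dur_s * 200) +
                     per_epoch(200, function(st, tl)
                       if (st == "REM") 35 * sin(2 * pi * 0.3 * tl +
                                                   runif(1, 0, 2 * pi))
                       else numeric(length(tl))), 200),
    channel_signal("EMGChin", "EMG",
                   per_epoch(200, function(st, tl)
                     emg_amp[[st]] * rnorm(length(tl))), 200),
    channel_signal("EffortTHO", "Effort",
                   gain_at(eff_gain, t100) * resp_wave +
                     0.08 * rnorm(length(t100)), 100),
    channel_signal("Airflow", "Airflow",
                   gain_at(flow_gain, t100) * resp_wave +
                     0.05 * rnorm(length(t100)), 100),
    channel_signal("SpO2", "SpO2", spo2, 1),
    channel_signal("ECG", "ECG", ecg, 200),
    channel_signal("Snore", "Snore", snore, snore_fs))

  n_art <- rpois(1, spec$artifact_per_h * dur_s / 3600)
  art <- if (n_art > 0) {
    st <- sort(runif(n_art, 0, dur_s - 20))
    artifact_intervals(st, st + runif(n_art, 5, 15), rep("*", n_art))
  } else artifact_intervals()

  rec <- psg_record(subject_id, channels, hyp, art)
  gt <- list(n_events = nrow(events),
             AHI = if (tst_h > 0) nrow(events) / tst_h else NA_real_,
             n_arousals = nrow(arousals),
             AI = if (tst_h > 0) nrow(arousals) / tst_h else NA_real_,
             TST_min = tst_h * 60)
  list(record = rec, events = events, arousals = arousals, ground_truth = gt)
}

# ---- biomarker marginals and coupling -------------------------------------

#' Biomarker marginal samplers
#'
#' Amyloid-beta 1-42 is near-symmetric (truncated normal, median 515 pg/ml,
#' IQR-matched SD 155); p-tau and t-tau are right-skewed lognormals with
#' medians 82 and 555 pg/ml and log-SDs matched to the reported IQRs.
#'
#' @return named list of functions \code{function(n)} and quantile functions.
#' @export
biomarker_marginals <- function() {
  list(
    abeta42 = list(
      r = function(n) pmax(50, rnorm(n, 515, 155)),
      q = function(p) pmax(50, qnorm(p, 515, 155))),
    ptau = list(
      r = function(n) rlnorm(n, log(82), 0.476),
      q = function(p) stats::qlnorm(p, log(82), 0.476)),
    ttau = list(
      r = function(n) rlnorm(n, log(555), 0.576),
      q = function(p) stats::qlnorm(p, log(555), 0.576)))
}

#' Default planted effect plan
#'
#' Feature-biomarker couplings at the magnitudes the pipeline is expected to
#' recover: EEG occipital skewness/alpha and CT90 with amyloid-beta, chin-EMG
#' maximum and thoracic-effort complexity with p-tau, thoracic-effort
#' complexity and sample entropy with t-tau.
#'
#' @return data.frame(feature, biomarker, r).
#' @export
default_effect_plan <- function() {
  data.frame(
    feature = c("EEGO1_A2_sk_N2", "EEGO1_A2_alpha_N2", "CT90",
                "sleep_quality", "EMGChin_max_N1", "EffortTHO_LempZiv_N2",
                "EffortTHO_LempZiv_N2", "EffortTHO_SampEnt_N2"),
    biomarker = c("abeta42", "abeta42", "abeta42", "abeta42",
                  "ptau", "ptau", "ttau", "ttau"),
    r = c(0.38, 0.41, 0.31, -0.39, -0.31, 0.31, 0.42, 0.39),
    stringsAsFactors = FALSE)
}

#' Couple biomarkers to realized features through a Gaussian copula
#'
#' Features named in the plan are rank-transformed to normal scores; per
#' biomarker, weights solving \code{C w = rho} (with \code{C} the empirical
#' normal-score correlation) reproduce the latent correlations, and the
#' latent draw is pushed through the biomarker's marginal quantile function.
#' Because a skewed marginal attenuates the Pearson correlation relative to
#' latent space, the latent targets are inflated by the marginal's
#' deterministic attenuation factor \code{cor(Z, q(pnorm(Z)))} so the
#' realized Pearson r lands on the plan's target. An effect plan requiring
#' latent variance \code{w'rho >= 1} is rejected as infeasible before
#' generation.
#'
#' @param features data.frame containing the plan's feature columns.
#' @param plan data.frame(feature, biomarker, r).
#' @param seed integer seed.
#' @param marginals see \code{\link{biomarker_marginals}}.
#' @return data.frame with one column per biomarker.
#' @export
couple_biomarkers <- function(features, plan, seed = 1L,
                              marginals = biomarker_marginals()) {
  n <- nrow(features)
  set.seed(derive_seed(seed, "biomarkers"))
  out <- list()
  for (bm in names(marginals)) {
    pl <- plan[plan$biomarker == bm, , drop = FALSE]
    pl <- pl[pl$feature %in% names(features), , drop = FALSE]
    if (nrow(pl) == 0L) {
      out[[bm]] <- marginals[[bm]]$r(n)
      next
    }
    # Pearson attenuation of the monotone marginal transform
    zg <- qnorm(stats::ppoints(20001))
    att <- cor(zg, marginals[[bm]]$q(pnorm(zg)))
    rho <- pmin(0.99, pl$r / att)
    Z <- vapply(pl$feature, function(f) {
      x <- features[[f]]
      z <- qnorm((rank(x, na.last = "keep") - 0.5) / sum(!is.na(x)))
      z[is.na(z)] <- 0
      z
    }, numeric(n))
    C <- cor(Z)
    w <- solve(C, rho)
    v <- sum(w * rho)
    if (v >= 1)
      stop("infeasible effect plan for ", bm,
           ": required latent variance ", round(v, 3), " >= 1")
    zb <- as.numeric(Z %*% w) + sqrt(1 - v) * rnorm(n)
    out[[bm]] <- marginals[[bm]]$q(pnorm(zb))
  }
  as.data.frame(out)
}

#' Cohort generation specification
#'
#' Defaults reproduce a realistic recruitment structure: 61 subjects of whom 3
#' lack a PSG recording and 9 lack biomarker measurements.
#'
#' @param n_subjects cohort size.
#' @param missing_psg,missing_biomarkers counts of subjects missing each
#'   modality (disjoint sets).
#' @param night a \code{\link{night_spec}} (signal mode).
#' @param effect_plan see \code{\link{default_effect_plan}}.
#' @param mode \code{"feature"} draws PSG features directly from their
#'   cohort-level distribution (fast, used for selection/model studies);
#'   \code{"signal"} synthesizes full records and runs the measurement
#'   pipeline per subject.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 61L, missing_psg = 3L,
                        missing_biomarkers = 9L, night = night_spec(),
                        effect_plan = default_effect_plan(),
                        mode = c("feature", "signal")) {
  stopifnot(missing_psg + missing_biomarkers <= n_subjects,
            all(abs(effect_plan$r) < 1))
  mode <- match.arg(mode)
  structure(list(n_subjects = as.integer(n_subjects),
                 missing_psg = as.integer(missing_psg),
                 missing_biomarkers = as.integer(missing_biomarkers),
                 night = night, effect_plan = effect_plan, mode = mode),
            class = "cohort_spec")
}

generate_clinical <- function(n, seed) {
  set.seed(derive_seed(seed, "clinical"))
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex_female = rbinom(n, 1, 0.508),
    age = round(rnorm(n, 75, 4.5)),
    bmi = round(rlnorm(n, log(28), 0.12), 1),
    hypertension = rbinom(n, 1, 0.639),
    diabetes = rbinom(n, 1, 0.164),
    dyslipidemia = rbinom(n, 1, 0.492),
    heart_disease = rbinom(n, 1, 0.197),
    mmse = pmin(30, pmax(20, round(rnorm(n, 23, 2.5)))),
    ess = pmin(24, pmax(0, round(rlnorm(n, log(5), 0.5)))),
    sleep_quality = round(runif(n, 0, 10)),
    sleep_duration_holidays = round(rnorm(n, 8, 1.2), 1),
    education_years = pmax(0, round(rnorm(n, 8, 4))),
    weight_kg = round(rnorm(n, 75, 12), 1),
    stringsAsFactors = FALSE)
}

generate_sleepvar_table <- function(n, seed) {
  set.seed(derive_seed(seed, "sleepvar"))
  tib <- rnorm(n, 420, 30)
  se <- 100 * stats::plogis(rnorm(n, stats::qlogis(0.664), 0.6))
  tst <- tib * se / 100
  ahi <- rlnorm(n, log(27), 0.55)
  p_raw <- cbind(rlnorm(n, log(12), 0.4), rlnorm(n, log(23), 0.4),
                 rlnorm(n, log(13.6), 0.5), rlnorm(n, log(6.6), 0.5))
  pct <- 100 * p_raw / rowSums(p_raw)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    TIB = round(tib, 1), TST = round(tst, 1), SE = round(se, 1),
    AI = round(rlnorm(n, log(36), 0.35), 1),
    AHI = round(ahi, 1),
    ODI = round(ahi * rlnorm(n, log(0.7), 0.3), 1),
    CT90 = round(rlnorm(n, log(1.9), 1), 2),
    mean_SaO2 = round(rnorm(n, 93, 1), 1),
    min_SaO2 = round(rnorm(n, 84, 4), 1),
    N1_pct = round(pct[, 1], 1), N2_pct = round(pct[, 2], 1),
    N3_pct = round(pct[, 3], 1), REM_pct = round(pct[, 4], 1),
    latency_N1 = round(rlnorm(n, log(23), 0.7), 1),
    latency_REM = round(rlnorm(n, log(127), 0.5), 1),
    stringsAsFactors = FALSE)
}

generate_psgvar_table <- function(n, seed, n_background = 40L) {
  # latent two-factor structure + noise; plan features included by name
  set.seed(derive_seed(seed, "psgvar"))
  plan_feats <- unique(default_effect_plan()$feature)
  plan_feats <- plan_feats[grepl("_(N1|N2|N3|REM)$", plan_feats)]
  codes <- c("rms", "var", "sk", "kurt", "max", "ShanEnt", "SampEnt",
             "LempZiv", "HFD", "MF", "DF", "TotalPw")
  chans <- c("EEGC3_A2", "EEGO1_A2", "EOG", "EMGChin", "EffortTHO",
             "Airflow", "SpO2", "ECG", "Snore")
  pool <- as.vector(outer(chans, outer(codes, c("N1", "N2", "N3", "REM"),
                                       paste, sep = "_"), paste, sep = "_"))
  pool <- setdiff(pool, plan_feats)
  feats <- c(plan_feats, sample(pool, n_background))
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- vapply(seq_along(feats), function(j) {
    l1 <- runif(1, -0.5, 0.5); l2 <- runif(1, -0.5, 0.5)
    l1 * f1 + l2 * f2 + rnorm(n, 0, sqrt(max(0.1, 1 - l1^2 - l2^2)))
  }, numeric(n))
  colnames(X) <- feats
  cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   stringsAsFactors = FALSE), as.data.frame(X))
}

#' Generate a synthetic cohort
#'
#' Produces the full input bundle of the analysis: a subject manifest with
#' a realistic missingness structure, a clinical table (CLINVAR), a
#' conventional sleep-parameter table (SLEEPVAR), a quantitative PSG feature
#' table (PSGVAR), and a biomarker panel coupled to the realized features via
#' the effect plan. In \code{"signal"} mode SLEEPVAR and PSGVAR are measured
#' by running the preprocessing and feature-extraction pipeline on per-subject
#' synthetic records; in \code{"feature"} mode they are drawn directly from
#' cohort-level distributions.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed.
#' @param config preprocessing configuration (signal mode).
#' @param window_s feature window in seconds (signal mode; shortened for
#'   short test nights).
#' @param params \code{\link{nonlinear_params}} used by the extraction
#'   (signal mode).
#' @return list(manifest, clinvar, sleepvar, psgvar, biomarkers, ground_truth).
#' @export
generate_cohort <- function(spec, seed = 1L, config = preprocess_config(),
                            window_s = 120, params = nonlinear_params()) {
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  set.seed(derive_seed(seed, "cohort"))
  no_psg <- sample(ids, spec$missing_psg)
  no_bio <- sample(setdiff(ids, no_psg), spec$missing_biomarkers)

  clin <- generate_clinical(n, seed)
  if (spec$mode == "feature") {
    sleepvar <- generate_sleepvar_table(n, seed)
    psgvar <- generate_psgvar_table(n, seed)
  } else {
    rows_s <- list(); rows_p <- list()
    for (i in seq_len(n)) {
      if (ids[i] %in% no_psg) next
      gen <- generate_record(spec$night, seed = derive_seed(seed, ids[i]),
                             subject_id = ids[i])
      sp <- derive_sleep_parameters(gen$record$hypnogram, gen$events,
                                    gen$arousals,
                                    gen$record$channels$SpO2)
      rows_s[[ids[i]]] <- sleep_parameters_row(sp)
      pre <- preprocess_record(gen$record, config)
      pv <- extract_psgvar(pre, params = params, window_s = window_s,
                           overlap = 0.5)
      rows_p[[ids[i]]] <- setNames(pv$value, pv$feature)
    }
    to_df <- function(rows) {
      feats <- unique(unlist(lapply(rows, names)))
      m <- t(vapply(rows, function(r) r[feats], numeric(length(feats))))
      colnames(m) <- feats
      cbind(data.frame(subject_id = names(rows), stringsAsFactors = FALSE),
            as.data.frame(m, row.names = NULL))
    }
    sleepvar <- to_df(rows_s)
    psgvar <- to_df(rows_p)
  }

  # assemble feature frame for the coupling (row order = ids)
  feat_all <- clin
  join <- function(a, b) merge(a, b, by = "subject_id", all.x = TRUE,
                               sort = FALSE)
  feat_all <- join(join(feat_all, sleepvar), psgvar)
  feat_all <- feat_all[match(ids, feat_all$subject_id), , drop = FALSE]
  bio <- couple_biomarkers(feat_all, spec$effect_plan, seed)
  bio <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), bio)
  bio[ids %in% no_bio, c("abeta42", "ptau", "ttau")] <- NA_real_

  realized <- vapply(seq_len(nrow(spec$effect_plan)), function(i) {
    f <- spec$effect_plan$feature[i]
    if (!f %in% names(feat_all)) return(NA_real_)
    ok <- complete.cases(feat_all[[f]], bio[[spec$effect_plan$biomarker[i]]])
    if (sum(ok) < 3) return(NA_real_)
    cor(feat_all[[f]][ok], bio[[spec$effect_plan$biomarker[i]]][ok])
  }, numeric(1))

  if (spec$mode == "feature") {
    sleepvar[sleepvar$subject_id %in% no_psg, -1] <- NA
    psgvar[psgvar$subject_id %in% no_psg, -1] <- NA
  }
  list(
    manifest = data.frame(subject_id = ids,
                          has_psg = !ids %in% no_psg,
                          has_biomarkers = !ids %in% no_bio,
                          stringsAsFactors = FALSE),
    clinvar = clin, sleepvar = sleepvar, psgvar = psgvar, biomarkers = bio,
    ground_truth = list(effect_plan = cbind(spec$effect_plan,
                                            realized_r = realized),
                        missing_psg = no_psg, missing_biomarkers = no_bio))
}
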