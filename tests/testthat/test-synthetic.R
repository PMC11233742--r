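test_that("Markov hypnogram respects the transition matrix and the seed", {
  absorb <- matrix(0, 5, 5, dimnames = list(somnomark:::.sm_stages,
                                            somnomark:::.sm_stages))
  absorb[, "N2"] <- 1
  spec <- night_spec(duration_min = 5, transition = absorb)
  hyp <- generate_hypnogram(spec, seed = 1)
  expect_true(all(hyp$stages[-1] == "N2"))
  spec2 <- night_spec(duration_min = 30 * 10000 / 60 / 2)
  h1 <- generate_hypnogram(spec2, seed = 3)
  h2 <- generate_hypnogram(spec2, seed = 3)
  expect_identical(h1$stages, h2$stages)
  # empirical transition frequencies near the matrix at 10^4 epochs
  spec3 <- night_spec(duration_min = 10000 * 30 / 60)
  hl <- generate_hypnogram(spec3, seed = 5)$stages
  P <- default_transition_matrix()
  emp <- prop.table(table(factor(head(hl, -1), levels = rownames(P)),
                          factor(tail(hl, -1), levels = rownames(P))), 1)
  expect_lt(max(abs(emp - P), na.rm = TRUE), 0.05)
})

test_that("stage-gated spectral content: delta in N3, spindles in N2", {
  deltas <- spindles <- logical(30)
  for (s in seq_len(30)) {
    # force a hypnogram with both N2 and N3 present
    hyp <- hypnogram(rep(c("N2", "N3"), each = 5))
    spec <- night_spec(duration_min = 5, artifact_per_h = 0)
    gen <- generate_record(spec, hyp = hyp, seed = s)
    eeg_only <- psg_record(gen$record$subject_id,
                           gen$record$channels["EEGO1_A2"], hyp)
    pre <- preprocess_record(eeg_only)
    bp <- function(st, lo, hi) {
      x <- pre$EEGO1_A2$spectral[[st]]$samples
      est <- welch_psd(x, 500, 16384)
      sel <- est$freqs >= lo & est$freqs <= hi
      sum(est$psd[sel])
    }
    deltas[s] <- bp("N3", 0.5, 4) > bp("N2", 0.5, 4)
    spindles[s] <- bp("N2", 12, 14) > bp("N3", 12, 14)
  }
  expect_gte(mean(deltas), 0.95)
  expect_gte(mean(spindles), 0.95)
})

test_that("biomarker marginals match the intended shapes", {
  set.seed(14)
  m <- biomarker_marginals()
  ab <- m$abeta42$r(3000); pt <- m$ptau$r(3000); tt <- m$ttau$r(3000)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew(ab)), 0.5)
  expect_gt(skew(pt), 0)
  expect_gt(skew(tt), 0)
  expect_equal(median(ab), 515, tolerance = 0.05 * 515)
  expect_equal(median(pt), 82, tolerance = 0.05 * 82)
  expect_equal(median(tt), 555, tolerance = 0.05 * 555)
})

test_that("copula coupling realizes target correlations and rejects infeasible plans", {
  plan <- data.frame(feature = "EffortTHO_LempZiv_N2", biomarker = "ttau",
                     r = 0.42)
  rs <- vapply(1:10, function(s) {
    set.seed(s)
    feats <- data.frame(EffortTHO_LempZiv_N2 = rnorm(300))
    bio <- couple_biomarkers(feats, plan, seed = s)
    cor(feats[[1]], bio$ttau)
  }, numeric(1))
  expect_gt(mean(rs), 0.37); expect_lt(mean(rs), 0.47)
  expect_gte(mean(rs >= 0.32 & rs <= 0.52), 0.8)
  # medians preserved within 5% under coupling at n = 500
  feats2 <- data.frame(EffortTHO_LempZiv_N2 = rnorm(500))
  bio2 <- couple_biomarkers(feats2, plan, seed = 9)
  expect_equal(median(bio2$ttau), 555, tolerance = 0.05 * 555)
  bad <- data.frame(feature = c("a", "b"), biomarker = "ttau",
                    r = c(0.9, 0.9))
  expect_error(couple_biomarkers(data.frame(a = rnorm(50),
                                            b = rnorm(50)), bad, 1),
               "infeasible")
})

test_that("cohort generation reproduces the study's missingness structure", {
  co <- tiny_cohort(61, 3, 9, seed = 2)
  expect_equal(sum(!co$manifest$has_psg), 3)
  expect_equal(sum(!co$manifest$has_biomarkers), 9)
  fc <- filter_cohort(co$manifest)
  expect_length(fc$kept, 49)
  # biomarker columns NA exactly for flagged subjects
  miss <- co$biomarkers$subject_id[is.na(co$biomarkers$ttau)]
  expect_setequal(miss, co$ground_truth$missing_biomarkers)
  # plan features present in the generated tables
  expect_true(all(c("EffortTHO_LempZiv_N2", "EffortTHO_SampEnt_N2") %in%
                    names(co$psgvar)))
  expect_true("CT90" %in% names(co$sleepvar))
})
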