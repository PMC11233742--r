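test_that("cohort filter keeps complete subjects with reasons for the rest", {
  man <- data.frame(subject_id = sprintf("S%02d", 1:61),
                    has_psg = c(rep(FALSE, 3), rep(TRUE, 58)),
                    has_biomarkers = c(rep(TRUE, 3), rep(FALSE, 9),
                                       rep(TRUE, 49)))
  fc <- filter_cohort(man)
  expect_length(fc$kept, 49)
  expect_equal(nrow(fc$excluded), 12)
  # all complete -> all kept
  man2 <- data.frame(subject_id = c("a", "b"), has_psg = TRUE,
                     has_biomarkers = TRUE)
  expect_length(filter_cohort(man2)$kept, 2)
  # failing both: excluded once with both reasons
  man3 <- data.frame(subject_id = "x", has_psg = FALSE,
                     has_biomarkers = FALSE)
  fc3 <- filter_cohort(man3)
  expect_equal(nrow(fc3$excluded), 1)
  expect_identical(fc3$excluded$reason, "missing_psg+missing_biomarkers")
})

test_that("missingness rule is strictly greater-than", {
  d <- data.frame(a = c(rep(NA, 5), 1:5),      # exactly 50% -> kept
                  b = c(rep(NA, 6), 1:4),      # 60% -> dropped
                  c = 1:10)
  out <- missingness_filter(d, 0.5)
  expect_named(out, c("a", "c"))
  d10 <- as.data.frame(matrix(rnorm(100), 10))
  d10[1:6, 1:3] <- NA
  expect_equal(ncol(missingness_filter(d10, 0.5)), 7)
})

test_that("target-correlation screen keeps signal and rejects noise", {
  y <- rnorm(200)
  d <- data.frame(same = y)
  expect_named(target_correlation_screen(d, y, 0.3), "same")
  keep_null <- keep_planted <- logical(100)
  for (s in 1:100) {
    set.seed(s)
    y <- rnorm(200)
    noise <- rnorm(200)
    planted <- 0.4 * scale(y)[, 1] + sqrt(1 - 0.16) * rnorm(200)
    d <- data.frame(noise = noise, planted = planted)
    kept <- names(target_correlation_screen(d, y, 0.3, strict = TRUE))
    keep_null[s] <- "noise" %in% kept
    keep_planted[s] <- "planted" %in% kept
  }
  expect_lte(mean(keep_null), 0.10)
  expect_gte(mean(keep_planted), 0.95)
  expect_warning(target_correlation_screen(data.frame(z = rep(1, 10)),
                                           rnorm(10), 0.1), "zero-variance")
})

test_that("dedup keeps the stronger-linked member and audits the bound", {
  set.seed(5)
  y <- rnorm(100)
  x <- 0.6 * scale(y)[, 1] + 0.8 * rnorm(100)
  d <- data.frame(x = x, xcopy = x, z = rnorm(100))
  out <- dedup_correlated(d, y, 0.9)
  expect_equal(sum(names(out) %in% c("x", "xcopy")), 1)
  x2 <- x + rnorm(100, sd = 0.01)
  d2 <- data.frame(weak = x2, strong = x, indep = rnorm(100))
  # make 'strong' the better-correlated member by construction
  if (abs(cor(d2$weak, y)) > abs(cor(d2$strong, y)))
    names(d2)[1:2] <- c("strong", "weak")
  out2 <- dedup_correlated(d2, y, 0.9)
  expect_length(names(out2), 2)
  expect_true("indep" %in% names(out2))
  cm <- abs(cor(out2))
  expect_lte(max(cm[upper.tri(cm)]), 0.9)
})

test_that("split/standardize is seeded, leak-free and exact on train moments", {
  set.seed(1)
  d <- as.data.frame(matrix(rnorm(49 * 6), 49))
  s1 <- split_standardize(d, 0.25, seed = 3)
  s2 <- split_standardize(d, 0.25, seed = 3)
  expect_identical(s1$test_idx, s2$test_idx)
  expect_length(s1$test_idx, round(49 * 0.25)) # 12
  expect_lt(max(abs(colMeans(s1$train))), 1e-9)
  expect_lt(max(abs(apply(s1$train, 2, sd) - 1)), 1e-9)
  # refitting the scaler on train rows only reproduces stored statistics
  tr_raw <- d[s1$train_idx, ]
  expect_identical(unname(colMeans(tr_raw)), unname(s1$center))
  expect_identical(unname(apply(tr_raw, 2, sd)), unname(s1$scale))
})

test_that("PCA retains the minimal component count for 90% variance", {
  d <- matrix(rnorm(200), 40, 5)
  ident <- d[, c(1, 1, 1, 1, 1)]
  colnames(ident) <- paste0("f", 1:5)
  p0 <- pca_reduce(ident, ident[1:5, ])
  expect_equal(p0$k, 1)
  expect_equal(p0$explained, 1)
  set.seed(2)
  X <- matrix(rnorm(500 * 10), 500)
  colnames(X) <- paste0("f", 1:10)
  X <- scale(X)
  p <- pca_reduce(X, X[1:5, ], variance = 0.9)
  ev <- p$explained_per_pc
  expect_gte(sum(ev[seq_len(p$k)]), 0.9)
  if (p$k > 1) expect_lt(sum(ev[seq_len(p$k - 1)]), 0.9) # minimality
  expect_length(p$pca_sel, length(unique(p$pca_sel)))
})

test_that("build_subsets shares the split and unions screened features", {
  co <- tiny_cohort(seed = 12)
  fc <- filter_cohort(co$manifest)
  keep <- function(d) d[d$subject_id %in% fc$kept, , drop = FALSE]
  b <- suppressWarnings(
    build_subsets(keep(co$clinvar), keep(co$sleepvar), keep(co$psgvar),
                  keep(co$biomarkers), "ttau", seed = 4))
  expect_setequal(names(b$subsets), c("CLINVAR", "SLEEPVAR", "PSGVAR", "ALL"))
  nf <- vapply(b$subsets, function(s) length(s$features), integer(1))
  # ALL is the dedup-pruned union of the three screened sets
  expect_lte(nf[["ALL"]], sum(nf[c("CLINVAR", "SLEEPVAR", "PSGVAR")]))
  expect_true(all(b$subsets$ALL$features %in%
                    unlist(lapply(b$subsets[1:3], `[[`, "features"))))
  # one shared split: y partitions agree across subsets by construction
  expect_equal(length(b$y_train) + length(b$y_test), b$n)
  for (s in b$subsets) {
    expect_equal(nrow(s$pca$train_scores), length(b$y_train))
    expect_equal(nrow(s$pca$test_scores), length(b$y_test))
    expect_gte(s$pca$explained, 0.9)
  }
  # determinism by seed
  b2 <- suppressWarnings(
    build_subsets(keep(co$clinvar), keep(co$sleepvar), keep(co$psgvar),
                  keep(co$biomarkers), "ttau", seed = 4))
  expect_identical(b$subsets$ALL$pca$train_scores,
                   b2$subsets$ALL$pca$train_scores)
})
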