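test_that("mae: hand arithmetic and the Jensen bound", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(500, 600), c(510, 580)), 15)
  set.seed(2)
  for (i in 1:20) {
    y <- rnorm(30); yh <- rnorm(30)
    expect_lte(mae(y, yh), sqrt(mean((y - yh)^2)) + 1e-12)
  }
  expect_error(mae(numeric(), numeric()), "positive length")
  expect_error(mae(1:3, 1:2), "equal")
})

test_that("the zoo holds exactly the fifteen named models with families", {
  zoo <- model_zoo(seed = 7)
  expect_length(zoo, 15)
  expect_setequal(names(zoo),
                  c("BR", "ETR", "RFR", "GBR_ls", "GBR_lad", "GBR_hb",
                    "RR", "LR", "GP_rbf", "GP_m32", "KNR",
                    "SVR_lin", "SVR_poly", "SVR_rbf", "SVR_sig"))
  fam <- vapply(zoo, `[[`, character(1), "family")
  expect_equal(sum(fam == "EM"), 6)
  expect_equal(sum(fam == "RLR"), 2)
  expect_equal(sum(fam == "GP"), 2)
  expect_equal(sum(fam == "SVR"), 4)
  expect_equal(sum(fam == "KNR"), 1)
  expect_true(all(vapply(zoo, `[[`, numeric(1), "seed") == 7))
})

test_that("cross-validation winner matches an exhaustive fold re-evaluation", {
  set.seed(5)
  n <- 40
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("PC", 1:3)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(n, sd = 0.3)
  for (nm in c("KNR", "RR")) {
    spec <- model_zoo(seed = 9)[[nm]]
    fit <- fit_cv(spec, X, y, k = 5)
    # oracle: recompute every grid point on the stored folds
    oracle <- vapply(seq_len(nrow(spec$grid)), function(g) {
      params <- as.list(spec$grid[g, , drop = FALSE])
      mean(vapply(1:5, function(f) {
        tr <- fit$folds != f
        m <- spec$fit(X[tr, , drop = FALSE], y[tr], params, spec$seed)
        mae(y[!tr], spec$predict(m, X[!tr, , drop = FALSE]))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(unname(fit$cv$cv_mae), unname(oracle), info = nm)
    expect_equal(unlist(fit$params),
                 unlist(as.list(spec$grid[which.min(oracle), , drop = FALSE])),
                 info = nm)
  }
  # one-point grid is chosen as-is, and n < k errors
  one <- model_zoo(seed = 1)$BR
  expect_equal(fit_cv(one, X, y)$params$dummy, 1)
  expect_error(fit_cv(model_zoo(1)$KNR, X[1:3, ], y[1:3], k = 5), "< k")
})

test_that("ridge approaches zero test error as noise vanishes", {
  set.seed(3)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("PC", 1:4)))
  y <- 3 * X[, 1] + rnorm(100, sd = 1e-4)
  spec <- model_zoo(seed = 3)$RR
  fit <- fit_cv(spec, X[1:75, ], y[1:75])
  err <- mae(y[76:100], spec$predict(fit$model, X[76:100, ]))
  expect_lt(err, 0.05)
})

test_that("GP restarts are seeded and both kernels interpolate smooth data", {
  set.seed(12)
  X <- matrix(seq(-2, 2, length.out = 25), ncol = 1,
              dimnames = list(NULL, "PC1"))
  y <- sin(2 * X[, 1]) * 3 + 500
  for (kern in c("rbf", "matern32")) {
    g1 <- gp_fit(X, y, kernel = kern, restarts = 5, seed = 4)
    g2 <- gp_fit(X, y, kernel = kern, restarts = 5, seed = 4)
    expect_identical(g1$nll, g2$nll)
    expect_lt(mae(y, predict(g1, X)), 0.5)
  }
})

test_that("boosting overfits small samples in the expected direction", {
  gaps <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, paste0("PC", 1:3)))
    y <- 40 * X[, 1] + rnorm(30, sd = 30) + 500
    spec <- model_zoo(seed = s)$GBR_ls
    fit <- spec$fit(X[1:22, ], y[1:22],
                    list(nrounds = 300L, eta = 0.1, max_depth = 3L), s)
    mae(y[1:22], spec$predict(fit, X[1:22, , drop = FALSE])) <=
      mae(y[23:30], spec$predict(fit, X[23:30, , drop = FALSE]))
  }, logical(1))
  expect_gte(mean(gaps), 0.8)
})

test_that("family aggregation reproduces per-model means and KNR has no SD", {
  co <- tiny_cohort(seed = 31)
  fc <- filter_cohort(co$manifest)
  keep <- function(d) d[d$subject_id %in% fc$kept, , drop = FALSE]
  b <- suppressWarnings(
    build_subsets(keep(co$clinvar), keep(co$sleepvar), keep(co$psgvar),
                  keep(co$biomarkers), "ptau", seed = 2))
  zoo <- model_zoo(seed = 2)[c("RR", "LR", "KNR")]
  res <- evaluate_matrix(list(ptau = list(subsets = b$subsets["CLINVAR"],
                                          y_train = b$y_train,
                                          y_test = b$y_test)),
                         zoo, seed = 2)
  ft <- family_table(res)
  rlr <- res[res$family %in% "RLR", ]
  expect_equal(ft$test_mean[ft$family == "RLR"], mean(rlr$test_mae))
  expect_equal(ft$test_sd[ft$family == "RLR"], sd(rlr$test_mae))
  expect_true(is.na(ft$test_sd[ft$family == "KNR"]))
  # rerun is byte-identical
  res2 <- evaluate_matrix(list(ptau = list(subsets = b$subsets["CLINVAR"],
                                           y_train = b$y_train,
                                           y_test = b$y_test)),
                          zoo, seed = 2)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})
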