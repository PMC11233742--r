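#' Mean absolute error
#' @param y,yhat numeric vectors of equal positive length.
#' @return mean of |y - yhat| (pg/ml when the inputs are biomarker levels).
#' @export
mae <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    stop("y and yhat must have equal positive length")
  mean(abs(y - yhat))
}

# glmnet needs >= 2 columns; pad single-column matrices with a zero column
pad2 <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `..pad` = 0)
}

#' The fifteen-model regression zoo
#'
#' Exactly the classical models benchmarked by the pipeline, with their family
#' assignment and small documented hyperparameter grids:
#' \itemize{
#' \item EM (ensembles): Bagging Regressor \code{BR} (random forest with
#'   \code{mtry = p}), Extra Trees \code{ETR}, Random Forest \code{RFR}
#'   (500 trees each), and three Gradient Boosting Regressors with least
#'   squares (\code{GBR_ls}), least absolute deviation (\code{GBR_lad}) and
#'   Huber (\code{GBR_hb}) losses (trees in \{100, 300\}, learning rate in
#'   \{0.03, 0.1\}, depth in \{2, 3\}).
#' \item RLR: Ridge \code{RR} and Lasso \code{LR} (penalty 10^-3..10^2).
#' \item GP: Gaussian processes with RBF (\code{GP_rbf}) and Matern 3/2
#'   (\code{GP_m32}) kernels, 20 seeded optimizer restarts instead of a grid.
#' \item KNR: k-nearest-neighbour regression (k in \{3, 5, 7, 9\}).
#' \item SVR: support vector regression with linear, polynomial, RBF and
#'   sigmoid kernels (C in \{0.1, 1, 10\}; kernel coefficient in
#'   \{1/p, 0.01, 0.1\} where it applies).
#' }
#'
#' @param seed integer seed recorded in every spec and used for the stochastic
#'   fitters.
#' @return named list of 15 model specs (name, family, grid, fit, predict).
#' @export
model_zoo <- function(seed = 1L) {
  specs <- list()
  add <- function(name, family, grid, fit, predict) {
    specs[[name]] <<- list(name = name, family = family, grid = grid,
                           fit = fit, predict = predict, seed = seed)
  }
  rf_fit <- function(bagging) function(X, y, params, seed) {
    set.seed(seed)
    mtry <- if (bagging) ncol(X) else max(1L, floor(ncol(X) / 3))
    randomForest::randomForest(x = X, y = y, ntree = 500L, mtry = mtry)
  }
  rf_pred <- function(fit, X) unname(predict(fit, X))
  add("BR", "EM", data.frame(dummy = 1), rf_fit(TRUE), rf_pred)
  add("ETR", "EM", data.frame(dummy = 1),
      function(X, y, params, seed) {
        d <- as.data.frame(X); d$..y <- y
        ranger::ranger(dependent.variable.name = "..y", data = d,
                       num.trees = 500L, mtry = ncol(X),
                       splitrule = "extratrees", num.random.splits = 1L,
                       replace = FALSE, sample.fraction = 1,
                       seed = seed, num.threads = 1L)
      },
      function(fit, X) predict(fit, data = as.data.frame(X),
                               num.threads = 1L)$predictions)
  add("RFR", "EM", data.frame(dummy = 1), rf_fit(FALSE), rf_pred)

  gbr_grid <- expand.grid(nrounds = c(100L, 300L), eta = c(0.03, 0.1),
                          max_depth = c(2L, 3L))
  gbr_fit <- function(objective) function(X, y, params, seed) {
    pars <- list(objective = objective, eta = params$eta,
                 max_depth = params$max_depth, nthread = 1L,
                 seed = seed, verbosity = 0L, base_score = mean(y))
    # Huber transition at 1.35 robust SDs of the target scale
    if (objective == "reg:pseudohubererror")
      pars$huber_slope <- 1.35 * max(mad(y), 1e-8)
    xgboost::xgb.train(params = pars,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = params$nrounds, verbose = 0L)
  }
  gbr_pred <- function(fit, X) predict(fit, xgboost::xgb.DMatrix(X))
  add("GBR_ls", "EM", gbr_grid, gbr_fit("reg:squarederror"), gbr_pred)
  add("GBR_lad", "EM", gbr_grid, gbr_fit("reg:absoluteerror"), gbr_pred)
  add("GBR_hb", "EM", gbr_grid, gbr_fit("reg:pseudohubererror"), gbr_pred)

  glm_grid <- data.frame(lambda = 10^seq(-3, 2, by = 1))
  glm_fit <- function(alpha) function(X, y, params, seed)
    structure(list(m = glmnet::glmnet(pad2(X), y, alpha = alpha,
                                      lambda = params$lambda),
                   lambda = params$lambda), class = "sm_glmnet")
  glm_pred <- function(fit, X)
    as.numeric(predict(fit$m, newx = pad2(X), s = fit$lambda))
  add("RR", "RLR", glm_grid, glm_fit(0), glm_pred)
  add("LR", "RLR", glm_grid, glm_fit(1), glm_pred)

  gp_make <- function(kern) function(X, y, params, seed)
    gp_fit(X, y, kernel = kern, restarts = 20L, seed = seed)
  gp_pred <- function(fit, X) predict(fit, X)
  add("GP_rbf", "GP", data.frame(dummy = 1), gp_make("rbf"), gp_pred)
  add("GP_m32", "GP", data.frame(dummy = 1), gp_make("matern32"), gp_pred)

  add("KNR", "KNR", data.frame(k = c(3L, 5L, 7L, 9L)),
      function(X, y, params, seed)
        caret::knnreg(x = as.data.frame(X), y = y,
                      k = min(params$k, nrow(X))),
      function(fit, X) unname(predict(fit, newdata = as.data.frame(X))))

  svr_grid_g <- expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1))
  svr_fit <- function(kernel) function(X, y, params, seed) {
    g <- if (is.null(params$gamma) || is.na(params$gamma)) 1 / ncol(X)
         else params$gamma
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
               cost = params$cost, gamma = g, scale = FALSE)
  }
  svr_pred <- function(fit, X) unname(predict(fit, X))
  add("SVR_lin", "SVR", data.frame(cost = c(0.1, 1, 10)), svr_fit("linear"),
      svr_pred)
  add("SVR_poly", "SVR", svr_grid_g, svr_fit("polynomial"), svr_pred)
  add("SVR_rbf", "SVR", svr_grid_g, svr_fit("radial"), svr_pred)
  add("SVR_sig", "SVR", svr_grid_g, svr_fit("sigmoid"), svr_pred)
  specs
}

#' Fit a model spec with 5-fold cross-validated grid search
#'
#' Folds are assigned by a seeded shuffle; every grid row is scored by its
#' mean out-of-fold MAE and the winner (ties: first row in grid order) is
#' refitted on the full training set. Gaussian-process specs have no grid ---
#' their 20 seeded restarts play the tuning role --- so they are fitted
#' directly.
#'
#' @param spec one element of \code{\link{model_zoo}}.
#' @param X_train matrix (n x p) with column names.
#' @param y_train numeric target.
#' @param k number of folds (default 5; \code{n >= k} required).
#' @param seed fold-assignment seed (defaults to the spec seed).
#' @return list(model, spec, params, cv: data.frame(grid, cv_mae), folds).
#' @export
fit_cv <- function(spec, X_train, y_train, k = 5L, seed = spec$seed) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < k) stop("n_train (", n, ") < k (", k, ")")
  grid <- spec$grid
  cv_mae <- rep(NA_real_, nrow(grid))
  folds <- NULL
  if (nrow(grid) > 1L) {
    set.seed(derive_seed(seed, paste0("cv_", spec$name)))
    folds <- sample(rep_len(seq_len(k), n))
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      errs <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- spec$fit(X_train[tr, , drop = FALSE], y_train[tr], params,
                        seed)
        mae(y_train[!tr], spec$predict(fit, X_train[!tr, , drop = FALSE]))
      }, numeric(1))
      cv_mae[g] <- mean(errs)
    }
    win <- which.min(cv_mae)
  } else win <- 1L
  params <- as.list(grid[win, , drop = FALSE])
  model <- spec$fit(X_train, y_train, params, seed)
  list(model = model, spec = spec, params = params,
       cv = cbind(grid, cv_mae = cv_mae), folds = folds)
}

#' Evaluate the model zoo over subsets and biomarkers
#'
#' Fills the full result matrix: every model of the zoo is tuned (5-fold CV)
#' and fitted on the PCA-score training matrix of every subset for every
#' biomarker, and train/test MAE are recorded. As the documented exception,
#' the Bagging Regressor is additionally trained on the raw (standardized)
#' features that PCA flagged as most variance-relevant (\code{pca_sel});
#' those extra rows carry the model name \code{BR_pca_sel} and no family, so
#' family aggregates stay over the 15 core models.
#'
#' @param built named list per biomarker: output of \code{\link{build_subsets}}.
#' @param zoo output of \code{\link{model_zoo}}.
#' @param seed evaluation seed.
#' @return data.frame of class \code{results_matrix}: biomarker, subset,
#'   model, family, train_mae, test_mae, params (JSON).
#' @export
evaluate_matrix <- function(built, zoo = model_zoo(seed), seed = 1L) {
  rows <- list()
  br_spec <- zoo$BR %||% model_zoo(seed)$BR # pca_sel exception always runs
  for (bm in names(built)) {
    bb <- built[[bm]]
    for (sn in names(bb$subsets)) {
      sub <- bb$subsets[[sn]]
      run_one <- function(spec, Xtr, Xte, model_name, family) {
        sd_cell <- derive_seed(seed, paste(bm, sn, model_name, sep = "_"))
        fit <- fit_cv(spec, Xtr, bb$y_train, seed = sd_cell)
        data.frame(
          biomarker = bm, subset = sn, model = model_name, family = family,
          train_mae = mae(bb$y_train, spec$predict(fit$model, Xtr)),
          test_mae = mae(bb$y_test, spec$predict(fit$model, Xte)),
          params = as.character(jsonlite::toJSON(fit$params,
                                                 auto_unbox = TRUE,
                                                 digits = NA)),
          stringsAsFactors = FALSE)
      }
      for (spec in zoo)
        rows[[length(rows) + 1L]] <-
          run_one(spec, sub$pca$train_scores, sub$pca$test_scores,
                  spec$name, spec$family)
      sel <- sub$pca$pca_sel
      rows[[length(rows) + 1L]] <-
        run_one(br_spec, sub$std$train[, sel, drop = FALSE],
                sub$std$test[, sel, drop = FALSE], "BR_pca_sel",
                NA_character_)
    }
  }
  structure(do.call(rbind, rows), class = c("results_matrix", "data.frame"))
}

#' Aggregate a results matrix by model family
#'
#' Mean and SD of the member-model MAEs per (biomarker, family, subset);
#' single-member families (KNR) report no SD. Rows without a family
#' (the \code{BR_pca_sel} exception) are excluded.
#'
#' @param results a \code{\link{evaluate_matrix}} result.
#' @return data.frame(biomarker, family, subset, train_mean, train_sd,
#'   test_mean, test_sd, n_models).
#' @export
family_table <- function(results) {
  d <- results[!is.na(results$family), , drop = FALSE]
  key <- interaction(d$biomarker, d$family, d$subset, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    data.frame(biomarker = g$biomarker[1], family = g$family[1],
               subset = g$subset[1],
               train_mean = mean(g$train_mae),
               train_sd = if (nrow(g) > 1) sd(g$train_mae) else NA_real_,
               test_mean = mean(g$test_mae),
               test_sd = if (nrow(g) > 1) sd(g$test_mae) else NA_real_,
               n_models = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$biomarker, out$family, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write result tables and per-model bar charts
#'
#' Emits the per-model results CSV, the family-aggregated CSV, and one
#' grouped bar chart per biomarker (test MAE per model, grouped by subset).
#'
#' @param results an \code{\link{evaluate_matrix}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
report_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "results_models.csv")
  p2 <- file.path(dir, "results_families.csv")
  write.csv(as.data.frame(results), p1, row.names = FALSE)
  write.csv(family_table(results), p2, row.names = FALSE)
  paths <- c(p1, p2)
  for (bm in unique(results$biomarker)) {
    d <- results[results$biomarker == bm & !is.na(results$family), ]
    d$model <- factor(d$model, levels = unique(results$model))
    gg <- ggplot2::ggplot(d, ggplot2::aes(x = model, y = test_mae,
                                          fill = subset)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(title = paste("Test MAE per model -", bm),
                    x = NULL, y = "MAE (pg/ml)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    fp <- file.path(dir, paste0("mae_", bm, ".png"))
    grDevices::png(fp, width = 1200, height = 600, res = 120)
    print(gg)
    grDevices::dev.off()
    paths <- c(paths, fp)
  }
  invisible(paths)
}
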