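#' Feature-selection configuration
#'
#' Defaults follow the selection protocol: features missing in more than half
#' the samples are excluded (strict >); the absolute Pearson correlation with
#' the target must reach 0.1 for clinical and conventional-PSG variables and
#' exceed 0.3 for quantitative signal features; redundant pairs above |r| 0.9
#' are pruned; PCA retains the minimal component count explaining 90\% of the
#' training variance; 25\% of subjects form the test partition.
#'
#' @param missing_max maximal tolerated missing fraction (strict >).
#' @param corr_min_clin,corr_min_psg target-correlation thresholds
#'   (CLINVAR/SLEEPVAR use >=, PSGVAR uses >).
#' @param pairwise_max redundancy threshold on |r|.
#' @param pca_variance cumulative explained-variance goal.
#' @param test_fraction test-partition fraction.
#' @return list of class \code{selection_config}.
#' @export
selection_config <- function(missing_max = 0.5, corr_min_clin = 0.1,
                             corr_min_psg = 0.3, pairwise_max = 0.9,
                             pca_variance = 0.9, test_fraction = 0.25) {
  stopifnot(missing_max > 0, missing_max < 1, test_fraction > 0,
            test_fraction < 1, pca_variance > 0, pca_variance <= 1)
  structure(list(missing_max = missing_max, corr_min_clin = corr_min_clin,
                 corr_min_psg = corr_min_psg, pairwise_max = pairwise_max,
                 pca_variance = pca_variance, test_fraction = test_fraction),
            class = "selection_config")
}

#' Filter a cohort manifest to analyzable subjects
#'
#' Keeps subjects that have both a PSG recording and a biomarker panel;
#' everyone else is excluded with per-subject reasons (a subject failing both
#' checks is excluded once, with both reasons recorded).
#'
#' @param manifest data.frame(subject_id, has_psg, has_biomarkers).
#' @return list(kept = character ids, excluded = data.frame(subject_id, reason)).
#' @export
filter_cohort <- function(manifest) {
  stopifnot(all(c("subject_id", "has_psg", "has_biomarkers") %in%
                  names(manifest)))
  if (anyDuplicated(manifest$subject_id)) stop("duplicate subject ids")
  keep <- manifest$has_psg & manifest$has_biomarkers
  reasons <- vapply(seq_len(nrow(manifest)), function(i) {
    r <- c(if (!manifest$has_psg[i]) "missing_psg",
           if (!manifest$has_biomarkers[i]) "missing_biomarkers")
    paste(r, collapse = "+")
  }, character(1))
  list(kept = manifest$subject_id[keep],
       excluded = data.frame(subject_id = manifest$subject_id[!keep],
                             reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Drop features with excessive missingness
#'
#' A feature is dropped when its missing fraction is strictly greater than
#' \code{max_frac}; exactly at the threshold it is kept.
#'
#' @param table data.frame of features (numeric columns).
#' @param max_frac threshold (default 0.5).
#' @return the filtered table.
#' @export
missingness_filter <- function(table, max_frac = 0.5) {
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  table[, frac <= max_frac, drop = FALSE]
}

#' Screen features by absolute correlation with the target
#'
#' Pearson correlation on pairwise-complete observations; binary categorical
#' features enter as 0/1 dummies (point-biserial). Kept when
#' \code{|r| >= min_abs_r} (or strictly greater with \code{strict = TRUE}).
#' Zero-variance features are dropped with a warning. Intended to be run on
#' the training partition only.
#'
#' @param table data.frame of numeric features.
#' @param target numeric target vector aligned with rows.
#' @param min_abs_r threshold.
#' @param strict use strict inequality (quantitative-signal subset rule).
#' @return the screened table.
#' @export
target_correlation_screen <- function(table, target, min_abs_r,
                                      strict = FALSE) {
  keep <- vapply(names(table), function(nm) {
    x <- table[[nm]]
    ok <- complete.cases(x, target)
    if (sum(ok) < 3L || sd(x[ok]) == 0) {
      warning("dropping zero-variance or empty feature '", nm, "'")
      return(FALSE)
    }
    r <- abs(cor(x[ok], target[ok]))
    if (strict) r > min_abs_r else r >= min_abs_r
  }, logical(1))
  table[, keep, drop = FALSE]
}

#' Prune highly redundant feature pairs
#'
#' Features are visited in order of decreasing absolute correlation with the
#' target (ties broken lexicographically by name); a feature is dropped when
#' its absolute pairwise correlation with any already-retained feature exceeds
#' \code{max_abs_r}. The result therefore contains no pair above the
#' threshold, and from each redundant pair the member more strongly linked to
#' the target survives.
#'
#' @param table data.frame of numeric features.
#' @param target numeric target vector.
#' @param max_abs_r redundancy threshold (default 0.9).
#' @return the pruned table.
#' @export
dedup_correlated <- function(table, target, max_abs_r = 0.9) {
  if (ncol(table) < 2L) return(table)
  tc <- vapply(table, function(x) {
    ok <- complete.cases(x, target)
    abs(cor(x[ok], target[ok]))
  }, numeric(1))
  ord <- names(table)[order(-tc, names(table))]
  kept <- character()
  for (nm in ord) {
    red <- FALSE
    for (k in kept) {
      ok <- complete.cases(table[[nm]], table[[k]])
      if (abs(cor(table[[nm]][ok], table[[k]][ok])) > max_abs_r) {
        red <- TRUE; break
      }
    }
    if (!red) kept <- c(kept, nm)
  }
  table[, names(table)[names(table) %in% kept], drop = FALSE]
}

#' Split subjects and standardize features with train statistics
#'
#' A seeded uniform draw without replacement assigns \code{round(n *
#' test_fraction)} subjects to the test partition. Every feature is z-scored
#' with the training mean and SD --- applied unchanged to the test rows, so no
#' test information enters the scaling. Features with zero training SD are
#' dropped with a warning.
#'
#' @param table data.frame of numeric features (rownames = subject ids).
#' @param test_fraction test share (default 0.25).
#' @param seed integer seed for the split.
#' @param split optional precomputed list(train_idx, test_idx) to reuse a
#'   shared split across subsets.
#' @return list(train, test: matrices; center, scale: named vectors;
#'   train_idx, test_idx: row indices).
#' @export
split_standardize <- function(table, test_fraction = 0.25, seed = 1L,
                              split = NULL) {
  n <- nrow(table)
  stopifnot(n >= 8L)
  if (is.null(split)) {
    n_test <- round(n * test_fraction)
    set.seed(seed)
    test_idx <- sort(sample.int(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)
  } else {
    train_idx <- split$train_idx; test_idx <- split$test_idx
  }
  tr <- as.matrix(table[train_idx, , drop = FALSE])
  te <- as.matrix(table[test_idx, , drop = FALSE])
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, sd)
  drop <- !is.finite(scl) | scl == 0
  if (any(drop)) {
    warning("dropping zero-train-SD feature(s): ",
            paste(colnames(tr)[drop], collapse = ", "))
    tr <- tr[, !drop, drop = FALSE]; te <- te[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
  }
  list(train = sweep(sweep(tr, 2, ctr), 2, scl, "/"),
       test = sweep(sweep(te, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl,
       train_idx = train_idx, test_idx = test_idx)
}

#' Train-fitted PCA reduction
#'
#' Principal components are fitted on the (already standardized) training
#' matrix only; the smallest component count whose cumulative explained
#' variance reaches \code{variance} is retained, and test rows are projected
#' with the train loadings. \code{pca_sel} names, for each retained component,
#' the original feature with the largest absolute loading (union, order of
#' components preserved) --- the features "best explaining the variance".
#'
#' @param train,test standardized matrices (train statistics).
#' @param variance cumulative explained-variance goal (default 0.9).
#' @return list(train_scores, test_scores, loadings, k, explained, pca_sel).
#' @export
pca_reduce <- function(train, test, variance = 0.9) {
  pc <- prcomp(train, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  sel <- unique(vapply(seq_len(k), function(j)
    rownames(load)[which.max(abs(load[, j]))], character(1)))
  list(train_scores = train %*% load, test_scores = test %*% load,
       loadings = load, k = k, explained = cumsum(ev)[k],
       explained_per_pc = ev, pca_sel = sel)
}

#' Assemble the four selected feature subsets for one target biomarker
#'
#' Runs, per subset, the selection cascade on a shared train/test split:
#' missingness filter, target-correlation screen on the training rows
#' (CLINVAR and SLEEPVAR at \code{>= corr_min_clin}, PSGVAR at
#' \code{> corr_min_psg}), then forms ALL as the union of the three screened
#' sets, prunes redundant pairs (|r| > 0.9, training rows), standardizes with
#' train statistics and reduces by train-fitted PCA. Features still containing
#' missing values after the screens are dropped (imputation is out of scope).
#'
#' @param clinvar,sleepvar,psgvar data.frames with a \code{subject_id} column.
#' @param biomarkers data.frame with \code{subject_id} and the target column.
#' @param target name of the biomarker column.
#' @param config a \code{\link{selection_config}}.
#' @param seed split seed.
#' @return list per subset name (CLINVAR, SLEEPVAR, PSGVAR, ALL):
#'   \code{subset} fields plus shared \code{y_train}, \code{y_test},
#'   \code{split}.
#' @export
build_subsets <- function(clinvar, sleepvar, psgvar, biomarkers, target,
                          config = selection_config(), seed = 1L) {
  ids <- Reduce(intersect, list(clinvar$subject_id, sleepvar$subject_id,
                                psgvar$subject_id, biomarkers$subject_id))
  align <- function(d) {
    d <- d[match(ids, d$subject_id), , drop = FALSE]
    d$subject_id <- NULL
    d[, vapply(d, is.numeric, logical(1)), drop = FALSE]
  }
  tabs <- list(CLINVAR = align(clinvar), SLEEPVAR = align(sleepvar),
               PSGVAR = align(psgvar))
  y <- biomarkers[[target]][match(ids, biomarkers$subject_id)]
  ok <- !is.na(y)
  tabs <- lapply(tabs, function(d) d[ok, , drop = FALSE])
  y <- y[ok]
  n <- length(y)
  set.seed(derive_seed(seed, paste0("split_", target)))
  test_idx <- sort(sample.int(n, round(n * config$test_fraction)))
  split <- list(train_idx = setdiff(seq_len(n), test_idx),
                test_idx = test_idx)

  screened <- list()
  for (nm in names(tabs)) {
    d <- missingness_filter(tabs[[nm]], config$missing_max)
    thr <- if (nm == "PSGVAR") config$corr_min_psg else config$corr_min_clin
    tr_rows <- d[split$train_idx, , drop = FALSE]
    keep <- names(suppressWarnings(
      target_correlation_screen(tr_rows, y[split$train_idx], thr,
                                strict = nm == "PSGVAR")))
    screened[[nm]] <- d[, keep, drop = FALSE]
    if (ncol(screened[[nm]]) == 0L)
      stop("subset ", nm, " is empty after the correlation screen")
  }
  all_tab <- do.call(cbind, unname(screened))
  out <- list()
  for (nm in c(names(screened), "ALL")) {
    d <- if (nm == "ALL") all_tab else screened[[nm]]
    # residual missingness cannot enter PCA; drop such features
    has_na <- vapply(d, anyNA, logical(1))
    if (any(has_na)) {
      warning("dropping feature(s) with residual missingness in ", nm, ": ",
              paste(names(d)[has_na], collapse = ", "))
      d <- d[, !has_na, drop = FALSE]
    }
    tr_pruned <- dedup_correlated(d[split$train_idx, , drop = FALSE],
                                  y[split$train_idx], config$pairwise_max)
    kept <- names(tr_pruned)
    dfull <- d[, kept, drop = FALSE]
    std <- split_standardize(dfull, split = split)
    pca <- pca_reduce(std$train, std$test, config$pca_variance)
    out[[nm]] <- list(name = nm, features = kept, std = std, pca = pca)
  }
  list(subsets = out, y_train = y[split$train_idx], y_test = y[split$test_idx],
       split = split, n = n)
}

#' Biomarker positivity cut-offs (pg/ml)
#'
#' Amyloid-beta 1-42 below 600 pg/ml indicates amyloid deposition; total tau
#' above 425 and phosphorylated tau above 65 pg/ml indicate neurofibrillary
#' tangles.
#'
#' @return named list with elements \code{abeta42}, \code{ttau}, \code{ptau},
#'   each \code{list(cutoff, positive_when)}.
#' @export
biomarker_cutoffs <- function() {
  list(abeta42 = list(cutoff = 600, positive_when = "below"),
       ttau = list(cutoff = 425, positive_when = "above"),
       ptau = list(cutoff = 65, positive_when = "above"))
}
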