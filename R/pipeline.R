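#' Pipeline run configuration
#'
#' A plain list validated once; every stage reads from and writes to
#' \code{out_dir}, so stages can be re-run individually. All randomness
#' derives from \code{seed} through \code{\link{derive_seed}}.
#'
#' @param out_dir run directory.
#' @param seed integer run seed.
#' @param n_subjects,missing_psg,missing_biomarkers cohort structure.
#' @param mode \code{"signal"} (full synthetic records) or \code{"feature"}.
#' @param duration_min night length in minutes (signal mode).
#' @param biomarkers targets to run.
#' @param models model names to evaluate (default: the whole zoo).
#' @param window_s feature window in seconds.
#' @param sampen_decimate sample-entropy decimation factor (see
#'   \code{\link{nonlinear_params}}).
#' @param selection a \code{\link{selection_config}}.
#' @param write_edf also write per-subject EDF/TSV files (signal mode).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, n_subjects = 20L,
                       missing_psg = 0L, missing_biomarkers = 0L,
                       mode = c("signal", "feature"), duration_min = 20,
                       biomarkers = c("abeta42", "ptau", "ttau"),
                       models = NULL, window_s = 120, sampen_decimate = 1L,
                       selection = selection_config(), write_edf = FALSE) {
  mode <- match.arg(mode)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 missing_psg = as.integer(missing_psg),
                 missing_biomarkers = as.integer(missing_biomarkers),
                 mode = mode, duration_min = duration_min,
                 biomarkers = biomarkers, models = models,
                 window_s = window_s,
                 sampen_decimate = as.integer(sampen_decimate),
                 selection = selection,
                 write_edf = write_edf),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with \code{run_config} fields.
#' @param out_dir,seed optional overrides.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sel <- do.call(selection_config, y$selection %||% list())
  y$selection <- NULL
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, c(y, list(selection = sel)))
}

log_line <- function(config, ...) {
  msg <- paste0(...)
  cat(msg, "\n", sep = "", file = stderr())
  cat(msg, "\n", sep = "",
      file = file.path(config$out_dir, "run_log.txt"), append = TRUE)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(config$n_subjects, config$missing_psg,
                      config$missing_biomarkers,
                      night = night_spec(duration_min = config$duration_min),
                      mode = config$mode)
  co <- generate_cohort(spec, seed = derive_seed(config$seed, "simulate"),
                        window_s = config$window_s,
                        params = nonlinear_params(
                          sampen_decimate = config$sampen_decimate))
  wr <- function(d, f) write.csv(d, file.path(config$out_dir, f),
                                 row.names = FALSE)
  wr(co$manifest, "manifest.csv"); wr(co$clinvar, "clinvar.csv")
  wr(co$sleepvar, "sleepvar.csv"); wr(co$psgvar, "psgvar.csv")
  wr(co$biomarkers, "biomarkers.csv")
  jsonlite::write_json(co$ground_truth,
                       file.path(config$out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (config$write_edf && config$mode == "signal") {
    sdir <- file.path(config$out_dir, "edf")
    dir.create(sdir, showWarnings = FALSE)
    seed0 <- derive_seed(config$seed, "simulate")
    for (id in co$manifest$subject_id[co$manifest$has_psg]) {
      gen <- generate_record(spec$night, seed = derive_seed(seed0, id),
                             subject_id = id)
      write_edf(gen$record, file.path(sdir, paste0(id, ".edf")))
      write_hypnogram(gen$record$hypnogram,
                      file.path(sdir, paste0(id, "_hypnogram.tsv")))
      write_artifacts(gen$record$artifacts,
                      file.path(sdir, paste0(id, "_artifacts.tsv")))
      write_events(gen$events, file.path(sdir, paste0(id, "_events.tsv")))
    }
  }
  log_line(config, "simulate: cohort of ", config$n_subjects, " subjects (",
           config$mode, " mode, ", config$duration_min, "-min nights)")
  invisible(co)
}

read_stage_inputs <- function(config) {
  rd <- function(f) read.csv(file.path(config$out_dir, f),
                             stringsAsFactors = FALSE, check.names = FALSE)
  list(manifest = rd("manifest.csv"), clinvar = rd("clinvar.csv"),
       sleepvar = rd("sleepvar.csv"), psgvar = rd("psgvar.csv"),
       biomarkers = rd("biomarkers.csv"))
}

#' @rdname run_pipeline
#' @export
stage_select <- function(config) {
  if (!file.exists(file.path(config$out_dir, "biomarkers.csv")))
    stop("stage select: biomarkers.csv not found in ", config$out_dir,
         "; run the simulate stage (or provide cohort CSVs) first")
  inp <- read_stage_inputs(config)
  fc <- filter_cohort(inp$manifest)
  keep <- function(d) d[d$subject_id %in% fc$kept, , drop = FALSE]
  built <- list()
  for (bm in config$biomarkers) {
    built[[bm]] <- build_subsets(keep(inp$clinvar), keep(inp$sleepvar),
                                 keep(inp$psgvar), keep(inp$biomarkers), bm,
                                 config = config$selection,
                                 seed = config$seed)
    sel <- lapply(built[[bm]]$subsets, function(s)
      list(features = s$features, k = s$pca$k,
           explained = s$pca$explained, pca_sel = s$pca$pca_sel))
    jsonlite::write_json(
      list(biomarker = bm, seed = config$seed,
           n = built[[bm]]$n,
           n_train = length(built[[bm]]$y_train),
           n_test = length(built[[bm]]$y_test), subsets = sel),
      file.path(config$out_dir, paste0("selection_", bm, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_line(config, "select: ", length(fc$kept), " subjects kept, ",
           nrow(fc$excluded), " excluded")
  invisible(built)
}

#' @rdname run_pipeline
#' @export
stage_stats <- function(config) {
  inp <- read_stage_inputs(config)
  fc <- filter_cohort(inp$manifest)
  keep <- function(d) d[d$subject_id %in% fc$kept, , drop = FALSE]
  feats <- merge(merge(keep(inp$clinvar), keep(inp$sleepvar),
                       by = "subject_id"),
                 keep(inp$psgvar), by = "subject_id")
  bio <- keep(inp$biomarkers)
  for (bm in config$biomarkers) {
    rep <- association_report(feats[, -1, drop = FALSE],
                              bio[[bm]][match(feats$subject_id,
                                              bio$subject_id)])
    write.csv(rep, file.path(config$out_dir,
                             paste0("associations_", bm, ".csv")),
              row.names = FALSE)
  }
  desc <- descriptives_table(keep(inp$clinvar)[, -1, drop = FALSE])
  write.csv(desc, file.path(config$out_dir, "descriptives.csv"),
            row.names = FALSE)
  log_line(config, "stats: association and descriptive tables written")
  invisible(NULL)
}

#' @rdname run_pipeline
#' @export
stage_train <- function(config, built = NULL) {
  if (is.null(built)) built <- stage_select(config)
  zoo <- model_zoo(seed = config$seed)
  if (!is.null(config$models)) zoo <- zoo[config$models]
  res <- evaluate_matrix(built, zoo, seed = config$seed)
  write.csv(as.data.frame(res),
            file.path(config$out_dir, "results_models.csv"),
            row.names = FALSE)
  log_line(config, "train: ", nrow(res), " result cells")
  invisible(res)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(config, results = NULL) {
  if (is.null(results))
    results <- read.csv(file.path(config$out_dir, "results_models.csv"),
                        stringsAsFactors = FALSE)
  write.csv(family_table(results),
            file.path(config$out_dir, "results_families.csv"),
            row.names = FALSE)
  for (bm in unique(results$biomarker)) {
    d <- results[results$biomarker == bm & !is.na(results$family), ]
    d$model <- factor(d$model, levels = unique(results$model))
    gg <- ggplot2::ggplot(d, ggplot2::aes(x = model, y = test_mae,
                                          fill = subset)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(title = paste("Test MAE per model -", bm), x = NULL,
                    y = "MAE (pg/ml)") +
      ggplot2::theme_minimal()
    grDevices::png(file.path(config$out_dir, paste0("mae_", bm, ".png")),
                   width = 1200, height = 600, res = 120)
    print(gg)
    grDevices::dev.off()
  }
  log_line(config, "report: family table and figures written")
  invisible(NULL)
}

write_checksums <- function(config) {
  fs <- list.files(config$out_dir, pattern = "\\.(csv|json|txt)$",
                   recursive = TRUE)
  fs <- sort(setdiff(fs, "checksums.txt"))
  md5 <- tools::md5sum(file.path(config$out_dir, fs))
  writeLines(paste(unname(md5), fs), file.path(config$out_dir,
                                               "checksums.txt"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, select, stats, train and report into one
#' reproducible run: all stage outputs land in \code{config$out_dir}, the run
#' log records the parameters in effect, and \code{checksums.txt} holds MD5
#' sums of every tabular/JSON/log artifact (figures excluded: PNG encoding is
#' library-dependent). Two runs with the same configuration and seed produce
#' byte-identical checksummed artifacts.
#'
#' @param config a \code{\link{run_config}}.
#' @return the results data frame, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "run_log.txt"))
  log_line(config, "run seed: ", config$seed)
  log_line(config, "config: ",
           as.character(jsonlite::toJSON(
             config[setdiff(names(config), c("selection", "out_dir"))],
             auto_unbox = TRUE, null = "null")))
  log_line(config, "selection: ",
           as.character(jsonlite::toJSON(unclass(config$selection),
                                         auto_unbox = TRUE)))
  stage_simulate(config)
  built <- stage_select(config)
  stage_stats(config)
  res <- stage_train(config, built)
  stage_report(config, res)
  write_checksums(config)
  invisible(res)
}
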