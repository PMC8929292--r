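#' Study configuration
#'
#' Bundles everything a full end-to-end run needs: where the cohort
#' comes from (the synthetic generator or a CSV on disk), which
#' modalities to use, the pipeline settings, the permutation budget and
#' the root seed. A run is fully reproducible from its configuration:
#' the same config and seed produce an identical report.
#'
#' @param input `"synthetic"` (default) or `"csv"`.
#' @param cohort A [cohort_config()] (synthetic input).
#' @param csv_path Path to a feature-table CSV (csv input).
#' @param modalities Modality subset used for the analysis.
#' @param pipeline A [bap_config()].
#' @param n_perm Permutations for the accuracy significance test
#'   (0 skips it).
#' @param perm_pipeline Optional [bap_config()] used only inside the
#'   permutation test (defaults to `pipeline`); permutations are
#'   typically run with `loocv_mode = "single"` since every permutation
#'   refits selection anyway and the observed statistic uses the same
#'   settings.
#' @param seed Root seed for the run.
#' @return An object of class `study_config`.
#' @export
study_config <- function(input = c("synthetic", "csv"),
                         cohort = cohort_config(),
                         csv_path = NULL,
                         modalities = c("sMRI", "fMRI", "DTI"),
                         pipeline = bap_config(),
                         n_perm = 0L,
                         perm_pipeline = NULL,
                         seed = 1L) {
  input <- match.arg(input)
  if (input == "csv" && is.null(csv_path))
    stop("csv input requires `csv_path`", call. = FALSE)
  structure(list(input = input, cohort = cohort, csv_path = csv_path,
                 modalities = modalities, pipeline = pipeline,
                 n_perm = as.integer(n_perm),
                 perm_pipeline = if (is.null(perm_pipeline)) pipeline
                                 else perm_pipeline,
                 seed = as.integer(seed)),
            class = "study_config")
}

.load_study_table <- function(config) {
  if (config$input == "synthetic") {
    cc <- config$cohort
    cc$seed <- config$seed
    generate_cohort(cc)$table
  } else {
    read_feature_table(config$csv_path)
  }
}

.band_t_tests <- function(records) {
  tests <- list()
  for (grp in c("NC", "SZ")) {
    for (band in c("youth", "middle")) {
      sub <- records[records$group == grp & records$age_band == band, ]
      key <- sprintf("ba_vs_ca_%s_%s", grp, band)
      tests[[key]] <- if (nrow(sub) >= 2L &&
                          stats::var(sub$ca) + stats::var(sub$ba_corrected) > 0)
        two_sample_t(sub$ba_corrected, sub$ca) else NULL
    }
  }
  for (band in c("youth", "middle")) {
    sz <- records$bag[records$group == "SZ" & records$age_band == band]
    nc <- records$bag[records$group == "NC" & records$age_band == band]
    key <- sprintf("bag_SZ_vs_NC_%s", band)
    tests[[key]] <- if (length(sz) >= 2L && length(nc) >= 2L)
      two_sample_t(sz, nc) else NULL
  }
  tests
}

#' Run the full brain-age trajectory study
#'
#' Executes the complete analysis in the fixed stage order: load or
#' generate the cohort, restrict to the configured modalities, estimate
#' control brain ages by LOOCV, fit the all-control model and predict
#' the patient group, fit the age-bias correction on the control
#' out-of-fold predictions and apply it to everyone, fit linear and
#' quadratic gap-versus-age trajectories in patients and compare them,
#' split all subjects into youth/middle bands at the quadratic vertex,
#' run the band-wise group comparisons, and (optionally) the
#' permutation significance test of the control accuracy.
#'
#' @param config A [study_config()].
#' @param table Optional pre-loaded feature table overriding the
#'   config's input source.
#' @return An object of class `study_report` (see the elements of the
#'   returned list); write it to disk with [write_study_report()].
#' @export
run_full_study <- function(config = study_config(), table = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- "load"
  report <- tryCatch({
    if (is.null(table)) table <- .load_study_table(config)
    table <- subset_modalities(table, config$modalities)
    nc <- table[table$group == "NC", , drop = FALSE]
    sz <- table[table$group == "SZ", , drop = FALSE]

    stage <- "nc_loocv"
    set.seed(config$seed)
    nc_loocv <- loocv_predict(nc, config$pipeline)
    acc <- accuracy(nc_loocv$ba, nc_loocv$age)

    stage <- "all_nc_model"
    set.seed(config$seed)
    model <- fit_brainage(nc, config$pipeline)
    top_weights <- rank_weights(model, 20L)

    stage <- "sz_predict"
    sz_ba <- if (nrow(sz)) predict(model, sz) else numeric(0)

    stage <- "bias_correction"
    bias <- fit_bias(nc_loocv$age, nc_loocv$ba,
                     ids = nc_loocv$subject_id)
    records <- rbind(
      prediction_records(nc_loocv$subject_id, "NC", nc_loocv$age,
                         nc_loocv$ba, bias),
      if (nrow(sz))
        prediction_records(sz$subject_id, "SZ", sz$age, sz_ba, bias))

    stage <- "trajectory"
    sz_rec <- records[records$group == "SZ", , drop = FALSE]
    traj_lin <- traj_quad <- comparison <- vertex <- NULL
    if (nrow(sz_rec) >= 4L && stats::var(sz_rec$ca) > 0) {
      traj_lin <- fit_trajectory(sz_rec$ca, sz_rec$bag, degree = 1L)
      traj_quad <- fit_trajectory(sz_rec$ca, sz_rec$bag, degree = 2L)
      comparison <- compare_trajectories(traj_lin, traj_quad)
      vertex <- trajectory_vertex(traj_quad)
    }

    stage <- "band_split"
    group_tests <- band_counts <- NULL
    if (!is.null(vertex)) {
      records <- split_by_vertex(records, vertex)
      band_counts <- as.data.frame(table(group = records$group,
                                         age_band = records$age_band))
      stage <- "group_tests"
      group_tests <- .band_t_tests(records)
    }

    stage <- "permutation"
    permutation <- NULL
    if (config$n_perm > 0L) {
      permutation <- permutation_test_mae(nc, config$perm_pipeline,
                                          n_perm = config$n_perm,
                                          seed = config$seed)
    }

    list(manifest = list(package = "bagtraj",
                         version = as.character(
                           utils::packageVersion("bagtraj")),
                         seed = config$seed,
                         modalities = config$modalities,
                         n_features = length(feature_cols(table)),
                         n_nc = nrow(nc), n_sz = nrow(sz),
                         pipeline = unclass(config$pipeline),
                         n_perm = config$n_perm),
         accuracy = acc,
         n_selected = model$selection$n_selected,
         selection_lambda = model$selection$lambda,
         top_weights = top_weights,
         bias = bias,
         trajectory = list(linear = traj_lin, quadratic = traj_quad,
                           comparison = comparison, vertex = vertex),
         band_counts = band_counts,
         group_tests = group_tests,
         permutation = permutation,
         records = records,
         model = model)
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  cohort: %d NC + %d SZ, %d features (%s)\n",
              x$manifest$n_nc, x$manifest$n_sz, x$manifest$n_features,
              paste(x$manifest$modalities, collapse = "+")))
  cat(sprintf("  NC LOOCV: r = %.3f, MAE = %.2f yr, R2 = %.3f, rMSE = %.2f yr\n",
              x$accuracy$r, x$accuracy$mae, x$accuracy$r2,
              x$accuracy$rmse))
  cat(sprintf("  selected features: %d (penalty %.4g)\n", x$n_selected,
              x$selection_lambda))
  if (!is.null(x$trajectory$vertex))
    cat(sprintf("  SZ BAG trajectory: quadratic a = %.4g, vertex = %.2f yr (preferred degree %d)\n",
                x$trajectory$quadratic$coefficients[["I(ca^2)"]],
                x$trajectory$vertex,
                x$trajectory$comparison$preferred$degree))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation test: p = %.4g (%d permutations)\n",
                x$permutation$p_value, x$permutation$n_perm))
  invisible(x)
}

#' Write a study report to a run directory
#'
#' Produces `manifest.json`, `model.json`, `predictions.csv`,
#' `tests.csv`, `report.json` and a human-readable `report.md`.
#'
#' @param report A [run_full_study()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.jsonable(report$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  serialize_to_json(report$model[c("selection", "intercept", "weights",
                                   "train_ids")],
                    file.path(dir, "model.json"))
  utils::write.csv(report$records, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  tests <- do.call(rbind, lapply(names(report$group_tests), function(k) {
    t <- report$group_tests[[k]]
    if (is.null(t)) return(NULL)
    data.frame(comparison = k, test = t$test, statistic = t$statistic,
               df = t$df, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tests))
    utils::write.csv(tests, file.path(dir, "tests.csv"),
                     row.names = FALSE)
  out <- report
  out$records <- NULL
  out$model <- NULL
  jsonlite::write_json(.jsonable(out), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  md <- c("# Brain-age trajectory study report", "",
          sprintf("- Cohort: %d NC + %d SZ, %d features (%s)",
                  report$manifest$n_nc, report$manifest$n_sz,
                  report$manifest$n_features,
                  paste(report$manifest$modalities, collapse = "+")),
          sprintf("- NC LOOCV accuracy: r = %.3f, MAE = %.2f yr, R2 = %.3f, rMSE = %.2f yr",
                  report$accuracy$r, report$accuracy$mae,
                  report$accuracy$r2, report$accuracy$rmse),
          sprintf("- Selected features: %d", report$n_selected))
  if (!is.null(report$trajectory$vertex))
    md <- c(md, sprintf("- SZ BAG trajectory vertex: %.2f yr (preferred degree %d)",
                        report$trajectory$vertex,
                        report$trajectory$comparison$preferred$degree))
  if (!is.null(report$permutation))
    md <- c(md, sprintf("- Permutation p-value: %.4g (%d permutations)",
                        report$permutation$p_value,
                        report$permutation$n_perm))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Modality-ablation accuracy comparison
#'
#' Re-runs the identical LOOCV estimation per modality subset and
#' tabulates the accuracy metrics, mirroring the comparison of
#' single-modality against multimodal prediction performance.
#'
#' @param table Full three-modality feature table (controls are used).
#' @param config A [bap_config()].
#' @param subsets List of modality subsets; defaults to the three
#'   singletons, the three pairs and the full set.
#' @param seed Seed applied before each subset run.
#' @return A data.frame with one row per subset: `subset`,
#'   `n_features`, `mae`, `r`, `r2`, `rmse`.
#' @export
ablate_modalities <- function(table, config = bap_config(),
                              subsets = NULL, seed = 1L) {
  if (is.null(subsets))
    subsets <- list("sMRI", "fMRI", "DTI",
                    c("sMRI", "fMRI"), c("sMRI", "DTI"),
                    c("fMRI", "DTI"), c("sMRI", "fMRI", "DTI"))
  if (length(subsets) == 0L)
    stop("at least one modality subset is required", call. = FALSE)
  nc <- table[table$group == "NC", , drop = FALSE]
  rows <- lapply(subsets, function(mods) {
    sub <- subset_modalities(nc, mods)
    set.seed(seed)
    pred <- loocv_predict(sub, config)
    acc <- accuracy(pred$ba, pred$age)
    data.frame(subset = paste(mods, collapse = "+"),
               n_features = length(feature_cols(sub)),
               mae = acc$mae, r = acc$r, r2 = acc$r2, rmse = acc$rmse,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
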