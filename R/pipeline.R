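# End-to-end orchestration: simulate -> extract -> FPCA -> screen -> fit ->
# validate, writing the report CSVs. Every stage draws its randomness from
# seeds derived from the single pipeline seed, so two runs with the same
# seed produce byte-identical reports.

.write_report <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

.po_fit_report <- function(fit, conf_level = 0.95) {
  or <- odds_ratios(fit, conf_level)
  J1 <- length(fit$intercepts)
  p <- length(fit$beta)
  icpt <- data.frame(feature = paste0("intercept_", seq_len(J1)),
                     coefficient = fit$intercepts,
                     ci_low_coef = NA_real_, ci_high_coef = NA_real_,
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     wald_p = unname(fit$wald_p[p + seq_len(J1)]))
  rbind(or, icpt)
}

#' Write a proportional-odds model to JSON
#'
#' @param fit a `po_fit`.
#' @param path output file.
#' @export
write_po_model <- function(fit, path) {
  jsonlite::write_json(
    list(feature_names = fit$feature_names,
         centers = as.list(fit$centers),
         beta = as.list(fit$beta),
         intercepts = fit$intercepts,
         covariance = fit$covariance,
         deviance = fit$deviance,
         levels = fit$levels, n = fit$n),
    path, digits = NA)
  invisible(path)
}

#' Run the full nodule invasiveness analysis on a synthetic cohort
#'
#' Generates a mechanistic cohort, extracts geometric/attenuation features,
#' fits the cohort FPCA and appends FPC scores, screens features at both
#' ordinal cutoffs, computes confounder-plot coordinates against the
#' reference predictor, fits the two proportional-odds models
#' (`class ~ volume_log + FPC1` and `class ~ volume_log + q875_hu`),
#' computes Monte-Carlo quartile probability changes for each predictor,
#' and cross-validates both models, writing all reports as CSV under
#' `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling every stage.
#' @param config cohort configuration; its seed is overridden by `seed`.
#' @param n_repeats Monte-Carlo CV repeats (default 200).
#' @param n_draws parameter draws for the quartile probability changes.
#' @param run_multiclass also write the one-vs-rest multiclass report?
#' @return invisibly, a list with the feature table, FPCA model, fits, CV
#'   results and written file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = cohort_config(),
                         n_repeats = 200L, n_draws = 1000L,
                         run_multiclass = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  cohort <- generate_mechanistic_cohort(config)
  features <- extract_cohort_features(cohort)
  fp <- add_fpc_scores(features, lapply(cohort, `[[`, "hu_values"))
  features <- fp$features
  paths <- character(0)
  paths["features"] <- .write_report(features, out_dir, "features.csv")
  write_fpca_model(fp$model, file.path(out_dir, "fpca_model.json"))

  paths["screening1"] <- .write_report(screen_features(features, 1L),
                                       out_dir, "screening_cutoff1.csv")
  paths["screening2"] <- .write_report(screen_features(features, 2L),
                                       out_dir, "screening_cutoff2.csv")
  paths["confounder"] <- .write_report(
    confounder_plot_data(features, reference = "volume_log"),
    out_dir, "confounder_plot.csv")

  models <- list(model1 = c("volume_log", "FPC1"),
                 model2 = c("volume_log", "q875_hu"))
  fits <- list()
  cvs <- list()
  changes <- list()
  for (i in seq_along(models)) {
    nm <- names(models)[i]
    feats <- models[[i]]
    fit <- fit_proportional_odds(features[feats], features$class)
    fits[[nm]] <- fit
    paths[paste0(nm, "_fit")] <- .write_report(.po_fit_report(fit), out_dir,
                                               paste0(nm, "_fit.csv"))
    write_po_model(fit, file.path(out_dir, paste0(nm, "_model.json")))
    for (j in seq_along(feats)) {
      ch <- quartile_probability_change(fit, features, feats[j],
                                        n_draws = n_draws,
                                        seed = seed + 100L * i + j)
      changes[[paste(nm, feats[j], sep = ".")]] <- data.frame(
        model = nm, predictor = feats[j], class = names(ch$delta),
        prob_at_q1 = unname(ch$class_probs_at_q1),
        prob_at_q3 = unname(ch$class_probs_at_q3),
        delta = unname(ch$delta),
        ci_low = unname(ch$delta_ci_low), ci_high = unname(ch$delta_ci_high),
        p_value = unname(ch$p_values))
    }
    cv <- monte_carlo_cv(features,
                         cv_config(paste("class ~", paste(feats, collapse = " + ")),
                                   n_repeats = n_repeats, seed = seed + 17L + i))
    cvs[[nm]] <- cv
    smry <- cbind(statistic = rownames(cv$summary), cv$summary)
    paths[paste0(nm, "_cv")] <- .write_report(smry, out_dir,
                                              paste0(nm, "_cv.csv"))
  }
  paths["probability_change"] <- .write_report(
    do.call(rbind, c(changes, list(make.row.names = FALSE))),
    out_dir, "probability_change.csv")
  if (run_multiclass) {
    mc <- multiclass_report(features,
                            cv_config("class ~ volume_log + q875_hu",
                                      n_repeats = n_repeats, seed = seed + 29L))
    paths["multiclass"] <- .write_report(mc, out_dir, "multiclass_report.csv")
  }
  invisible(list(features = features, fpca = fp$model, fits = fits,
                 cv = cvs, paths = paths))
}
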