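# End-to-end pipeline: simulate/ingest -> derive -> qc -> fit -> score,
# with machine-readable outputs and a plain-text report.

#' Pipeline configuration
#'
#' All stages of [run_pipeline()] are driven by one serialisable config.
#' Exactly one of `input_dir` (a directory of `animals.csv`,
#' `timeseries.csv`, `diets.csv`) or `cohort` (a [cohort_config()] to
#' simulate) must be given.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param input_dir Directory with input CSVs, or `NULL`.
#' @param cohort A [cohort_config()], or `NULL`.
#' @param lights_on,lights_off Photoperiod clock hours.
#' @param min_run_hours Short-run exclusion threshold, default 18.
#' @param spec Reference [model_spec()]; defaults to mass, temperature,
#'   activity and site on daily EE (the large-consortium model).
#' @param sex Sex scored, default `"M"`.
#' @param wt_label Wild-type genotype label.
#' @param exclude_strains Genotypes dropped before modelling.
#' @param sd_scope `"animal"` or `"strain"` (see [wt_residual_sd()]).
#' @param strict Stop with an error when any QC flag fires.
#' @param qc_params Detector parameter overrides (see [qc_report()]).
#' @param seed Seed recorded and used for any stochastic step.
#' @return A `mc_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, cohort = NULL,
                            lights_on = 6, lights_off = 18,
                            min_run_hours = 18,
                            spec = model_spec(
                              covariates = c("body_mass_g", "ambient_temp_c",
                                             "activity_pct", "site")),
                            sex = "M", wt_label = "WT",
                            exclude_strains = "Fbxl19",
                            sd_scope = "animal", strict = FALSE,
                            qc_params = list(), seed = 1) {
  if (is.null(input_dir) == is.null(cohort)) {
    stop("pipeline_config: give exactly one of input_dir or cohort",
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
                 lights_on = lights_on, lights_off = lights_off,
                 min_run_hours = min_run_hours, spec = spec, sex = sex,
                 wt_label = wt_label, exclude_strains = exclude_strains,
                 sd_scope = sd_scope, strict = strict,
                 qc_params = qc_params, seed = as.integer(seed)),
            class = "mc_pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes derive -> qc -> fit -> score on simulated or ingested data:
#' recomputes EE by Weir, removes short runs, runs every anomaly detector,
#' fits the wild-type reference model for the scored sex, decomposes
#' explained variance (LMG) and the institutional residual share, and
#' scores every strain in wild-type residual SD units. Writes
#' `derived_animals.csv`, `qc_report.json`, `models.json`,
#' `importance.csv`, `scores.csv` and `config.json` (with a config hash)
#' to `out_dir`. Identical config and inputs yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `mc_bundle` list with every stage object and the output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mc_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analytic configuration; the output location is not part of it
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])

  ## ingest / simulate
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
    data <- cohort[c("animals", "series", "diets")]
  } else {
    data <- read_cohort(config$input_dir)
  }

  ## derive
  kept <- filter_short_runs(data$series, config$min_run_hours)
  derived <- derive_animals(data$animals, kept$series, data$diets,
                            lights_on = config$lights_on,
                            lights_off = config$lights_off,
                            recompute_ee = TRUE)
  derived <- filter(derived, .data$animal_id %in% kept$series$animal_id)

  ## qc (detectors run on the pre-exclusion series so short runs are counted)
  qc <- qc_report(derived, data$series, params = c(
    config$qc_params, list(min_run_hours = config$min_run_hours)))
  if (config$strict && qc$any_flagged) {
    stop("run_pipeline: QC flagged the dataset and strict mode is set",
         call. = FALSE)
  }

  ## fit on wild-type animals of the scored sex
  wt <- derived |>
    filter(.data$genotype == config$wt_label, !is.na(.data$dee))
  if (!is.null(config$sex)) wt <- filter(wt, .data$sex == config$sex)
  model <- fit_reference(wt, config$spec,
                         scope = paste0(config$wt_label, "/",
                                        config$sex %||% "both"))
  wt_sd <- wt_residual_sd(model, scope = config$sd_scope,
                          seed = config$seed)
  regressors <- setdiff(
    intersect(config$spec$covariates, names(model$data)),
    model$dropped_terms)
  importance <- if (length(regressors) >= 2) {
    relative_importance(model$data, config$spec$response, regressors)
  } else NULL
  bio_covs <- setdiff(regressors, "site")
  inst_share <- if (length(unique(wt$site)) >= 2 && length(bio_covs) >= 1) {
    institutional_share(wt, model_spec(response = config$spec$response,
                                       covariates = bio_covs))
  } else NA_real_

  ## score strains
  scores <- score_all_strains(derived, model, wt_sd, sex = config$sex,
                              wt_label = config$wt_label,
                              exclude = config$exclude_strains)

  ## write artifacts
  paths <- list(
    derived = file.path(config$out_dir, "derived_animals.csv"),
    qc = file.path(config$out_dir, "qc_report.json"),
    models = file.path(config$out_dir, "models.json"),
    importance = file.path(config$out_dir, "importance.csv"),
    scores = file.path(config$out_dir, "scores.csv"),
    config = file.path(config$out_dir, "config.json")
  )
  d_out <- derived
  d_out$run_start <- format_ts(d_out$run_start)
  write.csv(d_out, paths$derived, row.names = FALSE, na = "")
  write_qc_report(qc, paths$qc)
  jsonlite::write_json(list(
    spec = unclass(config$spec), coefficients = model$coefficients,
    residual_sd = model$residual_sd, r_squared = model$r_squared,
    n = model$n, dropped_terms = model$dropped_terms,
    wt_residual_sd = wt_sd, sd_scope = config$sd_scope,
    institutional_share = inst_share, config_hash = cfg_hash
  ), paths$models, dataframe = "rows", digits = NA, auto_unbox = TRUE,
    na = "null")
  if (!is.null(importance)) {
    imp_out <- as.data.frame(importance)
    imp_out$total_r2 <- attr(importance, "total_r2")
    write.csv(imp_out, paths$importance, row.names = FALSE, na = "")
  }
  if (nrow(scores) > 0) {
    write.csv(scores, paths$scores, row.names = FALSE, na = "")
  }
  jsonlite::write_json(list(config = serialize_config(config),
                            hash = cfg_hash),
                       paths$config, digits = NA, auto_unbox = TRUE,
                       na = "null")

  invisible(structure(list(
    derived = derived, qc = qc, model = model, wt_sd = wt_sd,
    importance = importance, institutional_share = inst_share,
    scores = scores, config = config, config_hash = cfg_hash,
    paths = paths
  ), class = "mc_bundle"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten the config (and any nested cohort config) to JSON-safe values
serialize_config <- function(config) {
  drop_class <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_class) else x
  }
  drop_class(config)
}

#' Render a plain-text report of a pipeline run
#'
#' Summarises the reference-model coefficients, variance decomposition, QC
#' flags, and the strains with the largest |SD-unit| phenotypes into a
#' markdown document. With `plots = TRUE` and ggplot2 installed, also saves
#' an EE-vs-mass regression plot and a residual histogram next to the
#' report. A partial bundle produces a partial report with warnings.
#'
#' @param bundle A `mc_bundle` from [run_pipeline()].
#' @param path Output file, default `report.md` in the bundle's out_dir.
#' @param plots Also render figures, default FALSE.
#' @param top_n Number of top-scoring strains to list, default 10.
#' @return The report path, invisibly.
#' @export
report <- function(bundle, path = NULL, plots = FALSE, top_n = 10) {
  stopifnot(inherits(bundle, "mc_bundle"))
  path <- path %||% file.path(bundle$config$out_dir, "report.md")
  lines <- c("# Calorimetry pipeline report", "",
             sprintf("Config hash: `%s`", bundle$config_hash), "")

  if (!is.null(bundle$model)) {
    m <- bundle$model
    lines <- c(lines, "## Wild-type reference model", "",
               sprintf("n = %d, R^2 = %.3f, residual SD = %.3f kJ/hr, WT SD unit = %.3f kJ/hr",
                       m$n, m$r_squared, m$residual_sd, bundle$wt_sd), "",
               md_table(mutate(m$coefficients,
                               estimate = signif(.data$estimate, 4),
                               se = signif(.data$se, 3))), "")
  } else {
    warning("report: bundle has no fitted model", call. = FALSE)
  }

  if (!is.null(bundle$importance)) {
    imp <- mutate(as_tibble(bundle$importance),
                  share = signif(.data$share, 4),
                  share_normalized = signif(.data$share_normalized, 4))
    lines <- c(lines, "## Variance decomposition (LMG)", "",
               md_table(imp),
               sprintf("\nTotal R^2 = %.3f; institutional share of residual variation = %s",
                       attr(bundle$importance, "total_r2"),
                       if (is.na(bundle$institutional_share)) "n/a"
                       else sprintf("%.1f%%",
                                    100 * bundle$institutional_share)), "")
  }

  if (!is.null(bundle$qc)) {
    q <- bundle$qc
    flags <- c(
      sprintf("inverse mass effect: %s",
              paste0(q$inverse_mass$site[which(q$inverse_mass$flagged)],
                     collapse = ", ") %of% "none"),
      sprintf("constant intake: %s",
              paste0(q$constant_intake$site[which(q$constant_intake$flagged)],
                     collapse = ", ") %of% "none"),
      sprintf("non-Weir EE formula: %s",
              paste0(q$ee_formula$site[q$ee_formula$formula != "weir"],
                     collapse = ", ") %of% "none"),
      sprintf("short runs removed: %d", q$short_runs_removed))
    lines <- c(lines, "## QC", "", paste0("- ", flags), "")
  }

  if (!is.null(bundle$scores) && nrow(bundle$scores) > 0) {
    top <- head(bundle$scores, top_n) |>
      mutate(across(where(is.numeric), ~ signif(.x, 4)))
    lines <- c(lines, sprintf("## Top %d strains by |SD units|",
                              min(top_n, nrow(bundle$scores))), "",
               md_table(top), "")
  }

  if (plots && requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(bundle$model)) {
    gg <- ggplot2::ggplot(bundle$model$data,
                          ggplot2::aes(x = .data$body_mass_g, y = .data$dee,
                                       colour = .data$site)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "Body mass (g)", y = "DEE (kJ/hr)")
    fig1 <- file.path(dirname(path), "ee_vs_mass.png")
    ggplot2::ggsave(fig1, gg, width = 6, height = 4, dpi = 120)
    hh <- ggplot2::ggplot(data.frame(res = resid(bundle$model$fit)),
                          ggplot2::aes(x = .data$res)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "Residual EE (kJ/hr)")
    fig2 <- file.path(dirname(path), "residual_hist.png")
    ggplot2::ggsave(fig2, hh, width = 6, height = 4, dpi = 120)
    lines <- c(lines, "## Figures", "",
               sprintf("![EE vs mass](%s)", basename(fig1)),
               sprintf("![Residuals](%s)", basename(fig2)), "")
  }

  writeLines(lines, path)
  invisible(path)
}

`%of%` <- function(a, b) if (nzchar(a)) a else b

# minimal markdown table renderer
md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  paste(c(header, sep, body), collapse = "\n")
}
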