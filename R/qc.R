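# Detectors for the dataset anomalies documented in large multi-site
# calorimetry depositions, plus transient-outlier removal and the
# energy-balance/weight-change consistency check. Every detector is a pure
# function of its inputs.

#' Detect an inverse mass effect per site
#'
#' A site where larger animals apparently expend less energy indicates a
#' broken analysis pipeline upstream. Flags a site when the OLS slope of EE
#' (DEE) on body mass is negative with p < 0.05. Sites with fewer than
#' `min_n` usable animals are untestable (`NA` flag), not passes.
#'
#' @param animals Derived animal table with `site`, `body_mass_g` and the
#'   response column.
#' @param response Response column, default `"dee"`.
#' @param min_n Minimum animals per site to test, default 10.
#' @param alpha Significance level, default 0.05.
#' @return Tibble with `site`, `n`, `slope`, `p`, `flagged` (logical, `NA`
#'   when untestable).
#' @export
detect_inverse_mass_effect <- function(animals, response = "dee",
                                       min_n = 10, alpha = 0.05) {
  animals |>
    filter(!is.na(.data[[response]]), !is.na(.data$body_mass_g)) |>
    group_by(site = .data$site) |>
    group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        return(tibble(n = nrow(d), slope = NA_real_, p = NA_real_,
                      flagged = NA))
      }
      fit <- summary(lm(d[[response]] ~ d$body_mass_g))$coefficients
      slope <- fit[2, 1]; p <- fit[2, 4]
      tibble(n = nrow(d), slope = slope, p = p,
             flagged = slope < 0 && p < alpha)
    }) |>
    ungroup()
}

#' Detect site-wide constant food-intake records
#'
#' One deposited site reported every animal eating exactly 0.05 g of food
#' per hour. Flags a site when more than `threshold` of its animals have
#' zero within-animal variance in hourly intake. Individual flatlining
#' animals are tolerated; the documented anomaly was site-wide.
#'
#' @param series Hourly series with `animal_id` and `food_g`.
#' @param animals Animal table mapping `animal_id` to `site`.
#' @param threshold Fraction of constant-intake animals above which the
#'   site is flagged, default 0.5.
#' @return Tibble with `site`, `n_animals`, `frac_constant`, `flagged`
#'   (`NA` when food is entirely missing at the site).
#' @export
detect_constant_intake <- function(series, animals, threshold = 0.5) {
  series |>
    inner_join(select(animals, "animal_id", "site"), by = "animal_id") |>
    group_by(.data$site, .data$animal_id) |>
    summarise(const = if (all(is.na(.data$food_g))) NA
              else var(.data$food_g, na.rm = TRUE) == 0,
              .groups = "drop") |>
    group_by(site = .data$site) |>
    summarise(
      n_animals = n(),
      frac_constant = mean(.data$const, na.rm = TRUE),
      flagged = if (all(is.na(.data$const))) NA
                else mean(.data$const, na.rm = TRUE) > threshold,
      .groups = "drop"
    )
}

#' Classify which EE formula a site's reported values used
#'
#' Recomputes EE per hour with both the Weir and Lusk formulas and assigns
#' each site the formula whose median absolute relative deviation from the
#' reported EE is below `tol` (the better-matching one if both qualify);
#' otherwise `"unknown"`. Downstream, reported EE is always replaced by the
#' Weir recomputation regardless of classification.
#'
#' @param series Hourly series with `vo2_ml_hr`, `vco2_ml_hr`, `ee_kj_hr`.
#' @param animals Animal table mapping `animal_id` to `site`.
#' @param tol Median relative deviation tolerance, default 0.01 (robust to
#'   rounding in deposited data).
#' @return Tibble with `site`, `mard_weir`, `mard_lusk`, `formula`.
#' @export
classify_ee_formula <- function(series, animals, tol = 0.01) {
  need <- c("vo2_ml_hr", "vco2_ml_hr", "ee_kj_hr")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    stop("classify_ee_formula: series lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  series |>
    inner_join(select(animals, "animal_id", "site"), by = "animal_id") |>
    filter(.data$vo2_ml_hr > 0, !is.na(.data$ee_kj_hr)) |>
    mutate(
      weir = weir_ee(.data$vo2_ml_hr, .data$vco2_ml_hr),
      lusk = lusk_ee(.data$vo2_ml_hr, .data$vco2_ml_hr / .data$vo2_ml_hr)
    ) |>
    group_by(site = .data$site) |>
    summarise(
      mard_weir = median(abs(.data$ee_kj_hr - .data$weir) / .data$weir),
      mard_lusk = median(abs(.data$ee_kj_hr - .data$lusk) / .data$lusk),
      .groups = "drop"
    ) |>
    mutate(formula = case_when(
      .data$mard_weir < tol & .data$mard_weir <= .data$mard_lusk ~ "weir",
      .data$mard_lusk < tol ~ "lusk",
      .data$mard_weir < tol ~ "weir",
      TRUE ~ "unknown"
    ))
}

#' Remove runs shorter than a minimum duration
#'
#' Run duration is last minus first timestamp. Runs shorter than
#' `min_hours` (strictly) are excluded; a run of exactly `min_hours` is
#' retained. Idempotent.
#'
#' @param series Hourly series with `animal_id` and `timestamp`.
#' @param min_hours Minimum duration, default 18.
#' @return List with `series` (retained rows), `removed` (tibble of
#'   `animal_id`, `duration_h`), and `n_removed`.
#' @export
filter_short_runs <- function(series, min_hours = 18) {
  dur <- series |>
    group_by(.data$animal_id) |>
    summarise(duration_h = as.numeric(difftime(max(.data$timestamp),
                                               min(.data$timestamp),
                                               units = "hours")),
              .groups = "drop")
  bad <- dur |> filter(.data$duration_h < min_hours)
  list(series = filter(series, !.data$animal_id %in% bad$animal_id),
       removed = bad, n_removed = nrow(bad))
}

#' Remove transient EE outliers from a run
#'
#' Points recorded during momentary disturbances (e.g. cage opening) are
#' removed when their EE deviates from the median of a centred 5-point
#' window by more than `k` robust SDs, where the robust SD is 1.4826 times
#' the MAD of the window deviations over the whole run. When that MAD
#' degenerates to 0 (smooth or constant runs, where the median filter
#' reproduces most points exactly) a relative threshold of `rel_floor`
#' times the run's median level is used instead, so a constant run yields
#' no removals while isolated spikes are still caught. Removal is capped
#' at `max_frac` of points per run (largest deviations first; the cap is
#' reported).
#'
#' @param x Numeric EE series for one run (>= 12 points).
#' @param k Robust-SD multiplier, default 4.
#' @param window Window width (odd), default 5.
#' @param max_frac Removal cap as a fraction of points, default 0.05.
#' @param rel_floor Relative threshold used when the MAD degenerates,
#'   default 0.25.
#' @return List with `values` (cleaned series), `removed_idx` (indices into
#'   the input), and `cap_hit` (logical).
#' @export
remove_outliers <- function(x, k = 4, window = 5, max_frac = 0.05,
                            rel_floor = 0.25) {
  if (length(x) < 12) {
    stop("remove_outliers: need at least 12 points", call. = FALSE)
  }
  med <- runmed(x, window, endrule = "median")
  d <- x - med
  s <- mad(d)  # 1.4826 * median |d - median(d)|
  if (s > 0) {
    thr <- k * s
  } else {
    # degenerate scale: on smooth or constant runs the median filter
    # reproduces most points exactly and the MAD of deviations collapses
    # to 0. Fall back to a relative threshold: a point must deviate from
    # its window median by more than a quarter of the run's median level
    # (far beyond physiological hour-to-hour change, far below a
    # cage-opening artifact). A constant run removes nothing.
    thr <- rel_floor * median(abs(x))
  }
  if (thr <= 0) {
    return(list(values = x, removed_idx = integer(0), cap_hit = FALSE))
  }
  idx <- which(abs(d) > thr)
  cap <- floor(max_frac * length(x))
  cap_hit <- length(idx) > cap
  if (cap_hit) idx <- idx[order(abs(d[idx]), decreasing = TRUE)][seq_len(cap)]
  list(values = x[setdiff(seq_along(x), idx)], removed_idx = sort(idx),
       cap_hit = cap_hit)
}

#' Energy-balance / weight-change consistency check
#'
#' Animals in positive energy balance should gain weight. Regresses weight
#' change on per-animal energy balance; the dataset passes when the slope
#' is positive with p < 0.05 — a positive linear relationship speaks to the
#' quality of the acquired data.
#'
#' @param balance Per-animal energy balance, kJ/day.
#' @param delta_mass Per-animal body-mass change over the run, g.
#' @param min_n Minimum animals, default 10.
#' @param alpha Significance level, default 0.05.
#' @return List with `slope`, `p`, `pass` (`NA` when untestable), `n`.
#' @export
balance_weight_consistency <- function(balance, delta_mass, min_n = 10,
                                       alpha = 0.05) {
  ok <- complete.cases(balance, delta_mass)
  n <- sum(ok)
  if (n < min_n) {
    return(list(slope = NA_real_, p = NA_real_, pass = NA, n = n))
  }
  fit <- summary(lm(delta_mass[ok] ~ balance[ok]))$coefficients
  slope <- fit[2, 1]; p <- fit[2, 4]
  list(slope = slope, p = p, pass = slope > 0 && p < alpha, n = n)
}

#' Full QC report for a dataset
#'
#' Runs every site-level detector plus the balance/weight consistency
#' check and counts per-run transient outliers.
#'
#' @param animals Derived animal table (see [derive_animals()]); needs a
#'   `delta_mass_g` column for the balance check (skipped otherwise).
#' @param series Hourly series table.
#' @param params List of detector parameters overriding the defaults
#'   (`min_n`, `alpha`, `constant_intake_threshold`, `formula_tol`,
#'   `outlier_k`, `outlier_max_frac`, `min_run_hours`).
#' @return A `mc_qc_report` list with per-site flag tables, outlier counts,
#'   the balance check, the parameters used, and `any_flagged`.
#' @export
qc_report <- function(animals, series, params = list()) {
  p <- modifyList(list(min_n = 10, alpha = 0.05,
                       constant_intake_threshold = 0.5, formula_tol = 0.01,
                       outlier_k = 4, outlier_max_frac = 0.05,
                       min_run_hours = 18), params)

  short <- filter_short_runs(series, p$min_run_hours)
  inv <- detect_inverse_mass_effect(animals, min_n = p$min_n,
                                    alpha = p$alpha)
  const <- detect_constant_intake(series, animals,
                                  threshold = p$constant_intake_threshold)
  formula <- classify_ee_formula(series, animals, tol = p$formula_tol)

  outliers <- series |>
    group_by(animal_id = .data$animal_id) |>
    summarise(n_outliers = if (n() < 12) NA_integer_ else
      length(remove_outliers(.data$ee_kj_hr, k = p$outlier_k,
                             max_frac = p$outlier_max_frac)$removed_idx),
      .groups = "drop")

  balance <- if (all(c("energy_balance", "delta_mass_g") %in%
                     names(animals))) {
    balance_weight_consistency(animals$energy_balance, animals$delta_mass_g,
                               min_n = p$min_n, alpha = p$alpha)
  } else NULL

  flagged <- isTRUE(any(inv$flagged, na.rm = TRUE)) ||
    isTRUE(any(const$flagged, na.rm = TRUE)) ||
    any(formula$formula != "weir") ||
    short$n_removed > 0 ||
    (!is.null(balance) && isFALSE(balance$pass))

  structure(list(inverse_mass = inv, constant_intake = const,
                 ee_formula = formula, short_runs_removed = short$n_removed,
                 short_runs = short$removed, outliers = outliers,
                 balance = balance, params = p, any_flagged = flagged),
            class = "mc_qc_report")
}

#' Write a QC report to JSON
#'
#' @param report A `mc_qc_report` from [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "mc_qc_report"))
  jsonlite::write_json(unclass(report), path, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
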