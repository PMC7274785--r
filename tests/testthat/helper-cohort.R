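# Shared fixture builders. All cohorts are generated in code at test time.

# small 2-site cohort, defaults otherwise
small_cohort <- function(seed = 7, strains = list(), ...) {
  generate_cohort(cohort_config(n_sites = 2, animals_per_site_per_group = 12,
                                run_hours = 96, seed = seed,
                                strains = strains, ...))
}

# single-site noiseless cohort: DEE equals the linear predictor exactly
noiseless_cohort <- function(seed = 3, n = 20) {
  generate_cohort(cohort_config(
    n_sites = 1, animals_per_site_per_group = n, run_hours = 96,
    noise_sd = 0, seed = seed,
    sites = list(site_config("s1", intercept = 0.6, mass_slope = 0.03))))
}

# 4-site cohort with mid-range fixed slope: the anomaly-detection condition
anomaly_cohort <- function(seed, n_per_sex = 25, run_hours = 48) {
  sites <- lapply(1:4, function(i)
    site_config(paste0("s", i), mass_slope = 0.0325))
  generate_cohort(cohort_config(sites = sites,
                                animals_per_site_per_group = n_per_sex,
                                run_hours = run_hours, seed = seed))
}

derive_cohort <- function(cohort, ...) {
  derive_animals(cohort$animals, cohort$series, cohort$diets, ...)
}

# hourly single-animal series starting at a given clock hour
hourly_series <- function(hours, start_hour = 12, ee = 1.5,
                          start_date = "2019-03-01") {
  start <- as.POSIXct(paste(start_date, sprintf("%02d:00:00", start_hour)),
                      tz = "UTC")
  tibble::tibble(
    animal_id = "A1",
    timestamp = start + (seq_len(hours) - 1) * 3600,
    ee_kj_hr = rep_len(ee, hours)
  )
}

# brute-force LMG: average R^2 increment over all p! orderings of entry
lmg_bruteforce <- function(data, response, regressors) {
  p <- length(regressors)
  d <- data[stats::complete.cases(data[c(response, regressors)]), ]
  y <- d[[response]]
  r2_of <- function(terms) {
    if (length(terms) == 0) return(0)
    f <- stats::as.formula(paste(response, "~",
                                 paste(terms, collapse = " + ")))
    summary(stats::lm(f, data = d))$r.squared
  }
  perms <- permutations(p)
  shares <- setNames(numeric(p), regressors)
  for (i in seq_len(nrow(perms))) {
    ord <- regressors[perms[i, ]]
    for (j in seq_len(p)) {
      shares[ord[j]] <- shares[ord[j]] +
        r2_of(ord[seq_len(j)]) - r2_of(ord[seq_len(j - 1)])
    }
  }
  shares / nrow(perms)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# run the site-level anomaly detectors on a cohort
qc_flags <- function(cohort) {
  d <- derive_cohort(cohort)
  list(inverse = detect_inverse_mass_effect(d),
       const = detect_constant_intake(cohort$series, cohort$animals),
       formula = classify_ee_formula(cohort$series, cohort$animals),
       short = filter_short_runs(cohort$series)$n_removed)
}

# group p-value of a sex-contrast ANCOVA on a minimal generated cohort:
# n = 8 per group, residual SD 0.161, masses diverging by 6 g (the
# emulated diet-contrast condition), EE offset as given
sex_ancova_p <- function(seed, offset = 0, n = 8) {
  co <- generate_cohort(cohort_config(
    sites = list(site_config("s1", mass_slope = 0.03, activity_coeff = 0,
                             ambient_temp_sd = 0)),
    animals_per_site_per_group = n, run_hours = 42, seed = seed,
    sex_ee_shift = offset, sex_mass_diff = 6))
  d <- derive_cohort(co)
  ancova(d, "sex", "body_mass_g")$group_p
}
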