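# scoring model used throughout: the large-consortium covariate set
score_spec <- function() {
  model_spec(covariates = c("body_mass_g", "ambient_temp_c", "site"))
}

fit_wt_males <- function(d) {
  wt <- dplyr::filter(d, genotype == "WT", sex == "M", !is.na(dee))
  fit_reference(wt, score_spec())
}

test_that("sd bands use inclusive integer thresholds capped at 3", {
  expect_equal(sd_bands(c(0.62, -2.4, 1.0, 3.5, 0, -0.999, 2.0)),
               c(0L, 2L, 1L, 3L, 0L, 0L, 2L))
})

test_that("an injected shift scores at its magnitude in SD units", {
  co <- generate_cohort(cohort_config(
    n_sites = 2, animals_per_site_per_group = 40, run_hours = 48, seed = 19,
    strains = list(strain_effect("Shifted", 0.322, 10),
                   strain_effect("Null", 0, 10))))
  d <- derive_cohort(co)
  m <- fit_wt_males(d)
  wt_sd <- wt_residual_sd(m)
  scores <- score_all_strains(d, m, wt_sd)
  up <- scores[scores$genotype == "Shifted", ]
  nul <- scores[scores$genotype == "Null", ]
  # +0.322 kJ/hr against a ~0.161 kJ/hr unit is a ~2 SD phenotype
  expect_equal(up$sd_units, 2, tolerance = 0.35)
  expect_lt(up$p_value, 0.05)
  expect_equal(nul$sd_units, 0, tolerance = 0.45)
  expect_true(all(scores$testable))
  expect_equal(abs(up$sd_units) * wt_sd, abs(up$mean_residual_kj_hr),
               tolerance = 1e-9)
})

test_that("a -1 SD shift at n = 8 is recovered on average across seeds", {
  units <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_sites = 1, animals_per_site_per_group = 30, run_hours = 48,
      seed = s, strains = list(strain_effect("Ko", -0.161, 8))))
    d <- derive_cohort(co)
    wt <- dplyr::filter(d, genotype == "WT", sex == "M")
    m <- fit_reference(wt, model_spec(covariates = c("body_mass_g",
                                                     "ambient_temp_c")))
    score_strain(dplyr::filter(d, genotype == "Ko"), m,
                 wt_residual_sd(m))$sd_units
  }, numeric(1))
  expect_equal(mean(units), -1, tolerance = 0.5)
})

test_that("small strains are scored but flagged untestable", {
  co <- generate_cohort(cohort_config(
    n_sites = 1, animals_per_site_per_group = 30, run_hours = 48, seed = 23,
    strains = list(strain_effect("Tiny", 0.3, 3))))
  d <- derive_cohort(co)
  # a single-site scope: the constant site term is dropped automatically
  expect_warning(m <- fit_wt_males(d), "constant term: site")
  sc <- score_strain(dplyr::filter(d, genotype == "Tiny"), m,
                     wt_residual_sd(m))
  expect_false(sc$testable)
  expect_equal(sc$n, 3)
})

test_that("scoring is invariant to a consistent change of units", {
  co <- generate_cohort(cohort_config(
    n_sites = 2, animals_per_site_per_group = 25, run_hours = 48, seed = 29,
    strains = list(strain_effect("Ko", 0.25, 8))))
  d <- derive_cohort(co)
  m <- fit_wt_males(d)
  s1 <- score_all_strains(d, m, wt_residual_sd(m))
  # express energy in J/hr throughout: data and model rescale together
  d2 <- dplyr::mutate(d, dee = dee * 1000)
  m2 <- fit_wt_males(d2)
  s2 <- score_all_strains(d2, m2, wt_residual_sd(m2))
  expect_equal(s2$sd_units, s1$sd_units, tolerance = 1e-9)
  expect_equal(s2$band, s1$band)
})

test_that("bootstrap samples of the training animals centre on zero", {
  co <- generate_cohort(cohort_config(
    n_sites = 2, animals_per_site_per_group = 40, run_hours = 48, seed = 37))
  d <- derive_cohort(co)
  m <- fit_wt_males(d)
  wt_sd <- wt_residual_sd(m)
  wt <- dplyr::filter(d, genotype == "WT", sex == "M")
  set.seed(1)
  units <- vapply(1:50, function(i) {
    boot <- wt[sample(nrow(wt), replace = TRUE), ]
    score_strain(dplyr::mutate(boot, genotype = "boot"), m, wt_sd)$sd_units
  }, numeric(1))
  expect_lt(abs(mean(units)), 0.1)
})

test_that("strain-level pseudo-strain SD scales like sigma over sqrt(n)", {
  co <- generate_cohort(cohort_config(
    n_sites = 1, animals_per_site_per_group = 200, run_hours = 48,
    seed = 41))
  d <- derive_cohort(co)
  wt <- dplyr::filter(d, genotype == "WT", sex == "M")
  m <- fit_reference(wt, model_spec(covariates = c("body_mass_g",
                                                   "ambient_temp_c")))
  s_animal <- wt_residual_sd(m, scope = "animal")
  s_strain <- wt_residual_sd(m, scope = "strain", strain_size = 8, seed = 2)
  expect_equal(s_strain, s_animal / sqrt(8), tolerance = 0.35)
  expect_lt(s_strain, s_animal)
})

test_that("cross-site comparisons classify concordance", {
  # a site-independent +2 SD effect is significant and same-signed at most
  # sites in most seeds
  uni_ok <- 0
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(
      n_sites = 4, animals_per_site_per_group = 15, run_hours = 48,
      seed = s + 300, sexes = "M",
      strains = list(strain_effect("Ko", 0.322, 40))))
    d <- derive_cohort(co)
    models <- lapply(split(dplyr::filter(d, genotype == "WT"),
                           dplyr::filter(d, genotype == "WT")$site),
                     fit_reference,
                     spec = model_spec(covariates = c("body_mass_g",
                                                      "ambient_temp_c")))
    cmp <- site_residual_comparison("Ko", d, models)
    n_sig_pos <- sum(cmp$table$significant & cmp$table$diff_vs_wt > 0)
    uni_ok <- uni_ok + (n_sig_pos >= 3 && cmp$concordance == "unidirectional")
  }
  expect_gte(uni_ok, 8)
  # a site-by-strain interaction (+2 SD at one site, -2 SD at another)
  # produces a bidirectional classification
  co2 <- generate_cohort(cohort_config(
    n_sites = 4, animals_per_site_per_group = 15, run_hours = 48,
    seed = 71, sexes = "M",
    strains = list(strain_effect("KoInt", 0, 40,
                                 site_shifts = c(site_01 = 0.322,
                                                 site_02 = -0.322)))))
  d2 <- derive_cohort(co2)
  models2 <- lapply(split(dplyr::filter(d2, genotype == "WT"),
                          dplyr::filter(d2, genotype == "WT")$site),
                    fit_reference,
                    spec = model_spec(covariates = c("body_mass_g",
                                                     "ambient_temp_c")))
  cmp2 <- site_residual_comparison("KoInt", d2, models2)
  expect_equal(cmp2$concordance, "bidirectional")
  expect_error(site_residual_comparison(
    "KoInt", dplyr::filter(d2, site == "site_01"), models2), "fewer than 2")
})

test_that("interventions score through the same residual machinery", {
  co <- generate_cohort(cohort_config(
    n_sites = 2, animals_per_site_per_group = 40, run_hours = 48, seed = 43))
  d <- derive_cohort(co)
  m <- fit_wt_males(d)
  wt_sd <- wt_residual_sd(m)
  wt <- dplyr::filter(d, genotype == "WT", sex == "M")
  sham <- score_intervention(wt, m, wt_sd)
  expect_lt(abs(sham$sd_units), 0.2)
  # a +3 SD cold-exposure-like EE induction
  cold <- dplyr::mutate(wt, dee = dee + 3 * wt_sd)
  expect_equal(score_intervention(cold, m, wt_sd)$sd_units, 3,
               tolerance = 0.5)
  # shifting the temperature covariate itself is absorbed by a model that
  # includes temperature, but shows up under one that does not
  tc <- dplyr::filter(co$truth$sites, site == "site_01")$temp_coeff
  shifted <- wt |>
    dplyr::filter(site == "site_01") |>
    dplyr::mutate(ambient_temp_c = ambient_temp_c - 3,
                  dee = dee + tc * (-3))
  with_temp <- score_intervention(shifted, m, wt_sd)
  # residual only reflects the temperature-coefficient estimation error
  expect_lt(abs(with_temp$sd_units), 0.6)
  m_no_temp <- fit_reference(dplyr::filter(d, genotype == "WT", sex == "M"),
                             model_spec(covariates = c("body_mass_g",
                                                       "site")))
  no_temp <- score_intervention(shifted, m_no_temp,
                                wt_residual_sd(m_no_temp))
  expect_gt(no_temp$sd_units, 1)
  expect_error(score_intervention(dplyr::select(wt, -body_mass_g), m, wt_sd),
               "body_mass_g")
})
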