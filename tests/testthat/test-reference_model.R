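test_that("a zero-noise fit reproduces the generating coefficients exactly", {
  co <- noiseless_cohort()
  d <- derive_cohort(co)
  # the perfect-fit warning from summary.lm is the expected zero-noise case
  m <- suppressWarnings(
    fit_reference(d, model_spec(covariates = c("body_mass_g",
                                               "ambient_temp_c",
                                               "activity_pct", "sex"))))
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  tr <- co$truth$sites
  expect_equal(est[["body_mass_g"]], 0.03, tolerance = 1e-8)
  expect_equal(est[["ambient_temp_c"]], tr$temp_coeff[1], tolerance = 1e-8)
  expect_equal(est[["activity_pct"]], tr$activity_coeff[1], tolerance = 1e-8)
  expect_equal(est[["sexM"]], co$truth$sex_ee_shift, tolerance = 1e-8)
  expect_equal(est[["(Intercept)"]], 0.6 - 22 * tr$temp_coeff[1],
               tolerance = 1e-8)
  expect_gt(m$r_squared, 0.999)
  # prediction + residual reproduces the observed response
  expect_equal(predict(m, d) + resid(m$fit), d$dee, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fits recover coefficients within 3 SE and ignore row order", {
  co <- generate_cohort(cohort_config(
    sites = list(site_config("s1", intercept = 0.7, mass_slope = 0.03)),
    animals_per_site_per_group = 250, run_hours = 48, seed = 77))
  d <- derive_cohort(co)
  m <- fit_reference(d, model_spec(covariates = c("body_mass_g",
                                                  "ambient_temp_c",
                                                  "activity_pct", "sex")))
  tr <- co$truth$sites
  truth <- c(`(Intercept)` = 0.7 - 22 * tr$temp_coeff[1],
             body_mass_g = 0.03, ambient_temp_c = tr$temp_coeff[1],
             activity_pct = tr$activity_coeff[1],
             sexM = co$truth$sex_ee_shift)
  cf <- m$coefficients
  z <- abs(cf$estimate[match(names(truth), cf$term)] - truth) /
    cf$se[match(names(truth), cf$term)]
  expect_true(all(z < 3))
  # permutation invariance
  set.seed(1)
  m2 <- fit_reference(d[sample(nrow(d)), ], m$spec)
  expect_equal(m2$coefficients$estimate, cf$estimate, tolerance = 1e-10)
})

test_that("terms without data are dropped with a warning, fit proceeds", {
  co <- generate_cohort(cohort_config(
    sites = list(site_config("s1", records_activity = FALSE)),
    animals_per_site_per_group = 30, run_hours = 48, seed = 5))
  d <- derive_cohort(co)
  expect_warning(
    m <- fit_reference(d, model_spec(covariates = c("body_mass_g",
                                                    "activity_pct"))),
    "activity_pct")
  expect_equal(m$dropped_terms, "activity_pct")
  expect_false("activity_pct" %in% m$coefficients$term)
})

test_that("a singular design raises an error naming the collinear term", {
  d <- tibble::tibble(dee = rnorm(30), body_mass_g = rnorm(30, 27))
  d$lean_mass_g <- d$body_mass_g  # exact copy
  expect_error(fit_reference(d, model_spec(covariates = c("body_mass_g",
                                                          "lean_mass_g"))),
               "lean_mass_g")
})

test_that("ancova separates intercept shifts from slope differences", {
  mk <- function(n, slope, offset, group, mass_mu = 27, seed_shift = 0) {
    mass <- rnorm(n, mass_mu, 3)
    tibble::tibble(genotype = group, body_mass_g = mass,
                   dee = 0.8 + slope * mass + offset + rnorm(n, 0, 0.161))
  }
  # parallel groups offset by 0.4 kJ/hr: group effect without interaction
  hits_group <- 0; hits_int <- 0
  for (s in 1:20) {
    set.seed(s)
    d <- dplyr::bind_rows(mk(100, 0.03, 0, "a"), mk(100, 0.03, 0.4, "b"))
    res <- ancova(d, "genotype", "body_mass_g")
    hits_group <- hits_group + (res$group_p < 0.05)
    hits_int <- hits_int + (res$interaction_p > 0.05)
  }
  expect_gte(hits_group, 18)
  expect_gte(hits_int, 18)
  # genuinely different slopes flip the interaction test
  set.seed(99)
  d2 <- dplyr::bind_rows(mk(200, 0.02, 0, "a"), mk(200, 0.05, 0, "b"))
  res2 <- ancova(d2, "genotype", "body_mass_g")
  expect_lt(res2$interaction_p, 0.05)
  expect_equal(res2$slopes$slope, c(0.02, 0.05), tolerance = 0.3)
  # errors
  expect_error(ancova(mk(30, 0.03, 0, "only"), "genotype", "body_mass_g"),
               "two groups")
  tiny <- dplyr::bind_rows(mk(30, 0.03, 0, "a"), mk(2, 0.03, 0, "b"))
  expect_error(ancova(tiny, "genotype", "body_mass_g"), "n >= 3")
})

test_that("pairwise slope tests separate the printed slope extremes", {
  set.seed(4)
  mk <- function(n, slope, site) {
    mass <- rnorm(n, 27, 3)
    tibble::tibble(site = site, body_mass_g = mass,
                   dee = 0.8 + slope * mass + rnorm(n, 0, 0.161))
  }
  d <- dplyr::bind_rows(mk(240, 0.0118, "lo"), mk(240, 0.0532, "hi"))
  out <- compare_slopes_pairwise(d)
  expect_lt(out$p, 0.001)
  expect_equal(out$slope_b - out$slope_a, 0.0532 - 0.0118, tolerance = 0.5)
  expect_error(compare_slopes_pairwise(mk(50, 0.03, "solo")), "two sites")
  # under one common generating slope, unadjusted significance stays near
  # the nominal rate and Holm adjustment prunes it further
  hits <- 0; total <- 0; hits_holm <- 0
  for (s in 1:15) {
    set.seed(s + 100)
    d0 <- dplyr::bind_rows(lapply(paste0("s", 1:4),
                                  function(id) mk(60, 0.03, id)))
    o <- compare_slopes_pairwise(d0)
    hits <- hits + sum(o$p < 0.05); hits_holm <- hits_holm + sum(o$p_holm < 0.05)
    total <- total + nrow(o)
  }
  expect_lt(hits / total, 0.12)
  expect_lte(hits_holm, hits)
})

test_that("mass quartile binning is right-open with a closed last interval", {
  set.seed(6)
  d <- tibble::tibble(
    body_mass_g = c(20.75, 14.0, 41.0, 27.49, 34.25, rnorm(200, 27, 5)),
    dee = NA_real_)
  d$dee <- 0.8 + 0.03 * d$body_mass_g + rnorm(nrow(d), 0, 0.161)
  suppressWarnings(res <- mass_quartile_ancova(d))
  expect_s3_class(res, "mc_ancova")
  # boundary animals: 20.75 -> medium, 34.25 -> largest, 41.0 (last) kept
  bins <- findInterval(c(20.75, 14.0, 41.0, 27.49, 34.25),
                       c(14, 20.75, 27.5, 34.25, 41), rightmost.closed = TRUE)
  expect_equal(bins, c(2, 1, 4, 2, 4))
  # constant generating slope: no slope heterogeneity most of the time
  flat <- 0
  for (s in 1:20) {
    set.seed(s + 50)
    dd <- tibble::tibble(body_mass_g = runif(400, 14.5, 40.5))
    dd$lean_mass_g <- 0.75 * dd$body_mass_g
    dd$dee <- 0.8 + 0.04 * dd$lean_mass_g + rnorm(400, 0, 0.161)
    r <- suppressWarnings(
      mass_quartile_ancova(dd, covariate = "lean_mass_g"))
    flat <- flat + (r$interaction_p > 0.05)
  }
  expect_gte(flat, 18)
  # fat fraction rising with mass flattens the total-mass slope in heavy bins
  set.seed(11)
  mass <- runif(600, 14.5, 40.5)
  lf <- 0.9 - 0.012 * (mass - 14)          # lean fraction falls with mass
  lean <- lf * mass
  dd2 <- tibble::tibble(body_mass_g = mass, lean_mass_g = lean,
                        dee = 0.4 + 0.055 * lean + rnorm(600, 0, 0.161))
  r2 <- suppressWarnings(mass_quartile_ancova(dd2))
  expect_lt(r2$interaction_p, 0.05)
  s_small <- r2$slopes$slope[r2$slopes$group == "small"]
  s_large <- r2$slopes$slope[r2$slopes$group == "large"]
  expect_lt(s_large, s_small)
})

test_that("LMG shares match factorial enumeration and sum to R-squared", {
  set.seed(10)
  n <- 120
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(matrix(c(1, .6, .3,
                                                    .6, 1, .5,
                                                    .3, .5, 1), 3))
  d <- tibble::tibble(x1 = z[, 1], x2 = z[, 2], x3 = z[, 3],
                      f = sample(letters[1:3], n, TRUE))
  d$y <- 1 + 0.8 * d$x1 - 0.5 * d$x2 + 0.2 * d$x3 +
    c(a = 0, b = 0.4, c = -0.3)[d$f] + rnorm(n)
  regs <- c("x1", "x2", "x3", "f")
  imp <- relative_importance(d, "y", regs)
  oracle <- lmg_bruteforce(d, "y", regs)
  expect_equal(imp$share, unname(oracle[imp$term]), tolerance = 1e-10)
  r2 <- summary(lm(y ~ x1 + x2 + x3 + f, data = d))$r.squared
  expect_equal(sum(imp$share), r2, tolerance = 1e-9)
  expect_true(all(imp$share >= 0))
  expect_equal(attr(imp, "unexplained"), 1 - r2)
  # invariance under regressor reordering
  imp_rev <- relative_importance(d, "y", rev(regs))
  expect_equal(imp_rev$share[match(imp$term, imp_rev$term)], imp$share,
               tolerance = 1e-12)
})

test_that("LMG limiting cases: single regressor and orthogonal regressors", {
  set.seed(12)
  n <- 400
  x1 <- rnorm(n)
  x2 <- resid(lm(rnorm(n) ~ x1))  # exactly orthogonal in-sample
  y <- x1 + 0.8 * x2 + rnorm(n, 0, 1.2)
  one <- relative_importance(tibble::tibble(y = y, x1 = x1), "y", "x1")
  expect_equal(one$share, summary(lm(y ~ x1))$r.squared, tolerance = 1e-12)
  both <- relative_importance(tibble::tibble(y = y, x1 = x1, x2 = x2),
                              "y", c("x1", "x2"))
  marg1 <- summary(lm(y ~ x1))$r.squared
  marg2 <- summary(lm(y ~ x2))$r.squared
  expect_equal(both$share, c(marg1, marg2), tolerance = 1e-6)
  expect_error(relative_importance(tibble::tibble(y = y), "y",
                                   character(0)), ">= 1")
  wide <- as.data.frame(matrix(rnorm(20 * 13), 20))
  wide$y <- rnorm(20)
  expect_error(relative_importance(wide, "y", paste0("V", 1:13)),
               "unsupported")
})

test_that("institutional share recovers injected site spread and nulls", {
  sites_eq <- lapply(1:3, function(i)
    site_config(paste0("s", i), intercept = 0.7, mass_slope = 0.03))
  spec_bio <- model_spec(covariates = c("body_mass_g", "ambient_temp_c",
                                        "activity_pct", "sex"))
  low <- 0
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(sites = sites_eq,
                                        animals_per_site_per_group = 25,
                                        run_hours = 48, seed = s))
    d <- derive_cohort(co)
    low <- low + (institutional_share(d, spec_bio) < 0.02)
  }
  expect_gte(low, 4)
  # with site in the model the residuals are orthogonal to site
  co <- generate_cohort(cohort_config(n_sites = 3,
                                      animals_per_site_per_group = 25,
                                      run_hours = 48, seed = 8))
  d <- derive_cohort(co)
  spec_site <- model_spec(covariates = c("body_mass_g", "ambient_temp_c",
                                         "activity_pct", "sex", "site"))
  expect_lt(institutional_share(d, spec_site), 1e-10)
  expect_warning(
    s1 <- institutional_share(dplyr::filter(d, site == "site_01"), spec_bio),
    "single site")
  expect_equal(s1, 0)
})

test_that("fat-mass contribution follows the stated share formula", {
  set.seed(14)
  n <- 200
  mk <- function(bl, bf, site) {
    lean <- rnorm(n, 21, 2); fat <- rnorm(n, 6, 1.5)
    tibble::tibble(site = site, lean_mass_g = lean, fat_mass_g = fat,
                   dee = 0.5 + bl * lean + bf * fat + rnorm(n, 0, 0.05))
  }
  # beta_fat = 0: contribution ~ 0
  out0 <- fat_mass_contribution(mk(0.05, 0, "z"), include_activity = FALSE)
  expect_equal(out0$contribution_pct, 0, tolerance = 3)
  # balanced products: lean 21 * 0.04 = 0.84 = fat 6 * 0.14 -> 50%
  out50 <- fat_mass_contribution(mk(0.04, 0.14, "b"),
                                 include_activity = FALSE)
  expect_equal(out50$contribution_pct, 50, tolerance = 3)
  # negative fat coefficient propagates a negative percentage
  outneg <- fat_mass_contribution(mk(0.05, -0.05, "n"),
                                  include_activity = FALSE)
  expect_lt(outneg$contribution_pct, 0)
  expect_error(fat_mass_contribution(tibble::tibble(site = "x", dee = 1)),
               "lean_mass_g")
})

test_that("q-q slopes estimate per-sex SDs and their ratio", {
  set.seed(15)
  same <- tibble::tibble(sex = rep(c("M", "F"), each = 1000),
                         dee = rnorm(2000, 2, 0.3))
  r1 <- sex_variance_qq(same)
  expect_gt(r1$ratio, 0.9); expect_lt(r1$ratio, 1.1)
  # male SD set to twice female
  twice <- tibble::tibble(sex = rep(c("M", "F"), each = 1000),
                          dee = c(rnorm(1000, 2, 0.4), rnorm(1000, 2, 0.2)))
  r2 <- sex_variance_qq(twice)
  expect_equal(r2$ratio, 2, tolerance = 0.1)
  # the q-q slope agrees with the moment estimator of the SD
  x <- rnorm(2000, 0, 0.25)
  d <- tibble::tibble(sex = rep(c("M", "F"), each = 2000),
                      dee = c(x, rnorm(2000)))
  expect_equal(sex_variance_qq(d)$slopes[["M"]], sd(x), tolerance = 0.02)
  expect_error(sex_variance_qq(tibble::tibble(sex = "M", dee = rnorm(50))),
               "both sexes")
})
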