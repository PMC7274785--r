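# Seeded synthetic-cohort generator emulating the statistical structure of
# multi-site mouse calorimetry consortium data: site-specific intercepts and
# EE-vs-mass slopes, a negative ambient-temperature effect, a positive
# locomotor-activity effect, 12:12 circadian structure in EE/intake/activity/
# RER, additive strain-level EE shifts, and injectable data anomalies.

# Printed range of per-site EE-vs-mass slopes (kJ/hr per g) from which
# site slopes are drawn when not specified.
MASS_SLOPE_RANGE <- c(0.0118, 0.0532)

#' Site configuration for the synthetic generator
#'
#' Describes one institutional site: its wild-type reference-model
#' coefficients and the distributions of animal covariates housed there.
#' `intercept` and `mass_slope` left `NULL` are drawn at generation time
#' (the slope uniformly within the 1.18-5.32e-2 kJ/hr/g range observed
#' across real sites). If `lean_slope` and `fat_slope` are both given they
#' replace the total-mass term with a body-composition term
#' `lean_slope * lean + fat_slope * fat`.
#'
#' @param site_id Site label.
#' @param intercept Site intercept, kJ/hr (`NULL` = drawn).
#' @param mass_slope EE-vs-mass slope, kJ/hr per g (`NULL` = drawn).
#' @param temp_coeff Ambient-temperature coefficient, kJ/hr per deg C
#'   (non-positive by default: warmer housing lowers EE).
#' @param activity_coeff Activity coefficient, kJ/hr per activity percent.
#' @param ambient_temp_mean,ambient_temp_sd Housing temperature distribution,
#'   deg C.
#' @param mass_mean,mass_sd Body-mass distribution, g.
#' @param lean_fraction_mean Mean lean fraction of body mass, in (0, 1\].
#' @param lean_slope,fat_slope Optional composition coefficients, kJ/hr per g.
#' @param records_activity,records_temperature Whether the site reports beam
#'   breaks / ambient temperature (unreported covariates are emitted as
#'   missing, mirroring uneven site reporting).
#' @return A `mc_site_config` list.
#' @export
site_config <- function(site_id, intercept = NULL, mass_slope = NULL,
                        temp_coeff = -0.07, activity_coeff = 0.008,
                        ambient_temp_mean = 22, ambient_temp_sd = 0.6,
                        mass_mean = 27, mass_sd = 3,
                        lean_fraction_mean = 0.75,
                        lean_slope = NULL, fat_slope = NULL,
                        records_activity = TRUE, records_temperature = TRUE) {
  stopifnot(mass_sd >= 0, lean_fraction_mean > 0, lean_fraction_mean <= 1,
            ambient_temp_sd >= 0)
  if (!is.null(temp_coeff) && temp_coeff > 0) {
    warning("site_config: temp_coeff is positive; warmer housing usually lowers EE")
  }
  structure(list(
    site_id = as.character(site_id), intercept = intercept,
    mass_slope = mass_slope, temp_coeff = temp_coeff,
    activity_coeff = activity_coeff, ambient_temp_mean = ambient_temp_mean,
    ambient_temp_sd = ambient_temp_sd, mass_mean = mass_mean,
    mass_sd = mass_sd, lean_fraction_mean = lean_fraction_mean,
    lean_slope = lean_slope, fat_slope = fat_slope,
    records_activity = isTRUE(records_activity),
    records_temperature = isTRUE(records_temperature)
  ), class = "mc_site_config")
}

#' Strain effect for the synthetic generator
#'
#' An additive shift of a knockout strain's mean EE relative to the local
#' wild-type prediction, in kJ/hr (multiply a target in SD units by the
#' wild-type residual SD, 0.161 kJ/hr under defaults). Effects are
#' site-independent unless `site_shifts` supplies per-site overrides
#' (site-by-strain interaction).
#'
#' @param genotype Strain label.
#' @param ee_shift Additive EE shift, kJ/hr.
#' @param n_animals Number of animals (>= 1).
#' @param sex Sex of the strain's animals (consortium scoring defaults to
#'   males).
#' @param site Optional single site hosting every animal of the strain;
#'   `NULL` assigns each animal to a site uniformly at random.
#' @param site_shifts Optional named numeric vector of per-site shifts
#'   (kJ/hr) overriding `ee_shift` at those sites.
#' @return A `mc_strain_effect` list.
#' @export
strain_effect <- function(genotype, ee_shift, n_animals, sex = "M",
                          site = NULL, site_shifts = NULL) {
  stopifnot(n_animals >= 1)
  structure(list(genotype = as.character(genotype), ee_shift = ee_shift,
                 n_animals = as.integer(n_animals), sex = sex,
                 site = site, site_shifts = site_shifts),
            class = "mc_strain_effect")
}

#' Cohort configuration for the synthetic generator
#'
#' Defines the study conditions of a simulated multi-site calorimetry
#' cohort. The defaults emulate a consortium arm: four sites with drawn
#' intercepts and mass slopes, 25 wild-type animals per sex per site, 96-h
#' runs starting at noon under a 06:00/18:00 photoperiod, and a per-animal
#' residual EE standard deviation of 0.161 kJ/hr.
#'
#' @param n_sites Number of sites (ignored when `sites` is given).
#' @param animals_per_site_per_group Wild-type animals per site per sex.
#' @param sites Optional list of [site_config()]s.
#' @param strains List of [strain_effect()]s.
#' @param run_hours Run length in hours (one sample per hour).
#' @param lights_on,lights_off Photoperiod clock hours.
#' @param noise_sd Per-animal residual EE SD, kJ/hr.
#' @param seed Integer seed; fully determines the output.
#' @param sexes Sexes generated for wild-type animals.
#' @param sex_ee_shift Additive EE shift for males, kJ/hr.
#' @param sex_mass_diff Male-minus-female body-mass difference, g.
#' @param diet_id Diet fed to all animals (see [mousecal_diets()]).
#' @param run_start_hour Clock hour at which recordings start.
#' @param dark_ee_amplitude Fractional EE elevation in the dark phase.
#' @param dark_activity_ratio Dark:light ratio of mean beam breaks.
#' @param dark_food_share Fraction of daily intake eaten in the dark phase.
#' @param rer_light,rer_dark Hourly RER by photoperiod (carbohydrate diets
#'   push dark-phase RER up).
#' @param food_noise_cv Coefficient of variation of hourly intake noise.
#' @param balance_sd SD of per-animal daily energy balance, kJ/day.
#' @param tissue_kj_per_g Energy density of gained/lost tissue used to
#'   couple energy balance to weight change, kJ/g.
#' @param mass_change_noise_sd SD of measurement noise on weight change, g.
#' @param activity_mean,activity_sd Per-animal mean activity level
#'   distribution (arbitrary counts scale; analysis normalises per site).
#' @return A `mc_cohort_config` list.
#' @export
cohort_config <- function(n_sites = 4, animals_per_site_per_group = 25,
                          sites = NULL, strains = list(),
                          run_hours = 96, lights_on = 6, lights_off = 18,
                          noise_sd = 0.161, seed = 1,
                          sexes = c("M", "F"), sex_ee_shift = 0.25,
                          sex_mass_diff = 4, diet_id = "D12450B",
                          run_start_hour = 12,
                          dark_ee_amplitude = 0.3, dark_activity_ratio = 2.5,
                          dark_food_share = 0.65,
                          rer_light = 0.80, rer_dark = 0.95,
                          food_noise_cv = 0.15, balance_sd = 2,
                          tissue_kj_per_g = 32, mass_change_noise_sd = 0.05,
                          activity_mean = 30, activity_sd = 8) {
  if (!is.null(sites)) n_sites <- length(sites)
  stopifnot(n_sites >= 1, animals_per_site_per_group >= 1, run_hours > 0,
            noise_sd >= 0, length(seed) == 1, is.finite(seed))
  if (lights_on < 0 || lights_on >= 24 || lights_off < 0 || lights_off >= 24 ||
      isTRUE(all.equal(lights_on, lights_off))) {
    stop("cohort_config: invalid lights_on/lights_off clock times",
         call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites),
    animals_per_site_per_group = as.integer(animals_per_site_per_group),
    sites = sites, strains = strains, run_hours = as.integer(run_hours),
    lights_on = lights_on, lights_off = lights_off, noise_sd = noise_sd,
    seed = as.integer(seed), sexes = sexes, sex_ee_shift = sex_ee_shift,
    sex_mass_diff = sex_mass_diff, diet_id = diet_id,
    run_start_hour = run_start_hour, dark_ee_amplitude = dark_ee_amplitude,
    dark_activity_ratio = dark_activity_ratio,
    dark_food_share = dark_food_share, rer_light = rer_light,
    rer_dark = rer_dark, food_noise_cv = food_noise_cv,
    balance_sd = balance_sd, tissue_kj_per_g = tissue_kj_per_g,
    mass_change_noise_sd = mass_change_noise_sd,
    activity_mean = activity_mean, activity_sd = activity_sd
  ), class = "mc_cohort_config")
}

#' Built-in diet table
#'
#' The two purified research diets used by the emulated experiments:
#' D12450B (LFD, 10% of energy from fat, 15.69 kJ/g) and D12452 (HFD, 60%
#' of energy from fat, 21.92 kJ/g).
#'
#' @return A tibble with columns `diet_id`, `name`, `energy_density_kj_g`,
#'   `fat_energy_fraction`.
#' @export
mousecal_diets <- function() {
  tibble(
    diet_id = c("D12450B", "D12452"),
    name = c("low-fat diet", "high-fat diet"),
    energy_density_kj_g = c(15.69, 21.92),
    fat_energy_fraction = c(0.10, 0.60)
  )
}

#' Generate a synthetic multi-site calorimetry cohort
#'
#' Draws animals and hourly gas-exchange/intake/activity series under the
#' generative model: each animal's true 24-h mean EE is
#' `intercept + mass_slope * mass + temp_coeff * (T - 22) +
#' activity_coeff * activity_pct + sex_shift + strain_shift + N(0, noise_sd)`.
#' Hourly EE follows a 24-h-periodic circadian profile (dark-phase step plus
#' a cosine) whose mean over any complete 24-h block equals the animal's
#' mean exactly; VO2/VCO2 are back-solved from hourly EE and an hourly RER
#' schedule so the Weir formula reproduces the EE series exactly. Food
#' intake is dark-dominant and scaled so each animal's daily energy balance
#' is a draw around zero; weight change is coupled to that balance.
#'
#' Activity enters the truth as the same site-normalised percent the
#' analysis derives (the generator simulates beam breaks first, normalises
#' by the realised site maximum over post-acclimation blocks, then computes
#' EE), so refits recover `activity_coeff` without attenuation.
#'
#' @param config A [cohort_config()].
#' @return A `mc_cohort` list with tibbles `animals`, `series`, `diets`, a
#'   `truth` list of generating parameters (for parameter-recovery tests),
#'   the `config`, and an `anomalies` log.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mc_cohort_config"))
  set.seed(config$seed)
  cf <- config

  ## --- realise sites ---------------------------------------------------
  sites <- cf$sites
  if (is.null(sites)) {
    sites <- lapply(seq_len(cf$n_sites),
                    function(i) site_config(sprintf("site_%02d", i)))
  }
  sites <- lapply(sites, function(s) {
    if (is.null(s$intercept)) s$intercept <- runif(1, 0.4, 1.0)
    if (is.null(s$mass_slope)) {
      s$mass_slope <- runif(1, MASS_SLOPE_RANGE[1], MASS_SLOPE_RANGE[2])
    }
    s
  })
  site_ids <- vapply(sites, `[[`, character(1), "site_id")
  names(sites) <- site_ids
  site_tbl <- tibble(
    site = unname(site_ids),
    intercept = unname(vapply(sites, `[[`, numeric(1), "intercept")),
    mass_slope = unname(vapply(sites, `[[`, numeric(1), "mass_slope")),
    temp_coeff = unname(vapply(sites, `[[`, numeric(1), "temp_coeff")),
    activity_coeff = unname(vapply(sites, `[[`, numeric(1), "activity_coeff"))
  )

  ## --- assemble animal frame -------------------------------------------
  n_wt <- cf$animals_per_site_per_group
  wt <- expand.grid(site = site_ids, sex = cf$sexes, idx = seq_len(n_wt),
                    stringsAsFactors = FALSE)
  wt$genotype <- "WT"
  wt$strain_shift <- 0

  ko_list <- lapply(cf$strains, function(st) {
    site <- if (is.null(st$site)) {
      site_ids[sample.int(length(site_ids), st$n_animals, replace = TRUE)]
    } else rep(as.character(st$site), st$n_animals)
    shift <- rep(st$ee_shift, st$n_animals)
    if (!is.null(st$site_shifts)) {
      hit <- site %in% names(st$site_shifts)
      shift[hit] <- st$site_shifts[site[hit]]
    }
    data.frame(site = site, sex = rep(st$sex, length.out = st$n_animals),
               idx = seq_len(st$n_animals), genotype = st$genotype,
               strain_shift = shift, stringsAsFactors = FALSE)
  })
  animals <- bind_rows(wt, ko_list)
  n <- nrow(animals)
  animals$animal_id <- sprintf("A%05d", seq_len(n))

  ## --- animal covariate draws ------------------------------------------
  s_of <- function(field) {
    unname(vapply(sites[animals$site], `[[`, numeric(1), field))
  }
  mass_mu <- s_of("mass_mean") +
    ifelse(animals$sex == "M", cf$sex_mass_diff / 2, -cf$sex_mass_diff / 2)
  animals$body_mass_g <- pmax(12, rnorm(n, mass_mu, s_of("mass_sd")))
  lf <- pmin(0.95, pmax(0.5, rnorm(n, s_of("lean_fraction_mean"), 0.03)))
  animals$lean_mass_g <- lf * animals$body_mass_g
  animals$fat_mass_g <- 0.85 * (1 - lf) * animals$body_mass_g
  temp_true <- rnorm(n, s_of("ambient_temp_mean"), s_of("ambient_temp_sd"))
  records_temp <- vapply(sites[animals$site], `[[`, logical(1),
                         "records_temperature")
  records_act <- vapply(sites[animals$site], `[[`, logical(1),
                        "records_activity")
  animals$ambient_temp_c <- ifelse(records_temp, temp_true, NA_real_)
  animals$age_weeks <- 11
  animals$diet_id <- cf$diet_id
  doy <- sample.int(365, n, replace = TRUE)
  animals$run_start <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC") +
    (doy - 1) * 86400 + cf$run_start_hour * 3600
  act_level <- pmin(95, pmax(2, rnorm(n, cf$activity_mean, cf$activity_sd)))

  ## --- hourly grid -------------------------------------------------------
  H <- cf$run_hours
  hod <- (cf$run_start_hour + seq_len(H) - 1) %% 24
  dark <- annotate_photoperiod(hod, cf$lights_on, cf$lights_off) == "dark"

  ## beam breaks: dark-dominant, multiplicative noise, integer counts
  r_dark <- 2 * cf$dark_activity_ratio / (1 + cf$dark_activity_ratio)
  r_light <- 2 / (1 + cf$dark_activity_ratio)
  act_base <- outer(act_level * 12, ifelse(dark, r_dark, r_light)) # n x H
  breaks <- matrix(pmax(0, round(act_base * (1 + rnorm(n * H, 0, 0.2)))),
                   n, H)

  ## activity percent exactly as the analysis derives it
  post_h <- post_block_hours(H, cf$run_start_hour, cf$lights_on)
  act_hours <- if (length(post_h) > 0) post_h else seq_len(H)
  site_max <- vapply(split(seq_len(n), animals$site),
                     function(i) max(breaks[i, , drop = FALSE]), numeric(1))
  activity_pct <- unname(100 *
    rowMeans(breaks[, act_hours, drop = FALSE]) / site_max[animals$site])

  ## --- true mean EE ------------------------------------------------------
  mass_term <- vapply(seq_len(n), function(i) {
    s <- sites[[animals$site[i]]]
    if (!is.null(s$lean_slope) && !is.null(s$fat_slope)) {
      s$lean_slope * animals$lean_mass_g[i] + s$fat_slope * animals$fat_mass_g[i]
    } else {
      s$mass_slope * animals$body_mass_g[i]
    }
  }, numeric(1))
  ee_mean <- s_of("intercept") + mass_term +
    s_of("temp_coeff") * (temp_true - 22) +
    s_of("activity_coeff") * activity_pct +
    ifelse(animals$sex == "M", cf$sex_ee_shift, 0) +
    animals$strain_shift +
    rnorm(n, 0, cf$noise_sd)
  ee_mean <- pmax(0.3, ee_mean)

  ## --- hourly EE / RER / gases -------------------------------------------
  # 24-h-periodic profile with exact unit mean over any complete block
  profile <- 1 + cf$dark_ee_amplitude * (2 * dark - 1) +
    0.05 * cos(2 * pi * hod / 24)
  ee_h <- outer(ee_mean, profile)                       # n x H
  rer_h <- ifelse(dark, cf$rer_dark, cf$rer_light)
  rer_m <- matrix(rer_h, n, H, byrow = TRUE)
  vo2 <- ee_h * 1000 / (KJ_PER_KCAL * (WEIR_O2 + WEIR_CO2 * rer_m))
  vco2 <- rer_m * vo2

  ## --- food intake and energy balance ------------------------------------
  balance <- rnorm(n, 0, cf$balance_sd)                 # kJ/day
  density <- mousecal_diets()$energy_density_kj_g[
    match(cf$diet_id, mousecal_diets()$diet_id)]
  if (is.na(density)) stop("generate_cohort: unknown diet_id ", cf$diet_id)
  daily_g <- (ee_mean * 24 + balance) / density
  food_base <- outer(daily_g,
                     ifelse(dark, cf$dark_food_share / 12,
                            (1 - cf$dark_food_share) / 12))
  food <- pmax(0, food_base * (1 + rnorm(n * H, 0, cf$food_noise_cv)))

  ## weight change coupled to balance
  delta_mass <- balance * (H / 24) / cf$tissue_kj_per_g +
    rnorm(n, 0, cf$mass_change_noise_sd)

  ## --- emit tables -------------------------------------------------------
  ts0 <- rep(animals$run_start, each = H) + rep((seq_len(H) - 1) * 3600, n)
  series <- tibble(
    animal_id = rep(animals$animal_id, each = H),
    timestamp = ts0,
    vo2_ml_hr = as.vector(t(vo2)),
    vco2_ml_hr = as.vector(t(vco2)),
    ee_kj_hr = as.vector(t(ee_h)),
    food_g = as.vector(t(matrix(food, n, H))),
    beam_breaks = as.vector(t(breaks))
  )
  series$beam_breaks[rep(!records_act, each = H)] <- NA_real_

  animal_tbl <- tibble(
    animal_id = animals$animal_id, site = animals$site, sex = animals$sex,
    genotype = animals$genotype, diet_id = animals$diet_id,
    age_weeks = animals$age_weeks, body_mass_g = animals$body_mass_g,
    lean_mass_g = animals$lean_mass_g, fat_mass_g = animals$fat_mass_g,
    ambient_temp_c = animals$ambient_temp_c, run_start = animals$run_start,
    delta_mass_g = delta_mass
  )

  truth <- list(
    seed = cf$seed,
    sites = site_tbl,
    sex_ee_shift = cf$sex_ee_shift,
    noise_sd = cf$noise_sd,
    strains = tibble(
      genotype = vapply(cf$strains, `[[`, character(1), "genotype"),
      ee_shift = vapply(cf$strains, `[[`, numeric(1), "ee_shift")
    ),
    animals = tibble(animal_id = animals$animal_id, ee_mean_true = ee_mean,
                     activity_pct_true = activity_pct,
                     ambient_temp_true = temp_true, balance_true = balance)
  )

  structure(list(animals = animal_tbl, series = series,
                 diets = mousecal_diets(), truth = truth, config = cf,
                 anomalies = list()),
            class = "mc_cohort")
}

# hour indices (1-based) of the complete post-acclimation 24-h blocks for a
# run of H hourly samples starting at clock hour start_hod
post_block_hours <- function(H, start_hod, lights_on) {
  boundary <- 18 + ((lights_on - start_hod - 18) %% 24)
  k <- max(0, (H - boundary) %/% 24)
  if (k == 0) return(integer(0))
  boundary + seq_len(k * 24)
}

#' Inject a documented data anomaly into a synthetic cohort
#'
#' Reproduces, at one target site, the anomalies documented in large
#' consortium depositions: `inverse_mass` (larger animals paradoxically
#' expend less: each animal's EE is reflected about the site's mean-mass
#' prediction, negating the mass slope while preserving the site mean),
#' `constant_intake` (every hourly food reading keyed as exactly 0.05 g),
#' `lusk_ee` (reported EE computed with the Lusk caloric-equivalent formula
#' instead of Weir), and `short_run` (runs truncated below the 18-h minimum).
#' All other sites are untouched.
#'
#' @param cohort A `mc_cohort` from [generate_cohort()].
#' @param anomaly_kind One of `"inverse_mass"`, `"constant_intake"`,
#'   `"lusk_ee"`, `"short_run"`.
#' @param target_site Site label to corrupt.
#' @return The modified cohort, with the anomaly logged in `$anomalies`.
#' @export
inject_anomaly <- function(cohort, anomaly_kind, target_site) {
  stopifnot(inherits(cohort, "mc_cohort"))
  anomaly_kind <- match.arg(anomaly_kind,
                            c("inverse_mass", "constant_intake",
                              "lusk_ee", "short_run"))
  if (!target_site %in% cohort$animals$site) {
    stop("inject_anomaly: unknown site '", target_site, "'", call. = FALSE)
  }
  ids <- cohort$animals$animal_id[cohort$animals$site == target_site]
  rows <- cohort$series$animal_id %in% ids

  if (anomaly_kind == "inverse_mass") {
    sel <- cohort$animals$site == target_site
    mass <- cohort$animals$body_mass_g[sel]
    old <- cohort$truth$animals$ee_mean_true[
      match(cohort$animals$animal_id[sel], cohort$truth$animals$animal_id)]
    # negate the site's observed marginal EE-vs-mass slope (which includes
    # the sex/mass confound), reflecting each animal about the mean-mass
    # prediction so the site mean is preserved and EE stays positive
    slope <- unname(coef(lm(old ~ mass))[2])
    new <- old - 2 * slope * (mass - mean(mass))
    fac <- setNames(new / old, cohort$animals$animal_id[sel])
    f <- fac[cohort$series$animal_id[rows]]
    cohort$series$ee_kj_hr[rows] <- cohort$series$ee_kj_hr[rows] * f
    cohort$series$vo2_ml_hr[rows] <- cohort$series$vo2_ml_hr[rows] * f
    cohort$series$vco2_ml_hr[rows] <- cohort$series$vco2_ml_hr[rows] * f
    cohort$truth$animals$ee_mean_true[
      match(names(fac), cohort$truth$animals$animal_id)] <- new
  } else if (anomaly_kind == "constant_intake") {
    cohort$series$food_g[rows] <- 0.05
  } else if (anomaly_kind == "lusk_ee") {
    v <- cohort$series$vo2_ml_hr[rows]
    r <- cohort$series$vco2_ml_hr[rows] / v
    cohort$series$ee_kj_hr[rows] <- lusk_ee(v, r)
  } else { # short_run
    keep <- cohort$series |>
      group_by(.data$animal_id) |>
      mutate(.row = row_number()) |>
      ungroup()
    drop <- keep$.row > 18 & rows
    cohort$series <- cohort$series[!drop, , drop = FALSE]
  }
  cohort$anomalies <- c(cohort$anomalies,
                        list(list(kind = anomaly_kind, site = target_site)))
  cohort
}
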