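# Derived quantities from raw gas-exchange, food and activity measurements.
# Canonical units: energy kJ/hr, gas mL/hr, food g, temperature deg C.

# Abbreviated Weir constants (kcal per L O2 / CO2) and thermochemical kcal.
WEIR_O2 <- 3.941
WEIR_CO2 <- 1.106
KJ_PER_KCAL <- 4.184

# Caloric equivalents of oxygen (kcal/L) at the pure-fat and pure-carbohydrate
# respiratory quotients; the Lusk table is linear between these endpoints.
LUSK_RQ_LO <- 0.707
LUSK_RQ_HI <- 1.0
LUSK_CAL_LO <- 4.686
LUSK_CAL_HI <- 5.047

#' Energy expenditure from gas exchange (Weir formula)
#'
#' Computes energy expenditure from oxygen consumption and carbon dioxide
#' production using the abbreviated Weir formula,
#' EE = 4.184 (3.941 VO2 + 1.106 VCO2) / 1000 with gases in mL/hr,
#' returning kJ/hr. The function is linear and vectorised.
#'
#' @param vo2 Oxygen consumption, mL/hr (non-negative).
#' @param vco2 Carbon dioxide production, mL/hr (non-negative).
#' @return Energy expenditure in kJ/hr.
#' @examples
#' weir_ee(90, 72) # ~1.817 kJ/hr
#' @export
weir_ee <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    stop("weir_ee: vo2 and vco2 must be non-negative", call. = FALSE)
  }
  KJ_PER_KCAL * (WEIR_O2 * vo2 + WEIR_CO2 * vco2) / 1000
}

#' Respiratory exchange ratio
#'
#' RER = VCO2 / VO2, the ratio of carbon dioxide produced to oxygen consumed.
#' Values near 0.7 indicate fat oxidation, values near 1.0 carbohydrate
#' oxidation. Hours with zero oxygen consumption have undefined RER and
#' return `NA`.
#'
#' @param vo2 Oxygen consumption, mL/hr.
#' @param vco2 Carbon dioxide production, mL/hr.
#' @return RER (unitless); `NA` where `vo2` is 0.
#' @export
rer <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    stop("rer: vo2 and vco2 must be non-negative", call. = FALSE)
  }
  out <- vco2 / vo2
  out[!is.na(vo2) & vo2 == 0] <- NA_real_
  out
}

#' Energy expenditure from oxygen consumption (Lusk equation)
#'
#' EE from VO2 times an RER-dependent caloric equivalent of oxygen, linearly
#' interpolated between 4.686 kcal/L at RER 0.707 and 5.047 kcal/L at RER
#' 1.0 (RER clamped to that range), converted to kJ/hr. Used for classifying
#' which formula a deposited dataset applied, not for physiology.
#'
#' @param vo2 Oxygen consumption, mL/hr (non-negative).
#' @param rer Respiratory exchange ratio; clamped to \[0.707, 1.0\].
#' @return Energy expenditure in kJ/hr.
#' @export
lusk_ee <- function(vo2, rer) {
  if (any(vo2 < 0, na.rm = TRUE)) {
    stop("lusk_ee: vo2 must be non-negative", call. = FALSE)
  }
  rq <- pmin(pmax(rer, LUSK_RQ_LO), LUSK_RQ_HI)
  cal_eq <- LUSK_CAL_LO +
    (LUSK_CAL_HI - LUSK_CAL_LO) * (rq - LUSK_RQ_LO) / (LUSK_RQ_HI - LUSK_RQ_LO)
  (vo2 / 1000) * cal_eq * KJ_PER_KCAL
}

#' Energy intake from food mass
#'
#' Product of food mass consumed and the diet's energy density.
#'
#' @param food_mass Food consumed, g (non-negative).
#' @param diet A single row of a diet table (list or data frame row) with an
#'   `energy_density_kj_g` field, or a bare numeric energy density in kJ/g.
#' @return Energy intake in kJ.
#' @export
energy_intake <- function(food_mass, diet) {
  if (any(food_mass < 0, na.rm = TRUE)) {
    stop("energy_intake: food_mass must be non-negative", call. = FALSE)
  }
  density <- if (is.numeric(diet)) diet else diet[["energy_density_kj_g"]]
  if (is.null(density) || length(density) != 1 || is.na(density) || density <= 0) {
    stop("energy_intake: diet must supply a positive energy_density_kj_g",
         call. = FALSE)
  }
  food_mass * density
}

#' Energy balance
#'
#' Energy intake minus energy expenditure over the same period. Positive
#' balance predicts weight gain.
#'
#' @param intake Energy intake over the period, kJ.
#' @param ee_total Total energy expended over the same period, kJ.
#' @return Balance in kJ per period.
#' @export
energy_balance <- function(intake, ee_total) {
  intake - ee_total
}

#' Locomotor activity as percent of site maximum
#'
#' Beam-break counters differ between calorimeter manufacturers, so activity
#' is normalised as a percentage of the global maximum hourly count observed
#' at each site.
#'
#' @param beam_breaks Hourly beam-break counts.
#' @param site_max The site's global maximum hourly count (> 0).
#' @return Activity as percent of site maximum, in \[0, 100\].
#' @export
normalize_activity <- function(beam_breaks, site_max) {
  if (length(site_max) != 1 || is.na(site_max) || site_max <= 0) {
    stop("normalize_activity: site_max must be a single positive count",
         call. = FALSE)
  }
  100 * beam_breaks / site_max
}

#' Label timestamps by photoperiod
#'
#' Labels each timestamp dark or light under a lights-off/lights-on cycle.
#' The dark photoperiod is the half-open interval \[lights_off, lights_on):
#' the lights-off instant itself is dark, the lights-on instant is light.
#'
#' @param timestamps `POSIXct` vector, or numeric hours-of-day.
#' @param lights_on,lights_off Clock hours in \[0, 24) (may be fractional).
#' @return Character vector, `"dark"` or `"light"`.
#' @examples
#' annotate_photoperiod(c(18, 6, 5.99), lights_on = 6, lights_off = 18)
#' @export
annotate_photoperiod <- function(timestamps, lights_on = 6, lights_off = 18) {
  if (isTRUE(all.equal(lights_on %% 24, lights_off %% 24))) {
    stop("annotate_photoperiod: lights_on and lights_off must differ",
         call. = FALSE)
  }
  hod <- hour_of_day(timestamps)
  dark <- if (lights_off > lights_on) {
    hod >= lights_off | hod < lights_on
  } else {
    hod >= lights_off & hod < lights_on
  }
  ifelse(dark, "dark", "light")
}

# hour of day (possibly fractional) from POSIXct or numeric input
hour_of_day <- function(timestamps) {
  if (inherits(timestamps, "POSIXt")) {
    lt <- as.POSIXlt(timestamps)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    as.numeric(timestamps) %% 24
  }
}

#' Split a calorimetry run into acclimation and post-acclimation segments
#'
#' Mice need time to acclimate to a calorimeter before their behaviour
#' stabilises. The acclimation window runs from the start of recording to
#' the first lights-on boundary occurring at or after start + 18 h, so the
#' post-acclimation segment always begins with a full photoperiod. The two
#' segments partition the input exactly.
#'
#' @param series A single-animal tibble with a `timestamp` column
#'   (`POSIXct`), rows in time order.
#' @param lights_on Lights-on clock hour, default 6.
#' @return A list with elements `pre` and `post` (tibbles), `boundary`
#'   (`POSIXct` or `NA`), and `all_acclimation` (TRUE when the run spans
#'   less than 18 h and is therefore entirely acclimation).
#' @export
split_acclimation <- function(series, lights_on = 6) {
  stopifnot(is.data.frame(series), "timestamp" %in% names(series))
  ts <- series$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("split_acclimation: timestamps must be strictly increasing",
         call. = FALSE)
  }
  span_h <- as.numeric(difftime(ts[length(ts)], ts[1], units = "hours"))
  if (span_h < 18) {
    return(list(pre = series, post = series[0, , drop = FALSE],
                boundary = as.POSIXct(NA), all_acclimation = TRUE))
  }
  boundary <- acclimation_boundary(ts[1], lights_on)
  pre_idx <- ts < boundary
  list(pre = series[pre_idx, , drop = FALSE],
       post = series[!pre_idx, , drop = FALSE],
       boundary = boundary, all_acclimation = FALSE)
}

# first lights-on instant at or after start + 18 h (vectorised over start)
acclimation_boundary <- function(start, lights_on = 6) {
  start_hod <- hour_of_day(start)
  offset_h <- 18 + ((lights_on - start_hod - 18) %% 24)
  start + offset_h * 3600
}

#' Average a metric over whole 24-hour blocks
#'
#' Daily summaries (e.g. daily energy expenditure, DEE) are means over
#' complete 24-h blocks only; a partial trailing block would overweight one
#' photoperiod and is discarded.
#'
#' @param x Hourly values, one per hour, in time order.
#' @param hours_per_block Block length in samples, default 24 (hourly data).
#' @return The mean over all complete blocks.
#' @export
daily_average <- function(x, hours_per_block = 24) {
  k <- length(x) %/% hours_per_block
  if (k == 0) {
    stop("daily_average: no complete 24-h block in input", call. = FALSE)
  }
  mean(x[seq_len(k * hours_per_block)])
}

#' Meteorological season from a date
#'
#' Northern-hemisphere meteorological mapping: Dec-Feb winter, Mar-May
#' spring, Jun-Aug summer, Sep-Nov autumn.
#'
#' @param run_start `POSIXct` or `Date` vector.
#' @return Character vector of season labels.
#' @export
season_of <- function(run_start) {
  m <- as.POSIXlt(run_start)$mon + 1L
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Derive per-animal summary metrics from hourly series
#'
#' For each animal: recomputes EE from gas exchange with the Weir formula
#' (replacing any reported EE), drops the acclimation window, averages over
#' complete 24-h post-acclimation blocks to obtain daily EE (DEE), mean RER,
#' daily energy intake, activity as percent of the site's global maximum
#' hourly beam-break count, and energy balance (intake minus expenditure,
#' kJ/day). Adds a `season` label derived from `run_start`.
#'
#' Animals without a complete post-acclimation 24-h block get `NA` summaries
#' (run the short-run filter first in a pipeline).
#'
#' @param animals Animal table (see [read_animals()] for the schema).
#' @param series Hourly series table with columns `animal_id`, `timestamp`,
#'   `vo2_ml_hr`, `vco2_ml_hr`, `food_g`, `beam_breaks`.
#' @param diets Diet table with `diet_id` and `energy_density_kj_g`.
#' @param lights_on,lights_off Photoperiod clock hours.
#' @param recompute_ee Recompute EE by Weir from gases (default TRUE); if
#'   FALSE the reported `ee_kj_hr` column is used as-is.
#' @return The animal table with added columns `dee`, `rer_mean`,
#'   `energy_intake` (kJ/day), `activity_pct`, `energy_balance` (kJ/day),
#'   `season`, and `n_blocks`.
#' @export
derive_animals <- function(animals, series, diets, lights_on = 6,
                           lights_off = 18, recompute_ee = TRUE) {
  stopifnot(is.data.frame(animals), is.data.frame(series))
  series <- series |>
    inner_join(select(animals, "animal_id", "site", "diet_id"),
               by = "animal_id") |>
    arrange(.data$animal_id, .data$timestamp)

  if (recompute_ee || !"ee_kj_hr" %in% names(series)) {
    series$ee_kj_hr <- weir_ee(series$vo2_ml_hr, series$vco2_ml_hr)
  }
  series$rer_h <- rer(series$vo2_ml_hr, series$vco2_ml_hr)

  # site-wide global maximum hourly beam-break count (all hours)
  site_max <- series |>
    group_by(.data$site) |>
    summarise(site_max = suppressWarnings(max(.data$beam_breaks, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(site_max = ifelse(is.finite(.data$site_max) & .data$site_max > 0,
                             .data$site_max, NA_real_))
  series <- left_join(series, site_max, by = "site") |>
    mutate(act_pct = ifelse(is.na(.data$site_max), NA_real_,
                            100 * .data$beam_breaks / .data$site_max))

  summaries <- series |>
    group_by(.data$animal_id) |>
    group_modify(~ summarise_run(.x, lights_on)) |>
    ungroup()

  densities <- setNames(diets$energy_density_kj_g, diets$diet_id)
  out <- animals |>
    left_join(summaries, by = "animal_id") |>
    mutate(
      energy_intake = .data$daily_food_g * unname(densities[.data$diet_id]),
      energy_balance = energy_balance(.data$energy_intake, .data$dee * 24),
      season = season_of(.data$run_start)
    ) |>
    select(-"daily_food_g")
  as_tibble(out)
}

# per-run summary over complete post-acclimation 24-h blocks
summarise_run <- function(run, lights_on) {
  parts <- split_acclimation(run, lights_on = lights_on)
  post <- parts$post
  k <- nrow(post) %/% 24L
  if (k == 0L) {
    return(tibble(dee = NA_real_, rer_mean = NA_real_,
                  daily_food_g = NA_real_, activity_pct = NA_real_,
                  n_blocks = 0L))
  }
  block <- post[seq_len(k * 24L), , drop = FALSE]
  tibble(
    dee = mean(block$ee_kj_hr),
    rer_mean = mean(block$rer_h, na.rm = TRUE),
    daily_food_g = sum(block$food_g, na.rm = TRUE) / k,
    activity_pct = if (all(is.na(block$act_pct))) NA_real_
                   else mean(block$act_pct, na.rm = TRUE),
    n_blocks = k
  )
}
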