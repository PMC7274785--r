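# Residual-based scoring of knockout strains and interventions against a
# wild-type reference model, expressed in wild-type residual SD units.

#' Wild-type residual standard deviation
#'
#' The unit in which strain phenotypes are expressed. `scope = "animal"`
#' (default) returns the per-animal residual SD of the reference fit.
#' `scope = "strain"` instead shuffles the wild-type training animals into
#' pseudo-strains of size `strain_size` and returns the SD of pseudo-strain
#' mean residuals, i.e. the spread expected for null strains of that size.
#'
#' @param model A `mc_ref_model` from [fit_reference()].
#' @param scope `"animal"` or `"strain"`.
#' @param strain_size Pseudo-strain size for `scope = "strain"`, default 8.
#' @param seed Optional seed for the pseudo-strain shuffle.
#' @return The residual SD in kJ/hr.
#' @export
wt_residual_sd <- function(model, scope = c("animal", "strain"),
                           strain_size = 8, seed = NULL) {
  stopifnot(inherits(model, "mc_ref_model"))
  scope <- match.arg(scope)
  if (scope == "animal") return(model$residual_sd)
  res <- resid(model$fit)
  if (!is.null(seed)) set.seed(seed)
  res <- sample(res)
  k <- length(res) %/% strain_size
  if (k < 2) {
    stop("wt_residual_sd: too few animals for pseudo-strains", call. = FALSE)
  }
  means <- tapply(res[seq_len(k * strain_size)],
                  rep(seq_len(k), each = strain_size), mean)
  sd(means)
}

#' Assign SD bands to strain scores
#'
#' Band `k` (for `k` in 1, 2, 3) when `|sd_units| >= k`, taking the
#' largest qualifying `k`; effects of 3 SD or more all fall in band 3;
#' band 0 otherwise. The boundary is inclusive: `|sd_units| = 1` is band 1.
#'
#' @param sd_units Numeric vector of residual magnitudes in WT-SD units.
#' @return Integer band per element, in 0:3.
#' @export
sd_bands <- function(sd_units) {
  as.integer(pmin(floor(abs(sd_units) + 1e-9), 3))
}

#' Score a knockout strain against the wild-type reference
#'
#' The strain's phenotype is the mean deviation of its animals' observed
#' daily EE from the wild-type model prediction (the unexplained metabolic
#' effect), expressed in units of the wild-type residual SD. Significance
#' is a two-sided one-sample t-test of the per-animal residuals against 0.
#' Strains below the minimum group size are still scored but flagged
#' untestable.
#'
#' @param ko Rows of the derived animal table for one strain.
#' @param model A `mc_ref_model` fitted on wild-type animals.
#' @param wt_sd The wild-type residual SD, kJ/hr (see [wt_residual_sd()]).
#' @param min_n Minimum strain size for a testable score, default 4.
#' @param response Response column, default `"dee"`.
#' @return A one-row tibble: `genotype`, `n`, `mean_mass_g`,
#'   `mean_residual_kj_hr`, `sd_units`, `band`, `p_value`, `testable`.
#' @export
score_strain <- function(ko, model, wt_sd, min_n = 4, response = "dee") {
  stopifnot(inherits(model, "mc_ref_model"), wt_sd > 0)
  pred <- predict(model, ko)
  res <- ko[[response]] - pred
  ok <- !is.na(res)
  res <- res[ok]
  n <- length(res)
  if (n == 0) stop("score_strain: no scoreable animals", call. = FALSE)
  mean_res <- mean(res)
  p <- if (n >= 2 && sd(res) > 0) t.test(res)$p.value else NA_real_
  u <- mean_res / wt_sd
  tibble(genotype = as.character(unique(ko$genotype))[1], n = n,
         mean_mass_g = mean(ko$body_mass_g[ok]),
         mean_residual_kj_hr = mean_res, sd_units = u,
         band = sd_bands(u), p_value = p, testable = n >= min_n)
}

#' Score every strain in a cohort
#'
#' Applies [score_strain()] to each non-wild-type genotype of the selected
#' sex (consortium practice scores males), after dropping excluded
#' strains.
#'
#' @param animals Derived animal table.
#' @param model Wild-type `mc_ref_model`.
#' @param wt_sd Wild-type residual SD, kJ/hr.
#' @param sex Sex to score, default `"M"` (use `NULL` for both).
#' @param wt_label Wild-type genotype label, default `"WT"`.
#' @param exclude Genotypes dropped before scoring (default `"Fbxl19"`,
#'   excluded for highly variable values in the emulated curation).
#' @param min_n Minimum testable strain size, default 4.
#' @return Tibble of strain scores, one row per genotype, sorted by
#'   `|sd_units|` descending, with a `sex` column.
#' @export
score_all_strains <- function(animals, model, wt_sd, sex = "M",
                              wt_label = "WT", exclude = "Fbxl19",
                              min_n = 4) {
  d <- animals |>
    filter(.data$genotype != wt_label, !.data$genotype %in% exclude,
           !is.na(.data$dee))
  if (!is.null(sex)) d <- filter(d, .data$sex == !!sex)
  if (nrow(d) == 0) return(tibble())
  scores <- d |>
    group_by(.data$genotype) |>
    group_modify(~ score_strain(mutate(.x, genotype = .y$genotype),
                                model, wt_sd, min_n = min_n)[-1]) |>
    ungroup()
  scores$sex <- if (is.null(sex)) "both" else sex
  scores |>
    relocate("sex", .after = "genotype") |>
    arrange(desc(abs(.data$sd_units)))
}

#' Compare a strain's residuals across sites
#'
#' Computes the strain's residuals against each site's own wild-type
#' reference model (the difference from the controls at the specific site)
#' and tests them per site against the local wild-type residuals with a
#' Welch two-sample t-test. Classifies cross-site concordance: all
#' significant sites shifted the same way (`"unidirectional"`),
#' significant shifts in both directions (`"bidirectional"`), or no
#' significant site (`"none-significant"`).
#'
#' @param genotype Strain label.
#' @param animals Derived animal table (all sites, strain + wild type).
#' @param site_models Named list of per-site `mc_ref_model`s fitted on
#'   local wild-type animals; sites without a model are skipped with a
#'   warning.
#' @param alpha Significance level, default 0.05.
#' @param response Response column, default `"dee"`.
#' @return List with `table` (per-site tibble: `site`, `n_ko`,
#'   `mean_residual`, `diff_vs_wt`, `p`, `significant`) and `concordance`.
#' @export
site_residual_comparison <- function(genotype, animals, site_models,
                                     alpha = 0.05, response = "dee") {
  ko <- filter(animals, .data$genotype == !!genotype, !is.na(.data[[response]]))
  sites <- unique(ko$site)
  if (length(sites) < 2) {
    stop("site_residual_comparison: strain present at fewer than 2 sites",
         call. = FALSE)
  }
  rows <- lapply(sites, function(s) {
    m <- site_models[[s]]
    if (is.null(m)) {
      warning("site_residual_comparison: no wild-type model for site ", s,
              "; skipped", call. = FALSE)
      return(NULL)
    }
    ko_s <- ko[ko$site == s, , drop = FALSE]
    ko_res <- ko_s[[response]] - predict(m, ko_s)
    wt_res <- resid(m$fit)
    tt <- t.test(ko_res, wt_res)
    tibble(site = s, n_ko = length(ko_res), mean_residual = mean(ko_res),
           diff_vs_wt = mean(ko_res) - mean(wt_res), p = tt$p.value,
           significant = tt$p.value < alpha)
  })
  tab <- bind_rows(rows)
  sig <- tab[tab$significant, , drop = FALSE]
  concordance <- if (nrow(sig) == 0) "none-significant"
    else if (all(sig$diff_vs_wt > 0) || all(sig$diff_vs_wt < 0))
      "unidirectional"
    else "bidirectional"
  list(table = tab, concordance = concordance)
}

#' Score an intervention group in SD units
#'
#' Applies the residual/SD machinery to any labelled group of
#' animal-periods (e.g. mean EE over a 3-h post-dose window): the group's
#' mean deviation from the model prediction at matched covariates, in
#' wild-type residual SD units. Rows must carry every covariate the model
#' uses; a mismatch is an error.
#'
#' @param group_data Data frame of animal-periods with the model covariates
#'   and the response column.
#' @param model Wild-type `mc_ref_model`.
#' @param wt_sd Wild-type residual SD, kJ/hr.
#' @param response Response column, default `"dee"` (point it at a
#'   window-mean EE column for sub-daily periods).
#' @return List with `sd_units`, `mean_residual`, `n`, `p_value`.
#' @export
score_intervention <- function(group_data, model, wt_sd, response = "dee") {
  pred <- predict(model, group_data)
  res <- group_data[[response]] - pred
  res <- res[!is.na(res)]
  if (length(res) == 0) {
    stop("score_intervention: no scoreable periods", call. = FALSE)
  }
  list(sd_units = mean(res) / wt_sd, mean_residual = mean(res),
       n = length(res),
       p_value = if (length(res) >= 2 && sd(res) > 0) t.test(res)$p.value
                 else NA_real_)
}
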