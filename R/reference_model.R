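# Wild-type reference regressions, ANCOVA and slope-comparison analyses,
# and explained-variance decomposition (LMG relative importance,
# institutional residual share, fat-mass contribution, sex Q-Q variance).

CATEGORICAL_COVARIATES <- c("sex", "site", "season", "genotype", "diet_id")

#' Specify a reference model
#'
#' @param response Response column, default `"dee"` (daily energy
#'   expenditure, kJ/hr).
#' @param covariates Ordered character vector of covariate columns, from
#'   body composition (`body_mass_g`, `lean_mass_g`, `fat_mass_g`),
#'   `activity_pct`, `ambient_temp_c`, `sex`, `season`, `site`.
#' @param interactions Character vector of interaction terms in formula
#'   notation (e.g. `"site:body_mass_g"`).
#' @param reference_levels Named list of reference levels for categorical
#'   covariates.
#' @return A `mc_model_spec` list.
#' @export
model_spec <- function(response = "dee",
                       covariates = c("body_mass_g", "ambient_temp_c",
                                      "activity_pct", "sex"),
                       interactions = character(),
                       reference_levels = list()) {
  if (length(covariates) == 0) {
    stop("model_spec: covariates must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(covariates) || anyDuplicated(interactions)) {
    stop("model_spec: duplicate terms", call. = FALSE)
  }
  structure(list(response = response, covariates = covariates,
                 interactions = interactions,
                 reference_levels = reference_levels),
            class = "mc_model_spec")
}

#' Fit a wild-type reference regression
#'
#' Least-squares fit of the response on the spec's covariates. Covariates
#' with no observed data in the training scope are dropped with a warning
#' (sites differ in what they record); rows with missing values in the
#' remaining terms are excluded. Rank-deficient designs raise an error
#' naming the collinear terms.
#'
#' @param animals Derived animal table (training scope already applied,
#'   e.g. wild-type males of one site).
#' @param spec A [model_spec()].
#' @param scope Optional label describing the training scope (recorded in
#'   the fitted object).
#' @return A `mc_ref_model` with elements `spec`, `fit` (the `lm`),
#'   `coefficients` (tibble of term/estimate/se), `residual_sd`,
#'   `r_squared`, `n`, `dropped_terms`, `data` (training rows used), and
#'   `scope`.
#' @export
fit_reference <- function(animals, spec = model_spec(), scope = NULL) {
  stopifnot(inherits(spec, "mc_model_spec"))
  covs <- spec$covariates
  absent <- setdiff(covs, names(animals))
  all_na <- covs[vapply(covs, function(v)
    v %in% names(animals) && all(is.na(animals[[v]])), logical(1))]
  dropped <- union(absent, all_na)
  covs <- setdiff(covs, dropped)
  if (length(dropped) > 0) {
    warning("fit_reference: dropping term(s) with no data: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(covs) == 0) {
    stop("fit_reference: no usable covariates", call. = FALSE)
  }
  # interactions only between retained terms
  inter <- spec$interactions[vapply(spec$interactions, function(tm) {
    all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% covs)
  }, logical(1))]

  d <- animals[complete.cases(animals[c(spec$response, covs)]), , drop = FALSE]
  for (v in intersect(covs, CATEGORICAL_COVARIATES)) {
    d[[v]] <- factor(d[[v]])
    if (nlevels(d[[v]]) < 2) {
      # constant within the training scope (e.g. site in a per-site fit)
      warning("fit_reference: dropping constant term: ", v, call. = FALSE)
      dropped <- union(dropped, v)
      covs <- setdiff(covs, v)
      inter <- inter[!vapply(strsplit(inter, ":", fixed = TRUE),
                             function(tm) v %in% tm, logical(1))]
      next
    }
    ref <- spec$reference_levels[[v]]
    if (!is.null(ref)) d[[v]] <- relevel(d[[v]], ref = ref)
  }
  n_terms <- length(covs) + length(inter)
  if (nrow(d) <= n_terms + 1) {
    stop("fit_reference: n must exceed number of terms + 1", call. = FALSE)
  }
  fml <- as.formula(paste(spec$response, "~",
                          paste(c(covs, inter), collapse = " + ")))
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    stop("fit_reference: singular design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(
    spec = spec, fit = fit,
    coefficients = tibble(term = rownames(sm$coefficients),
                          estimate = sm$coefficients[, 1],
                          se = sm$coefficients[, 2]),
    residual_sd = sm$sigma, r_squared = sm$r.squared, n = nrow(d),
    dropped_terms = dropped, data = as_tibble(d), scope = scope
  ), class = "mc_ref_model")
}

#' @export
predict.mc_ref_model <- function(object, newdata, ...) {
  needed <- setdiff(all.vars(stats::formula(object$fit))[-1], names(newdata))
  if (length(needed) > 0) {
    stop("predict: newdata lacks covariate(s): ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  predict(object$fit, newdata = newdata, ...)
}

#' @export
print.mc_ref_model <- function(x, ...) {
  cat("Wild-type reference model:",
      deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("n = %d, R^2 = %.3f, residual SD = %.3f kJ/hr\n",
              x$n, x$r_squared, x$residual_sd))
  if (length(x$dropped_terms) > 0) {
    cat("dropped terms:", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ANCOVA: group comparison with a continuous covariate
#'
#' Fits the full model with a group-by-covariate interaction and reports
#' the interaction p-value (slope heterogeneity); the group effect is
#' tested in the common-slope model (covariate entered first). Per-group
#' slopes with standard errors and covariate-adjusted group means (at the
#' grand covariate mean) are returned.
#'
#' @param animals Data frame with the response, group and covariate columns.
#' @param group Grouping column (e.g. genotype, diet, quartile).
#' @param covariate Continuous covariate column (body mass or lean mass).
#' @param response Response column, default `"dee"`.
#' @return A `mc_ancova` list with `interaction_p`, `group_p`, `slopes`
#'   (tibble), `adjusted_means` (tibble), and `n`.
#' @export
ancova <- function(animals, group, covariate, response = "dee") {
  d <- tibble(y = animals[[response]], g = factor(animals[[group]]),
              x = animals[[covariate]])
  d <- d[complete.cases(d), , drop = FALSE]
  counts <- table(d$g)
  if (length(counts) < 2) {
    stop("ancova: need at least two groups", call. = FALSE)
  }
  if (any(counts < 3)) {
    stop("ancova: every group needs n >= 3", call. = FALSE)
  }
  if (all(tapply(d$x, d$g, function(v) var(v) == 0))) {
    stop("ancova: covariate constant within every group", call. = FALSE)
  }
  full <- lm(y ~ g * x, data = d)
  a_full <- anova(full)
  interaction_p <- a_full["g:x", "Pr(>F)"]
  common <- lm(y ~ x + g, data = d)
  a_common <- anova(common)
  group_p <- a_common["g", "Pr(>F)"]

  slopes <- d |>
    group_by(group = .data$g) |>
    group_modify(function(dd, key) {
      cf <- summary(lm(y ~ x, data = dd))$coefficients
      tibble(n = nrow(dd), slope = cf[2, 1], se = cf[2, 2])
    }) |>
    ungroup()
  adj <- tibble(group = levels(d$g))
  adj$adjusted_mean <- predict(common,
                               newdata = data.frame(x = mean(d$x),
                                                    g = adj$group))
  structure(list(interaction_p = interaction_p, group_p = group_p,
                 slopes = slopes, adjusted_means = adj, n = nrow(d)),
            class = "mc_ancova")
}

#' Pairwise comparison of per-site regression slopes
#'
#' Fits EE against the covariate separately per site and tests every pair
#' of slopes with a Welch-style t statistic (slope difference over the root
#' sum of squared standard errors, Satterthwaite degrees of freedom).
#' Unadjusted and Holm-adjusted p-values are both reported.
#'
#' @param animals Derived animal table.
#' @param site_col Site column, default `"site"`.
#' @param covariate Covariate column, default `"body_mass_g"`.
#' @param response Response column, default `"dee"`.
#' @param min_n Minimum animals per site, default 10 (smaller sites are
#'   dropped with a warning).
#' @return Tibble with one row per site pair: slopes, difference, `t`,
#'   `df`, `p`, `p_holm`.
#' @export
compare_slopes_pairwise <- function(animals, site_col = "site",
                                    covariate = "body_mass_g",
                                    response = "dee", min_n = 10) {
  d <- tibble(site = animals[[site_col]], x = animals[[covariate]],
              y = animals[[response]])
  d <- d[complete.cases(d), , drop = FALSE]
  small <- names(which(table(d$site) < min_n))
  if (length(small) > 0) {
    warning("compare_slopes_pairwise: dropping site(s) with n < ", min_n,
            ": ", paste(small, collapse = ", "), call. = FALSE)
    d <- filter(d, !.data$site %in% small)
  }
  sites <- sort(unique(d$site))
  if (length(sites) < 2) {
    stop("compare_slopes_pairwise: need at least two sites", call. = FALSE)
  }
  fits <- lapply(sites, function(s) {
    dd <- d[d$site == s, ]
    cf <- summary(lm(y ~ x, data = dd))$coefficients
    list(slope = cf[2, 1], se = cf[2, 2], df = nrow(dd) - 2)
  })
  names(fits) <- sites
  pairs <- utils::combn(sites, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- fits[[pairs[1, j]]]; b <- fits[[pairs[2, j]]]
    se <- sqrt(a$se^2 + b$se^2)
    tt <- (a$slope - b$slope) / se
    df <- se^4 / (a$se^4 / a$df + b$se^4 / b$df)
    tibble(site_a = pairs[1, j], site_b = pairs[2, j],
           slope_a = a$slope, slope_b = b$slope,
           diff = a$slope - b$slope, se = se, t = tt, df = df,
           p = 2 * pt(-abs(tt), df))
  })
  out <- bind_rows(out)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' ANCOVA over body-mass quartile bins
#'
#' Bins animals into mass groups by right-open boundaries (the last
#' interval is closed) — defaults to the small/medium/large/largest
#' quartile boundaries 14.00, 20.75, 27.50, 34.25, 41.00 g — then tests
#' slope heterogeneity of EE against the chosen covariate (total or lean
#' mass) across bins. Animals outside the boundary range and empty bins
#' are dropped with a warning.
#'
#' @param animals Derived animal table.
#' @param boundaries Increasing bin boundaries in g.
#' @param covariate Covariate column for the within-bin slopes, default
#'   `"body_mass_g"` (use `"lean_mass_g"` for composition-aware ANCOVA).
#' @param response Response column, default `"dee"`.
#' @return A `mc_ancova` (groups are the mass bins) with an extra
#'   `bin_counts` element.
#' @export
mass_quartile_ancova <- function(animals,
                                 boundaries = c(14.00, 20.75, 27.50,
                                                34.25, 41.00),
                                 covariate = "body_mass_g",
                                 response = "dee") {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("mass_quartile_ancova: boundaries must be increasing",
         call. = FALSE)
  }
  nb <- length(boundaries) - 1
  labels <- if (nb == 4) c("small", "medium", "large", "largest")
            else paste0("bin", seq_len(nb))
  bin <- findInterval(animals$body_mass_g, boundaries,
                      rightmost.closed = TRUE)
  outside <- bin == 0 | bin > nb
  if (any(outside, na.rm = TRUE)) {
    warning("mass_quartile_ancova: dropping ", sum(outside, na.rm = TRUE),
            " animal(s) outside the boundary range", call. = FALSE)
  }
  d <- animals[!is.na(bin) & !outside, , drop = FALSE]
  d$mass_bin <- labels[bin[!is.na(bin) & !outside]]
  present <- labels[labels %in% unique(d$mass_bin)]
  empty <- setdiff(labels, present)
  if (length(empty) > 0) {
    warning("mass_quartile_ancova: empty bin(s) dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  res <- ancova(d, group = "mass_bin", covariate = covariate,
                response = response)
  res$bin_counts <- table(factor(d$mass_bin, levels = present))
  res
}

#' LMG relative-importance decomposition of regression R-squared
#'
#' Decomposes the R-squared of a least-squares fit into non-negative
#' per-regressor shares: each regressor's share is the average, over all
#' orderings of regressor entry, of the increase in R-squared when it
#' enters. Computed exactly by the closed-form subset weighting
#' (increments weighted by |S|! (p-|S|-1)! / p!), feasible up to p = 12
#' regressors. Categorical covariates enter as single grouped blocks of
#' dummy columns, so one share is reported per factor.
#'
#' @param data Data frame with the response and regressor columns.
#' @param response Response column name.
#' @param regressors Character vector of regressor columns (1 to 12; a
#'   single regressor's share is its marginal R-squared).
#' @return A `mc_importance` tibble with columns `term`, `share`
#'   (fraction of response variance) and `share_normalized` (share of the
#'   explained variance, summing to 1), plus attributes `total_r2` and
#'   `unexplained`. Shares sum to the model R-squared.
#' @export
relative_importance <- function(data, response, regressors) {
  p <- length(regressors)
  if (p < 1) stop("relative_importance: need >= 1 regressor", call. = FALSE)
  if (p > 12) {
    stop("relative_importance: > 12 regressors is unsupported (exact LMG ",
         "enumerates 2^p subsets)", call. = FALSE)
  }
  d <- data[complete.cases(data[c(response, regressors)]), , drop = FALSE]
  if (nrow(d) <= p + 1) {
    stop("relative_importance: n must exceed regressors + 1", call. = FALSE)
  }
  y <- d[[response]]
  tss <- sum((y - mean(y))^2)
  blocks <- lapply(regressors, function(v) {
    x <- d[[v]]
    if (is.numeric(x)) matrix(x, ncol = 1, dimnames = list(NULL, v))
    else model.matrix(~ f, data.frame(f = factor(x)))[, -1, drop = FALSE]
  })

  r2_of <- function(mask) {
    if (mask == 0) return(0)
    X <- do.call(cbind, blocks[bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0])
    fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
    1 - sum(fit$residuals^2) / tss
  }
  r2 <- vapply(0:(2^p - 1), r2_of, numeric(1))

  w <- factorial(0:(p - 1)) * factorial(p - (0:(p - 1)) - 1) / factorial(p)
  shares <- vapply(seq_len(p), function(k) {
    bit_k <- bitwShiftL(1L, k - 1L)
    masks <- which(bitwAnd(0:(2^p - 1), bit_k) == 0) - 1L
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0),
                    numeric(1))
    sum(w[sizes + 1] * (r2[bitwOr(masks, bit_k) + 1] - r2[masks + 1]))
  }, numeric(1))

  total <- r2[2^p]
  out <- tibble(term = regressors, share = shares,
                share_normalized = if (total > 0) shares / total
                                   else rep(NA_real_, p))
  attr(out, "total_r2") <- total
  attr(out, "unexplained") <- 1 - total
  class(out) <- c("mc_importance", class(out))
  out
}

#' Institutional share of residual variation
#'
#' Fits the biological reference model (no site term), then regresses its
#' residuals on site indicators; the R-squared of that second-stage fit is
#' the fraction of biologically unexplained variation attributable to the
#' institutional site. Zero (with a warning) for a single site, and ~0 by
#' construction when the biological model already includes site.
#'
#' @param animals Derived animal table.
#' @param spec Biological [model_spec()] (should not include `site`).
#' @param site_col Site column, default `"site"`.
#' @return A single fraction in \[0, 1\].
#' @export
institutional_share <- function(animals, spec = model_spec(),
                                site_col = "site") {
  if (length(unique(animals[[site_col]])) < 2) {
    warning("institutional_share: single site; returning 0", call. = FALSE)
    return(0)
  }
  m <- fit_reference(animals, spec)
  res <- resid(m$fit)
  site <- factor(m$data[[site_col]])
  summary(lm(res ~ site))$r.squared
}

#' Per-site contribution of fat mass to energy expenditure
#'
#' Fits EE on lean and fat mass (plus activity where recorded) per site and
#' reports the fat-mass contribution as
#' `100 * beta_fat * mean(fat) / (beta_lean * mean(lean) + beta_fat *
#' mean(fat))`. The contribution can be negative in lean chow-fed cohorts.
#'
#' @param animals Derived animal table with `lean_mass_g`, `fat_mass_g`.
#' @param include_activity Include `activity_pct` where recorded, default
#'   TRUE.
#' @param response Response column, default `"dee"`.
#' @param min_n Minimum animals per site, default 10.
#' @return Tibble with `site`, `n`, `beta_lean`, `beta_fat`,
#'   `contribution_pct`.
#' @export
fat_mass_contribution <- function(animals, include_activity = TRUE,
                                  response = "dee", min_n = 10) {
  if (!all(c("lean_mass_g", "fat_mass_g") %in% names(animals))) {
    stop("fat_mass_contribution: lean_mass_g and fat_mass_g required",
         call. = FALSE)
  }
  animals |>
    filter(complete.cases(.data$lean_mass_g, .data$fat_mass_g,
                          .data[[response]])) |>
    group_by(site = .data$site) |>
    group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        return(tibble(n = nrow(d), beta_lean = NA_real_,
                      beta_fat = NA_real_, contribution_pct = NA_real_))
      }
      use_act <- include_activity && "activity_pct" %in% names(d) &&
        any(!is.na(d$activity_pct))
      fml <- if (use_act) {
        d <- d[!is.na(d$activity_pct), , drop = FALSE]
        as.formula(paste(response, "~ lean_mass_g + fat_mass_g + activity_pct"))
      } else {
        as.formula(paste(response, "~ lean_mass_g + fat_mass_g"))
      }
      cf <- coef(lm(fml, data = d))
      num <- cf[["fat_mass_g"]] * mean(d$fat_mass_g)
      den <- cf[["lean_mass_g"]] * mean(d$lean_mass_g) + num
      tibble(n = nrow(d), beta_lean = cf[["lean_mass_g"]],
             beta_fat = cf[["fat_mass_g"]],
             contribution_pct = 100 * num / den)
    }) |>
    ungroup()
}

#' Compare EE variance between sexes by quantile-quantile slope
#'
#' For each sex, regresses the ordered sample quantiles of EE on standard
#' normal quantiles; the slope estimates the theoretical SD of that sex's
#' EE distribution. Returns both slopes and their male/female ratio
#' (parallel lines mean similar variability).
#'
#' @param animals Derived animal table with `sex` and the response column.
#' @param response Response column, default `"dee"`.
#' @param min_n Minimum animals per sex, default 30.
#' @return A `mc_qq` list with `slopes` (named by sex) and `ratio`
#'   (male / female).
#' @export
sex_variance_qq <- function(animals, response = "dee", min_n = 30) {
  d <- animals[!is.na(animals[[response]]) & !is.na(animals$sex), ,
               drop = FALSE]
  sexes <- unique(d$sex)
  if (!all(c("M", "F") %in% sexes)) {
    stop("sex_variance_qq: both sexes required", call. = FALSE)
  }
  slopes <- vapply(c(M = "M", F = "F"), function(s) {
    x <- sort(d[[response]][d$sex == s])
    if (length(x) < min_n) {
      stop("sex_variance_qq: fewer than ", min_n, " animals for sex ", s,
           call. = FALSE)
    }
    unname(coef(lm(x ~ qnorm(ppoints(length(x)))))[2])
  }, numeric(1))
  structure(list(slopes = slopes, ratio = slopes[["M"]] / slopes[["F"]]),
            class = "mc_qq")
}
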