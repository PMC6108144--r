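#' Cohort simulation configuration
#'
#' Describes a synthetic DHS-style birth cohort: its size, geography
#' (districts nested in states), the marginal distribution of the three
#' demographic risk factors, the target marginal infant-mortality rate and
#' the dispersion of the latent risk effects on the logit scale.
#'
#' @param n_births Number of births to simulate.
#' @param n_states Number of states; districts are assigned to states in
#'   contiguous blocks as evenly as possible.
#' @param n_districts Number of districts (`>= n_states`). Each birth's
#'   district is drawn uniformly.
#' @param factor_proportions Named list with probability vectors `wealth`
#'   (5 levels), `education` (4 levels) and `age` (3 levels). Each must sum
#'   to 1 and be non-negative.
#' @param baseline_mortality Target marginal death rate in (0, 1); the
#'   intercept is calibrated so the cohort mean of the true risk hits it.
#' @param effect_scales Named numeric vector of logit-scale standard
#'   deviations, one entry per effect term (see [default_effect_scales()]).
#'   A scale of 0 switches a term off.
#' @param seed Master seed; per-stage sub-seeds are derived from it so the
#'   same configuration always yields the same cohort.
#' @return An object of class `cohort_config`.
#' @seealso [default_india_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_births,
                          n_states,
                          n_districts,
                          factor_proportions,
                          baseline_mortality = 0.065,
                          effect_scales = default_effect_scales(),
                          seed = 1L) {
  stopifnot(n_births >= 1, n_states >= 1, n_districts >= n_states)
  need <- c(wealth = 5L, education = 4L, age = 3L)
  if (!all(names(need) %in% names(factor_proportions))) {
    stop("factor_proportions must contain 'wealth', 'education' and 'age'")
  }
  for (f in names(need)) {
    p <- factor_proportions[[f]]
    if (length(p) != need[[f]]) {
      stop(sprintf("factor_proportions$%s must have %d entries", f, need[[f]]))
    }
    if (any(p < 0)) stop("factor proportions must be non-negative")
    if (abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("factor_proportions$%s must sum to 1 (got %.15f)", f, sum(p)))
    }
  }
  if (baseline_mortality <= 0 || baseline_mortality >= 1) {
    stop("baseline_mortality must be strictly inside (0, 1)")
  }
  all_terms <- names(enumerate_terms())
  if (!all(all_terms %in% names(effect_scales))) {
    stop("effect_scales must name every effect term; see default_effect_scales()")
  }
  if (any(effect_scales < 0)) stop("effect_scales must be non-negative")
  structure(
    list(
      n_births = as.integer(n_births),
      n_states = as.integer(n_states),
      n_districts = as.integer(n_districts),
      factor_proportions = factor_proportions[names(need)],
      baseline_mortality = baseline_mortality,
      effect_scales = effect_scales[all_terms],
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default logit-scale effect dispersions by interaction order
#'
#' Main effects 0.5, two-way 0.25, three-way 0.15, four-way 0.10 (standard
#' deviations on the logit scale). These produce district median risks
#' spanning roughly 0 to 15 percent at the India-like baseline, comparable
#' to the between-district spread seen in national DHS cohorts.
#'
#' @param main,two_way,three_way,four_way Standard deviation applied to each
#'   term of that interaction order.
#' @return Named numeric vector over the 15 effect terms.
#' @export
default_effect_scales <- function(main = 0.5, two_way = 0.25,
                                  three_way = 0.15, four_way = 0.10) {
  terms <- enumerate_terms()
  by_order <- c(main, two_way, three_way, four_way)
  stats::setNames(by_order[lengths(terms)], names(terms))
}

#' India-like cohort configuration
#'
#' A configuration matching the structure of the 1998-1999 India NFHS-2/DHS
#' birth cohort: 73,320 births across 436 districts in 26 states, marginal
#' factor frequencies equal to the survey's summary counts, and a marginal
#' infant-mortality rate of 65 per 1,000 births.
#'
#' @param n_births,seed Overrides for cohort size and master seed; the
#'   factor proportions and geography are kept at the India values.
#' @param effect_scales Logit-scale effect dispersions
#'   (see [default_effect_scales()]).
#' @return A [cohort_config()] object.
#' @export
default_india_config <- function(n_births = 73320L,
                                 effect_scales = default_effect_scales(),
                                 seed = 1L) {
  cohort_config(
    n_births = n_births,
    n_states = 26L,
    n_districts = 436L,
    factor_proportions = list(
      wealth    = c(14951, 14492, 15159, 15753, 12965) / 73320,
      education = c(40341, 11941, 15808, 5230) / 73320,
      age       = c(9391, 60201, 3728) / 73320
    ),
    baseline_mortality = 0.065,
    effect_scales = effect_scales,
    seed = seed
  )
}

# Contiguous-block district-to-state map, sizes as even as possible.
district_state_map <- function(n_districts, n_states) {
  base <- n_districts %/% n_states
  extra <- n_districts %% n_states
  sizes <- rep(base, n_states) + c(rep(1L, extra), rep(0L, n_states - extra))
  rep(seq_len(n_states), times = sizes)
}

#' Generate a synthetic birth cohort with known ground-truth risk
#'
#' Draws the three demographic factors independently from the configured
#' marginals and the district uniformly; draws a centred zero-mean Gaussian
#' effect for every level combination of every active term; calibrates the
#' intercept by root-finding so the cohort mean of the true risk matches
#' `baseline_mortality` to within 1e-4; and samples the survival outcome as
#' Bernoulli in the true risk. Identical configuration (including seed)
#' gives identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_sim` with elements `cohort` (a tibble
#'   with columns `district_id`, `state_id`, `wealth`, `education`,
#'   `age_cat`, `died`, `true_risk`) and `truth` (a `truth_params` object
#'   holding the intercept and per-term level effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 4L)
  n <- config$n_births

  covs <- with_seed(seeds[1], {
    tibble::tibble(
      wealth    = sample(1:5, n, replace = TRUE, prob = config$factor_proportions$wealth),
      education = sample(0:3, n, replace = TRUE, prob = config$factor_proportions$education),
      age_cat   = sample(0:2, n, replace = TRUE, prob = config$factor_proportions$age)
    )
  })
  district_id <- with_seed(seeds[2], sample.int(config$n_districts, n, replace = TRUE))
  d2s <- district_state_map(config$n_districts, config$n_states)

  cohort <- tibble::tibble(
    district_id = district_id,
    state_id = d2s[district_id],
    covs
  )

  truth <- with_seed(seeds[3], draw_truth_effects(config))
  eta <- linear_predictor(cohort, truth$term_effects)
  truth$intercept <- calibrate_intercept(eta, config$baseline_mortality)
  cohort$true_risk <- plogis(truth$intercept + eta)
  cohort$died <- with_seed(seeds[4], rbinom(n, 1L, cohort$true_risk))
  cohort <- cohort[, c("district_id", "state_id", "wealth", "education",
                       "age_cat", "died", "true_risk")]

  structure(list(cohort = cohort, truth = truth), class = "cohort_sim")
}

# Zero-mean Gaussian level effects for every active term, centred exactly.
draw_truth_effects <- function(config) {
  terms <- enumerate_terms()
  effects <- list()
  for (nm in names(terms)) {
    sd <- config$effect_scales[[nm]]
    if (sd == 0) next
    keys <- term_grid_keys(terms[[nm]], config$n_districts)
    e <- rnorm(length(keys), 0, sd)
    e <- e - mean(e)
    effects[[nm]] <- stats::setNames(e, keys)
  }
  structure(
    list(intercept = NA_real_, term_effects = effects,
         n_districts = config$n_districts),
    class = "truth_params"
  )
}

# Sum of term effects at each row's level combination (no intercept).
linear_predictor <- function(data, term_effects) {
  eta <- numeric(nrow(data))
  terms <- enumerate_terms()
  for (nm in names(term_effects)) {
    eff <- term_effects[[nm]]
    keys <- term_keys(data, terms[[nm]])
    idx <- match(keys, names(eff))
    if (anyNA(idx)) {
      stop("unknown level combination for term '", nm, "': ",
           keys[which(is.na(idx))[1]])
    }
    eta <- eta + unname(eff[idx])
  }
  eta
}

# Root-find the intercept c so that mean(plogis(c + eta)) = target.
calibrate_intercept <- function(eta, target, tol = 1e-12) {
  f <- function(c) mean(plogis(c + eta)) - target
  lo <- -35; hi <- 35
  if (f(lo) > 0 || f(hi) < 0) {
    stop("intercept calibration failed: effect scales too large for the ",
         "requested baseline mortality")
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Ground-truth mortality risk of birth records
#'
#' Evaluates the latent risk of the simulator's data-generating process:
#' the inverse logit of the intercept plus the sum of all term effects at
#' each record's level combination.
#'
#' @param records A data frame of birth records (one or more rows) with the
#'   factor columns `district_id`, `wealth`, `education`, `age_cat`.
#' @param params A `truth_params` object from [generate_cohort()].
#' @return Numeric vector of probabilities, one per row.
#' @export
true_risk <- function(records, params) {
  stopifnot(inherits(params, "truth_params"))
  plogis(params$intercept + linear_predictor(records, params$term_effects))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  births: %d  states: %d  districts: %d\n",
              x$n_births, x$n_states, x$n_districts))
  cat(sprintf("  baseline mortality: %.4f   seed: %d\n",
              x$baseline_mortality, x$seed))
  active <- sum(x$effect_scales > 0)
  cat(sprintf("  active effect terms: %d of %d\n",
              active, length(x$effect_scales)))
  invisible(x)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>\n")
  cat(sprintf("  %d births, %d districts, %d deaths (rate %.4f)\n",
              nrow(x$cohort), length(unique(x$cohort$district_id)),
              sum(x$cohort$died), mean(x$cohort$died)))
  invisible(x)
}
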