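# Shared fixtures and independent oracles for the test suite.

# A small, fully specified cohort configuration (uniform-ish marginals).
small_config <- function(n_births = 3000, n_states = 2, n_districts = 6,
                         seed = 7, effect_scales = default_effect_scales(),
                         baseline = 0.065) {
  cohort_config(
    n_births = n_births, n_states = n_states, n_districts = n_districts,
    factor_proportions = list(
      wealth = rep(0.2, 5),
      education = c(0.4, 0.2, 0.3, 0.1),
      age = c(0.1, 0.8, 0.1)
    ),
    baseline_mortality = baseline,
    effect_scales = effect_scales,
    seed = seed
  )
}

# Effect scales with every term off except the named overrides.
scales_only <- function(...) {
  s <- default_effect_scales(0, 0, 0, 0)
  ov <- c(...)
  s[names(ov)] <- ov
  s
}

# Hand-built toy birth table from parallel vectors.
toy_table <- function(district, state, wealth, education, age, died,
                      risk = NULL) {
  tab <- tibble::tibble(
    district_id = as.integer(district), state_id = as.integer(state),
    wealth = as.integer(wealth), education = as.integer(education),
    age_cat = as.integer(age), died = as.integer(died)
  )
  if (!is.null(risk)) tab$true_risk <- risk
  tab
}

risk_of <- function(values) {
  out <- tibble::tibble(posterior_mean = values, lower = values, upper = values)
  class(out) <- c("risk_estimates", class(out))
  out
}

# Independent fractional-knapsack oracle: the LP optimum has at most one
# fractional group, so enumerate every subset of fully included groups plus
# every choice of one extra fractional group. Exponential; fine for <= 12
# groups. Returns the maximal expected deaths captured (absolute count).
knapsack_oracle <- function(n_births, n_deaths, budget_births) {
  k <- length(n_births)
  best <- 0
  for (mask in 0:(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(0:(k - 1))))
    size <- sum(n_births[inset])
    if (size > budget_births + 1e-9) next
    value <- sum(n_deaths[inset])
    rem <- budget_births - size
    extra <- 0
    for (g in which(!inset)) {
      f <- min(1, rem / n_births[g])
      extra <- max(extra, f * n_deaths[g])
    }
    best <- max(best, value + extra)
  }
  best
}

# Random partition-style subgroup instance with calibrated mean risks
# (mean_risk equals the realised death rate, as for a perfectly calibrated
# risk model), so ranking by mean risk coincides with ranking by
# deaths-per-birth density.
random_subgroup_instance <- function(k, seed) {
  set.seed(seed)
  n <- sample(5:200, k, replace = TRUE)
  rate <- runif(k, 0.005, 0.4)
  d <- rbinom(k, n, rate)
  start <- cumsum(c(1, n[-k]))
  members <- lapply(seq_len(k), function(i) seq(start[i], start[i] + n[i] - 1))
  tibble::tibble(
    unit = seq_len(k), wealth = 1L, education = 0L, age_cat = 0L,
    n_births = n, n_deaths = d, mean_risk = d / n,
    members = members,
    key = sprintf("%09d|1|0|0", seq_len(k))
  )
}

# Realised deaths captured by a plan given per-group death counts.
plan_capture_count <- function(plan) {
  sum(plan$selected$inclusion_fraction * plan$selected$n_deaths)
}
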