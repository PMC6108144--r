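#' Share of deaths captured by a targeting plan
#'
#' The fraction of all deaths in the cohort that fall inside the targeted
#' set, with a fractionally included subgroup contributing its inclusion
#' fraction times its deaths (the expected capture of covering a random
#' fraction of the group).
#'
#' @param plan A `targeting_plan`.
#' @param data The birth table the plan's members index into.
#' @return A probability in `[0, 1]`.
#' @export
capture_rate <- function(plan, data) {
  stopifnot(inherits(plan, "targeting_plan"))
  total <- sum(data$died)
  if (total == 0) stop("cohort has zero deaths: capture rate is undefined")
  got <- sum(vapply(seq_len(nrow(plan$selected)), function(i) {
    plan$selected$inclusion_fraction[i] *
      sum(data$died[plan$selected$members[[i]]])
  }, 0))
  got / total
}

#' Expected deaths captured under the risk estimates themselves
#'
#' Replaces realised deaths with each member's estimated risk: the plan's
#' expected share of deaths if the risk estimates were the truth. Under
#' this measure the greedy fractional allocator is provably optimal among
#' all fractional selections of a partition, and refining the partition
#' (national to state to district) can never decrease it.
#'
#' @param plan A `targeting_plan`.
#' @param risks `risk_estimates` aligned with the cohort the plan indexes.
#' @return A probability in `[0, 1]`.
#' @export
expected_capture <- function(plan, risks) {
  stopifnot(inherits(plan, "targeting_plan"))
  total <- sum(risks$posterior_mean)
  got <- sum(vapply(seq_len(nrow(plan$selected)), function(i) {
    plan$selected$inclusion_fraction[i] *
      sum(risks$posterior_mean[plan$selected$members[[i]]])
  }, 0))
  got / total
}

#' Share of outside births whose risk exceeds a reference group's mean
#'
#' Computes the mean estimated risk within the reference level of a factor,
#' then the share of births outside that level whose estimated risk is
#' strictly higher. Quantifies how much high-risk mass a single-factor
#' targeting rule leaves on the table.
#'
#' @param risks `risk_estimates` aligned with `data`.
#' @param data Birth table.
#' @param reference_factor Column name: `"wealth"`, `"education"` or
#'   `"age_cat"`.
#' @param reference_level The level defining the reference group.
#' @param reference_mean Optional override of the computed reference mean
#'   (e.g. a published rounded value) for parity checks.
#' @return A probability in `[0, 1]`.
#' @export
exceedance_share <- function(risks, data, reference_factor, reference_level,
                             reference_mean = NULL) {
  stopifnot(reference_factor %in% names(data), nrow(data) == nrow(risks))
  ref <- data[[reference_factor]] == reference_level
  if (!any(ref)) stop("reference group is empty")
  if (all(ref)) stop("complement of the reference group is empty")
  m <- reference_mean %||% mean(risks$posterior_mean[ref])
  mean(risks$posterior_mean[!ref] > m)
}

#' Per-district summary of mortality, poverty and targeting intensity
#'
#' @param risks `risk_estimates` aligned with `data`.
#' @param data Birth table.
#' @param plan Optional `targeting_plan`; when given, each district's share
#'   of births flagged high-risk is reported (fractionally included members
#'   counted by their fraction).
#' @return Tibble with one row per district: `n_births`, `death_rate`,
#'   `poor_share` (births in the lowest wealth quintile), `high_risk_share`
#'   (if a plan is given) and the 25th/50th/75th percentiles of member
#'   risks (`risk_q25`, `risk_q50`, `risk_q75`).
#' @export
district_summary <- function(risks, data, plan = NULL) {
  stopifnot(nrow(data) == nrow(risks))
  w <- rep(0, nrow(data))
  if (!is.null(plan)) {
    for (i in seq_len(nrow(plan$selected))) {
      w[plan$selected$members[[i]]] <- plan$selected$inclusion_fraction[i]
    }
  }
  df <- tibble::tibble(district_id = data$district_id, died = data$died,
                       wealth = data$wealth, risk = risks$posterior_mean,
                       flag = w)
  out <- df |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      n_births = dplyr::n(),
      death_rate = mean(.data$died),
      poor_share = mean(.data$wealth == 1L),
      high_risk_share = mean(.data$flag),
      risk_q25 = quantile(.data$risk, 0.25, names = FALSE),
      risk_q50 = quantile(.data$risk, 0.50, names = FALSE),
      risk_q75 = quantile(.data$risk, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$district_id)
  if (is.null(plan)) out$high_risk_share <- NA_real_
  out
}

#' Translate capture rates into absolute annual counts
#'
#' Census-style arithmetic: annual births times the mortality rate gives the
#' implied deaths; each plan's capture rate times the unrounded death count
#' gives the deaths it identifies. All counts rounded half-up on the
#' unrounded products.
#'
#' @param annual_births Annual number of births.
#' @param mortality_rate Infant mortality rate in `[0, 1]`.
#' @param plan_capture Capture rate of the model-based plan.
#' @param baseline_capture Capture rate of the single-factor baseline.
#' @return A `projection` list: `annual_births`, `mortality_rate`,
#'   `implied_deaths`, `captured_by_plan`, `captured_by_baseline`.
#' @examples
#' project_counts(25642200, 0.044, 0.57, 0.30)
#' @export
project_counts <- function(annual_births, mortality_rate,
                           plan_capture, baseline_capture) {
  stopifnot(mortality_rate >= 0, mortality_rate <= 1,
            plan_capture >= 0, plan_capture <= 1,
            baseline_capture >= 0, baseline_capture <= 1)
  deaths <- annual_births * mortality_rate
  structure(
    list(annual_births = annual_births,
         mortality_rate = mortality_rate,
         implied_deaths = round_half_up(deaths),
         captured_by_plan = round_half_up(plan_capture * deaths),
         captured_by_baseline = round_half_up(baseline_capture * deaths)),
    class = "projection"
  )
}

#' @export
print.projection <- function(x, ...) {
  cat("<projection>\n")
  cat(sprintf("  %s births x rate %.4f = %s implied deaths\n",
              format(x$annual_births, big.mark = ","), x$mortality_rate,
              format(x$implied_deaths, big.mark = ",")))
  cat(sprintf("  captured by plan: %s; by baseline: %s\n",
              format(x$captured_by_plan, big.mark = ","),
              format(x$captured_by_baseline, big.mark = ",")))
  invisible(x)
}
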