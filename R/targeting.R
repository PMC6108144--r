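#' Cross-classify births into targeting subgroups
#'
#' Groups births by geographic unit and full demographic cell
#' (wealth x education x age category). The geographic unit is the district
#' (`scenario = "district"`: each district may target different cells), the
#' state (`"state"`: all districts of a state target the same cells), or the
#' whole country (`"national"`). Empty cells are omitted, so the returned
#' subgroups partition the cohort.
#'
#' @param data Birth table.
#' @param risks A `risk_estimates` tibble aligned row-for-row with `data`.
#' @param scenario One of `"district"`, `"state"`, `"national"`.
#' @return A tibble of subgroups: `unit`, the demographic cell, `n_births`,
#'   `n_deaths`, `mean_risk` (mean of members' posterior-mean risks), a
#'   deterministic sort `key`, and a `members` list column of row indices.
#' @export
define_subgroups <- function(data, risks,
                             scenario = c("district", "state", "national")) {
  scenario <- match.arg(scenario)
  stopifnot(nrow(data) == nrow(risks))
  unit <- switch(scenario,
    district = data$district_id,
    state    = data$state_id,
    national = rep(1L, nrow(data))
  )
  df <- tibble::tibble(
    unit = unit,
    wealth = data$wealth, education = data$education, age_cat = data$age_cat,
    died = data$died, risk = risks$posterior_mean,
    row = seq_len(nrow(data))
  )
  out <- df |>
    dplyr::group_by(.data$unit, .data$wealth, .data$education, .data$age_cat) |>
    dplyr::summarise(
      n_births = dplyr::n(),
      n_deaths = sum(.data$died),
      mean_risk = mean(.data$risk),
      members = list(.data$row),
      .groups = "drop"
    ) |>
    dplyr::mutate(key = sprintf("%09d|%d|%d|%d", .data$unit, .data$wealth,
                                .data$education, .data$age_cat)) |>
    dplyr::arrange(.data$key)
  out
}

#' Greedy fractional allocation of the intervention budget
#'
#' Sorts subgroups by mean estimated risk (descending; ties broken by larger
#' `n_births`, then by the lexicographic unit/cell key), includes whole
#' subgroups while they fit in the budget, and gives the single marginal
#' subgroup a fractional inclusion so that total coverage equals the budget
#' exactly. With expected deaths of a fraction f of a group equal to f times
#' the group's expected deaths, this greedy rule attains the fractional
#' relaxation optimum.
#'
#' @param subgroups A [define_subgroups()] tibble (must partition the
#'   cohort).
#' @param budget_fraction Share of all births the plan may cover, in (0, 1).
#' @param n_total Cohort size N.
#' @param scenario Label stored on the plan.
#' @param mode `"fractional"` (default) includes the marginal subgroup
#'   partially so coverage is exact; `"stop_before"` only includes whole
#'   subgroups, stopping before the budget is exceeded.
#' @return A `targeting_plan`: the selected subgroups in rank order with
#'   their `inclusion_fraction`, plus `total_covered_fraction`.
#' @export
allocate <- function(subgroups, budget_fraction = 0.20, n_total = NULL,
                     scenario = "district",
                     mode = c("fractional", "stop_before")) {
  mode <- match.arg(mode)
  if (budget_fraction <= 0 || budget_fraction >= 1) {
    stop("budget_fraction must be strictly inside (0, 1)")
  }
  n_total <- n_total %||% sum(subgroups$n_births)
  ord <- order(-subgroups$mean_risk, -subgroups$n_births, subgroups$key)
  sg <- subgroups[ord, , drop = FALSE]

  budget_births <- budget_fraction * n_total
  cum <- cumsum(as.numeric(sg$n_births))
  full <- which(cum <= budget_births + 1e-9)
  n_full <- if (length(full)) max(full) else 0L
  used <- if (n_full) cum[n_full] else 0

  sel <- sg[seq_len(n_full), , drop = FALSE]
  frac <- rep(1, n_full)
  if (mode == "fractional" && n_full < nrow(sg) && budget_births - used > 1e-9) {
    marginal <- sg[n_full + 1L, , drop = FALSE]
    sel <- dplyr::bind_rows(sel, marginal)
    frac <- c(frac, (budget_births - used) / marginal$n_births)
  }
  sel$inclusion_fraction <- frac
  covered <- sum(sel$inclusion_fraction * sel$n_births) / n_total

  structure(
    list(scenario = scenario,
         budget_fraction = budget_fraction,
         mode = mode,
         selected = sel,
         total_covered_fraction = covered,
         n_total = n_total),
    class = "targeting_plan"
  )
}

#' Conventional single-factor baseline: target the poorest wealth quintile
#'
#' The plan contains exactly the births whose household wealth is in the
#' lowest quintile, each fully included. Its covered fraction is the
#' quintile's empirical share of births (near 20 percent by construction of
#' wealth quintiles, but not forced).
#'
#' @inheritParams define_subgroups
#' @return A `targeting_plan` with scenario `"poorest_quintile"`.
#' @export
baseline_poorest_quintile <- function(data, risks) {
  stopifnot("wealth" %in% names(data), nrow(data) == nrow(risks))
  cells <- define_subgroups(data, risks, scenario = "national")
  sel <- cells[cells$wealth == 1L, , drop = FALSE]
  sel$inclusion_fraction <- rep(1, nrow(sel))
  structure(
    list(scenario = "poorest_quintile",
         budget_fraction = NA_real_,
         mode = "whole_group",
         selected = sel,
         total_covered_fraction = sum(sel$n_births) / nrow(data),
         n_total = nrow(data)),
    class = "targeting_plan"
  )
}

#' @export
print.targeting_plan <- function(x, ...) {
  cat("<targeting_plan>", x$scenario, "\n")
  cat(sprintf("  %d subgroups selected; covered fraction %.4f",
              nrow(x$selected), x$total_covered_fraction))
  if (!is.na(x$budget_fraction)) {
    cat(sprintf(" (budget %.2f)", x$budget_fraction))
  }
  cat("\n")
  invisible(x)
}
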