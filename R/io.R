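COHORT_COLS <- c("district_id", "state_id", "wealth", "education",
                 "age_cat", "died")

#' Write a birth table to delimited text
#'
#' One row per birth, comma-separated with a header; the optional
#' `true_risk` column (synthetic cohorts) is preserved.
#'
#' @param cohort Birth table or `cohort_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  tab <- if (inherits(cohort, "cohort_sim")) cohort$cohort else cohort
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a birth table
#'
#' Checks the required columns, the declared level ranges of every factor,
#' the binary outcome, and that each district maps to exactly one state.
#' Each defect is reported with a distinct message naming the offending
#' column and first offending row.
#'
#' @param path Delimited text file written by [write_cohort()] (or any file
#'   with the same header).
#' @return A validated birth table (tibble).
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COHORT_COLS, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  ranges <- list(wealth = 1:5, education = 0:3, age_cat = 0:2, died = 0:1)
  for (col in names(ranges)) {
    bad <- which(!(tab[[col]] %in% ranges[[col]]))
    if (length(bad)) {
      stop(sprintf("out-of-range value in column '%s' at row %d: %s",
                   col, bad[1], tab[[col]][bad[1]]))
    }
  }
  for (col in c("district_id", "state_id")) {
    bad <- which(is.na(tab[[col]]) | tab[[col]] < 1 |
                   tab[[col]] != floor(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("column '%s' must hold positive integers; row %d is %s",
                   col, bad[1], tab[[col]][bad[1]]))
    }
  }
  map <- unique(tab[, c("district_id", "state_id")])
  dup <- map$district_id[duplicated(map$district_id)]
  if (length(dup)) {
    stop("inconsistent district-to-state map: district ", dup[1],
         " appears under more than one state")
  }
  for (col in c("district_id", "state_id", "wealth", "education",
                "age_cat", "died")) {
    tab[[col]] <- as.integer(tab[[col]])
  }
  tab
}

#' Write simulator ground-truth parameters as YAML
#'
#' Key-value companion file for a synthetic cohort: the calibrated
#' intercept, the district count and every active term's level effects.
#'
#' @param truth A `truth_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  obj <- list(
    intercept = truth$intercept,
    n_districts = truth$n_districts,
    term_effects = lapply(truth$term_effects, as.list)
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read ground-truth parameters written by [write_truth()]
#'
#' @param path YAML file path.
#' @return A `truth_params` object.
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  eff <- lapply(obj$term_effects, function(e) unlist(e))
  structure(
    list(intercept = obj$intercept, term_effects = eff,
         n_districts = obj$n_districts),
    class = "truth_params"
  )
}

# Flatten a targeting plan for on-disk reporting (drops the members column).
plan_table <- function(plan) {
  sel <- plan$selected
  tibble::tibble(
    scenario = plan$scenario,
    rank = seq_len(nrow(sel)),
    unit = sel$unit, wealth = sel$wealth, education = sel$education,
    age_cat = sel$age_cat, n_births = sel$n_births, n_deaths = sel$n_deaths,
    mean_risk = sel$mean_risk, inclusion_fraction = sel$inclusion_fraction
  )
}
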