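# Risk-factor metadata shared by the simulator and the model.
#
# The four risk factors are maternal age category, maternal education,
# household wealth quintile and district of birth. Demographic factors have
# fixed level sets; the district level set is cohort-specific.

RISK_FACTORS <- c("age", "education", "wealth", "district")

# data column holding each factor
factor_column <- function(factor) {
  switch(factor,
    age       = "age_cat",
    education = "education",
    wealth    = "wealth",
    district  = "district_id",
    stop("unknown risk factor: ", factor)
  )
}

# declared level sets for the demographic factors (district is per-cohort)
factor_levels <- function(factor, n_districts = NULL) {
  switch(factor,
    age       = 0:2,   # <18, 19-35, >35
    education = 0:3,   # none, primary, secondary, higher
    wealth    = 1:5,   # poorest .. richest quintile
    district  = seq_len(n_districts),
    stop("unknown risk factor: ", factor)
  )
}

#' Enumerate effect terms over a set of risk factors
#'
#' Returns every non-empty subset of `factors` (main effects and all
#' interactions), ordered by interaction order then factor position. With the
#' full four factors this yields the 15 terms of the risk model: 4 main
#' effects, 6 two-way, 4 three-way and 1 four-way interaction.
#'
#' @param factors Character vector drawn from
#'   `c("age", "education", "wealth", "district")`.
#' @return A list of character vectors, one per term; names are the term
#'   labels (factors joined by `:`).
#' @examples
#' length(enumerate_terms())  # 15
#' @export
enumerate_terms <- function(factors = RISK_FACTORS) {
  stopifnot(all(factors %in% RISK_FACTORS), !anyDuplicated(factors))
  factors <- RISK_FACTORS[RISK_FACTORS %in% factors]  # canonical order
  if (length(factors) == 0L) return(stats::setNames(list(), character()))
  combos <- unlist(
    lapply(seq_along(factors), function(k) {
      m <- utils::combn(factors, k, simplify = FALSE)
      m
    }),
    recursive = FALSE
  )
  stats::setNames(combos, vapply(combos, paste, "", collapse = ":"))
}

term_name <- function(factors) paste(factors, collapse = ":")

# Level key of each data row for a term: factor values joined by "/".
# Vectorised over rows of `data`.
term_keys <- function(data, factors) {
  cols <- vapply(factors, factor_column, "")
  do.call(paste, c(unname(as.list(data[cols])), sep = "/"))
}

# Full grid of level keys for a term (used by the simulator, which draws an
# effect for every theoretically possible level combination).
term_grid_keys <- function(factors, n_districts) {
  lv <- lapply(factors, factor_levels, n_districts = n_districts)
  g <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  do.call(paste, c(unname(as.list(g)), sep = "/"))
}
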