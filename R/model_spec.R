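#' Hyperprior on random-effect variances
#'
#' @param family `"half_cauchy"` places a half-Cauchy prior on the
#'   random-term standard deviation (weakly informative default);
#'   `"inv_gamma"` places an inverse-gamma prior on the variance, the
#'   convention of classical Gibbs samplers for variance components.
#' @param scale Half-Cauchy scale (on the standard deviation).
#' @param shape,rate Inverse-gamma parameters (on the variance).
#' @return A `variance_prior` list.
#' @export
variance_prior <- function(family = c("half_cauchy", "inv_gamma"),
                           scale = 2.5, shape = 0.001, rate = 0.001) {
  family <- match.arg(family)
  stopifnot(scale > 0, shape > 0, rate > 0)
  structure(list(family = family, scale = scale, shape = shape, rate = rate),
            class = "variance_prior")
}

#' Build the model specification from a birth table
#'
#' Enumerates the effect terms over the requested risk factors (all main
#' effects and interactions; 15 terms for the full four factors), counts the
#' distinct level combinations each term takes in `data`, and classifies a
#' term as a random effect when it has more than `threshold` observed unique
#' levels and as a fixed effect otherwise. Fixed-term coefficients receive
#' independent zero-mean Gaussian priors with a known variance; random-term
#' coefficients receive a zero-mean Gaussian prior whose variance is
#' estimated under `var_prior`.
#'
#' @param data Birth table with columns `age_cat`, `education`, `wealth`,
#'   `district_id` (plus `died` for fitting).
#' @param threshold Level-count cutoff for the fixed/random split.
#' @param factors Risk factors to include; defaults to all four. An empty
#'   vector gives an intercept-only specification.
#' @param fixed_prior_variance Prior variance (logit scale) of the intercept
#'   and fixed-term coefficients.
#' @param var_prior A [variance_prior()] for random-term variances.
#' @return A `model_spec` object: a tibble of terms (name, factors,
#'   `n_levels`, `kind`, observed level keys) plus the prior settings.
#' @export
build_model_spec <- function(data,
                             threshold = 20L,
                             factors = RISK_FACTORS,
                             fixed_prior_variance = 10,
                             var_prior = variance_prior()) {
  stopifnot(nrow(data) > 0, fixed_prior_variance > 0,
            inherits(var_prior, "variance_prior"))
  for (f in factors) {
    col <- factor_column(f)
    if (!col %in% names(data)) stop("data lacks required column: ", col)
    if (length(unique(data[[col]])) < 2L) {
      stop("degenerate cohort: factor '", f, "' has a single observed level")
    }
  }
  terms <- enumerate_terms(factors)
  rows <- lapply(names(terms), function(nm) {
    keys <- sort(unique(term_keys(data, terms[[nm]])))
    tibble::tibble(
      term = nm,
      factors = list(terms[[nm]]),
      n_levels = length(keys),
      kind = if (length(keys) > threshold) "random" else "fixed",
      level_keys = list(keys)
    )
  })
  spec_terms <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(term = character(), factors = list(), n_levels = integer(),
                   kind = character(), level_keys = list())
  structure(
    list(terms = spec_terms,
         link = "logit",
         threshold = as.integer(threshold),
         fixed_prior_variance = fixed_prior_variance,
         var_prior = var_prior),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> Bernoulli-logit hierarchical model\n")
  cat(sprintf("  %d terms (%d fixed, %d random; random when > %d levels)\n",
              nrow(x$terms), sum(x$terms$kind == "fixed"),
              sum(x$terms$kind == "random"), x$threshold))
  cat(sprintf("  fixed prior variance: %g; random-variance prior: %s\n",
              x$fixed_prior_variance, x$var_prior$family))
  if (nrow(x$terms)) {
    print(as.data.frame(x$terms[, c("term", "n_levels", "kind")]),
          row.names = FALSE)
  }
  invisible(x)
}
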