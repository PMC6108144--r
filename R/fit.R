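#' MCMC sampler settings
#'
#' @param n_chains Number of chains.
#' @param n_adapt Adaptation iterations for the sampler.
#' @param n_warmup Burn-in iterations discarded after adaptation.
#' @param n_iter Kept iterations per chain.
#' @param seed Seed controlling chain initialisation and sampling; the same
#'   seed reproduces the draws exactly.
#' @param quiet Suppress sampler progress output.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 4L, n_adapt = 1000L, n_warmup = 1000L,
                         n_iter = 1000L, seed = 1L, quiet = TRUE) {
  stopifnot(n_chains >= 1, n_iter >= 2)
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_warmup = as.integer(n_warmup), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "mcmc_control")
}

# Collapse unit records to binomial counts over the covariate cells spanned
# by the spec's terms (sufficient statistics for the Bernoulli-logit model).
collapse_cells <- function(spec, data) {
  cols <- unique(unlist(lapply(spec$terms$factors, function(f)
    vapply(f, factor_column, ""))))
  if (length(cols) == 0L) {
    return(tibble::tibble(y = sum(data$died), n = nrow(data)))
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(y = sum(.data$died), n = dplyr::n(), .groups = "drop")
}

# JAGS model code for the spec: logit(p) = b0 + sum over terms of the
# term's coefficient at the cell's level.
jags_code <- function(spec) {
  nt <- nrow(spec$terms)
  prec_fixed <- sprintf("%.17g", 1 / spec$fixed_prior_variance)
  lp <- if (nt) paste0(" + u", seq_len(nt), "[ix", seq_len(nt), "[c]]",
                       collapse = "") else ""
  lines <- c(
    "model {",
    "  for (c in 1:C) {",
    "    y[c] ~ dbin(p[c], n[c])",
    paste0("    logit(p[c]) <- b0", lp),
    "  }",
    paste0("  b0 ~ dnorm(0, ", prec_fixed, ")")
  )
  for (t in seq_len(nt)) {
    if (spec$terms$kind[t] == "fixed") {
      lines <- c(lines, sprintf(
        "  for (j in 1:L%d) { u%d[j] ~ dnorm(0, %s) }", t, t, prec_fixed))
    } else {
      lines <- c(lines, sprintf(
        "  for (j in 1:L%d) { u%d[j] ~ dnorm(0, tau%d) }", t, t, t))
      vp <- spec$var_prior
      if (vp$family == "half_cauchy") {
        lines <- c(lines,
          sprintf("  sigma%d ~ dt(0, %.17g, 1) T(0,)", t, 1 / vp$scale^2),
          sprintf("  tau%d <- pow(sigma%d, -2)", t, t))
      } else {
        lines <- c(lines,
          sprintf("  tau%d ~ dgamma(%.17g, %.17g)", t, vp$shape, vp$rate),
          sprintf("  sigma%d <- pow(tau%d, -0.5)", t, t))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Sample the posterior of the hierarchical risk model
#'
#' Fits the Bernoulli-logit model `logit(pi_i) = intercept + sum over terms
#' of effect[term, levels_i(term)]` by MCMC. The unit-level likelihood is
#' collapsed to binomial counts over covariate cells, which is an exact
#' reformulation. Fixed-term coefficients have independent Gaussian priors
#' with the spec's known variance; random-term coefficients share a
#' term-level variance drawn from the spec's hyperprior.
#'
#' @param spec A [build_model_spec()] result built from (a superset of) the
#'   levels in `data`.
#' @param data Birth table including the `died` outcome.
#' @param mcmc An [mcmc_control()].
#' @return An `elm_posterior`: stacked posterior draws for the intercept,
#'   every term's level coefficients and every random-term standard
#'   deviation, plus per-parameter split R-hat and effective sample size.
#'   Emits a warning (never an error) if any split R-hat exceeds 1.05, or
#'   if a fixed-term level is entirely deaths or entirely survivals
#'   (complete separation).
#' @export
fit_posterior <- function(spec, data, mcmc = mcmc_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_control"),
            "died" %in% names(data))
  cells <- collapse_cells(spec, data)
  warn_separation(spec, data)

  nt <- nrow(spec$terms)
  jdata <- list(C = nrow(cells), y = as.integer(cells$y), n = as.integer(cells$n))
  for (t in seq_len(nt)) {
    keys <- term_keys(cells, spec$terms$factors[[t]])
    idx <- match(keys, spec$terms$level_keys[[t]])
    if (anyNA(idx)) stop("data contain levels absent from the model spec ",
                         "for term '", spec$terms$term[t], "'")
    jdata[[paste0("ix", t)]] <- idx
    jdata[[paste0("L", t)]] <- spec$terms$n_levels[t]
  }

  chain_seeds <- derive_seeds(mcmc$seed, mcmc$n_chains)
  inits <- lapply(seq_len(mcmc$n_chains), function(k)
    list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = chain_seeds[k]))

  monitors <- c("b0",
                if (nt) paste0("u", seq_len(nt)),
                if (any(spec$terms$kind == "random"))
                  paste0("sigma", which(spec$terms$kind == "random")))

  jm <- rjags::jags.model(textConnection(jags_code(spec)), data = jdata,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = mcmc$quiet)
  if (mcmc$n_warmup > 0) {
    stats::update(jm, mcmc$n_warmup,
                  progress.bar = if (mcmc$quiet) "none" else "text")
  }
  samp <- rjags::coda.samples(jm, monitors, n.iter = mcmc$n_iter,
                              progress.bar = if (mcmc$quiet) "none" else "text")

  post <- build_posterior(spec, samp, mcmc)
  bad <- post$diagnostics$rhat[is.finite(post$diagnostics$rhat)]
  if (length(bad) && max(bad) > 1.05) {
    warning(sprintf(
      "possible non-convergence: max split R-hat = %.3f (threshold 1.05); ",
      max(bad)), "inspect $diagnostics and increase warmup or iterations",
      call. = FALSE)
  }
  post
}

warn_separation <- function(spec, data) {
  fixed <- which(spec$terms$kind == "fixed")
  seps <- character()
  for (t in fixed) {
    keys <- term_keys(data, spec$terms$factors[[t]])
    y <- tapply(data$died, keys, sum)
    n <- tapply(data$died, keys, length)
    if (any(y == 0 | y == n)) seps <- c(seps, spec$terms$term[t])
  }
  if (length(seps)) {
    warning("complete separation: fixed term(s) with an all-deaths or ",
            "all-survivals level: ", paste(seps, collapse = ", "),
            "; the Gaussian prior regularises these coefficients",
            call. = FALSE)
  }
  invisible(NULL)
}

# Reshape coda output into stacked draw matrices keyed by term.
build_posterior <- function(spec, samp, mcmc) {
  m <- as.matrix(samp)          # chains stacked row-wise
  nt <- nrow(spec$terms)
  u <- list(); sigma <- list()
  for (t in seq_len(nt)) {
    L <- spec$terms$n_levels[t]
    cn <- if (L == 1L) paste0("u", t) else paste0("u", t, "[", seq_len(L), "]")
    ut <- m[, cn, drop = FALSE]
    colnames(ut) <- spec$terms$level_keys[[t]]
    u[[spec$terms$term[t]]] <- ut
    if (spec$terms$kind[t] == "random") {
      sigma[[spec$terms$term[t]]] <- m[, paste0("sigma", t)]
    }
  }
  diag <- diagnostics_table(samp)
  structure(
    list(spec = spec,
         draws = list(b0 = m[, "b0"], u = u, sigma = sigma),
         n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
         n_warmup = mcmc$n_warmup,
         diagnostics = diag),
    class = "elm_posterior"
  )
}

# Split R-hat: each chain halved, then the classic between/within ratio.
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  x <- cbind(mat[seq_len(half), , drop = FALSE],
             mat[(n - half + 1L):n, , drop = FALSE])
  w <- mean(apply(x, 2, stats::var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- half * stats::var(colMeans(x))
  sqrt(((half - 1) / half * w + b / half) / w)
}

diagnostics_table <- function(samp) {
  params <- colnames(samp[[1]])
  rhat <- vapply(params, function(p) {
    split_rhat(sapply(samp, function(ch) as.numeric(ch[, p])))
  }, 0)
  ess <- coda::effectiveSize(samp)
  tibble::tibble(parameter = params, rhat = unname(rhat),
                 ess = unname(ess[params]))
}

#' @export
print.elm_posterior <- function(x, ...) {
  cat("<elm_posterior>\n")
  cat(sprintf("  %d terms, %d chains x %d kept draws\n",
              nrow(x$spec$terms), x$n_chains, x$n_iter))
  r <- x$diagnostics$rhat[is.finite(x$diagnostics$rhat)]
  if (length(r)) cat(sprintf("  max split R-hat: %.3f\n", max(r)))
  invisible(x)
}

# One-draw posterior from explicit coefficients (testing / degenerate use).
posterior_from_coefs <- function(spec, intercept, effects, sigma = list()) {
  u <- list()
  for (t in seq_len(nrow(spec$terms))) {
    nm <- spec$terms$term[t]
    keys <- spec$terms$level_keys[[t]]
    vals <- effects[[nm]] %||% stats::setNames(rep(0, length(keys)), keys)
    stopifnot(all(keys %in% names(vals)))
    u[[nm]] <- matrix(vals[keys], nrow = 1,
                      dimnames = list(NULL, keys))
  }
  structure(
    list(spec = spec,
         draws = list(b0 = intercept, u = u, sigma = sigma),
         n_chains = 1L, n_iter = 1L, n_warmup = 0L,
         diagnostics = tibble::tibble(parameter = character(),
                                      rhat = numeric(), ess = numeric())),
    class = "elm_posterior"
  )
}

#' Per-birth posterior risk estimates
#'
#' Applies the inverse logit to the linear predictor of every posterior draw
#' for every birth, then summarises: the posterior mean and the empirical
#' 2.5/97.5 percentile interval. A level combination unseen at fit time is
#' marginalised over its random term's fitted variance (a fresh standard
#' normal per unseen level, scaled by the term's posterior standard
#' deviation, seeded for reproducibility); an unseen level of a fixed term
#' is an error.
#'
#' @param posterior An `elm_posterior` from [fit_posterior()].
#' @param data Birth table to predict for (typically the training cohort).
#' @param seed Seed for the unseen-level marginalisation.
#' @return A `risk_estimates` tibble with one row per row of `data`:
#'   `posterior_mean`, `lower`, `upper`.
#' @export
predict_risk <- function(posterior, data, seed = 1L) {
  stopifnot(inherits(posterior, "elm_posterior"))
  spec <- posterior$spec
  nt <- nrow(spec$terms)
  cols <- unique(unlist(lapply(spec$terms$factors, function(f)
    vapply(f, factor_column, ""))))
  cell_key <- if (length(cols)) do.call(paste, c(unname(as.list(data[cols])),
                                                 sep = "|")) else rep("", nrow(data))
  cells_first <- !duplicated(cell_key)
  cells <- data[cells_first, , drop = FALSE]
  row_cell <- match(cell_key, cell_key[cells_first])

  S <- length(posterior$draws$b0)
  C <- nrow(cells)
  unseen_seeds <- derive_seeds(seed, max(nt, 1L))

  # Per-term cell indices into the fitted coefficient matrices; for unseen
  # levels of random terms, a draw matrix marginalising over the term's
  # fitted variance (one fresh standard normal per unseen level).
  term_idx <- vector("list", nt)
  term_new <- vector("list", nt)     # S x n_unseen draw matrix
  term_new_idx <- vector("list", nt) # cell -> unseen-column map (NA if seen)
  for (t in seq_len(nt)) {
    nm <- spec$terms$term[t]
    keys <- term_keys(cells, spec$terms$factors[[t]])
    idx <- match(keys, spec$terms$level_keys[[t]])
    if (anyNA(idx)) {
      if (spec$terms$kind[t] == "fixed") {
        stop("level combination '", keys[is.na(idx)][1], "' of fixed term '",
             nm, "' was not seen at fit time")
      }
      new_keys <- unique(keys[is.na(idx)])
      z <- with_seed(unseen_seeds[t],
                     matrix(rnorm(S * length(new_keys)), nrow = S))
      term_new[[t]] <- z * posterior$draws$sigma[[nm]]  # recycled down rows
      term_new_idx[[t]] <- match(keys, new_keys)
    }
    term_idx[[t]] <- idx
  }

  pm <- numeric(C); lo <- numeric(C); hi <- numeric(C)
  for (block in split(seq_len(C), ceiling(seq_len(C) / 4000))) {
    eta <- matrix(posterior$draws$b0, nrow = S, ncol = length(block))
    for (t in seq_len(nt)) {
      nm <- spec$terms$term[t]
      idx <- term_idx[[t]][block]
      seen <- !is.na(idx)
      if (any(seen)) {
        eta[, seen] <- eta[, seen] +
          posterior$draws$u[[nm]][, idx[seen], drop = FALSE]
      }
      if (any(!seen)) {
        eta[, !seen] <- eta[, !seen] +
          term_new[[t]][, term_new_idx[[t]][block][!seen], drop = FALSE]
      }
    }
    p <- plogis(eta)
    pm[block] <- colMeans(p)
    qs <- apply(p, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    lo[block] <- qs[1, ]; hi[block] <- qs[2, ]
  }
  out <- tibble::tibble(
    posterior_mean = pm[row_cell],
    lower = lo[row_cell],
    upper = hi[row_cell]
  )
  class(out) <- c("risk_estimates", class(out))
  out
}

#' Oracle risk estimates from simulator ground truth
#'
#' Wraps the simulator's `true_risk` column as a degenerate (point-mass)
#' `risk_estimates` object, so the targeting and evaluation stages can run
#' on known risks without any model fitting.
#'
#' @param x A `cohort_sim` or a birth table with a `true_risk` column.
#' @return A `risk_estimates` tibble.
#' @export
risk_from_truth <- function(x) {
  tab <- if (inherits(x, "cohort_sim")) x$cohort else x
  if (!"true_risk" %in% names(tab)) stop("no true_risk column available")
  out <- tibble::tibble(posterior_mean = tab$true_risk,
                        lower = tab$true_risk, upper = tab$true_risk)
  class(out) <- c("risk_estimates", class(out))
  out
}
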