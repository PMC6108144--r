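#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a simulation
#' configuration or a cohort file (exactly one), the model settings, the
#' targeting settings and an optional output directory.
#'
#' @param simulate A [cohort_config()] to generate the cohort, or `NULL`.
#' @param input Path to a cohort file readable by [read_cohort()], or
#'   `NULL`. Exactly one of `simulate`/`input` must be given.
#' @param threshold Fixed/random level-count cutoff for
#'   [build_model_spec()].
#' @param oracle If `TRUE`, skip model fitting and use the simulator's true
#'   risks as the estimates (requires a `true_risk` column); bounds the
#'   targeting and evaluation stages' runtime to seconds.
#' @param mcmc [mcmc_control()] used when fitting.
#' @param fixed_prior_variance,var_prior Prior settings for
#'   [build_model_spec()].
#' @param budget_fraction Intervention budget as a share of births.
#' @param scenarios Geographic constraint scenarios to run.
#' @param mode Marginal-subgroup handling for [allocate()].
#' @param out_dir Directory for on-disk artifacts, or `NULL` for none.
#' @param seed Seed for any stage not otherwise seeded.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, input = NULL,
                       threshold = 20L, oracle = FALSE,
                       mcmc = mcmc_control(),
                       fixed_prior_variance = 10,
                       var_prior = variance_prior(),
                       budget_fraction = 0.20,
                       scenarios = c("district", "state", "national"),
                       mode = "fractional",
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(input)) {
    stop("exactly one of 'simulate' and 'input' must be provided")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_config"))
  if (budget_fraction <= 0 || budget_fraction >= 1) {
    stop("budget_fraction must be strictly inside (0, 1)")
  }
  scenarios <- match.arg(scenarios, c("district", "state", "national"),
                         several.ok = TRUE)
  structure(
    list(simulate = simulate, input = input, threshold = as.integer(threshold),
         oracle = isTRUE(oracle), mcmc = mcmc,
         fixed_prior_variance = fixed_prior_variance, var_prior = var_prior,
         budget_fraction = budget_fraction, scenarios = scenarios,
         mode = mode, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Read a run configuration from a YAML file (CLI entry point).
#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `simulate` block
#' holds [cohort_config()] fields, the `mcmc` block [mcmc_control()] fields
#' and the `var_prior` block [variance_prior()] fields. A `simulate` block
#' equal to the string `"india"` expands to [default_india_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- if (identical(y$simulate, "india")) {
      default_india_config()
    } else {
      s <- y$simulate
      scales <- default_effect_scales()
      if (!is.null(s$effect_scales)) {
        ov <- unlist(s$effect_scales)
        scales[names(ov)] <- ov
      }
      cohort_config(
        n_births = s$n_births, n_states = s$n_states,
        n_districts = s$n_districts,
        factor_proportions = lapply(s$factor_proportions, unlist),
        baseline_mortality = s$baseline_mortality %||% 0.065,
        effect_scales = scales,
        seed = s$seed %||% (y$seed %||% 1L)
      )
    }
  }
  mc <- do.call(mcmc_control, y$mcmc %||% list())
  vp <- do.call(variance_prior, y$var_prior %||% list())
  run_config(
    simulate = sim, input = y$input,
    threshold = y$threshold %||% 20L, oracle = y$oracle %||% FALSE,
    mcmc = mc, fixed_prior_variance = y$fixed_prior_variance %||% 10,
    var_prior = vp, budget_fraction = y$budget_fraction %||% 0.20,
    scenarios = y$scenarios %||% c("district", "state", "national"),
    mode = y$mode %||% "fractional",
    out_dir = y$out_dir, seed = y$seed %||% 1L
  )
}

#' Run the full two-step targeting pipeline
#'
#' Simulate or read the cohort; build the model specification; fit the
#' posterior (or take the oracle risks); predict per-birth risk; define
#' subgroups and allocate the budget under each scenario; add the
#' poorest-quintile baseline; and evaluate everything. With an output
#' directory, writes the cohort, risk estimates, plans, district summary
#' and a capture-rate table, plus a run log; every file name is stable and
#' every run with the same configuration and seed reproduces the same
#' outputs.
#'
#' @param config A [run_config()].
#' @return An `evaluation_report`: `capture_table` (scenario, covered
#'   fraction, capture rate and expected capture, in percent),
#'   `exceedance`, `district_table`, the `plans`, the `risks`, the cohort
#'   and, for simulated cohorts, the ground truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  say("run starting; config hash ", cfg_hash)

  truth <- NULL
  if (!is.null(config$simulate)) {
    say("simulating cohort: ", config$simulate$n_births, " births, seed ",
        config$simulate$seed)
    sim <- generate_cohort(config$simulate)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    say("reading cohort from ", config$input)
    cohort <- read_cohort(config$input)
  }
  say(sprintf("cohort: %d births, %d deaths (rate %.4f), %d districts",
              nrow(cohort), sum(cohort$died), mean(cohort$died),
              length(unique(cohort$district_id))))

  posterior <- NULL
  if (config$oracle) {
    say("oracle mode: using simulator true risks as estimates")
    risks <- risk_from_truth(cohort)
  } else {
    say("building model spec (threshold ", config$threshold, ")")
    spec <- build_model_spec(cohort, threshold = config$threshold,
                             fixed_prior_variance = config$fixed_prior_variance,
                             var_prior = config$var_prior)
    say(sum(spec$terms$kind == "fixed"), " fixed and ",
        sum(spec$terms$kind == "random"), " random terms")
    say("sampling posterior: ", config$mcmc$n_chains, " chains x ",
        config$mcmc$n_iter, " kept draws (seed ", config$mcmc$seed, ")")
    posterior <- fit_posterior(spec, cohort, config$mcmc)
    r <- posterior$diagnostics$rhat
    say(sprintf("max split R-hat %.3f; min ESS %.0f",
                max(r[is.finite(r)]), min(posterior$diagnostics$ess)))
    risks <- predict_risk(posterior, cohort, seed = config$seed)
  }

  plans <- list()
  for (sc in config$scenarios) {
    sg <- define_subgroups(cohort, risks, scenario = sc)
    plans[[sc]] <- allocate(sg, config$budget_fraction,
                            n_total = nrow(cohort), scenario = sc,
                            mode = config$mode)
    say("scenario ", sc, ": ", nrow(sg), " subgroups, ",
        nrow(plans[[sc]]$selected), " selected")
  }
  plans[["poorest_quintile"]] <- baseline_poorest_quintile(cohort, risks)

  capture_table <- dplyr::bind_rows(lapply(names(plans), function(nm) {
    p <- plans[[nm]]
    tibble::tibble(
      scenario = nm,
      covered_fraction = p$total_covered_fraction,
      capture_pct = 100 * capture_rate(p, cohort),
      expected_capture_pct = 100 * expected_capture(p, risks)
    )
  }))
  say("capture table computed")

  exceedance <- tibble::tibble(
    statistic = c("richer_quintiles_above_poorest_mean",
                  "educated_above_no_education_mean"),
    share = c(exceedance_share(risks, cohort, "wealth", 1L),
              exceedance_share(risks, cohort, "education", 0L))
  )
  dt <- district_summary(risks, cohort,
                         plan = plans[[config$scenarios[1]]])

  report <- structure(
    list(capture_table = capture_table, exceedance = exceedance,
         district_table = dt, plans = plans, risks = risks,
         cohort = cohort, truth = truth, posterior = posterior,
         config_hash = cfg_hash,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "evaluation_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    stamp <- function(tab) dplyr::mutate(tab, config_hash = cfg_hash)
    if (!is.null(config$simulate)) {
      write_cohort(cohort, out("cohort.csv"))
      write_truth(truth, out("truth.yaml"))
    }
    readr::write_csv(stamp(dplyr::bind_cols(
      cohort[, intersect(names(cohort), COHORT_COLS)], risks)),
      out("risk_estimates.csv"), progress = FALSE)
    for (nm in names(plans)) {
      readr::write_csv(stamp(plan_table(plans[[nm]])),
                       out(paste0("plan_", nm, ".csv")), progress = FALSE)
    }
    readr::write_csv(stamp(capture_table), out("capture_table.csv"),
                     progress = FALSE)
    readr::write_csv(stamp(dt), out("district_summary.csv"), progress = FALSE)
    say("artifacts written to ", config$out_dir)
    writeLines(log_lines, out("run.log"))
  }
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  %d births; elapsed %.1fs; config %s\n",
              nrow(x$cohort), x$elapsed, x$config_hash))
  print(as.data.frame(x$capture_table), row.names = FALSE, digits = 4)
  invisible(x)
}
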