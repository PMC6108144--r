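test_that("capture rate counts deaths inside the plan, fractions pro rata", {
  # 10 births, 2 deaths; plan fully contains one death
  tab <- toy_table(rep(1, 10), 1, rep(1:5, 2), rep(0:3, length.out = 10),
                   rep(0:2, length.out = 10),
                   c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  plan <- structure(list(
    scenario = "manual", budget_fraction = 0.3, mode = "fractional",
    selected = tibble::tibble(
      unit = 1L, wealth = 1L, education = 0L, age_cat = 0L,
      n_births = 3L, n_deaths = 1L, mean_risk = 0.5,
      members = list(c(1L, 2L, 3L)), key = "k", inclusion_fraction = 1),
    total_covered_fraction = 0.3, n_total = 10L), class = "targeting_plan")
  expect_equal(capture_rate(plan, tab), 0.5)

  # fractional marginal group: (3 + 0.5 * 4) / 10
  tab2 <- toy_table(rep(1, 20), 1, rep(1:5, 4), rep(0:3, 5),
                    rep(0:2, length.out = 20),
                    c(rep(1, 3), rep(0, 5), rep(1, 4), rep(0, 4), 1, 1, 1, 0))
  expect_equal(sum(tab2$died), 10L)
  plan2 <- structure(list(
    scenario = "manual", budget_fraction = NA_real_, mode = "fractional",
    selected = tibble::tibble(
      unit = c(1L, 1L), wealth = 1L, education = 0L, age_cat = 0L,
      n_births = c(8L, 8L), n_deaths = c(3L, 4L), mean_risk = c(0.5, 0.4),
      members = list(1:8, 9:16), key = c("a", "b"),
      inclusion_fraction = c(1, 0.5)),
    total_covered_fraction = 0.6, n_total = 20L), class = "targeting_plan")
  expect_equal(capture_rate(plan2, tab2), (3 + 0.5 * 4) / 10)
})

test_that("whole-cohort plans capture everything; empty plans nothing", {
  sim <- generate_cohort(small_config(n_births = 500, seed = 91))
  risks <- risk_from_truth(sim)
  sg <- define_subgroups(sim$cohort, risks, "national")
  full <- structure(list(
    scenario = "all", budget_fraction = NA_real_, mode = "whole_group",
    selected = dplyr::mutate(sg, inclusion_fraction = 1),
    total_covered_fraction = 1, n_total = 500L), class = "targeting_plan")
  expect_equal(capture_rate(full, sim$cohort), 1)
  expect_equal(expected_capture(full, risks), 1)
  empty <- full
  empty$selected <- full$selected[0, ]
  empty$total_covered_fraction <- 0
  expect_equal(capture_rate(empty, sim$cohort), 0)
})

test_that("capture is additive over disjoint selected groups", {
  sim <- generate_cohort(small_config(n_births = 800, seed = 92))
  risks <- risk_from_truth(sim)
  sg <- define_subgroups(sim$cohort, risks, "national")
  sel <- dplyr::mutate(sg, inclusion_fraction = 1)
  mk <- function(rows) structure(list(
    scenario = "part", budget_fraction = NA_real_, mode = "whole_group",
    selected = sel[rows, ], total_covered_fraction = NA_real_,
    n_total = 800L), class = "targeting_plan")
  half1 <- seq_len(floor(nrow(sel) / 2))
  half2 <- setdiff(seq_len(nrow(sel)), half1)
  expect_equal(capture_rate(mk(half1), sim$cohort) +
                 capture_rate(mk(half2), sim$cohort),
               capture_rate(mk(seq_len(nrow(sel))), sim$cohort))
})

test_that("a cohort with zero deaths makes capture undefined", {
  tab <- toy_table(c(1, 1, 2), 1, c(1, 2, 3), c(0, 1, 2), c(0, 1, 2),
                   c(0, 0, 0))
  bl <- baseline_poorest_quintile(tab, risk_of(rep(0.1, 3)))
  expect_error(capture_rate(bl, tab), "zero deaths")
})

test_that("exceedance share matches hand enumeration on a toy cohort", {
  # six births: reference = wealth quintile 1 holds risks .10 and .06
  # (mean .08); outside risks .09, .07, .12, .02 -> 2 of 4 exceed .08
  tab <- toy_table(rep(1, 6), 1, c(1, 1, 2, 3, 4, 5), rep(0, 6),
                   rep(1, 6), rep(0, 6))
  risks <- risk_of(c(.10, .06, .09, .07, .12, .02))
  expect_equal(exceedance_share(risks, tab, "wealth", 1L), 0.5)
  # override with a published rounded reference mean
  expect_equal(exceedance_share(risks, tab, "wealth", 1L,
                                reference_mean = 0.06), 3 / 4)
})

test_that("exceedance share is zero at degenerate configurations", {
  tab <- toy_table(rep(1, 5), 1, c(1, 2, 3, 4, 5), rep(0, 5), rep(1, 5),
                   rep(0, 5))
  expect_equal(exceedance_share(risk_of(rep(0.07, 5)), tab, "wealth", 1L), 0)
  # reference group holds the single highest-risk birth
  risks <- risk_of(c(.5, .1, .2, .3, .4))
  expect_equal(exceedance_share(risks, tab, "wealth", 1L), 0)
})

test_that("exceedance share ignores how non-reference levels are labelled", {
  sim <- generate_cohort(small_config(n_births = 2000, seed = 93))
  risks <- risk_from_truth(sim)
  base <- exceedance_share(risks, sim$cohort, "wealth", 1L)
  relabelled <- sim$cohort
  map <- c(1L, 4L, 5L, 2L, 3L)  # permute quintiles 2..5, fix quintile 1
  relabelled$wealth <- map[relabelled$wealth]
  expect_equal(exceedance_share(risks, relabelled, "wealth", 1L), base)
})

test_that("exceedance errors on empty reference or complement", {
  tab <- toy_table(c(1, 1), 1, c(2, 3), c(0, 1), c(0, 1), c(0, 0))
  r <- risk_of(c(.1, .2))
  expect_error(exceedance_share(r, tab, "wealth", 1L), "reference group is empty")
  tab2 <- toy_table(c(1, 1), 1, c(1, 1), c(0, 1), c(0, 1), c(0, 0))
  expect_error(exceedance_share(r, tab2, "wealth", 1L), "complement")
})

test_that("district summaries match an independent aggregation", {
  tab <- toy_table(
    district = c(1, 1, 1, 2, 2, 3, 3, 3, 3),
    state    = c(1, 1, 1, 1, 1, 2, 2, 2, 2),
    wealth   = c(1, 1, 2, 3, 1, 5, 4, 1, 1),
    education= c(0, 1, 0, 2, 3, 1, 0, 0, 2),
    age      = c(0, 1, 2, 1, 1, 0, 1, 2, 1),
    died     = c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  )
  risks <- risk_of(c(.2, .1, .15, .05, .3, .02, .04, .25, .35))
  out <- district_summary(risks, tab)
  expect_equal(out$district_id, 1:3)
  # independent loop-based aggregation
  for (d in 1:3) {
    i <- tab$district_id == d
    row <- out[out$district_id == d, ]
    expect_equal(row$n_births, sum(i))
    expect_equal(row$death_rate, sum(tab$died[i]) / sum(i))
    expect_equal(row$poor_share, sum(tab$wealth[i] == 1) / sum(i))
    expect_equal(row$risk_q25, unname(quantile(risks$posterior_mean[i], .25)))
    expect_equal(row$risk_q50, unname(quantile(risks$posterior_mean[i], .50)))
    expect_equal(row$risk_q75, unname(quantile(risks$posterior_mean[i], .75)))
    expect_true(row$risk_q25 <= row$risk_q50 && row$risk_q50 <= row$risk_q75)
  }
})

test_that("single-district summaries reduce to cohort aggregates", {
  sim <- generate_cohort(small_config(n_births = 300, n_states = 1,
                                      n_districts = 1, seed = 94))
  risks <- risk_from_truth(sim)
  out <- district_summary(risks, sim$cohort)
  expect_equal(nrow(out), 1L)
  expect_equal(out$death_rate, mean(sim$cohort$died))
  all_poor <- sim$cohort
  all_poor$wealth <- 1L
  expect_equal(district_summary(risks, all_poor)$poor_share, 1)
})

test_that("district high-risk shares count fractional members by fraction", {
  sim <- generate_cohort(small_config(n_births = 1500, seed = 95))
  risks <- risk_from_truth(sim)
  plan <- allocate(define_subgroups(sim$cohort, risks, "district"), 0.2, 1500)
  out <- district_summary(risks, sim$cohort, plan)
  # weighted flags must aggregate to the covered fraction
  total_flagged <- sum(out$high_risk_share * out$n_births)
  expect_equal(total_flagged / 1500, plan$total_covered_fraction,
               tolerance = 1e-9)
})

test_that("census projections reproduce the published-scale arithmetic", {
  p <- project_counts(25642200, 0.044, 0.57, 0.30)
  expect_identical(p$implied_deaths, 1128257)
  expect_identical(p$captured_by_plan, 643106)
  expect_identical(p$captured_by_baseline, 338477)
  expect_lte(p$captured_by_plan, p$implied_deaths)
  z <- project_counts(5e6, 0, 0.5, 0.3)
  expect_identical(z$implied_deaths, 0)
  expect_identical(z$captured_by_plan, 0)
  expect_identical(z$captured_by_baseline, 0)
})

test_that("targeting on the true risks is an upper bound for expected capture", {
  for (seed in 1:10) {
    sim <- generate_cohort(small_config(n_births = 2000, seed = 700 + seed))
    truth_risks <- risk_from_truth(sim)
    noisy <- risk_of(plogis(qlogis(sim$cohort$true_risk) +
                              with_seed(seed, rnorm(2000, 0, 1))))
    cap <- function(r) {
      plan <- allocate(define_subgroups(sim$cohort, r, "district"), 0.2, 2000)
      # measure both plans against the true risks
      sum(vapply(seq_len(nrow(plan$selected)), function(i)
        plan$selected$inclusion_fraction[i] *
          sum(sim$cohort$true_risk[plan$selected$members[[i]]]), 0)) /
        sum(sim$cohort$true_risk)
    }
    expect_gte(cap(truth_risks) + 1e-12, cap(noisy))
    # and any greedy plan beats uniform coverage (= the budget share)
    expect_gte(cap(truth_risks) + 1e-12, 0.20)
  }
})
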