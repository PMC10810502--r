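# Simulator: determinism, truth consistency, analytic AUC, presets.

test_that("identical config and seed reproduce the cohort exactly", {
  config <- make_table1_preset("development", n = 200)
  a <- simulate_cohort(config, seed = 3)
  b <- simulate_cohort(config, seed = 3)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(config, seed = 4)
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("degenerate configurations behave exactly", {
  config <- simulation_config(n = 100, mortality = 0,
                              sign_prevalence = c(crt = 0.2, bcs = 0.3))
  sim <- simulate_cohort(config, seed = 1)
  expect_equal(sum(sim$cohort$outcome == "died"), 0)

  config2 <- simulation_config(n = 50, mortality = 0.2,
                               sign_prevalence = c(crt = 0.2, bcs = 0.3),
                               missingness = c(crt = 1))
  sim2 <- simulate_cohort(config2, seed = 1)
  expect_true(all(is.na(sim2$cohort$crt_seconds)))
})

test_that("emitted vitals are consistent with the latent sign truth", {
  config <- make_table1_preset("development", n = 400)
  config$missingness[] <- 0
  sim <- simulate_cohort(config, seed = 6)
  coh <- sim$cohort; tr <- sim$truth
  rr_thr <- lookup_cutoff(rr_p90_cutoffs(), coh$age_months)
  expect_identical(coh$respiratory_rate > rr_thr,
                   tr$respiratory_rate_abnormal)
  expect_identical(coh$crt_seconds > 3, tr$crt_abnormal)
  expect_identical(coh$bcs < 5, tr$bcs_abnormal)
  expect_identical(coh$pallor == "moderate-or-severe", tr$pallor_abnormal)
  expect_identical(coh$outcome == "died", tr$died)
  expect_true(all(coh$age_months >= 2 & coh$age_months < 192))
})

test_that("observed mortality stays within binomial error of the target", {
  config <- simulation_config(n = 10000, mortality = 0.15,
                              sign_prevalence = c(crt = 0.2))
  sim <- simulate_cohort(config, seed = 8)
  p_hat <- mean(sim$cohort$outcome == "died")
  se <- sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(p_hat - 0.15), 3 * se)
})

test_that("analytic AUC matches hand enumeration on discrete levels", {
  expect_equal(analytic_auc(c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 0)), 1)
  expect_equal(analytic_auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  # event (0.2, 0.8), non-event (0.8, 0.2): enumerate the 4 level pairs
  manual <- 0.2 * 0.8 * 0.5 + 0.8 * 0.8 + 0.8 * 0.2 * 0.5
  expect_equal(analytic_auc(c(0.2, 0.8), c(0.8, 0.2)), manual)
  expect_error(analytic_auc(c(1), c(0.5, 0.5)), "support")
})

test_that("score-distribution cohorts realise their conditional laws", {
  p_e <- c(0.05, 0.15, 0.3, 0.3, 0.2)
  p_n <- c(0.35, 0.3, 0.2, 0.1, 0.05)
  config <- simulation_config(n = 5000, model = "score-distribution",
                              mortality = 0.2, p_score_event = p_e,
                              p_score_nonevent = p_n)
  sim <- simulate_cohort(config, seed = 12)
  expect_equal(sim$truth$true_score,
               rowSums(sim$truth[, paste0(config$score_components,
                                          "_abnormal")]))
  # rescoring the emitted records recovers the drawn scores exactly
  sc <- score_cohort(sim$cohort, test_definition())
  expect_equal(sc$score, sim$truth$true_score)
})

test_that("zeroed severity slopes decouple the score from the outcome", {
  config <- simulation_config(
    n = 6000, mortality = 0.2,
    sign_prevalence = c(respiratory_rate = 0.11, crt = 0.16, bcs = 0.25,
                        pallor = 0.20),
    sign_slope = 0, mortality_slope = 1.2)
  sim <- simulate_cohort(config, seed = 13)
  auc <- empirical_auc(score_cohort(sim$cohort, test_definition()))
  expect_lt(abs(auc$auc - 0.5), 0.03)  # independence limit
})

test_that("preset marginals are recovered within sampling error", {
  config <- make_table1_preset("development", n = 8000)
  config$missingness[] <- 0
  sim <- simulate_cohort(config, seed = 14)
  tr <- sim$truth
  for (f in names(config$sign_prevalence)) {
    p <- config$sign_prevalence[[f]]
    se <- sqrt(p * (1 - p) / 8000)
    expect_lt(abs(mean(tr[[paste0(f, "_abnormal")]]) - p), 3.5 * se)
  }
})

test_that("MCAR exclusion rates match the combinatorial expectation", {
  rates <- c(respiratory_rate = 0.3, crt = 0.1, bcs = 0.05, pallor = 0.05)
  config <- simulation_config(
    n = 8000, mortality = 0.2,
    sign_prevalence = c(respiratory_rate = 0.11, crt = 0.16, bcs = 0.25,
                        pallor = 0.20),
    missingness = rates, missing_slope = 0)
  sim <- simulate_cohort(config, seed = 15)
  sc <- score_cohort(sim$cohort, test_definition())
  # P(>= 2 of 4 independent fields missing)
  q <- rates
  p0 <- prod(1 - q)
  p1 <- sum(vapply(seq_along(q), function(i) {
    q[i] * prod(1 - q[-i])
  }, numeric(1)))
  p_excl <- 1 - p0 - p1
  se <- sqrt(p_excl * (1 - p_excl) / 8000)
  expect_lt(abs(mean(sc$excluded) - p_excl), 3 * se)
})

test_that("severity-coupled missingness concentrates deaths in exclusions", {
  config <- make_table1_preset("development", n = 12000)
  config$missing_slope <- 0.8
  sim <- simulate_cohort(config, seed = 16)
  sc <- score_cohort(sim$cohort, test_definition())
  died <- sim$truth$died
  mort_excl <- mean(died[sc$excluded])
  mort_incl <- mean(died[!sc$excluded])
  expect_gt(mort_excl, mort_incl)
})

test_that("preset mortality rises with the score level", {
  sim <- simulate_cohort(make_table1_preset("development", n = 12000),
                         seed = 17)
  cal <- calibration_table(score_cohort(sim$cohort, bqsofa_definition()))
  filled <- cal[cal$n >= 30, ]
  expect_true(all(diff(filled$mortality) > 0))
})
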