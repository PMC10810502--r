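# Component predicates, the missing-data policy, and cohort scoring.

test_that("predicates use the strict comparison conventions", {
  rec <- list(id = "x", age_months = 24, respiratory_rate = 50,
              crt_seconds = 3, bcs = 5, pallor = "none",
              outcome = "survived")
  def <- test_definition()
  # RR cutoff at 24 months is 50: equal is normal, strictly above abnormal
  expect_equal(evaluate_component(rec, def$components$rr_high), "normal")
  rec$respiratory_rate <- 50.1
  expect_equal(evaluate_component(rec, def$components$rr_high), "abnormal")
  # CRT exactly 3 s is normal; 3.5 abnormal
  expect_equal(evaluate_component(rec, def$components$crt_long), "normal")
  rec$crt_seconds <- 3.5
  expect_equal(evaluate_component(rec, def$components$crt_long), "abnormal")
  # BCS 5 is normal, anything below abnormal
  expect_equal(evaluate_component(rec, def$components$bcs_low), "normal")
  rec$bcs <- 4
  expect_equal(evaluate_component(rec, def$components$bcs_low), "abnormal")
  # pallor level drives the flag
  expect_equal(evaluate_component(rec, def$components$pallor), "normal")
  rec$pallor <- "moderate-or-severe"
  expect_equal(evaluate_component(rec, def$components$pallor), "abnormal")
})

test_that("missing fields propagate to missing component status", {
  def <- test_definition()
  rec <- list(id = "x", age_months = 24, respiratory_rate = NA,
              crt_seconds = NA, crt_prolonged = NA, bcs = NA, pallor = NA,
              outcome = "survived")
  for (comp in def$components) {
    expect_equal(evaluate_component(rec, comp), "missing")
  }
  # age missing makes an age-adjusted vital unevaluable too
  rec2 <- list(id = "y", age_months = NA, respiratory_rate = 80,
               outcome = "survived")
  expect_equal(evaluate_component(rec2, def$components$rr_high), "missing")
})

test_that("CRT accepts seconds or the pre-coded flag, seconds first", {
  comp <- test_definition()$components$crt_long
  base <- list(id = "x", age_months = 24, outcome = "survived")
  expect_equal(evaluate_component(c(base, crt_prolonged = "yes"), comp),
               "abnormal")
  expect_equal(evaluate_component(c(base, crt_prolonged = "no"), comp),
               "normal")
  both <- c(base, list(crt_seconds = 2, crt_prolonged = "yes"))
  expect_equal(evaluate_component(both, comp), "normal")  # seconds win
})

test_that("compute_score applies the exclusion-then-assume policy in order", {
  def <- test_definition()
  all_abn <- list(id = "x", age_months = 24, respiratory_rate = 80,
                  crt_seconds = 5, bcs = 0, pallor = "moderate-or-severe",
                  outcome = "died")
  expect_equal(compute_score(all_abn, def)$value, 4)

  one_missing <- list(id = "x", age_months = 24, respiratory_rate = NA,
                      crt_seconds = 2, bcs = 5, pallor = "none",
                      outcome = "survived")
  r <- compute_score(one_missing, def)
  expect_equal(r$value, 0)                   # assumed normal
  expect_equal(r$n_missing_components, 1)
  r_abn <- compute_score(one_missing, def,
                         missing_policy(single_missing = "abnormal"))
  expect_equal(r_abn$value, 1)               # assumed abnormal

  two_missing <- list(id = "x", age_months = 24, respiratory_rate = NA,
                      crt_seconds = NA, bcs = 0,
                      pallor = "moderate-or-severe", outcome = "died")
  r2 <- compute_score(two_missing, def)
  expect_true(is.na(r2$value))
  expect_equal(r2$excluded_reason, "too-many-missing")

  # missing outcome is checked before component missingness
  no_outcome <- list(id = "x", age_months = 24, respiratory_rate = NA,
                     crt_seconds = NA, bcs = 0, pallor = "none",
                     outcome = NA)
  expect_equal(compute_score(no_outcome, def)$excluded_reason,
               "missing-outcome")
})

test_that("complete records score as the brute-force abnormal count", {
  def <- test_definition()
  coh <- test_cohort()
  sc <- score_cohort(coh, def)
  for (i in seq_len(nrow(coh))) {
    manual <- sum(vapply(def$components, function(comp) {
      evaluate_component(coh[i, ], comp) == "abnormal"
    }, logical(1)))
    expect_equal(sc$score[i], manual)
  }
  expect_equal(attr(sc, "included_fraction"), 1)
})

test_that("score_cohort logs exclusions and reports the included fraction", {
  def <- test_definition()
  raw <- as.data.frame(test_cohort())
  raw$respiratory_rate[1] <- NA; raw$crt_seconds[1] <- NA
  raw$outcome[2] <- NA
  sc <- score_cohort(cohort(raw), def)
  log <- attr(sc, "exclusion_log")
  expect_equal(nrow(log), 2)
  expect_setequal(log$excluded_reason, c("too-many-missing",
                                         "missing-outcome"))
  expect_equal(attr(sc, "included_fraction"), 4 / 6)
  # all outcomes missing -> everything excluded for that reason
  raw2 <- as.data.frame(test_cohort()); raw2$outcome <- NA
  sc2 <- score_cohort(cohort(raw2), def)
  expect_true(all(sc2$excluded_reason == "missing-outcome"))
})

test_that("score is monotone under single component flips", {
  def <- test_definition()
  set.seed(21)
  for (rep in 1:25) {
    rec <- list(id = "x", age_months = runif(1, 2, 191),
                respiratory_rate = runif(1, 20, 80),
                crt_seconds = runif(1, 1, 6),
                bcs = sample(0:5, 1),
                pallor = sample(c("none", "moderate-or-severe"), 1),
                outcome = "survived")
    base <- compute_score(rec, def)$value
    flipped <- rec
    flipped$respiratory_rate <- 200  # force RR abnormal
    flipped$crt_seconds <- max(rec$crt_seconds, 4)
    expect_gte(compute_score(flipped, def)$value, base)
  }
})

test_that("assume-abnormal never scores below assume-normal", {
  def <- test_definition()
  set.seed(22)
  for (rep in 1:25) {
    rec <- list(id = "x", age_months = runif(1, 2, 191),
                respiratory_rate =
                  if (runif(1) < 0.5) NA else runif(1, 20, 80),
                crt_seconds = if (runif(1) < 0.5) NA else runif(1, 1, 6),
                bcs = sample(0:5, 1),
                pallor = "none", outcome = "survived")
    a <- compute_score(rec, def, missing_policy(3, "normal"))
    b <- compute_score(rec, def, missing_policy(3, "abnormal"))
    if (!is.na(a$value) && !is.na(b$value)) expect_gte(b$value, a$value)
  }
})

test_that("scoring is deterministic", {
  def <- test_definition()
  sim <- simulate_cohort(make_table1_preset("development", n = 120),
                         seed = 5)
  expect_identical(score_cohort(sim$cohort, def),
                   score_cohort(sim$cohort, def))
})

test_that("integer weights multiply a component's contribution", {
  def <- score_definition("weighted", list(
    score_component("bcs_low", "bcs-below", weight = 2),
    score_component("pallor", "flag-present", field = "pallor")))
  expect_equal(def$max_score, 3)
  rec <- list(id = "x", age_months = 24, bcs = 1,
              pallor = "moderate-or-severe", outcome = "died")
  expect_equal(compute_score(rec, def)$value, 3)
})

test_that("score configs round-trip through YAML with policy block", {
  def <- test_definition()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_config(def, path, policy = missing_policy(2, "abnormal"))
  back <- read_score_config(path)
  expect_true(definitions_equal(def, back))
  expect_equal(attr(back, "policy")$single_missing, "abnormal")
})
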