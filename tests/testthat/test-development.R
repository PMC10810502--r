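# Univariate screening, candidate amendments, and the stepwise engine.

test_that("screening flags a perfectly prognostic predictor via Fisher", {
  raw <- data.frame(
    id = as.character(1:12), age_months = 24,
    pallor = c(rep("moderate-or-severe", 4), rep("none", 8)),
    outcome = c(rep("died", 4), rep("survived", 8)),
    stringsAsFactors = FALSE)
  tab <- univariate_screen(
    cohort(raw),
    list(score_component("pallor", "flag-present", field = "pallor")))
  expect_equal(tab$test, "fisher")
  expect_equal(tab$p_value,
               fisher_p_by_enumeration(matrix(c(4, 0, 0, 8), 2,
                                              byrow = TRUE)),
               tolerance = 1e-9)
  expect_true(tab$significant)
  expect_equal(tab$abnormal_died, 4)
  expect_equal(tab$normal_survived, 8)
})

test_that("an outcome-independent predictor is rarely significant", {
  # type-I error check: identical conditional prevalence by construction
  set.seed(51)
  hits <- 0
  for (rep in 1:100) {
    n <- 400
    raw <- data.frame(
      id = as.character(1:n), age_months = 24,
      poor_nutrition = sample(c("yes", "no"), n, TRUE, prob = c(0.3, 0.7)),
      outcome = sample(c("died", "survived"), n, TRUE,
                       prob = c(0.2, 0.8)),
      stringsAsFactors = FALSE)
    tab <- univariate_screen(
      cohort(raw),
      list(score_component("mal", "flag-present",
                           field = "poor_nutrition")))
    if (isTRUE(tab$significant)) hits <- hits + 1
  }
  expect_lte(hits, 10)  # nominal alpha = 0.05 over 100 replicates
})

test_that("a predictor missing everywhere is reported untestable", {
  raw <- data.frame(id = c("a", "b"), age_months = 24,
                    dehydration = NA_character_,
                    outcome = c("died", "survived"),
                    stringsAsFactors = FALSE)
  tab <- univariate_screen(
    cohort(raw),
    list(score_component("dehydr", "flag-present", field = "dehydration")))
  expect_true(tab$untestable)
  expect_true(is.na(tab$p_value))
})

test_that("modifications apply structurally and reject the inapplicable", {
  def <- test_definition()
  sub <- apply_modification(def, substitute_cutoff("rr_high",
                                                   test_rr_table(c(80, 70, 60))))
  expect_equal(sub$components$rr_high$cutoffs$bands$threshold, c(80, 70, 60))
  rem <- apply_modification(def, remove_component("rr_high"))
  expect_null(rem$components$rr_high)
  expect_equal(rem$max_score, 3)
  add <- apply_modification(rem, add_component(
    score_component("dehydr", "flag-present", field = "dehydration")))
  expect_equal(add$max_score, 4)
  expect_error(apply_modification(def, remove_component("nope")), "nope")
  expect_error(apply_modification(def, add_component(
    score_component("pallor", "flag-present", field = "pallor"))),
    "already exists")
  expect_error(apply_modification(def, substitute_cutoff(
    "crt_long", test_rr_table())), "no cutoff table")
})

test_that("removing an always-normal component changes nothing", {
  raw <- as.data.frame(test_cohort())
  raw$respiratory_rate <- 20  # RR normal for every child
  coh <- cohort(raw)
  step <- evaluate_modification(test_definition(),
                                remove_component("rr_high"), coh,
                                nri_cutoffs = c(1, 2))
  expect_equal(step$auc$auc, step$baseline_auc$auc)
  expect_equal(step$nri[["1"]]$nri, 0)
  expect_equal(step$nri[["2"]]$nri, 0)
})

test_that("adding an oracle predictor yields AUC 1 and is accepted", {
  raw <- as.data.frame(test_cohort())
  # a flag identical to the outcome, via a passthrough column
  raw$oracle <- ifelse(raw$outcome == "died", "yes", "no")
  coh <- cohort(raw)
  base <- score_definition("tiny", list(
    score_component("crt_long", "crt-prolonged")))
  trace <- stepwise_develop(
    base,
    list(add_component(score_component("oracle", "flag-present",
                                       field = "oracle", weight = 3))),
    coh, nri_cutoffs = c(0))
  expect_true(trace$steps[[1]]$accepted)
  expect_equal(empirical_auc(score_cohort(coh, trace$final))$auc, 1)
})

test_that("raising a cutoff never raises any child's score", {
  sim <- simulate_cohort(make_table1_preset("development", n = 300),
                         seed = 9)
  def <- test_definition()
  higher <- apply_modification(def, substitute_cutoff(
    "rr_high", test_rr_table(c(75, 65, 55))))
  s_old <- score_cohort(sim$cohort, def)
  s_new <- score_cohort(sim$cohort, higher)
  both <- !s_old$excluded & !s_new$excluded
  expect_true(all(s_new$score[both] <= s_old$score[both]))
})

test_that("the stepwise trace chains accepted baselines deterministically", {
  sim <- simulate_cohort(make_table1_preset("development", n = 400),
                         seed = 10)
  lq <- lqsofa_definition()
  t1 <- stepwise_develop(lq, bqsofa_development_sequence(), sim$cohort)
  t2 <- stepwise_develop(lq, bqsofa_development_sequence(), sim$cohort)
  expect_identical(summary(t1), summary(t2))
  current <- lq
  for (s in t1$steps) {
    if (s$accepted) {
      current <- s$definition
    }
  }
  expect_true(definitions_equal(current, t1$final))
  # empty candidate list: trace of length 0, baseline unchanged
  t0 <- stepwise_develop(lq, list(), sim$cohort)
  expect_length(t0$steps, 0)
  expect_true(definitions_equal(t0$final, lq))
})

test_that("replaying the recorded amendment sequence reproduces BqSOFA", {
  final <- Reduce(apply_modification, bqsofa_development_sequence(),
                  lqsofa_definition())
  expect_true(definitions_equal(final, bqsofa_definition()))
  expect_equal(final$max_score, 4)
})
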