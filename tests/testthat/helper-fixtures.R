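# Fixtures are built in code. Score definitions used by unit tests rely on
# synthetic cutoff tables so nothing depends on the shipped (editable)
# threshold transcriptions.

# one synthetic three-band RR table and a matching four-component score
test_rr_table <- function(thresholds = c(60, 50, 40)) {
  cutoff_table("respiratory_rate",
               data.frame(lower = c(2, 12, 60), upper = c(12, 60, 192),
                          threshold = thresholds))
}

test_hr_table <- function(thresholds = c(180, 160, 140)) {
  cutoff_table("heart_rate",
               data.frame(lower = c(2, 12, 60), upper = c(12, 60, 192),
                          threshold = thresholds))
}

test_definition <- function() {
  score_definition("test-score", list(
    score_component("rr_high", "vital-above-cutoff",
                    cutoffs = test_rr_table()),
    score_component("crt_long", "crt-prolonged", threshold_seconds = 3),
    score_component("bcs_low", "bcs-below", value = 5),
    score_component("pallor", "flag-present", field = "pallor")))
}

# a fully observed 6-record cohort with known component pattern
test_cohort <- function() {
  cohort(data.frame(
    id = paste0("c", 1:6),
    age_months = c(6, 24, 100, 30, 8, 70),
    respiratory_rate = c(70, 30, 45, 52, 55, 39),  # abn, n, abn, abn, n, n
    crt_seconds = c(4, 2, 3, 5, 1, 2),             # abn, n, n, abn, n, n
    bcs = c(5, 5, 2, 3, 5, 5),                     # n, n, abn, abn, n, n
    pallor = c("none", "none", "moderate-or-severe",
               "moderate-or-severe", "none", "none"),
    outcome = c("survived", "survived", "died", "died", "survived",
                "survived"),
    stringsAsFactors = FALSE))
}

# wrap raw score/outcome vectors in a scored_cohort container for metric
# tests that do not need the scoring engine
fake_scored <- function(score, outcome, max_score = max(score),
                        id = NULL, definition = "fake") {
  n <- length(score)
  out <- data.frame(id = id %||% paste0("r", seq_len(n)),
                    score = as.integer(score), n_missing = 0L,
                    excluded = FALSE, excluded_reason = NA_character_,
                    outcome = as.integer(outcome),
                    stringsAsFactors = FALSE)
  structure(out, class = c("scored_cohort", "data.frame"),
            definition = definition, max_score = as.integer(max_score),
            included_fraction = 1,
            exclusion_log = out[0, c("id", "excluded_reason", "n_missing")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent AUC oracle: exhaustive event/non-event pair enumeration
auc_by_enumeration <- function(score, outcome) {
  ev <- score[outcome == 1]; ne <- score[outcome == 0]
  total <- 0
  for (e in ev) for (s in ne) {
    total <- total + (e > s) + 0.5 * (e == s)
  }
  total / (length(ev) * length(ne))
}

# random discrete-score cohort guaranteed to contain both outcomes
random_score_outcome <- function(n, max_score = 4) {
  repeat {
    score <- sample(0:max_score, n, replace = TRUE)
    outcome <- stats::rbinom(n, 1, 0.3)
    if (any(outcome == 1) && any(outcome == 0)) {
      return(list(score = score, outcome = outcome))
    }
  }
}

# two-sided Fisher p by hypergeometric enumeration over fixed margins
fisher_p_by_enumeration <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
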