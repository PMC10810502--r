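# Comparing classifiers: binary net reclassification index, univariate
# association tests, and the assume-normal vs assume-abnormal sensitivity
# analysis for missing components.

#' Binary net reclassification index
#'
#' Quantifies how reclassification at one binary cutoff per score changes
#' when moving from an old score to a new one, on the records included under
#' both. The event component is P(reclassified negative-to-positive | died)
#' minus P(positive-to-negative | died); the non-event component is the
#' mirror image among survivors; the NRI is their sum, reported in percent.
#' For one cutoff per score this equals the change in sensitivity plus the
#' change in specificity. The confidence interval is the asymptotic normal
#' one, with the two components' multinomial variances summed:
#' \eqn{var = [p_{up,e}+p_{down,e}-(p_{up,e}-p_{down,e})^2]/n_e +
#'            [p_{up,s}+p_{down,s}-(p_{down,s}-p_{up,s})^2]/n_s}.
#'
#' @param old,new \code{\link{scored_cohort}}s over the same record ids with
#'   identical outcomes.
#' @param old_cutoff,new_cutoff Integer cutoffs for each score.
#' @param old_semantics,new_semantics \code{"ge"} or \code{"gt"} per score.
#' @param level Confidence level.
#' @return A list of class \code{"nri_result"}: \code{nri}, \code{ci_low},
#'   \code{ci_high} (percent), \code{event_component},
#'   \code{nonevent_component} (proportions), counts, and the cutoffs used.
#' @export
nri_binary <- function(old, new, old_cutoff, new_cutoff,
                       old_semantics = c("gt", "ge"),
                       new_semantics = c("gt", "ge"), level = 0.95) {
  old_semantics <- match.arg(old_semantics)
  new_semantics <- match.arg(new_semantics)
  so <- .included(old); sn <- .included(new)
  common <- intersect(so$id, sn$id)
  if (!length(common)) stop("no records included under both scores")
  so <- so[match(common, so$id), ]; sn <- sn[match(common, sn$id), ]
  if (!identical(so$outcome, sn$outcome)) {
    stop("outcome mismatch between the two scored cohorts on shared ids")
  }
  pos_old <- .positives(so$score, old_cutoff, old_semantics)
  pos_new <- .positives(sn$score, new_cutoff, new_semantics)
  ev <- so$outcome == 1
  n_e <- sum(ev); n_s <- sum(!ev)
  if (n_e == 0 || n_s == 0) {
    stop("degenerate cohort: need deaths and survivors included under both")
  }
  up <- !pos_old & pos_new; down <- pos_old & !pos_new
  p_up_e <- sum(up & ev) / n_e;    p_down_e <- sum(down & ev) / n_e
  p_up_s <- sum(up & !ev) / n_s;   p_down_s <- sum(down & !ev) / n_s
  ev_comp <- p_up_e - p_down_e
  ne_comp <- p_down_s - p_up_s
  nri <- ev_comp + ne_comp
  var_e <- (p_up_e + p_down_e - ev_comp^2) / n_e
  var_s <- (p_down_s + p_up_s - ne_comp^2) / n_s
  se <- sqrt(var_e + var_s)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(nri = 100 * nri,
                 ci_low = 100 * (nri - z * se),
                 ci_high = 100 * (nri + z * se),
                 event_component = ev_comp,
                 nonevent_component = ne_comp,
                 n_events = n_e, n_nonevents = n_s,
                 old_cutoff = old_cutoff, old_semantics = old_semantics,
                 new_cutoff = new_cutoff, new_semantics = new_semantics,
                 level = level),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI %.2f%% (%g%%-CI %.2f-%.2f) [events %+.3f, non-events %+.3f]\n",
    x$nri, 100 * x$level, x$ci_low, x$ci_high,
    x$event_component, x$nonevent_component))
  invisible(x)
}

#' Crude association between a binary sign and outcome
#'
#' Tests a 2x2 table of sign (abnormal/normal) by outcome (died/survived)
#' with Pearson's chi-square (no continuity correction) or, when any
#' expected cell count is below 5, Fisher's exact test (two-sided).
#' Significance is flagged at the two-sided 0.05 level.
#'
#' @param table A 2x2 matrix of counts, rows = sign abnormal/normal,
#'   columns = died/survived.
#' @param alpha Significance level.
#' @return A list of class \code{"association_result"}: \code{counts},
#'   \code{test} (\code{"chi-square"} or \code{"fisher"}), \code{p_value},
#'   \code{significant}.
#' @export
association_test <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("undefined test: 2x2 table has an empty row or column margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    test <- "fisher"
    p <- stats::fisher.test(table)$p.value
  } else {
    test <- "chi-square"
    p <- stats::chisq.test(table, correct = FALSE)$p.value
  }
  structure(list(counts = table, test = test, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g%s\n", x$test, x$p_value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Sensitivity analysis of the assume-normal convention
#'
#' Scores the cohort twice, once treating tolerated missing components as
#' normal and once as abnormal (everything else identical), and reports both
#' AUCs with confidence intervals and their difference. A small difference
#' relative to the interval width indicates the missing-data convention does
#' not drive the discrimination result.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param definition A \code{\link{score_definition}}.
#' @param level Confidence level.
#' @param exclusion_threshold Passed to both policies.
#' @param ci_method AUC CI method.
#' @return A list of class \code{"missingness_sensitivity"} with
#'   \code{assume_normal}, \code{assume_abnormal} (both
#'   \code{\link{empirical_auc}} results) and \code{difference}
#'   (abnormal minus normal).
#' @export
missingness_sensitivity <- function(cohort, definition, level = 0.95,
                                    exclusion_threshold = 2L,
                                    ci_method = "delong") {
  a_norm <- empirical_auc(
    score_cohort(cohort, definition,
                 missing_policy(exclusion_threshold, "normal")),
    level = level, ci_method = ci_method)
  a_abn <- empirical_auc(
    score_cohort(cohort, definition,
                 missing_policy(exclusion_threshold, "abnormal")),
    level = level, ci_method = ci_method)
  structure(list(assume_normal = a_norm, assume_abnormal = a_abn,
                 difference = a_abn$auc - a_norm$auc),
            class = "missingness_sensitivity")
}

#' @export
print.missingness_sensitivity <- function(x, ...) {
  cat("missing components assumed normal:   "); print(x$assume_normal)
  cat("missing components assumed abnormal: "); print(x$assume_abnormal)
  cat(sprintf("difference (abnormal - normal): %+.4f\n", x$difference))
  invisible(x)
}
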