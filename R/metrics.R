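# Prognostic-performance statistics on scored cohorts.
#
# All discrimination metrics operate on the included records only.  Scores
# take few discrete values, so AUC uses the Mann-Whitney convention with
# half credit for ties, and the DeLong variance (which is tie-aware) is the
# default confidence-interval method.

#' Binomial proportion confidence interval
#'
#' Clopper-Pearson exact intervals (default; conservative and defensible
#' for the small event counts typical of mortality cohorts) or Wilson score
#' intervals.
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level.
#' @param method \code{"clopper-pearson"} or \code{"wilson"}.
#' @return A list of class \code{"metric_ci"} with \code{estimate},
#'   \code{ci_low}, \code{ci_high}, \code{level}, \code{method}.
#' @export
proportion_ci <- function(x, n, level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 0, x >= 0, x <= n)
  if (n == 0) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, level = level, method = method,
                          x = x, n = n), class = "metric_ci"))
  }
  p <- x / n
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  }
  structure(list(estimate = p, ci_low = lo, ci_high = hi, level = level,
                 method = method, x = x, n = n), class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%.3f (%g%%-CI %.3f-%.3f, %s)\n", x$estimate, 100 * x$level,
              x$ci_low, x$ci_high, x$method))
  invisible(x)
}

.positives <- function(score, cutoff, semantics) {
  if (semantics == "ge") score >= cutoff else score > cutoff
}

#' Cross-tabulate score positivity against outcome
#'
#' Dichotomises the score at a cutoff and tabulates against in-hospital
#' outcome. Both cutoff conventions in routine use are supported:
#' \code{"ge"} (score >= cutoff positive, as printed for LqSOFA) and
#' \code{"gt"} (score > cutoff positive, as printed for BqSOFA and
#' FEAST-PET). Every report carries the semantics used.
#'
#' @param scored A \code{\link{scored_cohort}}.
#' @param cutoff Integer cutoff.
#' @param semantics \code{"ge"} or \code{"gt"}.
#' @return A list of class \code{"confusion_table"} with \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}, \code{cutoff}, \code{semantics}.
#' @export
confusion_at_cutoff <- function(scored, cutoff, semantics = c("ge", "gt")) {
  semantics <- match.arg(semantics)
  s <- .included(scored)
  pos <- .positives(s$score, cutoff, semantics)
  structure(list(tp = sum(pos & s$outcome == 1),
                 fp = sum(pos & s$outcome == 0),
                 tn = sum(!pos & s$outcome == 0),
                 fn = sum(!pos & s$outcome == 1),
                 cutoff = cutoff, semantics = semantics),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion at score %s %d: tp %d fp %d tn %d fn %d>\n",
              if (x$semantics == "ge") ">=" else ">", x$cutoff,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classification metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' confusion table, each with a binomial confidence interval. A metric with
#' a zero denominator (e.g. PPV when nothing tests positive) is reported as
#' undefined (\code{NA}), never as 0.
#'
#' @param ct A \code{\link{confusion_at_cutoff}} result.
#' @param level Confidence level.
#' @param method CI method, see \code{\link{proportion_ci}}.
#' @return A list of class \code{"classification_metrics"} with elements
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv} (each a
#'   \code{metric_ci}) plus the cutoff and semantics.
#' @export
classification_metrics <- function(ct, level = 0.95,
                                   method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "confusion_table"))
  structure(list(
    sensitivity = proportion_ci(ct$tp, ct$tp + ct$fn, level, method),
    specificity = proportion_ci(ct$tn, ct$tn + ct$fp, level, method),
    ppv = proportion_ci(ct$tp, ct$tp + ct$fp, level, method),
    npv = proportion_ci(ct$tn, ct$tn + ct$fn, level, method),
    cutoff = ct$cutoff, semantics = ct$semantics),
    class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("score %s %d:\n", if (x$semantics == "ge") ">=" else ">",
              x$cutoff))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-11s ", m)); print(x[[m]])
  }
  invisible(x)
}

# Mann-Whitney AUC with half credit for ties, plus per-observation
# placements used by the DeLong variance.
.auc_core <- function(events, nonevents) {
  n1 <- length(events); n0 <- length(nonevents)
  # placements via the rank trick: O((n0+n1) log n)
  all <- c(events, nonevents)
  r <- rank(all, ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # V10_i = P-hat(event_i beats a random non-event), via ranks within groups
  r1 <- rank(events, ties.method = "average")
  r0 <- rank(nonevents, ties.method = "average")
  v10 <- (r[seq_len(n1)] - r1) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - r0) / n1
  list(auc = auc, v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' Empirical AUC of a scored cohort
#'
#' The probability that a randomly chosen child who died scores higher than
#' a randomly chosen survivor, with ties given half credit -- the
#' Mann-Whitney functional, essential for scores taking five or fewer
#' discrete values. Confidence intervals by DeLong's distribution-free
#' variance (default) or the Hanley-McNeil approximation, truncated to
#' [0, 1].
#'
#' @param scored A \code{\link{scored_cohort}}, or a list/data.frame with
#'   numeric \code{score} and 0/1 \code{outcome} vectors.
#' @param level Confidence level.
#' @param ci_method \code{"delong"} or \code{"hanley-mcneil"}.
#' @return A list of class \code{"auc_result"}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, \code{se}, \code{n_events}, \code{n_nonevents},
#'   \code{ci_method}.
#' @export
empirical_auc <- function(scored, level = 0.95,
                          ci_method = c("delong", "hanley-mcneil")) {
  ci_method <- match.arg(ci_method)
  if (inherits(scored, "scored_cohort")) {
    s <- .included(scored)
    score <- s$score; outcome <- s$outcome
  } else {
    score <- scored$score; outcome <- scored$outcome
    keep <- !is.na(score) & !is.na(outcome)
    score <- score[keep]; outcome <- outcome[keep]
    if (sum(outcome == 1) == 0 || sum(outcome == 0) == 0) {
      stop("degenerate cohort: need at least one death and one survivor")
    }
  }
  core <- .auc_core(score[outcome == 1], score[outcome == 0])
  a <- core$auc
  if (ci_method == "delong") {
    var_a <- 0
    if (core$n1 > 1) var_a <- var_a + stats::var(core$v10) / core$n1
    if (core$n0 > 1) var_a <- var_a + stats::var(core$v01) / core$n0
  } else {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    var_a <- (a * (1 - a) + (core$n1 - 1) * (q1 - a^2) +
                (core$n0 - 1) * (q2 - a^2)) / (core$n1 * core$n0)
    var_a <- max(var_a, 0)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(var_a)
  structure(list(auc = a, ci_low = max(0, a - z * se),
                 ci_high = min(1, a + z * se), se = se,
                 n_events = core$n1, n_nonevents = core$n0,
                 level = level, ci_method = ci_method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%%-CI %.3f-%.3f, %s; %d deaths, %d survivors)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$ci_method,
              x$n_events, x$n_nonevents))
  invisible(x)
}

#' Observed mortality by score level
#'
#' The calibration summary used for bedside scores: for every attainable
#' integer score level 0..max, the number of children at that level, the
#' number who died, and the mortality proportion (\code{NA} at empty
#' levels). Levels with no children are reported explicitly.
#'
#' @param scored A \code{\link{scored_cohort}}.
#' @return A data.frame of class \code{"calibration_table"} with columns
#'   \code{score}, \code{n}, \code{deaths}, \code{mortality}.
#' @export
calibration_table <- function(scored) {
  s <- .included(scored, require_both_classes = FALSE)
  levels <- 0:attr(scored, "max_score")
  n <- vapply(levels, function(l) sum(s$score == l), integer(1))
  deaths <- vapply(levels, function(l) sum(s$score == l & s$outcome == 1),
                   integer(1))
  out <- data.frame(score = levels, n = n, deaths = deaths,
                    mortality = ifelse(n > 0, deaths / n, NA_real_))
  class(out) <- c("calibration_table", "data.frame")
  out
}
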