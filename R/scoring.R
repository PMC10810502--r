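# Scoring engine: evaluates components over records, applies the
# missing-data policy, and produces per-record results plus an exclusion
# log at cohort level.
#
# Missing-data policy, in order:
#   1. records with missing outcome are excluded (missing-outcome);
#   2. records with >= exclusion_threshold missing components are excluded
#      (too-many-missing; threshold 2 by default, i.e. "two or more");
#   3. remaining missing components score 0 (assume-normal, default) or
#      their weight (assume-abnormal, the sensitivity-analysis variant).

#' Missing-data policy for scoring
#'
#' @param exclusion_threshold Exclude a record when at least this many score
#'   components are missing (default 2).
#' @param single_missing How a tolerated missing component contributes:
#'   \code{"normal"} scores it 0 (default); \code{"abnormal"} scores its
#'   weight. The abnormal variant exists for sensitivity analysis of the
#'   assume-normal convention.
#' @return An object of class \code{"missing_policy"}.
#' @export
missing_policy <- function(exclusion_threshold = 2L,
                           single_missing = c("normal", "abnormal")) {
  single_missing <- match.arg(single_missing)
  stopifnot(exclusion_threshold >= 1)
  structure(list(exclusion_threshold = as.integer(exclusion_threshold),
                 single_missing = single_missing),
            class = "missing_policy")
}

.flag_abnormal_levels <- c("yes", "moderate-or-severe")
.flag_normal_levels   <- c("no", "none")

# vectorised component evaluation over a cohort data.frame;
# returns a character vector in {"normal","abnormal","missing"}
.evaluate_component_vec <- function(data, comp) {
  res <- switch(comp$predicate,
    "vital-above-cutoff" = {
      val <- data[[comp$variable]]
      age <- data$age_months
      out <- rep(NA, nrow(data))
      ok <- !is.na(val) & !is.na(age)
      if (any(ok)) {
        thr <- lookup_cutoff(comp$cutoffs, age[ok])
        out[ok] <- val[ok] > thr
      }
      out
    },
    "crt-prolonged" = {
      sec <- data$crt_seconds
      flag <- data$crt_prolonged
      out <- rep(NA, nrow(data))
      use_flag <- is.na(sec) & !is.na(flag)
      out[!is.na(sec)] <- sec[!is.na(sec)] > comp$threshold_seconds
      out[use_flag] <- flag[use_flag] == "yes"
      out
    },
    "bcs-below" = data$bcs < comp$value,
    "flag-present" = {
      f <- comp$field
      if (is.null(data[[f]])) {
        stop(sprintf("cohort has no column '%s' for component '%s'",
                     f, comp$name))
      }
      val <- data[[f]]
      known <- is.na(val) | val %in% c(.flag_abnormal_levels,
                                       .flag_normal_levels)
      if (!all(known)) {
        stop(sprintf("component '%s': unknown level '%s' in field '%s'",
                     comp$name, val[!known][1], f))
      }
      ifelse(is.na(val), NA, val %in% .flag_abnormal_levels)
    })
  ifelse(is.na(res), "missing", ifelse(res, "abnormal", "normal"))
}

#' Evaluate one score component on one record
#'
#' @param record A single patient record: a one-row \code{\link{cohort}} (or
#'   data.frame) or a named list of fields.
#' @param component A \code{\link{score_component}}.
#' @return \code{"normal"}, \code{"abnormal"} or \code{"missing"}. The
#'   result is missing exactly when an underlying field (including the age,
#'   for age-adjusted vitals) is missing.
#' @export
evaluate_component <- function(record, component) {
  stopifnot(inherits(component, "score_component"))
  rec <- .as_record_df(record)
  .evaluate_component_vec(rec, component)[1]
}

.as_record_df <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    if (!inherits(record, "cohort")) record <- cohort(record, validate = FALSE)
    record
  } else {
    cohort(as.data.frame(record, stringsAsFactors = FALSE), validate = FALSE)
  }
}

# component-status matrix (records x components) for a cohort
.component_matrix <- function(data, definition) {
  m <- vapply(definition$components, function(comp) {
    .evaluate_component_vec(data, comp)
  }, character(nrow(data)))
  if (nrow(data) == 1) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, names(definition$components)))
  m
}

.score_from_matrix <- function(status, definition, policy, outcome) {
  w <- vapply(definition$components, `[[`, integer(1), "weight")
  n_missing <- rowSums(status == "missing")
  abnormal <- status == "abnormal"
  if (policy$single_missing == "abnormal") {
    abnormal <- abnormal | status == "missing"
  }
  value <- as.integer(abnormal %*% w)
  excluded_reason <- rep(NA_character_, nrow(status))
  excluded_reason[n_missing >= policy$exclusion_threshold] <- "too-many-missing"
  excluded_reason[is.na(outcome)] <- "missing-outcome"  # takes precedence
  value[!is.na(excluded_reason)] <- NA_integer_
  list(value = value, n_missing = as.integer(n_missing),
       excluded_reason = excluded_reason)
}

#' Score a single record
#'
#' Applies the missing-data policy to one record: exclusion for missing
#' outcome first, then for too many missing components; otherwise the score
#' is the weighted sum over abnormal components, with tolerated missing
#' components contributing per the policy.
#'
#' @param record A single record (see \code{\link{evaluate_component}}).
#' @param definition A \code{\link{score_definition}}.
#' @param policy A \code{\link{missing_policy}}.
#' @return A list of class \code{"score_result"} with \code{record_id},
#'   \code{value} (integer or \code{NA} when excluded),
#'   \code{n_missing_components} and \code{excluded_reason} (\code{NA},
#'   \code{"too-many-missing"} or \code{"missing-outcome"}).
#' @export
compute_score <- function(record, definition, policy = missing_policy()) {
  rec <- .as_record_df(record)
  status <- .component_matrix(rec, definition)
  outcome <- .outcome01(rec$outcome)
  r <- .score_from_matrix(status, definition, policy, outcome)
  structure(list(record_id = rec$id[1], value = r$value[1],
                 n_missing_components = r$n_missing[1],
                 excluded_reason = r$excluded_reason[1]),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  if (is.na(x$excluded_reason)) {
    cat(sprintf("<score %d (record %s, %d missing component%s)>\n",
                x$value, x$record_id, x$n_missing_components,
                if (x$n_missing_components == 1) "" else "s"))
  } else {
    cat(sprintf("<record %s excluded: %s>\n", x$record_id,
                x$excluded_reason))
  }
  invisible(x)
}

.outcome01 <- function(outcome) {
  ifelse(is.na(outcome), NA_integer_,
         ifelse(outcome == "died", 1L, 0L))
}

#' Score a whole cohort
#'
#' Applies \code{\link{compute_score}} to every record (vectorised), keeping
#' row order, and reports the exclusion log and included fraction.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param definition A \code{\link{score_definition}}.
#' @param policy A \code{\link{missing_policy}}.
#' @return An object of class \code{"scored_cohort"}: a data.frame with
#'   columns \code{id}, \code{score}, \code{n_missing}, \code{excluded},
#'   \code{excluded_reason}, \code{outcome} (0/1, \code{NA} when missing),
#'   with attributes \code{definition} (its name), \code{max_score},
#'   \code{included_fraction} and \code{exclusion_log}.
#' @export
score_cohort <- function(cohort, definition, policy = missing_policy()) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(definition, "score_definition"),
            inherits(policy, "missing_policy"))
  outcome <- .outcome01(cohort$outcome)
  if (nrow(cohort)) {
    status <- .component_matrix(cohort, definition)
    r <- .score_from_matrix(status, definition, policy, outcome)
  } else {
    r <- list(value = integer(), n_missing = integer(),
              excluded_reason = character())
  }
  out <- data.frame(id = cohort$id, score = r$value,
                    n_missing = r$n_missing,
                    excluded = !is.na(r$excluded_reason),
                    excluded_reason = r$excluded_reason,
                    outcome = outcome,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("scored_cohort", "data.frame"),
            definition = definition$name,
            max_score = definition$max_score,
            policy = policy,
            included_fraction = if (nrow(out)) mean(!out$excluded) else NA_real_,
            exclusion_log = out[out$excluded,
                                c("id", "excluded_reason", "n_missing")])
}

#' @export
print.scored_cohort <- function(x, ...) {
  n <- nrow(x); inc <- sum(!x$excluded)
  cat(sprintf("<scored cohort: %s, %d/%d included (%.1f%%), max score %d>\n",
              attr(x, "definition"), inc, n,
              100 * attr(x, "included_fraction"), attr(x, "max_score")))
  invisible(x)
}

# included score / outcome vectors, checking the cohort is usable for
# discrimination metrics
.included <- function(scored, require_both_classes = TRUE) {
  stopifnot(inherits(scored, "scored_cohort"))
  s <- scored[!scored$excluded, , drop = FALSE]
  if (require_both_classes &&
      (sum(s$outcome == 1) == 0 || sum(s$outcome == 0) == 0)) {
    stop("degenerate cohort: need at least one death and one survivor ",
         "among included records")
  }
  s
}
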