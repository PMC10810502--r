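# Score-development workflow: univariate predictor screening, then
# stepwise substitute / remove / add amendments evaluated by AUC and NRI.
#
# The engine is sequential-greedy: candidates are tried in order against
# the current baseline, and an accepted candidate becomes the next
# baseline. Each amendment rescores the cohort from scratch, re-applying
# the missing-data policy to the new component set (different component
# sets give different exclusion patterns).

#' Univariate screening of candidate predictors
#'
#' For each candidate binary predictor, evaluates it across the cohort,
#' drops records with a missing predictor value or missing outcome
#' (pairwise deletion), and tests the resulting abnormal/normal by
#' died/survived table with \code{\link{association_test}}. Predictors with
#' no evaluable 2x2 table (fewer than two evaluable records, or an empty
#' margin) are reported as untestable rather than dropped.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param predictors List of \code{\link{score_component}}s to screen.
#' @param alpha Two-sided significance level.
#' @return A data.frame of class \code{"screening_table"}: one row per
#'   predictor with the four cell counts
#'   (\code{abnormal_died}, \code{abnormal_survived}, \code{normal_died},
#'   \code{normal_survived}), mortality among abnormal and normal,
#'   \code{test}, \code{p_value}, \code{significant}, \code{untestable}.
#' @export
univariate_screen <- function(cohort, predictors, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"), length(predictors) >= 1)
  outcome <- .outcome01(cohort$outcome)
  rows <- lapply(predictors, function(comp) {
    status <- .evaluate_component_vec(cohort, comp)
    keep <- status != "missing" & !is.na(outcome)
    ab <- status[keep] == "abnormal"; died <- outcome[keep] == 1
    cnt <- c(abnormal_died = sum(ab & died),
             abnormal_survived = sum(ab & !died),
             normal_died = sum(!ab & died),
             normal_survived = sum(!ab & !died))
    tab <- matrix(cnt, 2, 2, byrow = TRUE)
    res <- if (sum(keep) < 2 || any(rowSums(tab) == 0) ||
               any(colSums(tab) == 0)) {
      list(test = NA_character_, p_value = NA_real_, significant = NA,
           untestable = TRUE)
    } else {
      at <- association_test(tab, alpha)
      list(test = at$test, p_value = at$p_value,
           significant = at$significant, untestable = FALSE)
    }
    data.frame(predictor = comp$name,
               abnormal_died = cnt[[1]], abnormal_survived = cnt[[2]],
               normal_died = cnt[[3]], normal_survived = cnt[[4]],
               mortality_abnormal =
                 if (sum(ab) > 0) mean(died[ab]) else NA_real_,
               mortality_normal =
                 if (sum(!ab) > 0) mean(died[!ab]) else NA_real_,
               test = res$test, p_value = res$p_value,
               significant = res$significant, untestable = res$untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_table", "data.frame")
  out
}

#' Describe a candidate score amendment
#'
#' Three kinds of amendment are supported, matching how bedside scores are
#' amended in practice: replacing a component's age-banded cutoff table
#' (\code{substitute_cutoff}), dropping a component
#' (\code{remove_component}), and adding a new one (\code{add_component}).
#'
#' @param component Component name (substitute/remove) or a
#'   \code{\link{score_component}} (add).
#' @param new_cutoffs A \code{\link{cutoff_table}} (substitute).
#' @param label Human-readable label for the development trace; a default
#'   is built from the arguments.
#' @return An object of class \code{"score_modification"}.
#' @name modifications
#' @export
substitute_cutoff <- function(component, new_cutoffs, label = NULL) {
  stopifnot(is.character(component), inherits(new_cutoffs, "cutoff_table"))
  structure(list(kind = "substitute-cutoff", component = component,
                 new_cutoffs = new_cutoffs,
                 label = label %||% paste0("substitute cutoffs of ",
                                           component)),
            class = "score_modification")
}

#' @rdname modifications
#' @export
remove_component <- function(component, label = NULL) {
  stopifnot(is.character(component))
  structure(list(kind = "remove-component", component = component,
                 label = label %||% paste0("remove ", component)),
            class = "score_modification")
}

#' @rdname modifications
#' @export
add_component <- function(component, label = NULL) {
  stopifnot(inherits(component, "score_component"))
  structure(list(kind = "add-component", component = component,
                 label = label %||% paste0("add ", component$name)),
            class = "score_modification")
}

#' Apply a modification to a score definition
#'
#' @param definition A \code{\link{score_definition}}.
#' @param mod A \code{\link{modifications}} object.
#' @return The amended \code{\link{score_definition}}. Inapplicable
#'   modifications (unknown component to substitute/remove, adding an
#'   existing name, removing the last component) raise an error.
#' @export
apply_modification <- function(definition, mod) {
  stopifnot(inherits(definition, "score_definition"),
            inherits(mod, "score_modification"))
  comps <- definition$components
  if (mod$kind == "substitute-cutoff") {
    if (is.null(comps[[mod$component]])) {
      stop("cannot substitute cutoffs: no component named '",
           mod$component, "'")
    }
    comp <- comps[[mod$component]]
    if (comp$predicate != "vital-above-cutoff") {
      stop("component '", mod$component, "' has no cutoff table")
    }
    if (mod$new_cutoffs$variable != comp$variable) {
      stop("replacement cutoff table is for ", mod$new_cutoffs$variable,
           ", component measures ", comp$variable)
    }
    comp$cutoffs <- mod$new_cutoffs
    comps[[mod$component]] <- comp
  } else if (mod$kind == "remove-component") {
    if (is.null(comps[[mod$component]])) {
      stop("cannot remove: no component named '", mod$component, "'")
    }
    if (length(comps) == 1) stop("cannot remove the last component")
    comps[[mod$component]] <- NULL
  } else {
    if (!is.null(comps[[mod$component$name]])) {
      stop("cannot add: component '", mod$component$name,
           "' already exists")
    }
    comps <- c(comps, list(mod$component))
  }
  score_definition(definition$name, unname(comps))
}

#' Evaluate one candidate amendment
#'
#' Applies the modification, rescores the cohort under the amended
#' definition (the missing-data policy is re-applied, since the component
#' set may have changed), and reports the new AUC together with the NRI
#' versus the baseline at each requested cutoff.
#'
#' @param baseline Baseline \code{\link{score_definition}}.
#' @param mod A \code{\link{modifications}} object.
#' @param cohort A \code{\link{cohort}}.
#' @param policy A \code{\link{missing_policy}}.
#' @param nri_cutoffs Integer cutoffs at which NRI vs baseline is computed;
#'   the first is the primary cutoff used by the default acceptance rule.
#' @param semantics Cutoff semantics used for all NRIs.
#' @param level Confidence level.
#' @return A list of class \code{"development_step"}: \code{label},
#'   \code{definition} (amended), \code{auc} (an
#'   \code{\link{empirical_auc}} result), \code{baseline_auc}, \code{nri}
#'   (named list of \code{\link{nri_binary}} results keyed by cutoff) and
#'   \code{accepted} (\code{NA} until a stepwise rule decides).
#' @export
evaluate_modification <- function(baseline, mod, cohort,
                                  policy = missing_policy(),
                                  nri_cutoffs = c(1, 2),
                                  semantics = "gt", level = 0.95) {
  amended <- apply_modification(baseline, mod)
  scored_old <- score_cohort(cohort, baseline, policy)
  scored_new <- score_cohort(cohort, amended, policy)
  nri <- lapply(nri_cutoffs, function(k) {
    nri_binary(scored_old, scored_new, old_cutoff = k, new_cutoff = k,
               old_semantics = semantics, new_semantics = semantics,
               level = level)
  })
  names(nri) <- as.character(nri_cutoffs)
  structure(list(label = mod$label, modification = mod,
                 definition = amended,
                 auc = empirical_auc(scored_new, level = level),
                 baseline_auc = empirical_auc(scored_old, level = level),
                 nri = nri, accepted = NA),
            class = "development_step")
}

#' @export
print.development_step <- function(x, ...) {
  cat(sprintf("step '%s'%s\n", x$label,
              if (is.na(x$accepted)) "" else
                if (x$accepted) " [accepted]" else " [rejected]"))
  cat(sprintf("  AUC %.3f (baseline %.3f)\n", x$auc$auc, x$baseline_auc$auc))
  for (k in names(x$nri)) {
    cat(sprintf("  NRI at >%s: %.2f%%\n", k, x$nri[[k]]$nri))
  }
  invisible(x)
}

#' Default step-acceptance rule
#'
#' Accept an amendment when it increases the AUC or has a positive NRI at
#' the primary cutoff. Any function of a \code{development_step} returning
#' a single logical can be used in its place.
#'
#' @param step A \code{"development_step"}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
accept_if_improves <- function(step) {
  primary <- step$nri[[1]]
  isTRUE(step$auc$auc > step$baseline_auc$auc) || isTRUE(primary$nri > 0)
}

#' Stepwise score development
#'
#' Evaluates candidate amendments in order. In \code{"chained"} mode
#' (default) an accepted candidate's definition becomes the baseline for
#' the next candidate; in \code{"fixed-baseline"} mode every candidate is
#' compared against the original baseline and the last accepted candidate
#' wins (useful when several alternative additions are screened against one
#' intermediate score). The full trace is returned whether steps were
#' accepted or not, so the development history is auditable.
#'
#' @param baseline Starting \code{\link{score_definition}}.
#' @param candidates List of \code{\link{modifications}} objects, in the
#'   order they are to be tried.
#' @param cohort A \code{\link{cohort}}.
#' @param policy A \code{\link{missing_policy}}.
#' @param nri_cutoffs,semantics,level Passed to
#'   \code{\link{evaluate_modification}}.
#' @param accept Acceptance rule; see \code{\link{accept_if_improves}}.
#' @param mode \code{"chained"} or \code{"fixed-baseline"}.
#' @return A list of class \code{"development_trace"} with \code{steps}
#'   (each a decided \code{development_step}) and \code{final} (the
#'   definition after all accepted amendments).
#' @export
stepwise_develop <- function(baseline, candidates, cohort,
                             policy = missing_policy(),
                             nri_cutoffs = c(1, 2), semantics = "gt",
                             level = 0.95, accept = accept_if_improves,
                             mode = c("chained", "fixed-baseline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "score_definition"))
  current <- baseline
  steps <- list()
  for (mod in candidates) {
    base_for_step <- if (mode == "chained") current else baseline
    step <- evaluate_modification(base_for_step, mod, cohort, policy,
                                  nri_cutoffs, semantics, level)
    step$accepted <- isTRUE(accept(step))
    steps[[length(steps) + 1]] <- step
    if (step$accepted) current <- step$definition
  }
  structure(list(steps = steps, baseline = baseline, final = current,
                 mode = mode),
            class = "development_trace")
}

#' @export
print.development_trace <- function(x, ...) {
  cat(sprintf("<development trace: %d candidate(s), %s mode>\n",
              length(x$steps), x$mode))
  for (s in x$steps) print(s)
  cat(sprintf("final score: '%s' with %d components\n",
              x$final$name, length(x$final$components)))
  invisible(x)
}

#' Summarise a development trace as a table
#'
#' @param object A \code{"development_trace"}.
#' @param ... Unused.
#' @return A data.frame with one row per candidate: label, AUC, baseline
#'   AUC, NRI at each cutoff, accepted flag.
#' @export
summary.development_trace <- function(object, ...) {
  rows <- lapply(object$steps, function(s) {
    nri <- vapply(s$nri, `[[`, numeric(1), "nri")
    names(nri) <- paste0("nri_gt", names(s$nri))
    cbind(data.frame(label = s$label, auc = s$auc$auc,
                     baseline_auc = s$baseline_auc$auc,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(nri)),
          data.frame(accepted = s$accepted))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
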