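# Declarative score definitions: named binary components, each a predicate
# over a patient record that evaluates to normal / abnormal / missing.
# All comparison conventions are strict: vitals abnormal strictly above the
# age cutoff, CRT abnormal strictly above the threshold in seconds, BCS
# abnormal strictly below the stated value.

.predicate_kinds <- c("vital-above-cutoff", "crt-prolonged", "bcs-below",
                      "flag-present")

#' Define a score component
#'
#' A component is a named binary predicate over a patient record with an
#' integer weight (1 for all qSOFA-family scores; larger weights support
#' multi-point scores such as FEAST-PET). Four predicate kinds exist:
#' \describe{
#'   \item{\code{vital-above-cutoff}}{abnormal when the vital (\code{variable})
#'     is strictly above its age-banded cutoff (\code{cutoffs}, a
#'     \code{\link{cutoff_table}}); missing when the vital or the age is
#'     missing.}
#'   \item{\code{crt-prolonged}}{abnormal when capillary refill time is
#'     strictly greater than \code{threshold_seconds} (default 3, the WHO
#'     ETAT shock convention). Accepts either measured \code{crt_seconds} or
#'     the pre-coded \code{crt_prolonged} flag; seconds take precedence when
#'     both are present.}
#'   \item{\code{bcs-below}}{abnormal when the Blantyre Coma Score is
#'     strictly below \code{value} (default 5).}
#'   \item{\code{flag-present}}{abnormal when the categorical \code{field}
#'     equals \code{"yes"} or \code{"moderate-or-severe"}; normal for
#'     \code{"no"}/\code{"none"}.}
#' }
#'
#' @param name Unique component name.
#' @param predicate One of the kinds above.
#' @param weight Positive integer contribution when abnormal.
#' @param variable,cutoffs For \code{vital-above-cutoff}.
#' @param threshold_seconds For \code{crt-prolonged}.
#' @param value For \code{bcs-below}.
#' @param field For \code{flag-present}; any categorical column of the
#'   cohort, including passthrough columns.
#' @return An object of class \code{"score_component"}.
#' @export
score_component <- function(name, predicate, weight = 1L,
                            variable = NULL, cutoffs = NULL,
                            threshold_seconds = 3, value = 5, field = NULL) {
  predicate <- match.arg(predicate, .predicate_kinds)
  stopifnot(is.character(name), nchar(name) > 0,
            weight >= 1, weight == round(weight))
  params <- switch(predicate,
    "vital-above-cutoff" = {
      stopifnot(inherits(cutoffs, "cutoff_table"))
      if (is.null(variable)) variable <- cutoffs$variable
      stopifnot(variable %in% c("heart_rate", "respiratory_rate"))
      list(variable = variable, cutoffs = cutoffs)
    },
    "crt-prolonged" = list(threshold_seconds = as.numeric(threshold_seconds)),
    "bcs-below" = list(value = as.numeric(value)),
    "flag-present" = {
      stopifnot(is.character(field))
      list(field = field)
    }
  )
  structure(c(list(name = name, predicate = predicate,
                   weight = as.integer(weight)), params),
            class = "score_component")
}

#' @export
print.score_component <- function(x, ...) {
  desc <- switch(x$predicate,
    "vital-above-cutoff" = sprintf("%s > age-banded cutoff", x$variable),
    "crt-prolonged" = sprintf("CRT > %g s", x$threshold_seconds),
    "bcs-below" = sprintf("BCS < %g", x$value),
    "flag-present" = sprintf("%s present", x$field))
  cat(sprintf("<component '%s': %s, weight %d>\n", x$name, desc, x$weight))
  invisible(x)
}

#' Define a composite score
#'
#' @param name Score name (e.g. \code{"LqSOFA"}).
#' @param components List of \code{\link{score_component}}s with unique
#'   names. The maximum score is the sum of the weights.
#' @return An object of class \code{"score_definition"}.
#' @export
score_definition <- function(name, components) {
  stopifnot(is.character(name), length(components) >= 1,
            all(vapply(components, inherits, logical(1), "score_component")))
  nms <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate component names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(components) <- nms
  structure(list(name = name, components = components,
                 max_score = sum(vapply(components, `[[`, integer(1),
                                        "weight"))),
            class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score '%s': %d components, max %d>\n",
              x$name, length(x$components), x$max_score))
  for (comp in x$components) print(comp)
  invisible(x)
}

#' Test two score definitions for structural equality
#'
#' Definitions are equal when they hold the same components in the same
#' order, with identical predicate kinds, parameters (cutoff bands compared
#' numerically), and weights. Score display names are not compared.
#'
#' @param a,b \code{\link{score_definition}}s.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
definitions_equal <- function(a, b) {
  stopifnot(inherits(a, "score_definition"), inherits(b, "score_definition"))
  if (length(a$components) != length(b$components)) return(FALSE)
  for (i in seq_along(a$components)) {
    ca <- a$components[[i]]; cb <- b$components[[i]]
    if (ca$name != cb$name || ca$predicate != cb$predicate ||
        ca$weight != cb$weight) {
      return(FALSE)
    }
    same <- switch(ca$predicate,
      "vital-above-cutoff" = ca$variable == cb$variable &&
        isTRUE(all.equal(ca$cutoffs$bands, cb$cutoffs$bands,
                         check.attributes = FALSE)),
      "crt-prolonged" = ca$threshold_seconds == cb$threshold_seconds,
      "bcs-below" = ca$value == cb$value,
      "flag-present" = ca$field == cb$field)
    if (!isTRUE(same)) return(FALSE)
  }
  TRUE
}

# ---- config serialisation (YAML / JSON via yaml syntax superset) ----------

.component_to_list <- function(comp) {
  out <- list(name = comp$name, predicate = comp$predicate,
              weight = comp$weight)
  switch(comp$predicate,
    "vital-above-cutoff" = {
      out$variable <- comp$variable
      b <- comp$cutoffs$bands
      out$cutoffs <- lapply(seq_len(nrow(b)), function(i) {
        list(lower = b$lower[i], upper = b$upper[i],
             threshold = b$threshold[i])
      })
    },
    "crt-prolonged" = out$threshold_seconds <- comp$threshold_seconds,
    "bcs-below" = out$value <- comp$value,
    "flag-present" = out$field <- comp$field)
  out
}

.component_from_list <- function(x) {
  stopifnot(!is.null(x$name), !is.null(x$predicate))
  cutoffs <- NULL
  if (identical(x$predicate, "vital-above-cutoff")) {
    b <- do.call(rbind, lapply(x$cutoffs, function(bb) {
      data.frame(lower = bb$lower, upper = bb$upper,
                 threshold = bb$threshold)
    }))
    cutoffs <- cutoff_table(x$variable, b)
  }
  score_component(
    name = x$name, predicate = x$predicate,
    weight = x$weight %||% 1L,
    variable = x$variable, cutoffs = cutoffs,
    threshold_seconds = x$threshold_seconds %||% 3,
    value = x$value %||% 5, field = x$field)
}

#' Read a score definition from a YAML config file
#'
#' The config format holds the score name and a list of components, each
#' with its predicate kind and parameters; cutoff tables are written inline
#' as band lists (edges in months, threshold). An optional \code{policy}
#' block with \code{exclusion_threshold} and \code{single_missing} is
#' returned as the \code{"policy"} attribute when present.
#'
#' @param path YAML (or JSON) file.
#' @return A \code{\link{score_definition}}.
#' @export
read_score_config <- function(path) {
  if (!file.exists(path)) stop("score config not found: ", path)
  x <- yaml::read_yaml(path)
  stopifnot(!is.null(x$name), length(x$components) >= 1)
  def <- score_definition(x$name, lapply(x$components, .component_from_list))
  if (!is.null(x$policy)) {
    attr(def, "policy") <- missing_policy(
      exclusion_threshold = x$policy$exclusion_threshold %||% 2L,
      single_missing = x$policy$single_missing %||% "normal")
  }
  def
}

#' Write a score definition to a YAML config file
#'
#' @param definition A \code{\link{score_definition}}.
#' @param path Destination file.
#' @param policy Optional \code{\link{missing_policy}} to embed.
#' @return \code{path}, invisibly.
#' @export
write_score_config <- function(definition, path, policy = NULL) {
  stopifnot(inherits(definition, "score_definition"))
  x <- list(name = definition$name,
            components = lapply(definition$components, .component_to_list))
  names(x$components) <- NULL
  if (!is.null(policy)) {
    x$policy <- list(exclusion_threshold = policy$exclusion_threshold,
                     single_missing = policy$single_missing)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}
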