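# Shipped configurations: the LqSOFA and BqSOFA definitions, the cutoff
# tables used in development, the recorded amendment sequence that turns
# the one into the other, and simulation presets emulating the published
# cohort descriptions.

.pkg_file <- function(...) {
  f <- system.file("extdata", ..., package = "bqsofa")
  if (f == "") stop("packaged file not found: ", file.path(...))
  f
}

#' Read / write an age-banded cutoff table config
#'
#' YAML with a \code{variable} and a \code{bands} list of
#' \code{\{lower, upper, threshold\}} entries (edges in months).
#'
#' @param path YAML file.
#' @return A \code{\link{cutoff_table}}.
#' @export
read_cutoff_config <- function(path) {
  if (!file.exists(path)) stop("cutoff config not found: ", path)
  x <- yaml::read_yaml(path)
  b <- do.call(rbind, lapply(x$bands, function(bb) {
    data.frame(lower = bb$lower, upper = bb$upper, threshold = bb$threshold)
  }))
  cutoff_table(x$variable, b)
}

#' @rdname read_cutoff_config
#' @param table A \code{\link{cutoff_table}} to write.
#' @export
write_cutoff_config <- function(table, path) {
  stopifnot(inherits(table, "cutoff_table"))
  b <- table$bands
  yaml::write_yaml(list(
    variable = table$variable,
    bands = lapply(seq_len(nrow(b)), function(i) {
      list(lower = b$lower[i], upper = b$upper[i],
           threshold = b$threshold[i])
    })), path)
  invisible(path)
}

#' Shipped score definitions
#'
#' \code{lqsofa_definition()} loads the four-component LqSOFA
#' (age-adjusted heart rate, age-adjusted respiratory rate, CRT > 3 s,
#' BCS < 5); \code{bqsofa_definition()} loads the BqSOFA (respiratory rate
#' above three-band 90th-percentile cutoffs, CRT > 3 s, BCS < 5, pallor);
#' \code{feast_pet_template()} loads an eight-slot template in the shape
#' of the FEAST-PET comparator, whose components and weights must be
#' completed by the user. All cutoff values live in editable YAML under
#' \code{inst/extdata/scores/}, not in code.
#'
#' @return A \code{\link{score_definition}}.
#' @name shipped_scores
#' @export
lqsofa_definition <- function() {
  read_score_config(.pkg_file("scores", "lqsofa.yaml"))
}

#' @rdname shipped_scores
#' @export
bqsofa_definition <- function() {
  read_score_config(.pkg_file("scores", "bqsofa.yaml"))
}

#' @rdname shipped_scores
#' @export
feast_pet_template <- function() {
  read_score_config(.pkg_file("scores", "feast_pet_template.yaml"))
}

#' Shipped 90th-percentile cutoff tables
#'
#' The three-band study-population-style 90th-percentile cutoffs for
#' respiratory rate (identical to the table inside the BqSOFA definition)
#' and heart rate (used only by the recorded development sequence, which
#' subsequently drops heart rate).
#'
#' @return A \code{\link{cutoff_table}}.
#' @name shipped_cutoffs
#' @export
rr_p90_cutoffs <- function() {
  read_cutoff_config(.pkg_file("cutoffs", "rr_p90_dev.yaml"))
}

#' @rdname shipped_cutoffs
#' @export
hr_p90_cutoffs <- function() {
  read_cutoff_config(.pkg_file("cutoffs", "hr_p90_dev.yaml"))
}

#' The recorded LqSOFA-to-BqSOFA amendment sequence
#'
#' The historical development path, as an ordered candidate list for
#' \code{\link{stepwise_develop}} (or \code{\link{apply_modification}}):
#' substitute the heart-rate and respiratory-rate cutoff tables with the
#' study-population 90th-percentile tables, remove heart rate (weakly and
#' inversely associated with mortality in the setting the score targets),
#' and add moderate/severe pallor (the candidate with the highest NRI).
#' Applying the sequence to \code{\link{lqsofa_definition}} yields a
#' definition structurally equal to \code{\link{bqsofa_definition}}.
#'
#' @return A list of \code{\link{modifications}} objects.
#' @export
bqsofa_development_sequence <- function() {
  list(
    substitute_cutoff("heart_rate_high", hr_p90_cutoffs(),
                      label = "substitute HR cutoffs with 90th percentile"),
    substitute_cutoff("respiratory_rate_high", rr_p90_cutoffs(),
                      label = "substitute RR cutoffs with 90th percentile"),
    remove_component("heart_rate_high", label = "remove heart rate"),
    add_component(score_component("pallor", "flag-present",
                                  field = "pallor"),
                  label = "add pallor"))
}

#' Simulation presets emulating the published cohort descriptions
#'
#' Latent-severity configurations whose marginal sign prevalences,
#' mortality, age distribution and per-field missingness match the
#' descriptive table of the development cohort (N = 493: mortality 15.4%,
#' respiratory rate above the 90th-percentile cutoffs 11.4%, heart rate
#' 12.7%, CRT > 3 s 15.7%, BCS < 5 24.7%, pallor 20.2%, dehydration 15.0%,
#' poor nutrition 8.5%; median age 17 months, IQR 9-36) or the validation
#' cohort (N = 377: mortality 22.0%, respiratory rate 9.9%, heart rate
#' 7.6%, CRT 41.5%, BCS 52.0%, pallor 5.5%, dehydration 18.3%, poor
#' nutrition 18.1%; median age 26.7 months, IQR 8.2-74). Missingness rates
#' per field reproduce the published per-field denominators, with a
#' positive severity slope so sicker children are more often unmeasured.
#' Severity slopes couple signs to outcome so that mortality rises with
#' the score level; joint sign structure is not identified by marginal
#' tables, so the slopes are simulator parameters, not cohort facts.
#'
#' @param cohort \code{"development"} or \code{"validation"}.
#' @param n Cohort size; defaults to the published cohort size.
#' @return A \code{\link{simulation_config}}.
#' @export
make_table1_preset <- function(cohort = c("development", "validation"),
                               n = NULL) {
  cohort <- match.arg(cohort)
  if (cohort == "development") {
    simulation_config(
      n = n %||% 493L,
      model = "latent-severity",
      age_median = 17, age_iqr = c(9, 36),
      mortality = 0.154, mortality_slope = 1.2,
      sign_prevalence = c(heart_rate = 0.127, respiratory_rate = 0.114,
                          crt = 0.157, bcs = 0.247, pallor = 0.202,
                          dehydration = 0.150, poor_nutrition = 0.085),
      sign_slope = c(heart_rate = 0.3, respiratory_rate = 0.8, crt = 1.0,
                     bcs = 1.2, pallor = 0.8, dehydration = 0.6,
                     poor_nutrition = 0.6),
      missingness = c(heart_rate = 13 / 493, respiratory_rate = 204 / 493,
                      crt = 48 / 493, bcs = 20 / 493, pallor = 17 / 493,
                      dehydration = 21 / 493, poor_nutrition = 34 / 493,
                      outcome = 12 / 505),
      missing_slope = 0.4)
  } else {
    simulation_config(
      n = n %||% 377L,
      model = "latent-severity",
      age_median = 26.7, age_iqr = c(8.2, 74),
      mortality = 0.220, mortality_slope = 1.2,
      sign_prevalence = c(heart_rate = 0.076, respiratory_rate = 0.099,
                          crt = 0.415, bcs = 0.520, pallor = 0.055,
                          dehydration = 0.183, poor_nutrition = 0.181),
      sign_slope = c(heart_rate = 0.3, respiratory_rate = 0.8, crt = 1.0,
                     bcs = 1.2, pallor = 0.8, dehydration = 0.6,
                     poor_nutrition = 0.6),
      missingness = c(heart_rate = 10 / 377, respiratory_rate = 3 / 377,
                      crt = 8 / 377, bcs = 0, pallor = 16 / 377,
                      dehydration = 6 / 377, poor_nutrition = 1 / 377),
      missing_slope = 0.4)
  }
}
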