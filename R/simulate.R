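# Synthetic-cohort simulator.
#
# Two outcome models:
#   * "score-distribution": the marginal mortality plus conditional
#     distributions of the score given death / survival are stated
#     directly; components are then assigned consistently with the drawn
#     score. This mode has a closed-form AUC (analytic_auc), so empirical
#     AUC recovery can be tested against exact ground truth.
#   * "latent-severity": each child carries a standard-normal latent
#     severity z; death has probability plogis(alpha + beta * z) and each
#     sign is abnormal with probability plogis(gamma_k + delta_k * z).
#     Intercepts are calibrated numerically so the marginal rates match
#     their targets, whatever the slopes. This gives correlated signs and
#     graded score-level mortality, the structure real cohorts show.
#
# Emission: numeric vitals are drawn uniformly on either side of the
# child's age-band cutoff, consistent with the latent sign truth (only the
# threshold crossing matters to any score). Missingness is applied last,
# per field, MCAR or with a severity-dependent slope so that sicker
# children lose more measurements (the mechanism behind excluded children
# having higher mortality).

.sim_fields <- c("heart_rate", "respiratory_rate", "crt", "bcs", "pallor",
                 "dehydration", "poor_nutrition")
# cohort column that missingness acts on, per simulated sign
.sim_field_column <- c(heart_rate = "heart_rate",
                       respiratory_rate = "respiratory_rate",
                       crt = "crt_seconds", bcs = "bcs", pallor = "pallor",
                       dehydration = "dehydration",
                       poor_nutrition = "poor_nutrition")

#' Calibrate a logistic intercept against a marginal rate
#'
#' Finds gamma such that \eqn{E[logit^{-1}(\gamma + \delta Z)] = p} for
#' standard-normal Z, by numerical integration and root finding. With
#' \code{slope = 0} this is just \code{qlogis(p)}.
#'
#' @param target Marginal probability in (0, 1).
#' @param slope Slope on the latent severity.
#' @return The intercept gamma.
#' @export
calibrate_intercept <- function(target, slope = 0) {
  stopifnot(target > 0, target < 1)
  if (slope == 0) return(stats::qlogis(target))
  marg <- function(g) {
    stats::integrate(function(z) stats::plogis(g + slope * z) *
                       stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - target
  }
  stats::uniroot(marg, c(-30, 30), tol = 1e-9)$root
}

.lnorm_from_median_iqr <- function(median, iqr) {
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  list(meanlog = log(median), sdlog = sdlog)
}

#' Build a simulation configuration
#'
#' @param n Cohort size.
#' @param model \code{"latent-severity"} or \code{"score-distribution"}.
#' @param age_median,age_iqr Target median and interquartile range of age
#'   in months; ages are drawn log-normal (moment-matched on the log scale)
#'   truncated to [2, 192).
#' @param mortality Marginal in-hospital mortality probability.
#' @param sign_prevalence Named vector of marginal abnormality
#'   probabilities over (a subset of) \code{heart_rate},
#'   \code{respiratory_rate}, \code{crt}, \code{bcs}, \code{pallor},
#'   \code{dehydration}, \code{poor_nutrition} (latent-severity mode).
#' @param sign_slope Named vector (or scalar, recycled) of severity slopes
#'   per sign; 0 makes a sign independent of outcome.
#' @param mortality_slope Severity slope on the log-odds of death.
#' @param p_score_event,p_score_nonevent Conditional score distributions
#'   over levels 0..length-1 (score-distribution mode); must each sum to 1
#'   and share one support.
#' @param score_components Character vector naming which unit-weight signs
#'   realise the score in score-distribution mode (length = max score).
#' @param cutoffs Named list of \code{\link{cutoff_table}}s for
#'   \code{heart_rate} and \code{respiratory_rate}, used to draw numeric
#'   vitals consistent with sign truth. Defaults to the shipped tables.
#' @param missingness Named vector of marginal missingness rates per
#'   emitted field (names among the signs plus \code{outcome}).
#' @param missing_slope Severity slope of missingness (latent-severity
#'   mode): positive values make sicker children more often unmeasured.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n,
                              model = c("latent-severity",
                                        "score-distribution"),
                              age_median = 17, age_iqr = c(9, 36),
                              mortality = 0.15,
                              sign_prevalence = NULL, sign_slope = 1,
                              mortality_slope = 1.2,
                              p_score_event = NULL, p_score_nonevent = NULL,
                              score_components = c("respiratory_rate",
                                                   "crt", "bcs", "pallor"),
                              cutoffs = NULL, missingness = NULL,
                              missing_slope = 0) {
  model <- match.arg(model)
  stopifnot(n >= 1, mortality >= 0, mortality <= 1)
  if (model == "latent-severity") {
    if (is.null(sign_prevalence)) {
      sign_prevalence <- c(respiratory_rate = 0.11, crt = 0.16, bcs = 0.25,
                           pallor = 0.20)
    }
    stopifnot(all(names(sign_prevalence) %in% .sim_fields),
              all(sign_prevalence >= 0 & sign_prevalence <= 1))
    if (length(sign_slope) == 1) {
      sign_slope <- stats::setNames(rep(sign_slope,
                                        length(sign_prevalence)),
                                    names(sign_prevalence))
    }
    stopifnot(setequal(names(sign_slope), names(sign_prevalence)))
  } else {
    stopifnot(!is.null(p_score_event), !is.null(p_score_nonevent),
              length(p_score_event) == length(p_score_nonevent),
              abs(sum(p_score_event) - 1) < 1e-8,
              abs(sum(p_score_nonevent) - 1) < 1e-8,
              length(score_components) == length(p_score_event) - 1,
              all(score_components %in% .sim_fields))
  }
  if (!is.null(missingness)) {
    stopifnot(all(names(missingness) %in% c(.sim_fields, "outcome")),
              all(missingness >= 0 & missingness <= 1))
  } else {
    missingness <- numeric(0)
  }
  if (is.null(cutoffs)) {
    cutoffs <- list(heart_rate = hr_p90_cutoffs(),
                    respiratory_rate = rr_p90_cutoffs())
  }
  structure(list(n = as.integer(n), model = model,
                 age = .lnorm_from_median_iqr(age_median, age_iqr),
                 age_median = age_median, age_iqr = age_iqr,
                 mortality = mortality,
                 sign_prevalence = sign_prevalence,
                 sign_slope = sign_slope,
                 mortality_slope = mortality_slope,
                 p_score_event = p_score_event,
                 p_score_nonevent = p_score_nonevent,
                 score_components = score_components,
                 cutoffs = cutoffs,
                 missingness = missingness,
                 missing_slope = missing_slope),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation config: %s, n = %d, mortality %.3f>\n",
              x$model, x$n, x$mortality))
  invisible(x)
}

.draw_ages <- function(n, age) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rlnorm(2 * n + 10, age$meanlog, age$sdlog)
    out <- c(out, cand[cand >= 2 & cand < 192])
  }
  out[seq_len(n)]
}

# numeric vital consistent with truth: strictly above the age cutoff when
# abnormal, at or below (but positive) when normal
.draw_vital <- function(truth, age, table) {
  thr <- lookup_cutoff(table, age)
  ifelse(truth,
         thr + stats::runif(length(age)) * 0.6 * thr,
         thr * (0.35 + 0.65 * stats::runif(length(age))))
}

#' Simulate a cohort with known ground truth
#'
#' Draws a synthetic cohort under the given configuration (see
#' \code{\link{simulation_config}}) and returns it together with the
#' per-child truth: latent severity, the true abnormality of every
#' simulated sign before missingness, the true score, and the outcome.
#' The emitted record agrees with the truth wherever it is non-missing.
#' Reproducible: the same config and seed give identical output.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer seed.
#' @param name Cohort label.
#' @return A list with elements \code{cohort} (a \code{\link{cohort}}) and
#'   \code{truth} (a data.frame, one row per child).
#' @export
simulate_cohort <- function(config, seed = 1L, name = "simulated") {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  set.seed(seed)
  age <- .draw_ages(n, config$age)

  if (config$model == "latent-severity") {
    z <- stats::rnorm(n)
    died <- if (config$mortality %in% c(0, 1)) {
      rep(config$mortality == 1, n)
    } else {
      alpha <- calibrate_intercept(config$mortality, config$mortality_slope)
      stats::runif(n) < stats::plogis(alpha + config$mortality_slope * z)
    }
    truth_signs <- lapply(names(config$sign_prevalence), function(f) {
      p <- config$sign_prevalence[[f]]
      if (p == 0) return(rep(FALSE, n))
      if (p == 1) return(rep(TRUE, n))
      g <- calibrate_intercept(p, config$sign_slope[[f]])
      stats::runif(n) < stats::plogis(g + config$sign_slope[[f]] * z)
    })
    names(truth_signs) <- names(config$sign_prevalence)
  } else {
    z <- rep(NA_real_, n)
    died <- stats::runif(n) < config$mortality
    levels <- seq_along(config$p_score_event) - 1L
    score <- integer(n)
    if (any(died)) {
      score[died] <- sample(levels, sum(died), replace = TRUE,
                            prob = config$p_score_event)
    }
    if (any(!died)) {
      score[!died] <- sample(levels, sum(!died), replace = TRUE,
                             prob = config$p_score_nonevent)
    }
    k <- length(config$score_components)
    # realise each score as a uniformly chosen subset of abnormal signs:
    # rank i.i.d. uniforms within each record, flag the s lowest
    u <- matrix(stats::runif(n * k), n, k)
    rk <- matrix(0L, n, k)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (b != a) rk[, a] <- rk[, a] + (u[, b] < u[, a])
      }
    }
    truth_signs <- lapply(seq_len(k), function(j) rk[, j] < score)
    names(truth_signs) <- config$score_components
  }

  sim_fields <- names(truth_signs)
  rec <- data.frame(id = sprintf("sim-%05d", seq_len(n)), age_months = age,
                    stringsAsFactors = FALSE)
  rec$heart_rate <- if ("heart_rate" %in% sim_fields) {
    .draw_vital(truth_signs$heart_rate, age, config$cutoffs$heart_rate)
  } else NA_real_
  rec$respiratory_rate <- if ("respiratory_rate" %in% sim_fields) {
    .draw_vital(truth_signs$respiratory_rate, age,
                config$cutoffs$respiratory_rate)
  } else NA_real_
  rec$crt_seconds <- if ("crt" %in% sim_fields) {
    ifelse(truth_signs$crt, 3 + stats::runif(n) * 7,
           0.5 + stats::runif(n) * 2.5)
  } else NA_real_
  rec$bcs <- if ("bcs" %in% sim_fields) {
    ifelse(truth_signs$bcs, sample(0:4, n, replace = TRUE), 5)
  } else NA_real_
  rec$pallor <- if ("pallor" %in% sim_fields) {
    ifelse(truth_signs$pallor, "moderate-or-severe", "none")
  } else NA_character_
  rec$dehydration <- if ("dehydration" %in% sim_fields) {
    ifelse(truth_signs$dehydration, "moderate-or-severe", "none")
  } else NA_character_
  rec$poor_nutrition <- if ("poor_nutrition" %in% sim_fields) {
    ifelse(truth_signs$poor_nutrition, "yes", "no")
  } else NA_character_
  rec$outcome <- ifelse(died, "died", "survived")

  # missingness last: per-field, MCAR or severity-tilted
  for (f in names(config$missingness)) {
    rate <- config$missingness[[f]]
    if (rate <= 0) next
    slope <- if (config$model == "latent-severity") config$missing_slope else 0
    p_miss <- if (slope == 0 || rate >= 1) {
      rep(rate, n)
    } else {
      m0 <- calibrate_intercept(rate, slope)
      stats::plogis(m0 + slope * z)
    }
    col <- if (f == "outcome") "outcome" else .sim_field_column[[f]]
    rec[[col]][stats::runif(n) < p_miss] <- NA
  }

  truth <- data.frame(id = rec$id, severity = z, died = died,
                      stringsAsFactors = FALSE)
  for (f in sim_fields) truth[[paste0(f, "_abnormal")]] <- truth_signs[[f]]
  truth$true_score <- Reduce(`+`, lapply(truth_signs, as.integer))
  list(cohort = cohort(rec, name = name), truth = truth)
}

#' Closed-form AUC for discrete conditional score distributions
#'
#' The Mann-Whitney functional with half credit for ties:
#' \deqn{AUC = \sum_s \sum_{t<s} P(t|survived) P(s|died)
#'       + 0.5 \sum_s P(s|survived) P(s|died).}
#' This is the exact AUC a score attains when deaths and survivors draw
#' their levels from these distributions, and is the ground truth against
#' which empirical AUC recovery is tested.
#'
#' @param p_score_given_event,p_score_given_nonevent Probability vectors
#'   over the same ordered score support, each summing to 1.
#' @return The AUC, a number in [0, 1].
#' @export
analytic_auc <- function(p_score_given_event, p_score_given_nonevent) {
  pe <- p_score_given_event; pn <- p_score_given_nonevent
  if (length(pe) != length(pn)) {
    stop("conditional score distributions on mismatched support")
  }
  stopifnot(abs(sum(pe) - 1) < 1e-8, abs(sum(pn) - 1) < 1e-8,
            all(pe >= 0), all(pn >= 0))
  cum_n <- cumsum(pn)
  below <- c(0, cum_n[-length(cum_n)])
  sum(pe * below) + 0.5 * sum(pe * pn)
}
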