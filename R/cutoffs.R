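# Age-banded vital-sign cutoff tables.
#
# Bands are half-open intervals on age in months, [lower, upper), and must
# jointly cover the paediatric inclusion range [2, 192) without gaps or
# overlaps. A value is abnormal when strictly above the band threshold.

.AGE_MIN <- 2
.AGE_MAX <- 192

#' Construct an age-banded cutoff table
#'
#' A cutoff table holds the threshold above which a vital sign is abnormal,
#' in age bands. Band edges are in months; each band is lower-inclusive,
#' upper-exclusive, and together the bands must cover ages 2 to 192 months
#' (2 months to 16 years) exactly.
#'
#' @param variable Which vital the table applies to: \code{"heart_rate"}
#'   (beats/min) or \code{"respiratory_rate"} (breaths/min).
#' @param bands A data.frame (or list of 3-element vectors) with columns
#'   \code{lower}, \code{upper}, \code{threshold}: band edges in months and
#'   the strictly positive abnormal-if-above threshold.
#' @return An object of class \code{"cutoff_table"}.
#' @export
#' @examples
#' rr <- cutoff_table("respiratory_rate",
#'                    data.frame(lower = c(2, 12, 60), upper = c(12, 60, 192),
#'                               threshold = c(60, 50, 40)))
#' lookup_cutoff(rr, age_months = 14)
cutoff_table <- function(variable = c("respiratory_rate", "heart_rate"),
                         bands) {
  variable <- match.arg(variable)
  if (!is.data.frame(bands)) {
    bands <- as.data.frame(do.call(rbind, lapply(bands, as.numeric)))
    names(bands) <- c("lower", "upper", "threshold")
  }
  stopifnot(all(c("lower", "upper", "threshold") %in% names(bands)))
  bands <- bands[order(bands$lower), c("lower", "upper", "threshold")]
  rownames(bands) <- NULL
  if (any(bands$upper <= bands$lower)) {
    stop("each band needs upper > lower")
  }
  if (any(bands$threshold <= 0)) stop("thresholds must be strictly positive")
  edges_ok <- bands$lower[1] == .AGE_MIN &&
    bands$upper[nrow(bands)] == .AGE_MAX &&
    (nrow(bands) == 1 ||
       all(bands$lower[-1] == bands$upper[-nrow(bands)]))
  if (!edges_ok) {
    gaps <- paste(sprintf("[%g, %g)", bands$lower, bands$upper),
                  collapse = " ")
    stop(sprintf(
      "bands must partition [%g, %g) months exactly; got %s",
      .AGE_MIN, .AGE_MAX, gaps))
  }
  structure(list(variable = variable, bands = bands),
            class = "cutoff_table")
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat(sprintf("<cutoff table: %s abnormal if above>\n", x$variable))
  print(x$bands)
  invisible(x)
}

#' Look up the age-appropriate threshold
#'
#' Returns the threshold of the unique band containing the given age. Band
#' membership is lower-inclusive, upper-exclusive, so an age equal to a band
#' edge falls in the upper band. Ages outside the table's coverage raise an
#' explicit error; there is no silent default.
#'
#' @param table A \code{\link{cutoff_table}}.
#' @param age_months Age(s) in months; vectorised.
#' @return Numeric threshold(s).
#' @export
lookup_cutoff <- function(table, age_months) {
  stopifnot(inherits(table, "cutoff_table"))
  b <- table$bands
  idx <- findInterval(age_months, c(b$lower, b$upper[nrow(b)]),
                      rightmost.closed = FALSE)
  oob <- !is.na(age_months) &
    (age_months < b$lower[1] | age_months >= b$upper[nrow(b)])
  if (any(oob)) {
    stop(sprintf(
      "age %g months outside cutoff-table coverage [%g, %g)",
      age_months[oob][1], b$lower[1], b$upper[nrow(b)]))
  }
  out <- rep(NA_real_, length(age_months))
  ok <- !is.na(age_months)
  out[ok] <- b$threshold[idx[ok]]
  out
}

#' Derive percentile cutoffs from a cohort
#'
#' Computes, per age band, the stated percentile of the non-missing values of
#' a vital sign in the cohort, producing a \code{\link{cutoff_table}} with
#' abnormal-if-above direction. This is how study-population cutoffs (e.g.
#' the development cohort's age-specific 90th percentile for respiratory
#' rate) are obtained. The quantile rule is linear interpolation between
#' order statistics (\code{\link[stats]{quantile}} type 7, the common
#' statistical-software default); other \code{type}s can be requested.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param variable \code{"respiratory_rate"} or \code{"heart_rate"}.
#' @param age_bands Data.frame with columns \code{lower}, \code{upper}
#'   (months, half-open) covering [2, 192).
#' @param percentile Percentile in (0, 100].
#' @param type Quantile type passed to \code{\link[stats]{quantile}}.
#' @return A \code{\link{cutoff_table}}.
#' @export
derive_percentile_cutoffs <- function(cohort, variable, age_bands,
                                      percentile = 90, type = 7) {
  stopifnot(inherits(cohort, "cohort"),
            variable %in% c("respiratory_rate", "heart_rate"),
            percentile > 0, percentile <= 100)
  age_bands <- as.data.frame(age_bands)
  thr <- numeric(nrow(age_bands))
  for (i in seq_len(nrow(age_bands))) {
    lo <- age_bands$lower[i]; hi <- age_bands$upper[i]
    sel <- !is.na(cohort$age_months) & cohort$age_months >= lo &
      cohort$age_months < hi & !is.na(cohort[[variable]])
    vals <- cohort[[variable]][sel]
    if (length(vals) < 2) {
      stop(sprintf(
        "band [%g, %g) has %d non-missing %s observation(s); need at least 2",
        lo, hi, length(vals), variable))
    }
    thr[i] <- unname(stats::quantile(vals, percentile / 100, type = type))
  }
  cutoff_table(variable,
               data.frame(lower = age_bands$lower, upper = age_bands$upper,
                          threshold = thr))
}
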