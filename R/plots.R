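# Minimal base-graphics views: the two figures one draws for a bedside
# score -- mortality by score level, and the empirical ROC curve.

#' Bar chart of mortality by score level
#'
#' @param scored A \code{\link{scored_cohort}}.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @return The \code{\link{calibration_table}}, invisibly.
#' @export
plot_calibration <- function(scored, ...) {
  cal <- calibration_table(scored)
  graphics::barplot(height = ifelse(is.na(cal$mortality), 0, cal$mortality),
                    names.arg = cal$score,
                    xlab = "score", ylab = "observed mortality",
                    main = attr(scored, "definition"), ...)
  invisible(cal)
}

#' Empirical ROC curve of a scored cohort
#'
#' Plots sensitivity against 1 - specificity over every attainable cutoff
#' (score >= k positive, k = 0..max+1).
#'
#' @param scored A \code{\link{scored_cohort}}.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @return A data.frame of (fpr, tpr) points, invisibly.
#' @export
plot_roc <- function(scored, ...) {
  s <- .included(scored)
  ks <- 0:(attr(scored, "max_score") + 1)
  pts <- t(vapply(ks, function(k) {
    pos <- s$score >= k
    c(fpr = sum(pos & s$outcome == 0) / sum(s$outcome == 0),
      tpr = sum(pos & s$outcome == 1) / sum(s$outcome == 1))
  }, numeric(2)))
  pts <- as.data.frame(pts)
  graphics::plot(pts$fpr, pts$tpr, type = "b", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity", main = attr(scored, "definition"),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(pts)
}
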