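#' Extrapolated risk profile at ages 50 and 100
#'
#' Evaluates the fitted model's cumulative risk \eqn{F(t) = 1 - S(t)} at
#' ages 50 and 100 under baseline covariates, and the relative increase in
#' risk with age, \eqn{(F(100) - F(50))/F(50)}.  `F50` measures how much
#' risk accrues early in life; the relative increase measures how fast risk
#' grows at older ages.
#'
#' @param model fitted `multistage_model`.
#' @return list `F50`, `F100`, `relative_increase` (`NA` with a `flagged`
#'   marker when `F50 = 0`).
#' @examples
#' risk_profile(weibull_ph(5, 100))  # F50 ~ 0.0308, F100 ~ 0.632
#' @export
risk_profile <- function(model) {
  F50 <- 1 - model_survival(model, 50)
  F100 <- 1 - model_survival(model, 100)
  rel <- if (F50 > 0) (F100 - F50) / F50 else NA_real_
  list(F50 = F50, F100 = F100, relative_increase = rel, flagged = F50 == 0)
}

#' Sporadic score
#'
#' The product \eqn{F(50) \times F(50)/F(100) = F(50)^2/F(100)}: large for
#' diseases with appreciable risk by 50 that grows slowly afterwards
#' (sporadic), small for diseases whose negligible early risk rises rapidly
#' with age (late-onset).  \eqn{F(50)/F(100)} is the probability of disease
#' by 50 given disease by 100.
#'
#' @param F50,F100 cumulative risks at ages 50 and 100, `F100 > 0`.
#' @return score in `[0, F50]`.
#' @export
sporadic_score <- function(F50, F100) {
  stopifnot(all(F100 > 0), all(F50 >= 0), all(F50 <= F100))
  F50^2 / F100
}

#' Classify diseases into sporadic / mid-range / late-onset tertiles
#'
#' Boundaries at the empirical 1/3 and 2/3 quantiles of the sporadic scores;
#' the top tertile is labelled sporadic and the bottom late-onset.  Boundary
#' ties go to the lower-score tertile, deterministically; an all-equal score
#' vector degenerates to all mid-range (logged).
#'
#' @param scores sporadic scores across `>= 3` diseases.
#' @return factor with levels `sporadic`, `mid-range`, `late-onset`.
#' @export
classify_tertiles <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 diseases to form tertiles")
  stopifnot(all(is.finite(scores)))
  lv <- c("sporadic", "mid-range", "late-onset")
  if (length(unique(scores)) == 1L) {
    message("all scores equal: every disease labelled mid-range")
    return(factor(rep("mid-range", length(scores)), levels = lv))
  }
  q <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  lab <- ifelse(scores <= q[1L], "late-onset",
                ifelse(scores <= q[2L], "mid-range", "sporadic"))
  factor(lab, levels = lv)
}

#' Cross-tabulate tertile labels by ICD-10 chapter
#'
#' @param labels factor from [classify_tertiles()].
#' @param chapters chapter numerals, same length.
#' @return contingency table (tertile x chapter); totals preserved.
#' @export
chapter_composition <- function(labels, chapters) {
  stopifnot(length(labels) == length(chapters))
  table(tertile = labels, chapter = chapters)
}

#' Classification table across an ensemble of fitted diseases
#'
#' @param fits named list of `multistage_fit` (names = disease ids).
#' @param chapters optional named chapter numerals per disease.
#' @param included optional logical vector naming which diseases passed the
#'   inclusion screen; others are dropped before tertiles are formed.
#' @return data.frame: disease, chapter, F50, F100, relative_increase,
#'   sporadic_score, tertile.
#' @export
classification_table <- function(fits, chapters = NULL, included = NULL) {
  ids <- names(fits)
  if (!is.null(included)) ids <- ids[included[ids]]
  if (length(ids) < 3L) stop("need >= 3 included diseases")
  prof <- lapply(ids, function(id) risk_profile(fits[[id]]$model))
  tab <- data.frame(
    disease = ids,
    chapter = if (is.null(chapters)) NA_character_ else unname(chapters[ids]),
    F50 = vapply(prof, `[[`, 0, "F50"),
    F100 = vapply(prof, `[[`, 0, "F100"),
    relative_increase = vapply(prof, `[[`, 0, "relative_increase"),
    stringsAsFactors = FALSE)
  tab$sporadic_score <- sporadic_score(tab$F50, tab$F100)
  tab$tertile <- classify_tertiles(tab$sporadic_score)
  rownames(tab) <- NULL
  tab
}

#' Sporadic-vs-late-onset scatter (risk at 50 vs relative increase by 100)
#'
#' Renders the classification table as a log-log scatter of `F50` against
#' the relative risk increase by age 100, coloured by tertile.
#'
#' @param tab output of [classification_table()].
#' @return a ggplot object.
#' @export
classification_plot <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$F50,
                                    y = .data$relative_increase,
                                    colour = .data$tertile)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      "sporadic" = "darkorange", "mid-range" = "forestgreen",
      "late-onset" = "firebrick")) +
    ggplot2::labs(x = "probability of first admission by age 50, F(50)",
                  y = "(F(100) - F(50)) / F(50)", colour = NULL) +
    ggplot2::theme_bw()
}
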