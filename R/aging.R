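#' Relative risk and relative aging rate of a covariate profile
#'
#' A Weibull proportional-hazards model can be read two ways: the familiar
#' relative risk \eqn{e^{\eta_X}} multiplies the hazard, while rearranging
#' the cumulative hazard as \eqn{H(t) = (t e^{\eta_X/m}/L)^m} shows the same
#' profile multiplies *age* by the relative aging rate
#' \eqn{e^{\eta_X/m}} — so the influence of risk factors on the effective
#' age is suppressed by a factor \eqn{1/m}, and always
#' `relative_aging_rate^m == relative_risk`.  Multi-factor profiles multiply
#' (their \eqn{\eta_X} add).
#'
#' @param model a fitted `multistage_model` (Weibull family for the aging
#'   rate interpretation).
#' @param x covariate profile as in [linear_predictor()]; default baseline
#'   (rate 1).
#' @return positive scalar (or vector over rows of `x`).
#' @examples
#' s <- covariate_schema(diabetes = c("no", "yes"))
#' w <- weibull_ph(5, 100, beta = c("diabetes=yes" = 0.5), covariate_schema = s)
#' relative_risk(w, list(diabetes = "yes"))        # e^0.5
#' relative_aging_rate(w, list(diabetes = "yes"))  # e^0.1 ~ 1.105
#' @export
relative_aging_rate <- function(model, x = NULL) {
  stopifnot(model$m > 0)
  exp(linear_predictor(model, x) / model$m)
}

#' @rdname relative_aging_rate
#' @export
relative_risk <- function(model, x = NULL) {
  exp(linear_predictor(model, x))
}

#' Effective age under a risk profile
#'
#' A person aged `t` with relative aging rate `rar` is at the disease risk
#' of a baseline person aged `t * rar`: the defining identity is
#' \eqn{H(t\,e^{\eta_X/m} \mid \mathrm{baseline}) = H(t \mid X)}.
#'
#' @param t chronological age, years.
#' @param rar relative aging rate, `> 0`.
#' @return effective age in years.
#' @examples
#' effective_age(50, 1.1)  # 55
#' effective_age(70, 1.3)  # 91
#' @export
effective_age <- function(t, rar) {
  stopifnot(all(t >= 0), all(rar > 0))
  t * rar
}

#' Equivalent screening age for a different risk group
#'
#' The age at which the target group's cumulative hazard equals the
#' reference group's at `reference_age`:
#' `reference_age * rar_ref / rar_target`.  Useful for risk stratification —
#' inviting higher-risk groups earlier and lower-risk groups later at equal
#' risk.
#'
#' @param reference_age age at which the reference group is screened, years.
#' @param rar_ref,rar_target relative aging rates of the two groups.
#' @return age in years.
#' @examples
#' equivalent_screening_age(55, 1, 1.1)  # 50: the higher-risk group reaches
#'                                       # the same risk five years earlier
#' @export
equivalent_screening_age <- function(reference_age, rar_ref, rar_target) {
  stopifnot(all(rar_ref > 0), all(rar_target > 0), all(reference_age >= 0))
  reference_age * rar_ref / rar_target
}

#' Expected age at first disease under a risk profile
#'
#' If a baseline person aged `a` expects `Y` further disease-free years,
#' a person with relative aging rate `rar` on average reaches age
#' `(a + Y) / rar` before their first disease, i.e. `(a + Y)/rar - a`
#' disease-free years.  Ages are also reported rounded to whole years.
#'
#' @param baseline_age current age `a`, years.
#' @param disease_free_years expected baseline disease-free years `Y > 0`.
#' @param rar relative aging rate `> 0`.
#' @return list: `age`, `disease_free_years` (exact), `age_rounded`,
#'   `disease_free_years_rounded`.  A warning is raised if the rate is so
#'   extreme that the expected first-disease age falls below `baseline_age`.
#' @examples
#' expected_first_disease_age(40, 25, 1.1)  # ~59 y, 19 disease-free years
#' @export
expected_first_disease_age <- function(baseline_age, disease_free_years, rar) {
  stopifnot(disease_free_years > 0, rar > 0, baseline_age >= 0)
  age <- (baseline_age + disease_free_years) / rar
  dfy <- age - baseline_age
  if (dfy < 0)
    warning("relative aging rate so extreme that expected first-disease age ",
            "precedes the current age")
  list(age = age, disease_free_years = dfy,
       age_rounded = round(age),
       disease_free_years_rounded = round(age) - baseline_age)
}

#' Per-disease relative risks and aging rates, long format
#'
#' One row per (disease, covariate term) with the relative risk
#' \eqn{e^{\beta_j}} and relative aging rate \eqn{e^{\beta_j/m}}.
#'
#' @param fits named list of `multistage_fit` with covariate-adjusted
#'   Weibull models.
#' @return data.frame: disease, term, beta, relative_risk,
#'   relative_aging_rate.
#' @export
aging_rate_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    mod <- fits[[id]]$model
    if (length(mod$beta) == 0L) return(NULL)
    data.frame(disease = id, term = names(mod$beta),
               beta = unname(mod$beta),
               relative_risk = exp(unname(mod$beta)),
               relative_aging_rate = exp(unname(mod$beta) / mod$m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare relative aging rates (or risks) between disease groups
#'
#' Welch two-sample t-tests per covariate term between e.g. the sporadic and
#' late-onset tertiles, with Benjamini--Hochberg adjustment across terms.
#'
#' @param group_a,group_b data.frames in [aging_rate_table()] format (or any
#'   with columns `term` and `value_col`).
#' @param value_col which column to compare (default
#'   `"relative_aging_rate"`; use `"relative_risk"` for risks).
#' @return data.frame: term, n_a, n_b, mean_a, mean_b, mean_diff,
#'   t_statistic, p_value, q_value.
#' @export
compare_groups <- function(group_a, group_b,
                           value_col = "relative_aging_rate") {
  terms <- intersect(unique(group_a$term), unique(group_b$term))
  if (length(terms) == 0L) stop("no shared covariate terms")
  rows <- lapply(terms, function(tm) {
    a <- group_a[[value_col]][group_a$term == tm]
    b <- group_b[[value_col]][group_b$term == tm]
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 diseases per group for term ", tm)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("degenerate (zero) variance in both groups for term ", tm)
    tt <- stats::t.test(a, b)
    data.frame(term = tm, n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               mean_diff = mean(a) - mean(b),
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- fdr_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Box plot of relative risks / aging rates by disease group
#'
#' Median, interquartile range, whiskers at 1 x IQR.
#'
#' @param tab long data.frame with columns `term`, a value column and
#'   `group`.
#' @param value_col column to plot.
#' @return a ggplot object.
#' @export
aging_rate_boxplot <- function(tab, value_col = "relative_aging_rate") {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term,
                                    y = .data[[value_col]],
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(coef = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = value_col, fill = NULL) +
    ggplot2::theme_bw()
}
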