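#' Kaplan--Meier estimator with delayed entry
#'
#' Product-limit estimator over event ages with risk sets honouring entry
#' ages (left truncation), with Greenwood variances on the survival scale.
#' Rows censored exactly at entry carry no information and are dropped with
#' a message.  By the Kaplan--Meier convention \eqn{\hat S = 1} just before
#' the first event age, even though on an age timescale the true survival
#' may already be below 1 at study start — see [estimate_H1()] for the
#' offset correction.
#'
#' @param data cohort data.frame (`entry_age`, `exit_age`, `status`).
#' @return A `km_curve`: `time` (distinct event ages), `surv`, `var`
#'   (Greenwood), `n_event`, `n_risk`.
#' @export
kaplan_meier_delayed_entry <- function(data) {
  check_cohort(data)
  if (sum(data$status) < 1L) stop("no events: Kaplan-Meier undefined")
  zero <- data$exit_age <= data$entry_age
  if (any(zero)) {
    if (any(data$status[zero] == 1))
      stop("event recorded at or before entry age")
    message(sum(zero), " zero-length censored row(s) dropped")
    data <- data[!zero, , drop = FALSE]
  }
  sf <- survival::survfit(
    survival::Surv(entry_age, exit_age, status) ~ 1,
    data = data, conf.type = "none")
  sm <- summary(sf, censored = FALSE)
  keep <- sm$n.event > 0
  structure(list(time = sm$time[keep], surv = sm$surv[keep],
                 var = sm$std.err[keep]^2,
                 n_event = sm$n.event[keep], n_risk = sm$n.risk[keep]),
            class = "km_curve")
}

#' Estimate the pre-observation cumulative-hazard offset H1
#'
#' On an age timescale the cohort enters observation in middle age, so the
#' true survival at the first observed event age \eqn{t_1} is already below
#' 1: \eqn{H(t) = H_1 + \hat H(t)} with \eqn{H_1 = \int_0^{t_1} h\,ds}.
#' With a parametric model for \eqn{H} and the Kaplan--Meier estimate for
#' \eqn{\hat H = -\log \hat S}, the offset is estimated by averaging over
#' the observed event ages:
#' \deqn{H_1 \simeq \frac{1}{n}\sum_{i=1}^{n} (H(t_i) - \hat H(t_i)),}
#' introducing no additional free parameters.  The sum runs over the n
#' observed event ages (tied events each count); censored rows do not enter.
#'
#' @param model fitted parametric `multistage_model` on the same cohort.
#' @param km a `km_curve` from [kaplan_meier_delayed_entry()].
#' @param x covariate profile at which to evaluate the model's cumulative
#'   hazard (default baseline).
#' @return the dimensionless offset `H1`.
#' @export
estimate_H1 <- function(model, km, x = NULL) {
  stopifnot(inherits(km, "km_curve"))
  n <- sum(km$n_event)
  if (n == 0L) stop("no events")
  H_model <- model_cumhaz(model, km$time, x)
  H_hat <- -log(km$surv)
  sum(km$n_event * (H_model - H_hat)) / n
}

#' Apply the H1 offset to a Kaplan--Meier curve
#'
#' Multiplies the step survival pointwise by \eqn{e^{-H_1}}, so the adjusted
#' curve estimates the cause-specific survival from birth,
#' \eqn{S(t) = e^{-H_1} e^{-\hat H(t)}}.  `H1` is treated as fixed (it adds
#' no free parameters), so variances scale by \eqn{e^{-2 H_1}}.
#'
#' @param km a `km_curve`.
#' @param H1 finite offset, typically `>= 0` for age-timescale cohorts.
#' @return An `adjusted_km` (extends `km_curve`): adds `H1`, `surv_adj`,
#'   `var_adj`.
#' @export
adjust_km <- function(km, H1) {
  stopifnot(inherits(km, "km_curve"), is.finite(H1))
  out <- unclass(km)
  out$H1 <- H1
  out$surv_adj <- exp(-H1) * km$surv
  out$var_adj <- exp(-2 * H1) * km$var
  structure(out, class = c("adjusted_km", "km_curve"))
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  d <- data.frame(age = x$time, S_hat = x$surv, var = x$var,
                  n_event = x$n_event, n_risk = x$n_risk)
  if (inherits(x, "adjusted_km")) {
    d$S_adj <- x$surv_adj
    d$var_adj <- x$var_adj
  }
  d
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Delayed-entry Kaplan-Meier: %d event ages, %d events\n",
              length(x$time), sum(x$n_event)))
  if (inherits(x, "adjusted_km"))
    cat(sprintf("  offset H1 = %.5g (survival scaled by %.5g)\n",
                x$H1, exp(-x$H1)))
  invisible(x)
}
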