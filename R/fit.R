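#' Indicator design matrix for a covariate schema
#'
#' Expands the factor/character covariate columns of a cohort into 0/1
#' indicator columns named `"covariate=level"`, one per non-baseline level,
#' matching [schema_terms()].
#'
#' @param data data.frame holding one column per schema covariate.
#' @param schema a [covariate_schema()].
#' @return numeric matrix with `schema_terms(schema)` columns.
#' @export
schema_design <- function(data, schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  cols <- list()
  for (nm in names(schema$covariates)) {
    lv <- schema$covariates[[nm]]
    if (!nm %in% names(data)) stop("cohort lacks covariate column '", nm, "'")
    v <- as.character(data[[nm]])
    bad <- !v %in% lv & !is.na(v)
    if (any(bad)) stop("unknown level(s) for '", nm, "': ",
                       paste(unique(v[bad]), collapse = ", "))
    for (l in lv[-1L]) cols[[paste0(nm, "=", l)]] <- as.numeric(v == l)
  }
  do.call(cbind, cols)
}

check_cohort <- function(data) {
  stopifnot(all(c("entry_age", "exit_age", "status") %in% names(data)))
  if (any(data$exit_age < data$entry_age))
    stop("exit_age < entry_age for some rows")
  invisible(data)
}

#' Left-truncated, right-censored log-likelihood
#'
#' \deqn{\ell = \sum_i \left[\delta_i \log f(t_i \mid x_i)
#'   + (1 - \delta_i) \log S(t_i \mid x_i) - \log S(t_{0i} \mid x_i)\right],}
#' with \eqn{t_{0i}} the entry age, \eqn{t_i} the exit age and
#' \eqn{\delta_i} the event indicator.  A parameter/data combination giving a
#' non-positive density at an event age yields `-Inf` (reported, never an
#' error), so optimizers can retreat.
#'
#' @param model a `multistage_model`.
#' @param data cohort data.frame (`entry_age`, `exit_age`, `status`,
#'   covariate columns when the model has a schema).
#' @return log-likelihood in nats.
#' @export
multistage_loglik <- function(model, data) {
  check_cohort(data)
  X <- if (length(model$beta)) schema_design(data, model$covariate_schema)
       else NULL
  d <- data$status == 1
  H_exit <- model_cumhaz(model, data$exit_age, X)
  H_entry <- model_cumhaz(model, data$entry_age, X)
  ll <- -H_exit + H_entry                 # log S(t) - log S(t0)
  if (any(d)) {
    h <- model_hazard(model, data$exit_age[d],
                      if (is.null(X)) NULL else X[d, , drop = FALSE])
    if (any(h <= 0 | !is.finite(h))) return(-Inf)
    ll[d] <- ll[d] + log(h)
  }
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

#' Starting values for maximum-likelihood fitting
#'
#' Coefficients start at a semi-parametric proportional-hazards (Cox) fit;
#' `(m, L)` start from least squares of the log Kaplan--Meier cumulative
#' hazard against log age (the unadjusted step estimator).  The NSM reuses
#' the Weibull `(m0, L0)` — for the rare diseases targeted here
#' \eqn{t \ll L}, where the NSM onset CDF reduces to the Weibull form.
#' A degenerate design (a covariate level with no events, or a failed Cox
#' fit) falls back to zero coefficients with a message.
#'
#' @param data cohort data.frame with at least 2 events.
#' @param family `"weibull"` or `"nsm"`.
#' @param schema optional [covariate_schema()].
#' @return list `m0`, `L0`, `beta0`.
#' @export
initial_values <- function(data, family = c("weibull", "nsm"), schema = NULL) {
  family <- match.arg(family)
  check_cohort(data)
  if (sum(data$status) < 2L) stop("need at least 2 events for initial values")

  beta0 <- stats::setNames(numeric(0), character(0))
  if (!is.null(schema)) {
    X <- schema_design(data, schema)
    beta0 <- stats::setNames(rep(0, ncol(X)), colnames(X))
    no_info <- vapply(seq_len(ncol(X)),
                      function(j) sum(X[data$status == 1, j]) == 0, TRUE)
    ok_cols <- which(!no_info)
    if (length(ok_cols) < ncol(X))
      message("no events at level(s) ",
              paste(colnames(X)[no_info], collapse = ", "),
              "; their starting coefficients set to 0")
    if (length(ok_cols)) {
      cx <- try(survival::coxph(
        survival::Surv(data$entry_age, data$exit_age, data$status) ~
          X[, ok_cols, drop = FALSE]), silent = TRUE)
      if (!inherits(cx, "try-error") && all(is.finite(stats::coef(cx)))) {
        beta0[ok_cols] <- stats::coef(cx)
      } else message("Cox starting fit failed; coefficients start at 0")
    }
  }

  km <- kaplan_meier_delayed_entry(data)
  Hhat <- -log(km$surv)
  use <- Hhat > 0 & is.finite(Hhat) & km$time > 0
  if (sum(use) >= 2L) {
    ls <- stats::lm.fit(cbind(1, log(km$time[use])), log(Hhat[use]))
    m0 <- ls$coefficients[2L]
    m0 <- min(max(m0, 0.3), 25)
    L0 <- exp(-ls$coefficients[1L] / m0)
    L0 <- min(max(L0, 1), 1e6)
  } else {
    m0 <- 1; L0 <- max(data$exit_age)
  }
  list(m0 = unname(m0), L0 = unname(L0), beta0 = beta0)
}

#' Fit a multistage model by maximum likelihood
#'
#' Numerically maximizes the left-truncated, right-censored log-likelihood
#' over \eqn{(\log m, \log L, \beta)} (the log transform enforces
#' positivity) with BFGS; standard errors come from the inverse observed
#' information at the optimum, mapped to the natural scale by the delta
#' method.  Non-convergence is reported in the result, never silently.
#'
#' @param data cohort data.frame with at least 1 event (>= 2 for the default
#'   starting values).
#' @param family `"weibull"` or `"nsm"`.
#' @param schema optional [covariate_schema()] naming the adjustment
#'   covariates; omit for an unadjusted fit.
#' @param init optional list `m0`, `L0`, `beta0` overriding
#'   [initial_values()].
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return A `multistage_fit`: `model` (with estimates), `estimates` table
#'   (term, estimate, se), `loglik`, `vcov_log` (covariance of
#'   `(log m, log L, beta)`), `convergence`, `n_events`, `n_subjects`,
#'   `init`.
#' @examples
#' cfg <- generator_config(2000, weibull_ph(5, 100), seed = 7)
#' fit <- fit_multistage(generate_cohort(cfg))
#' fit$estimates
#' @export
fit_multistage <- function(data, family = c("weibull", "nsm"), schema = NULL,
                           init = NULL, reltol = 1e-10) {
  family <- match.arg(family)
  check_cohort(data)
  n_events <- sum(data$status)
  if (n_events < 1L) stop("no events: nothing to fit")
  if (all(data$exit_age <= data$entry_age))
    stop("all rows censored at entry: no information")
  if (is.null(init)) init <- initial_values(data, family, schema)

  ctor <- if (family == "weibull") weibull_ph else nsm_model
  terms <- if (is.null(schema)) character(0) else schema_terms(schema)
  npar <- 2L + length(terms)
  theta0 <- c(log(init$m0), log(init$L0),
              if (length(terms)) init$beta0[terms] else numeric(0))

  make_model <- function(theta) {
    theta <- unname(theta)
    beta <- if (length(terms)) stats::setNames(theta[-(1:2)], terms)
            else numeric(0)
    ctor(m = exp(theta[1L]), L = exp(theta[2L]), beta = beta,
         covariate_schema = schema)
  }
  negll <- function(theta) {
    if (any(!is.finite(theta)) || theta[1L] > 10 || theta[1L] < -10 ||
        theta[2L] > 30 || theta[2L] < -10) return(1e10)
    ll <- multistage_loglik(make_model(theta), data)
    if (!is.finite(ll)) 1e10 else -ll
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = reltol),
                      hessian = TRUE)
  model <- make_model(opt$par)

  se_log <- rep(NA_real_, npar)
  vcov_log <- matrix(NA_real_, npar, npar)
  hess_ok <- FALSE
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) &&
      all(diag(vc) > 0)) {
    vcov_log <- vc
    se_log <- sqrt(diag(vc))
    hess_ok <- TRUE
  }
  # delta method: se(m) = m * se(log m), se(L) = L * se(log L)
  se_nat <- se_log
  se_nat[1L] <- model$m * se_log[1L]
  se_nat[2L] <- model$L * se_log[2L]

  estimates <- data.frame(
    term = c("m", "L", terms),
    estimate = c(model$m, model$L, unname(model$beta)),
    se = se_nat, stringsAsFactors = FALSE)

  structure(list(
    family = family, model = model, estimates = estimates,
    loglik = -opt$value, vcov_log = vcov_log,
    convergence = list(converged = opt$convergence == 0 && hess_ok,
                       code = opt$convergence,
                       message = if (!is.null(opt$message)) opt$message else "",
                       hessian_ok = hess_ok,
                       evaluations = opt$counts),
    n_events = n_events, n_subjects = nrow(data),
    init = init), class = "multistage_fit")
}

#' @export
print.multistage_fit <- function(x, ...) {
  cat(sprintf("Multistage %s fit: %d subjects, %d events, loglik %.3f\n",
              x$family, x$n_subjects, x$n_events, x$loglik))
  if (!x$convergence$converged) cat("  ** did not converge cleanly **\n")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-18s %10.5g  (se %.4g)\n", est$term[i], est$estimate[i],
                est$se[i]))
  invisible(x)
}

#' Confidence interval for the effective number of steps
#'
#' Wald interval on the log scale (respects positivity), mapped back.
#'
#' @param fit a `multistage_fit`.
#' @param level confidence level.
#' @return length-2 numeric vector.
#' @export
confint_m <- function(fit, level = 0.95) {
  se_logm <- sqrt(fit$vcov_log[1L, 1L])
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log(fit$model$m) + c(-1, 1) * z * se_logm)
}

#' Write fit results as a delimited table
#'
#' One row per (disease, family, term) with estimate, SE, log-likelihood and
#' convergence flag; fixed, documented columns.
#'
#' @param fits named list of `multistage_fit` objects (names = disease ids).
#' @param path CSV path.
#' @return the table, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    cbind(data.frame(disease = id, family = f$family,
                     n_subjects = f$n_subjects, n_events = f$n_events,
                     loglik = f$loglik,
                     converged = f$convergence$converged,
                     stringsAsFactors = FALSE),
          f$estimates)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
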