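#' Weibull proportional-hazards multistage model
#'
#' Constructs the sequential multistage (Armitage--Doll type) model in its
#' Weibull proportional-hazards form.  The cumulative hazard is
#' \deqn{H(t \mid X) = e^{\eta_X} (t/L)^m = \left(\frac{t e^{\eta_X/m}}{L}\right)^m,}
#' with \eqn{\eta_X = \sum_j \beta_j X_j} and survival
#' \eqn{S(t) = \exp(-H(t))}.  \code{m} is the effective number of
#' rate-limiting steps (real-valued, not constrained to an integer) and
#' \code{L} the timescale in age-years.  The second form of \eqn{H} shows that
#' a risk profile multiplies age by the relative aging rate
#' \eqn{e^{\eta_X/m}}; see [relative_aging_rate()].
#'
#' @param m effective number of steps; positive real.
#' @param L timescale in age-years; positive.
#' @param beta named numeric vector of log-hazard-ratio coefficients, one per
#'   non-baseline covariate level (may be empty).
#' @param covariate_schema optional [covariate_schema()] describing covariate
#'   names, levels and baseline level; when supplied, `names(beta)` must equal
#'   the schema's non-baseline level labels.
#' @return An object of class `weibull_ph`.
#' @examples
#' mod <- weibull_ph(m = 5, L = 100)
#' model_survival(mod, 50)         # ~0.969
#' cumhaz_ratio(mod, 50, 100)      # 2^5 = 32
#' @seealso [nsm_model()], [model_survival()], [fit_multistage()]
#' @export
weibull_ph <- function(m, L, beta = numeric(0), covariate_schema = NULL) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0,
            is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  beta <- as.numeric_named(beta)
  if (!is.null(covariate_schema)) {
    expected <- schema_terms(covariate_schema)
    if (!identical(names(beta), expected))
      stop("names(beta) must match the schema's non-baseline levels: ",
           paste(expected, collapse = ", "))
  }
  structure(list(family = "weibull", m = m, L = L, beta = beta,
                 covariate_schema = covariate_schema),
            class = c("weibull_ph", "multistage_model"))
}

#' Non-sequential multistage model (NSM)
#'
#' In the non-sequential model all \eqn{m} rate-limiting events must occur,
#' in any order, each at approximately constant rate \eqn{1/L}.  Its survival
#' function is \deqn{S(t) = 1 - (1 - e^{-t/L})^m.}
#' For integer \eqn{m} the onset age is distributed as the maximum of
#' \eqn{m} iid exponential(\eqn{1/L}) waits (see
#' [simulate_parallel_stages()], the brute-force oracle).  The model carries
#' no covariates by default; an optional proportional-hazards multiplier on
#' its hazard can be enabled for experimentation via `beta` plus a schema.
#'
#' @inheritParams weibull_ph
#' @return An object of class `nsm_model`.
#' @examples
#' mod <- nsm_model(m = 2, L = 100)
#' model_survival(mod, 100)   # 1 - (1 - e^{-1})^2 ~ 0.600
#' @export
nsm_model <- function(m, L, beta = numeric(0), covariate_schema = NULL) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0,
            is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  beta <- as.numeric_named(beta)
  if (!is.null(covariate_schema)) {
    expected <- schema_terms(covariate_schema)
    if (!identical(names(beta), expected))
      stop("names(beta) must match the schema's non-baseline levels")
  }
  structure(list(family = "nsm", m = m, L = L, beta = beta,
                 covariate_schema = covariate_schema),
            class = c("nsm_model", "multistage_model"))
}

as.numeric_named <- function(beta) {
  beta <- unlist(beta)
  if (length(beta) == 0L) return(stats::setNames(numeric(0), character(0)))
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("beta must be a named vector")
  beta
}

#' Covariate schema
#'
#' Ordered description of categorical covariates with a designated baseline
#' level per covariate.  The model's linear predictor is
#' \eqn{\eta_X = \sum \beta_j X_j} over indicator columns for every
#' non-baseline level, so \eqn{\eta_X = 0} at baseline.
#'
#' @param ... one or more named arguments, each a character vector of levels
#'   for that covariate; the first level is the baseline.
#' @return An object of class `covariate_schema`.
#' @examples
#' covariate_schema(diabetes = c("no", "yes"),
#'                  smoking = c("never", "previous", "current"))
#' @export
covariate_schema <- function(...) {
  covs <- list(...)
  if (length(covs) == 0L || is.null(names(covs)) || any(names(covs) == ""))
    stop("supply named covariates, e.g. covariate_schema(diabetes = c('no','yes'))")
  for (nm in names(covs)) {
    lv <- covs[[nm]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      stop("covariate '", nm, "' needs >= 2 distinct character levels")
  }
  structure(list(covariates = covs), class = "covariate_schema")
}

#' Non-baseline term labels of a schema ("covariate=level")
#' @param schema a [covariate_schema()].
#' @return character vector, one entry per non-baseline level, in schema order.
#' @export
schema_terms <- function(schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  unlist(lapply(names(schema$covariates), function(nm) {
    lv <- schema$covariates[[nm]]
    paste0(nm, "=", lv[-1L])
  }), use.names = FALSE)
}

#' Linear predictor eta_X for covariate level profiles
#'
#' @param model a `multistage_model`.
#' @param x either `NULL`/missing (baseline, \eqn{\eta_X = 0}); a named list /
#'   character vector giving the level of each covariate (levels not mentioned
#'   sit at baseline); or a data.frame of indicator columns named like the
#'   model's beta (one row per observation).
#' @return numeric vector of linear predictors.
#' @export
linear_predictor <- function(model, x = NULL) {
  beta <- model$beta
  if (is.null(x)) return(0)
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.matrix(x)
    if (length(beta) == 0L) {
      if (ncol(x) > 0L) stop("model has no covariates but x has columns")
      return(rep(0, nrow(x)))
    }
    missing_terms <- setdiff(names(beta), colnames(x))
    if (length(missing_terms))
      stop("x lacks indicator columns: ", paste(missing_terms, collapse = ", "))
    return(drop(x[, names(beta), drop = FALSE] %*% beta))
  }
  # named level profile, e.g. list(smoking = "current")
  x <- unlist(x)
  if (length(x) == 0L) return(0)
  schema <- model$covariate_schema
  if (is.null(schema)) stop("level profiles need a model with a covariate_schema")
  eta <- 0
  for (nm in names(x)) {
    if (!nm %in% names(schema$covariates))
      stop("unknown covariate '", nm, "'")
    lv <- schema$covariates[[nm]]
    if (!x[[nm]] %in% lv)
      stop("unknown level '", x[[nm]], "' for covariate '", nm, "'")
    if (x[[nm]] != lv[1L]) {
      term <- paste0(nm, "=", x[[nm]])
      eta <- eta + beta[[term]]
    }
  }
  unname(eta)
}

check_ages <- function(t, positive = FALSE) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("ages must be finite numeric")
  if (positive) {
    if (any(t <= 0)) stop("ages must be > 0")
  } else if (any(t < 0)) stop("ages must be >= 0")
  invisible(t)
}

#' Cumulative hazard, survival, hazard and density of a multistage model
#'
#' Closed-form evaluation at ages `t` (years).  For the Weibull
#' proportional-hazards family \eqn{H(t) = e^{\eta_X}(t/L)^m}; for the NSM
#' \eqn{S(t) = 1 - (1 - e^{-t/L})^m} (an optional proportional-hazards
#' multiplier \eqn{e^{\eta_X}} scales the NSM hazard when the model carries
#' coefficients).  Always \eqn{H = -\log S}, \eqn{f = h S}.
#'
#' @param model a `multistage_model` ([weibull_ph()] or [nsm_model()]).
#' @param t ages in years, `>= 0` (`> 0` for hazard/density when `m < 1`,
#'   where the hazard diverges at the origin).
#' @param x covariate specification as in [linear_predictor()]; default baseline.
#' @return numeric vector, one value per age (recycled against rows of `x`).
#' @examples
#' w <- weibull_ph(5, 100)
#' model_cumhaz(w, 50)    # 0.5^5 = 0.03125
#' model_hazard(w, 50)    # (5/50) * 0.5^5
#' @name model-evaluation
NULL

#' @rdname model-evaluation
#' @export
model_cumhaz <- function(model, t, x = NULL) UseMethod("model_cumhaz")

#' @rdname model-evaluation
#' @export
model_survival <- function(model, t, x = NULL) UseMethod("model_survival")

#' @rdname model-evaluation
#' @export
model_hazard <- function(model, t, x = NULL) UseMethod("model_hazard")

#' @rdname model-evaluation
#' @export
model_density <- function(model, t, x = NULL) {
  model_hazard(model, t, x) * model_survival(model, t, x)
}

#' @export
model_cumhaz.weibull_ph <- function(model, t, x = NULL) {
  check_ages(t)
  eta <- linear_predictor(model, x)
  # log-scale for numerical stability; H(0) = 0 exactly
  out <- exp(eta + model$m * (log(t) - log(model$L)))
  out[t == 0] <- 0
  out
}

#' @export
model_survival.weibull_ph <- function(model, t, x = NULL) {
  exp(-model_cumhaz(model, t, x))
}

#' @export
model_hazard.weibull_ph <- function(model, t, x = NULL) {
  check_ages(t, positive = model$m < 1)
  eta <- linear_predictor(model, x)
  m <- model$m
  h <- (m / model$L) * exp(eta + (m - 1) * (log(t) - log(model$L)))
  if (m > 1) h[t == 0] <- 0
  if (m == 1) h[t == 0] <- exp(eta) / model$L
  h
}

#' @export
model_cumhaz.nsm_model <- function(model, t, x = NULL) {
  -log(model_survival(model, t, x))
}

#' @export
model_survival.nsm_model <- function(model, t, x = NULL) {
  check_ages(t)
  eta <- linear_predictor(model, x)
  s0 <- 1 - (-expm1(-t / model$L))^model$m
  if (all(eta == 0)) s0 else s0^exp(eta)  # optional PH multiplier on the hazard
}

#' @export
model_hazard.nsm_model <- function(model, t, x = NULL) {
  check_ages(t, positive = model$m < 1)
  eta <- linear_predictor(model, x)
  m <- model$m; L <- model$L
  Ft <- (-expm1(-t / L))^m                       # (1 - e^{-t/L})^m
  f0 <- (m / L) * exp(-t / L) * (-expm1(-t / L))^(m - 1)
  if (m > 1) f0[t == 0] <- 0
  if (m == 1) f0[t == 0] <- 1 / L
  h0 <- f0 / (1 - Ft)
  if (all(eta == 0)) h0 else exp(eta) * h0
}

#' Ratio of cumulative hazards at two ages
#'
#' For the Weibull family \eqn{H(t_2)/H(t_1) = (t_2/t_1)^m}, independent of
#' the timescale \eqn{L} and of covariates, e.g.
#' \eqn{H(100)/H(50) = 2^m}.  For the NSM the ratio is computed from the
#' closed form and does depend on \eqn{L}.
#'
#' @param model a `multistage_model`.
#' @param t1,t2 ages with `0 < t1 < t2`.
#' @param x covariates (cancel exactly for the Weibull family).
#' @return dimensionless ratio.
#' @export
cumhaz_ratio <- function(model, t1, t2, x = NULL) {
  stopifnot(is.numeric(t1), is.numeric(t2))
  if (any(t1 <= 0) || any(t2 <= t1)) stop("need 0 < t1 < t2")
  if (inherits(model, "weibull_ph")) return((t2 / t1)^model$m)
  model_cumhaz(model, t2, x) / model_cumhaz(model, t1, x)
}

#' @export
print.multistage_model <- function(x, ...) {
  fam <- if (x$family == "weibull") "Weibull proportional-hazards" else "non-sequential (NSM)"
  cat(sprintf("%s multistage model\n  m (effective steps): %.6g\n  L (timescale, years): %.6g\n",
              fam, x$m, x$L))
  if (length(x$beta)) {
    cat("  coefficients (log hazard ratios):\n")
    for (nm in names(x$beta)) cat(sprintf("    %s: %+.6g\n", nm, x$beta[[nm]]))
  }
  invisible(x)
}

#' Serialize / deserialize a model as flat key-value text
#'
#' Writes `family`, `m`, `L`, one `beta.<term>` line per coefficient and the
#' schema as `schema.<covariate>` level lists.  Numeric values are written
#' with full precision (`format(..., digits = 17)`) so a read back
#' reconstructs the model bit-exactly.
#'
#' @param model a `multistage_model`.
#' @param path file to write / read.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "multistage_model"))
  num <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(paste0("family: ", model$family),
             paste0("m: ", num(model$m)),
             paste0("L: ", num(model$L)))
  for (nm in names(model$beta))
    lines <- c(lines, paste0("beta.", nm, ": ", num(model$beta[[nm]])))
  if (!is.null(model$covariate_schema))
    for (nm in names(model$covariate_schema$covariates))
      lines <- c(lines, paste0("schema.", nm, ": ",
                               paste(model$covariate_schema$covariates[[nm]],
                                     collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  get1 <- function(k) vals[match(k, keys)]
  fam <- get1("family")
  m <- as.numeric(get1("m")); L <- as.numeric(get1("L"))
  bi <- grepl("^beta\\.", keys)
  beta <- stats::setNames(as.numeric(vals[bi]), sub("^beta\\.", "", keys[bi]))
  si <- grepl("^schema\\.", keys)
  schema <- NULL
  if (any(si)) {
    covs <- lapply(vals[si], function(v) strsplit(v, ",", fixed = TRUE)[[1L]])
    names(covs) <- sub("^schema\\.", "", keys[si])
    schema <- do.call(covariate_schema, covs)
  }
  ctor <- switch(fam, weibull = weibull_ph, nsm = nsm_model,
                 stop("unknown family: ", fam))
  ctor(m = m, L = L, beta = beta, covariate_schema = schema)
}
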