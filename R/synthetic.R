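#' Synthetic cohort generator configuration
#'
#' Describes a cohort with the structure assumed by the incidence analysis:
#' middle-aged entry (ages drawn from a Normal(57, 8) truncated to
#' \[49, 69\], matching the enrolment profile of large population cohorts),
#' left truncation at entry (subjects are disease-free when they join),
#' right censoring at study end a fixed number of follow-up years later, and
#' optional censoring at an independently drawn competing cancer age.
#'
#' @param n_subjects number of subjects.
#' @param true_model the data-generating [weibull_ph()] or [nsm_model()];
#'   if it carries coefficients it must also carry a covariate schema.
#' @param prevalences named list, one entry per schema covariate: numeric
#'   vector of level prevalences (summing to 1, in level order).  Required
#'   when the model has covariates.
#' @param followup_years follow-up per subject, years (> 0 unless you want a
#'   degenerate all-censored cohort).
#' @param entry_age_mean,entry_age_sd,entry_age_min,entry_age_max truncated
#'   normal entry-age law, years.
#' @param competing_cancer_rate per-year rate of a competing cancer that
#'   censors follow-up; 0 disables it.
#' @param seed integer seed recorded in the config and used by
#'   [generate_cohort()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_subjects, true_model, prevalences = NULL,
                             followup_years = 10,
                             entry_age_mean = 57, entry_age_sd = 8,
                             entry_age_min = 49, entry_age_max = 69,
                             competing_cancer_rate = 0, seed = 1L) {
  stopifnot(n_subjects > 0, followup_years >= 0,
            entry_age_min < entry_age_max, entry_age_sd > 0,
            competing_cancer_rate >= 0,
            inherits(true_model, "multistage_model"))
  schema <- true_model$covariate_schema
  if (length(true_model$beta) > 0 && is.null(schema))
    stop("a model with coefficients needs a covariate_schema")
  if (!is.null(schema)) {
    if (is.null(prevalences) ||
        !setequal(names(prevalences), names(schema$covariates)))
      stop("prevalences must name every schema covariate")
    for (nm in names(schema$covariates)) {
      p <- prevalences[[nm]]
      if (length(p) != length(schema$covariates[[nm]]) ||
          abs(sum(p) - 1) > 1e-8 || any(p < 0))
        stop("prevalences for '", nm, "' must be non-negative and sum to 1")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), true_model = true_model,
                 prevalences = prevalences, followup_years = followup_years,
                 entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
                 entry_age_min = entry_age_min, entry_age_max = entry_age_max,
                 competing_cancer_rate = competing_cancer_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample entry ages from the truncated normal law
#'
#' Inverse-CDF sampling (deterministic given the uniform deviates), so
#' cohorts are reproducible across platforms.
#'
#' @param n number of draws, or `u` a vector of uniforms.
#' @param config a [generator_config()].
#' @param u optional uniform deviates in (0,1); drawn if missing.
#' @return entry ages in years.
#' @export
sample_entry_ages <- function(n, config, u = stats::runif(n)) {
  plo <- stats::pnorm(config$entry_age_min, config$entry_age_mean, config$entry_age_sd)
  phi <- stats::pnorm(config$entry_age_max, config$entry_age_mean, config$entry_age_sd)
  stats::qnorm(plo + u * (phi - plo), config$entry_age_mean, config$entry_age_sd)
}

#' Draw disease onset ages conditional on being event-free at entry
#'
#' Inverts the closed-form survival functions.  For the Weibull
#' proportional-hazards model the solution of \eqn{S(t) = u\,S(t_0)} is
#' \deqn{t = L\left((t_0/L)^m - e^{-\eta_X} \log u\right)^{1/m},}
#' and for the NSM the onset CDF \eqn{F(t) = (1 - e^{-t/L})^m} is inverted at
#' \eqn{F(t_0) + u\,(1 - F(t_0))} (here `u` plays the role of the conditional
#' CDF level rather than a survival level, so increasing `u` gives later
#' onset; either convention yields the same law for uniform `u`).
#'
#' @param t0 entry ages (years), `>= 0`.
#' @param model a `multistage_model`.
#' @param u uniform deviates strictly inside (0, 1).
#' @param x covariates as in [linear_predictor()] (Weibull only).
#' @return onset ages `t >= t0`.
#' @examples
#' sample_onset_weibull(0, weibull_ph(1, 100), u = 0.5)  # 69.3147
#' @export
sample_onset_weibull <- function(t0, model, u, x = NULL) {
  stopifnot(inherits(model, "weibull_ph"), all(t0 >= 0))
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  eta <- linear_predictor(model, x)
  m <- model$m; L <- model$L
  L * ((t0 / L)^m - exp(-eta) * log(u))^(1 / m)
}

#' @rdname sample_onset_weibull
#' @export
sample_onset_nsm <- function(t0, model, u) {
  stopifnot(inherits(model, "nsm_model"), all(t0 >= 0))
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  m <- model$m; L <- model$L
  F0 <- (-expm1(-t0 / L))^m
  Ft <- F0 + u * (1 - F0)
  -L * log(1 - Ft^(1 / m))
}

onset_sampler <- function(model) {
  if (inherits(model, "weibull_ph")) {
    function(t0, u, x) sample_onset_weibull(t0, model, u, x)
  } else {
    function(t0, u, x) sample_onset_nsm(t0, model, u)
  }
}

draw_covariates <- function(n, schema, prevalences) {
  out <- list()
  for (nm in names(schema$covariates)) {
    lv <- schema$covariates[[nm]]
    out[[nm]] <- factor(sample(lv, n, replace = TRUE, prob = prevalences[[nm]]),
                        levels = lv)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a left-truncated, right-censored synthetic cohort
#'
#' For each subject: draw covariate levels and an entry age; draw a disease
#' onset age from the true model conditional on being event-free at entry
#' (`truncation = "conditional"`, the default) or by discarding simulated
#' subjects whose onset precedes entry (`"rejection"`, kept to validate that
#' both routes give the same truncated law); censor at study end
#' (entry + follow-up) and, when `competing_cancer_rate > 0`, at an
#' independent exponential competing-cancer age.  Deterministic given the
#' config's seed.
#'
#' @param config a [generator_config()].
#' @param truncation `"conditional"` or `"rejection"`.
#' @return A data.frame of class `cohort` with columns `id`, `sex`,
#'   `entry_age`, `exit_age`, `status` (1 = disease onset observed) and one
#'   column per schema covariate; the config is attached as an attribute.
#' @export
generate_cohort <- function(config, truncation = c("conditional", "rejection")) {
  stopifnot(inherits(config, "generator_config"))
  truncation <- match.arg(truncation)
  model <- config$true_model
  schema <- model$covariate_schema
  n <- config$n_subjects
  set.seed(config$seed)

  draw_block <- function(nb) {
    entry <- sample_entry_ages(nb, config)
    covs <- if (!is.null(schema)) draw_covariates(nb, schema, config$prevalences)
            else NULL
    X <- if (!is.null(schema)) schema_design(covs, schema) else NULL
    u <- stats::runif(nb)
    t0 <- if (truncation == "conditional") entry else rep(0, nb)
    onset <- onset_sampler(model)(t0, u, X)
    list(entry = entry, covs = covs, onset = onset)
  }

  if (truncation == "conditional") {
    b <- draw_block(n)
  } else {
    # keep only subjects still event-free at entry
    entry <- numeric(0); onset <- numeric(0); covs <- NULL
    while (length(entry) < n) {
      nb <- max(1000L, n - length(entry))
      blk <- draw_block(nb)
      keep <- blk$onset >= blk$entry
      entry <- c(entry, blk$entry[keep])
      onset <- c(onset, blk$onset[keep])
      covs <- if (is.null(covs)) blk$covs[keep, , drop = FALSE]
              else rbind(covs, blk$covs[keep, , drop = FALSE])
    }
    b <- list(entry = entry[seq_len(n)], onset = onset[seq_len(n)],
              covs = if (!is.null(covs)) covs[seq_len(n), , drop = FALSE])
  }

  study_end <- b$entry + config$followup_years
  censor <- study_end
  if (config$competing_cancer_rate > 0) {
    cancer_age <- b$entry + stats::rexp(n, config$competing_cancer_rate)
    censor <- pmin(censor, cancer_age)
  }
  status <- as.integer(b$onset <= censor)
  exit <- pmin(b$onset, censor)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  out <- data.frame(id = seq_len(n), sex = sex, entry_age = b$entry,
                    exit_age = exit, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(b$covs)) out <- cbind(out, b$covs)
  class(out) <- c("cohort", "data.frame")
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  out
}

#' Brute-force multistage simulators (test oracles)
#'
#' `simulate_sequential_multistage` draws onset ages as sums of independent
#' exponential stage waits (a hypoexponential law) — the sequential
#' multistage picture whose small-age CDF is approximated by the Weibull
#' form \eqn{F(t) \approx (\prod_i \lambda_i)\, t^m / m!}.
#' `simulate_parallel_stages` draws onset ages as the maximum of `m` iid
#' exponential(\eqn{1/L}) waits — exactly the NSM law for integer `m`.
#'
#' @param rates positive per-year rates, one per sequential stage.
#' @param L timescale in years; `m` integer number of parallel stages.
#' @param n number of draws; `seed` RNG seed.
#' @return numeric vector of onset ages (years).
#' @export
simulate_sequential_multistage <- function(rates, n, seed = 1L) {
  stopifnot(length(rates) >= 1L, all(rates > 0), n > 0)
  set.seed(seed)
  waits <- vapply(rates, function(r) stats::rexp(n, r), numeric(n))
  if (n == 1L) sum(waits) else rowSums(matrix(waits, nrow = n))
}

#' @rdname simulate_sequential_multistage
#' @export
simulate_parallel_stages <- function(L, m, n, seed = 1L) {
  stopifnot(L > 0, m >= 1, m == as.integer(m), n > 0)
  set.seed(seed)
  draws <- matrix(stats::rexp(n * m, 1 / L), nrow = n)
  apply(draws, 1L, max)
}

#' Exact CDF of the sum of independent exponential stage waits
#'
#' Closed-form hypoexponential CDF (distinct rates via partial fractions;
#' equal rates via the Erlang/gamma form).  Used as the independent oracle
#' for the sequential simulator and the small-age Weibull approximation.
#'
#' @param t ages (years).
#' @param rates positive per-year rates, one per stage.
#' @return `P(sum of waits <= t)`.
#' @export
hypoexp_cdf <- function(t, rates) {
  stopifnot(all(rates > 0))
  k <- length(rates)
  if (length(unique(rates)) == 1L)
    return(stats::pgamma(t, shape = k, rate = rates[1L]))
  if (anyDuplicated(rates))
    stop("rates must be all-equal or all-distinct")
  w <- vapply(seq_len(k), function(i) prod(rates[-i] / (rates[-i] - rates[i])), 0)
  vapply(t, function(tt) 1 - sum(w * exp(-rates * tt)), 0)
}

#' Generate a synthetic hospital-episode table with known ground truth
#'
#' Emits per-subject episodes (age, ICD-10 code, primary-diagnosis flag) for
#' a set of diseases in (possibly) different ICD-10 chapters, together with
#' the ground truth the preparation stage must recover: which subjects carry
#' a disqualifying pre-entry cancer, and each subject's true first primary
#' event per chapter.  Some subjects receive later same-chapter episodes and
#' non-primary episodes, which first-event extraction must ignore.
#'
#' @param config a [generator_config()] (entry-age law, follow-up and seed
#'   are used; its true model is the onset law for every disease unless a
#'   disease provides its own).
#' @param diseases data.frame with columns `code` (ICD-10, e.g. "I21.0") and
#'   optionally `m`, `L` (per-disease Weibull parameters; the config model's
#'   are used when absent).
#' @param prob_prior_cancer probability a subject carries a pre-entry cancer
#'   episode (excluded ground truth); `prob_secondary` probability that an
#'   event also generates a later non-primary episode in the same chapter.
#' @return list with `subjects` (id, sex, entry_age, exit_age), `episodes`
#'   (id, age, code, primary) and `truth` (`excluded_ids`, `first_events`).
#' @export
generate_episode_table <- function(config, diseases,
                                   prob_prior_cancer = 0.05,
                                   prob_secondary = 0.3) {
  stopifnot(inherits(config, "generator_config"),
            is.data.frame(diseases), "code" %in% names(diseases))
  set.seed(config$seed)
  n <- config$n_subjects
  entry <- sample_entry_ages(n, config)
  study_end <- entry + config$followup_years
  sex <- sample(c("F", "M"), n, replace = TRUE)
  subjects <- data.frame(id = seq_len(n), sex = sex, entry_age = entry,
                         exit_age = study_end, stringsAsFactors = FALSE)

  chapters <- icd10_chapter(diseases$code)
  ep <- list(); truth_ev <- list()
  for (d in seq_len(nrow(diseases))) {
    m <- if ("m" %in% names(diseases)) diseases$m[d] else config$true_model$m
    L <- if ("L" %in% names(diseases)) diseases$L[d] else config$true_model$L
    mod <- weibull_ph(m = m, L = L)
    onset <- sample_onset_weibull(entry, mod, stats::runif(n))
    obs <- onset <= study_end
    if (any(obs)) {
      ep[[length(ep) + 1L]] <- data.frame(
        id = subjects$id[obs], age = onset[obs],
        code = diseases$code[d], primary = TRUE, stringsAsFactors = FALSE)
      truth_ev[[length(truth_ev) + 1L]] <- data.frame(
        id = subjects$id[obs], chapter = chapters[d], age = onset[obs],
        code = diseases$code[d], stringsAsFactors = FALSE)
      # later same-chapter secondary (non-primary) episodes: must be ignored
      sec <- obs & (stats::runif(n) < prob_secondary)
      if (any(sec))
        ep[[length(ep) + 1L]] <- data.frame(
          id = subjects$id[sec], age = onset[sec] + stats::runif(sum(sec), 0.1, 2),
          code = diseases$code[d], primary = FALSE, stringsAsFactors = FALSE)
    }
  }
  prior <- stats::runif(n) < prob_prior_cancer
  if (any(prior))
    ep[[length(ep) + 1L]] <- data.frame(
      id = subjects$id[prior],
      age = pmax(entry[prior] - stats::runif(sum(prior), 0.5, 10), 1),
      code = "C50.9", primary = TRUE, stringsAsFactors = FALSE)

  episodes <- do.call(rbind, ep)
  episodes <- episodes[order(episodes$id, episodes$age), , drop = FALSE]
  rownames(episodes) <- NULL

  fe <- do.call(rbind, truth_ev)
  fe <- fe[!fe$id %in% subjects$id[prior], , drop = FALSE]
  # ground-truth first primary event per (subject, chapter)
  fe <- fe[order(fe$id, fe$chapter, fe$age, fe$code), , drop = FALSE]
  fe <- fe[!duplicated(fe[c("id", "chapter")]), , drop = FALSE]
  rownames(fe) <- NULL

  list(subjects = subjects, episodes = episodes,
       truth = list(excluded_ids = subjects$id[prior], first_events = fe))
}

#' Serialize a generator configuration as YAML
#'
#' Round-trips every field including the true model (family, m, L, named
#' coefficients, schema levels) and the seed, so a simulation is fully
#' reproducible from its config file.
#'
#' @param config a [generator_config()].
#' @param path YAML file to write / read.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` the config.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  mod <- config$true_model
  x <- list(
    n_subjects = config$n_subjects, seed = config$seed,
    followup_years = config$followup_years,
    entry_age = list(mean = config$entry_age_mean, sd = config$entry_age_sd,
                     min = config$entry_age_min, max = config$entry_age_max),
    competing_cancer_rate = config$competing_cancer_rate,
    prevalences = config$prevalences,
    true_model = list(
      family = mod$family, m = mod$m, L = mod$L,
      beta = if (length(mod$beta)) as.list(mod$beta) else NULL,
      schema = if (!is.null(mod$covariate_schema))
        mod$covariate_schema$covariates else NULL))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  schema <- if (!is.null(x$true_model$schema))
    do.call(covariate_schema, x$true_model$schema) else NULL
  ctor <- switch(x$true_model$family, weibull = weibull_ph, nsm = nsm_model)
  mod <- ctor(m = x$true_model$m, L = x$true_model$L,
              beta = unlist(x$true_model$beta), covariate_schema = schema)
  generator_config(
    n_subjects = x$n_subjects, true_model = mod,
    prevalences = lapply(x$prevalences, unlist),
    followup_years = x$followup_years,
    entry_age_mean = x$entry_age$mean, entry_age_sd = x$entry_age$sd,
    entry_age_min = x$entry_age$min, entry_age_max = x$entry_age$max,
    competing_cancer_rate = x$competing_cancer_rate, seed = x$seed)
}

#' Write a cohort and its generator metadata as delimited text
#'
#' @param cohort a `cohort` data.frame.
#' @param path CSV path; a sidecar `<path>.meta` records the seed.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  seed <- attr(cohort, "seed")
  if (!is.null(seed))
    writeLines(paste0("seed: ", seed), paste0(path, ".meta"))
  invisible(path)
}
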