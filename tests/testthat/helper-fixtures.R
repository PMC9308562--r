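# shared fixtures built in code

diabetes_schema <- function() covariate_schema(diabetes = c("no", "yes"))

study_model <- function(beta_diabetes = 0.5) {
  weibull_ph(m = 5, L = 100,
             beta = c("diabetes=yes" = beta_diabetes),
             covariate_schema = diabetes_schema())
}

study_config <- function(n = 20000, seed = 1L, model = study_model(), ...) {
  prev <- if (length(model$beta)) list(diabetes = c(0.9, 0.1)) else NULL
  generator_config(n, model, prevalences = prev, seed = seed, ...)
}

# cohort with every subject entering at the same age (no entry-age spread)
common_entry_cohort <- function(n, model, entry = 50, followup = 30, seed = 1L) {
  set.seed(seed)
  onset <- sample_onset_weibull(rep(entry, n), model, stats::runif(n))
  cens <- entry + followup
  data.frame(id = seq_len(n), entry_age = entry,
             exit_age = pmin(onset, cens),
             status = as.integer(onset <= cens))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(n * p[o][i:n] / (i:n)))
  }, 0)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
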