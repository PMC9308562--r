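test_that("conditional onset sampling inverts the closed forms", {
  w1 <- weibull_ph(1, 100)
  expect_equal(sample_onset_weibull(0, w1, 0.5), -100 * log(0.5))  # 69.3147
  expect_equal(sample_onset_weibull(0, w1, 0.5), 69.3147, tolerance = 1e-5)
  # u -> 1 means no further waiting beyond entry
  expect_equal(sample_onset_weibull(50, weibull_ph(5, 100), 1 - 1e-12), 50,
               tolerance = 1e-6)
  n1 <- nsm_model(1, 100)
  expect_equal(sample_onset_nsm(0, n1, 0.5), 69.3147, tolerance = 1e-4)
  # inverts the NSM survival example: S(100) = 0.60042 so F(100) = 0.39958
  n2 <- nsm_model(2, 100)
  expect_equal(sample_onset_nsm(0, n2, 1 - model_survival(n2, 100)), 100,
               tolerance = 1e-8)
  expect_error(sample_onset_weibull(0, w1, 0), "u must")
  expect_error(sample_onset_nsm(0, n1, 1), "u must")
})

test_that("draws at delayed entry follow the conditional law (KS at n = 1e5)", {
  n <- 1e5
  ks_threshold <- 1.36 / sqrt(n)
  set.seed(7)
  w <- weibull_ph(5, 100)
  tw <- sample_onset_weibull(rep(50, n), w, runif(n))
  expect_true(all(tw >= 50))
  cdf_w <- function(t) 1 - exp(-(model_cumhaz(w, t) - model_cumhaz(w, 50)))
  Dw <- suppressWarnings(ks.test(tw, cdf_w)$statistic)
  expect_lt(Dw, ks_threshold)
  nm <- nsm_model(3, 60)
  tn <- sample_onset_nsm(rep(50, n), nm, runif(n))
  expect_true(all(tn >= 50))
  cdf_n <- function(t) 1 - model_survival(nm, t) / model_survival(nm, 50)
  Dn <- suppressWarnings(ks.test(tn, cdf_n)$statistic)
  expect_lt(Dn, ks_threshold)
})

test_that("cohort generation is deterministic and respects the config", {
  cfg <- study_config(n = 3000, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(a$exit_age >= a$entry_age))
  expect_true(all(a$entry_age >= 49 & a$entry_age <= 69))
  # zero follow-up: everyone censored at entry
  cfg0 <- study_config(n = 500, seed = 5, followup_years = 0)
  z <- generate_cohort(cfg0)
  expect_equal(sum(z$status), 0)
  expect_equal(z$exit_age, z$entry_age)
})

test_that("observed event fraction matches the closed-form expectation", {
  mod <- weibull_ph(5, 100)
  cfg <- generator_config(20000, mod, followup_years = 10, seed = 21)
  co <- generate_cohort(cfg)
  # P(event) = E over entry law of 1 - S(t0 + 10)/S(t0)
  dens <- function(t0) {
    plo <- pnorm(49, 57, 8); phi <- pnorm(69, 57, 8)
    dnorm(t0, 57, 8) / (phi - plo)
  }
  p_event <- integrate(function(t0) {
    dens(t0) * (1 - model_survival(mod, t0 + 10) / model_survival(mod, t0))
  }, 49, 69)$value
  se <- sqrt(p_event * (1 - p_event) / 20000)
  expect_lt(abs(mean(co$status) - p_event), 3 * se)
})

test_that("rejection and conditional truncation modes give the same law", {
  mod <- weibull_ph(5, 100)
  cfg <- generator_config(8000, mod, followup_years = 30, seed = 9)
  cond <- generate_cohort(cfg, truncation = "conditional")
  rej <- generate_cohort(cfg, truncation = "rejection")
  ev_c <- cond$exit_age[cond$status == 1]
  ev_r <- rej$exit_age[rej$status == 1]
  expect_gt(length(ev_c), 500)
  expect_gt(suppressWarnings(ks.test(ev_c, ev_r)$p.value), 1e-3)
})

test_that("sequential simulator matches the hypoexponential closed form", {
  # one stage: exponential with mean 1/rate
  x1 <- simulate_sequential_multistage(0.01, n = 2e4, seed = 3)
  expect_equal(mean(x1), 100, tolerance = 3 * 100 / sqrt(2e4) / 100)
  # mean = sum of stage means, within 3 standard errors
  rates <- c(0.01, 0.02, 0.05)
  x <- simulate_sequential_multistage(rates, n = 2e4, seed = 4)
  se <- sd(x) / sqrt(2e4)
  expect_lt(abs(mean(x) - sum(1 / rates)), 3 * se)
  # closed-form CDF: two equal stages at 0.01/y, F(10) = 1 - e^{-0.1}(1.1)
  expect_equal(hypoexp_cdf(10, c(0.01, 0.01)), 1 - exp(-0.1) * 1.1)
  expect_equal(hypoexp_cdf(10, c(0.01, 0.01)), 0.004679, tolerance = 1e-4)
  x2 <- simulate_sequential_multistage(c(0.01, 0.01), n = 1e5, seed = 5)
  expect_lt(abs(mean(x2 <= 10) - 0.004679), 3 * sqrt(0.004679 / 1e5))
  # distinct-rate partial fractions agree with the empirical CDF
  D <- suppressWarnings(ks.test(x, function(t) hypoexp_cdf(t, rates))$statistic)
  expect_lt(D, 1.36 / sqrt(2e4))
})

test_that("small-age Weibull form converges to the sequential CDF", {
  rates <- c(0.01, 0.01)
  m <- 2
  L <- (factorial(m) / prod(rates))^(1 / m)   # sqrt(20000) ~ 141.42
  expect_equal(L, sqrt(20000))
  expect_equal((10 / L)^m, 0.005)
  ratio <- sapply(c(0.01, 0.05, 0.1), function(frac) {
    t <- frac * L
    (t / L)^m / hypoexp_cdf(t, rates)
  })
  expect_true(all(diff(ratio) > 0))            # approaches 1 from above as t -> 0
  expect_lt(abs(ratio[1] - 1), 0.05)
})

test_that("parallel-stage oracle reproduces the NSM law", {
  x1 <- simulate_parallel_stages(100, m = 1, n = 2e4, seed = 6)
  D1 <- suppressWarnings(ks.test(x1, pexp, rate = 0.01)$statistic)
  expect_lt(D1, 1.36 / sqrt(2e4))
  n <- 1e5
  x2 <- simulate_parallel_stages(100, m = 2, n = n, seed = 7)
  S100 <- 1 - (1 - exp(-1))^2
  expect_lt(abs(mean(x2 > 100) - S100), 3 * sqrt(S100 * (1 - S100) / n))
  mod <- nsm_model(2, 100)
  D2 <- suppressWarnings(
    ks.test(x2, function(t) 1 - model_survival(mod, t))$statistic)
  expect_lt(D2, 1.36 / sqrt(n))
})

test_that("raising one sequential rate lifts log H and flattens its slope", {
  # three equal rate-limiting stages vs one stage accelerated 100-fold
  fit_slope <- function(rates, seed) {
    onset <- simulate_sequential_multistage(rates, n = 6000, seed = seed)
    d <- data.frame(entry_age = 0, exit_age = pmin(onset, 60),
                    status = as.integer(onset <= 60))
    fit <- fit_multistage(d)
    c(m = fit$model$m, logH50 = log(model_cumhaz(fit$model, 50)))
  }
  base <- fit_slope(c(0.02, 0.02, 0.02), seed = 31)
  fast <- fit_slope(c(2.00, 0.02, 0.02), seed = 32)
  expect_lt(fast[["m"]], base[["m"]])          # a rate-limiting step vanishes
  expect_gt(fast[["logH50"]], base[["logH50"]])
})

test_that("generator configs round-trip through YAML", {
  cfg <- study_config(n = 1234, seed = 99, followup_years = 8,
                      competing_cancer_rate = 0.002)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$n_subjects, cfg$n_subjects)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$true_model$m, cfg$true_model$m)
  expect_equal(back$true_model$beta, cfg$true_model$beta)
  expect_equal(back$prevalences$diabetes,
               unname(cfg$prevalences$diabetes))
  # and the cohorts they generate are identical
  a <- generate_cohort(back); b <- generate_cohort(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
})

test_that("episode tables carry recoverable ground truth", {
  cfg <- generator_config(800, weibull_ph(3, 60), followup_years = 10,
                          seed = 13)
  diseases <- data.frame(code = c("I21", "K52", "C34"),
                         m = c(3, 2, 4), L = c(60, 80, 90))
  tab <- generate_episode_table(cfg, diseases)
  tab2 <- generate_episode_table(cfg, diseases)
  expect_identical(tab, tab2)                  # seed determinism
  expect_true(all(c("id", "age", "code", "primary") %in% names(tab$episodes)))
  fe <- tab$truth$first_events
  expect_true(all(fe$chapter %in% c("IX", "XI", "II")))
  # excluded subjects have a pre-entry cancer episode and no truth rows
  for (id in tab$truth$excluded_ids) {
    ep <- tab$episodes[tab$episodes$id == id, ]
    entry <- tab$subjects$entry_age[tab$subjects$id == id]
    expect_true(any(ep$code == "C50.9" & ep$age < entry))
    expect_false(id %in% fe$id)
  }
})
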