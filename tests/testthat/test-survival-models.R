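test_that("Weibull closed forms match hand-evaluated values", {
  w <- weibull_ph(m = 5, L = 100)
  expect_equal(model_cumhaz(w, 0), 0)
  expect_equal(model_cumhaz(w, 100), 1)                # (L/L)^m = 1
  expect_equal(model_cumhaz(w, 50), 0.5^5)             # 0.03125
  expect_equal(model_survival(w, 0), 1)
  expect_equal(model_survival(w, 100), exp(-1))
  expect_equal(model_survival(w, 50), exp(-0.03125))
  expect_equal(model_hazard(w, 50), (5 / 50) * 0.5^5)  # 0.003125
  w1 <- weibull_ph(m = 1, L = 100)
  expect_equal(model_hazard(w1, 50), 0.01)             # exponential rate 1/L
})

test_that("Weibull agrees with the standard shape/scale parameterization", {
  s <- covariate_schema(smoking = c("never", "current"))
  w <- weibull_ph(3.2, 85, beta = c("smoking=current" = 0.7),
                  covariate_schema = s)
  x <- list(smoking = "current")
  t <- c(1, 20, 50, 80, 120)
  # H = e^eta (t/L)^m is a Weibull with shape m, scale L e^{-eta/m}
  scale <- 85 * exp(-0.7 / 3.2)
  expect_equal(model_survival(w, t, x),
               pweibull(t, shape = 3.2, scale = scale, lower.tail = FALSE))
  expect_equal(model_density(w, t, x),
               dweibull(t, shape = 3.2, scale = scale))
})

test_that("NSM closed form, density and small-age hazard behave", {
  n2 <- nsm_model(m = 2, L = 100)
  expect_equal(model_survival(n2, 0), 1)
  expect_equal(model_survival(n2, 100), 1 - (1 - exp(-1))^2)  # ~0.60042
  # m = 1 reduces to the exponential for all t
  n1 <- nsm_model(1, 100)
  t <- seq(0, 300, by = 7)
  expect_equal(model_survival(n1, t), exp(-t / 100))
  expect_equal(model_density(n1, t), 0.01 * exp(-t / 100))
  # density equals the numerical derivative of F = 1 - S
  grid <- seq(5, 250, by = 5)
  eps <- 1e-5
  fd <- (model_survival(n2, grid - eps) - model_survival(n2, grid + eps)) /
    (2 * eps)
  expect_equal(model_density(n2, grid), fd, tolerance = 1e-6)
  # h(t) -> (m/L)(t/L)^{m-1} as t -> 0 for integer m
  for (m in 2:4) {
    mod <- nsm_model(m, 100)
    t0 <- 1e-3 * 100
    expect_equal(model_hazard(mod, t0), (m / 100) * (t0 / 100)^(m - 1),
                 tolerance = 5e-3)
  }
})

test_that("survival identities hold on random parameter draws", {
  set.seed(42)
  grid <- seq(0.5, 150, length.out = 60)
  for (i in 1:25) {
    m <- runif(1, 0.5, 9)
    L <- runif(1, 30, 500)
    mod <- if (i %% 2) weibull_ph(m, L) else nsm_model(m, L)
    S <- model_survival(mod, grid)
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(diff(S) <= 0))
    ok <- S > 0   # H = -log S only representable while S has not underflowed
    expect_lt(max(abs(model_cumhaz(mod, grid)[ok] - (-log(S[ok])))), 1e-12)
    expect_equal(model_density(mod, grid) / model_hazard(mod, grid), S)
  }
  # NSM m = 1 and Weibull m = 1 with equal L coincide
  expect_equal(model_survival(nsm_model(1, 77), grid),
               model_survival(weibull_ph(1, 77), grid))
})

test_that("log cumulative hazard is linear in log age with slope m; covariates shift it", {
  s <- covariate_schema(diabetes = c("no", "yes"))
  w <- weibull_ph(4.2, 120, beta = c("diabetes=yes" = 0.6),
                  covariate_schema = s)
  t <- exp(seq(log(2), log(140), length.out = 20))
  lH <- log(model_cumhaz(w, t))
  slope <- diff(lH) / diff(log(t))
  expect_equal(slope, rep(4.2, 19))
  lH_dia <- log(model_cumhaz(w, t, list(diabetes = "yes")))
  expect_equal(lH_dia - lH, rep(0.6, 20))   # vertical displacement only
})

test_that("cumulative hazard ratios depend only on m", {
  expect_equal(cumhaz_ratio(weibull_ph(1, 100), 50, 100), 2)
  expect_equal(cumhaz_ratio(weibull_ph(5, 100), 50, 100), 32)
  s <- covariate_schema(diabetes = c("no", "yes"))
  a <- weibull_ph(5, 100)
  b <- weibull_ph(5, 350, beta = c("diabetes=yes" = 1.2), covariate_schema = s)
  expect_equal(cumhaz_ratio(a, 50, 100), cumhaz_ratio(b, 50, 100))
  expect_error(cumhaz_ratio(a, 0, 100), "t1")
})

test_that("invalid inputs are rejected", {
  expect_error(weibull_ph(-1, 100))
  expect_error(weibull_ph(5, 0))
  expect_error(model_cumhaz(weibull_ph(5, 100), c(1, NA)), "finite")
  expect_error(model_hazard(weibull_ph(0.5, 100), 0), "> 0")
  s <- covariate_schema(diabetes = c("no", "yes"))
  w <- weibull_ph(5, 100, beta = c("diabetes=yes" = 0.5), covariate_schema = s)
  expect_error(model_cumhaz(w, 50, list(diabetes = "maybe")), "level")
  expect_error(weibull_ph(5, 100, beta = c("smoking=yes" = 1),
                          covariate_schema = s), "schema")
})

test_that("models round-trip through the flat key-value format bit-exactly", {
  s <- covariate_schema(diabetes = c("no", "yes"),
                        smoking = c("never", "previous", "current"))
  w <- weibull_ph(m = 4.123456789012345, L = 97.87654321098765,
                  beta = c("diabetes=yes" = 0.512345678901234,
                           "smoking=previous" = -0.1,
                           "smoking=current" = 1 / 3),
                  covariate_schema = s)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(w, path)
  back <- read_model(path)
  expect_identical(back$m, w$m)
  expect_identical(back$L, w$L)
  expect_identical(back$beta, w$beta)
  expect_identical(back$covariate_schema$covariates, s$covariates)
  n <- nsm_model(2.5, 333.25)
  write_model(n, path)
  expect_identical(read_model(path)[c("family", "m", "L")],
                   n[c("family", "m", "L")])
})
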