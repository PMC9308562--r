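test_that("relative aging rate is the m-th root of relative risk", {
  s <- covariate_schema(diabetes = c("no", "yes"))
  w <- weibull_ph(5, 100, beta = c("diabetes=yes" = 0.5),
                  covariate_schema = s)
  expect_equal(relative_aging_rate(w), 1)                   # baseline
  expect_equal(relative_aging_rate(w, list(diabetes = "yes")), exp(0.1))
  expect_equal(relative_aging_rate(w, list(diabetes = "yes")), 1.10517,
               tolerance = 1e-5)
  expect_equal(relative_risk(w, list(diabetes = "yes")), exp(0.5))
  # doubling both eta and m leaves the rate unchanged
  w2 <- weibull_ph(10, 100, beta = c("diabetes=yes" = 1.0),
                   covariate_schema = s)
  expect_equal(relative_aging_rate(w2, list(diabetes = "yes")),
               relative_aging_rate(w, list(diabetes = "yes")))
  # rar^m = rr to machine precision on random draws
  set.seed(8)
  for (i in 1:20) {
    m <- runif(1, 0.5, 12); b <- rnorm(1)
    wi <- weibull_ph(m, 100, beta = c("diabetes=yes" = b),
                     covariate_schema = s)
    expect_equal(relative_aging_rate(wi, list(diabetes = "yes"))^m,
                 relative_risk(wi, list(diabetes = "yes")))
  }
})

test_that("multi-factor profiles multiply their aging rates", {
  s <- covariate_schema(diabetes = c("no", "yes"),
                        education = c("degree", "minimum"),
                        bmi = c("mid", "max"))
  w <- weibull_ph(4, 100,
                  beta = c("diabetes=yes" = 0.4, "education=minimum" = 0.3,
                           "bmi=max" = 0.35), covariate_schema = s)
  profile <- list(diabetes = "yes", education = "minimum", bmi = "max")
  expect_equal(relative_aging_rate(w, profile),
               relative_aging_rate(w, list(diabetes = "yes")) *
                 relative_aging_rate(w, list(education = "minimum")) *
                 relative_aging_rate(w, list(bmi = "max")))
  expect_equal(relative_aging_rate(w, profile), exp((0.4 + 0.3 + 0.35) / 4))
})

test_that("effective age satisfies its defining cumulative-hazard identity", {
  expect_equal(effective_age(50, 1.1), 55)
  expect_equal(effective_age(70, 1.3), 91)
  expect_equal(effective_age(63, 1.0), 63)
  s <- covariate_schema(smoking = c("never", "current"))
  set.seed(15)
  for (i in 1:15) {
    w <- weibull_ph(runif(1, 0.8, 9), runif(1, 50, 300),
                    beta = c("smoking=current" = rnorm(1, 0, 0.8)),
                    covariate_schema = s)
    t <- runif(1, 20, 90)
    rar <- relative_aging_rate(w, list(smoking = "current"))
    # H at the effective age under baseline equals H at t under exposure
    expect_equal(model_cumhaz(w, effective_age(t, rar)),
                 model_cumhaz(w, t, list(smoking = "current")))
  }
})

test_that("equivalent screening ages invert the effective-age map", {
  expect_equal(equivalent_screening_age(55, 1, 1), 55)
  expect_equal(equivalent_screening_age(55, 1, 1.1), 50)
  expect_equal(equivalent_screening_age(55, 2, 2.2), 50)  # common factor cancels
})

test_that("disease-free-years arithmetic reproduces the worked example", {
  r <- expected_first_disease_age(40, 25, 1.1)
  expect_equal(r$age, 65 / 1.1)
  expect_equal(r$age, 59.0909, tolerance = 1e-5)
  expect_equal(r$age_rounded, 59)
  expect_equal(r$disease_free_years_rounded, 19)
  r0 <- expected_first_disease_age(40, 25, 1.0)
  expect_equal(r0$age, 65)
  expect_equal(r0$disease_free_years, 25)
  expect_warning(expected_first_disease_age(60, 5, 1.5), "precedes")
})

test_that("group comparisons run Welch t-tests with FDR across terms", {
  mk <- function(vals, term = "diabetes=yes") {
    data.frame(disease = seq_along(vals), term = term,
               relative_aging_rate = vals)
  }
  same <- mk(c(1.05, 1.1, 1.15, 1.2))
  out <- compare_groups(same, same)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$q_value, 1)
  expect_error(compare_groups(mk(rep(1.1, 3)), mk(rep(1.05, 3))),
               "degenerate")
  expect_error(compare_groups(mk(1.1), mk(c(1, 1.2))), ">= 2")
  # a clear gap is detected
  set.seed(5)
  a <- mk(rnorm(30, 1.10, 0.02))
  b <- mk(rnorm(30, 1.05, 0.02))
  out2 <- compare_groups(a, b)
  expect_lt(out2$q_value, 0.05)
  expect_gt(out2$mean_diff, 0)
})

test_that("sporadic diseases with smaller m show larger aging rates", {
  # equal beta, smaller m in the sporadic group -> larger e^{beta/m}
  set.seed(6)
  beta <- 0.4
  m_sporadic <- runif(25, 1, 3)
  m_late <- runif(25, 4, 9)
  rar_s <- exp(beta / m_sporadic)
  rar_l <- exp(beta / m_late)
  expect_gt(mean(rar_s), mean(rar_l))
  tt <- t.test(rar_s, rar_l)
  expect_lt(tt$p.value, 0.001)
})

test_that("long-format RR/RAR tables expose every coefficient", {
  s <- covariate_schema(diabetes = c("no", "yes"))
  fits <- list(
    d1 = list(model = weibull_ph(2, 150, beta = c("diabetes=yes" = 0.4),
                                 covariate_schema = s)),
    d2 = list(model = weibull_ph(6, 90, beta = c("diabetes=yes" = 0.4),
                                 covariate_schema = s)))
  tab <- aging_rate_table(fits)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$relative_risk, rep(exp(0.4), 2))
  expect_equal(tab$relative_aging_rate, exp(0.4 / c(2, 6)))
})
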