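test_that("Cox fit recovers null and known effects", {
  set.seed(1)
  d <- data.frame(time = rexp(200, 0.05), event = 1,
                  x = rep(0:1, each = 100))
  d$x <- sample(d$x)  # label permutation: no association
  f0 <- fit_cox(survival::Surv(time, event) ~ x, d)
  expect_lt(abs(f0$coefficients[["x"]]), 3 * f0$se[["x"]])
  # simulation oracle: true HR 2, large n, no censoring
  set.seed(2)
  n <- 20000
  x <- rep(0:1, n / 2)
  t2 <- rexp(n, 0.02 * 2^x)
  f2 <- fit_cox(survival::Surv(time, event) ~ x,
                data.frame(time = t2, event = 1, x = x))
  expect_gt(f2$hazard_ratio[["x"]], 1.9)
  expect_lt(f2$hazard_ratio[["x"]], 2.1)
})

test_that("Cox coefficient matches brute-force partial likelihood", {
  d <- data.frame(time = 1:6, event = 1, x = rep(0:1, 3))
  fit <- fit_cox(survival::Surv(time, event) ~ x, d)
  beta_oracle <- oracle_cox_beta(d$time, d$event, d$x)
  expect_equal(unname(fit$coefficients[["x"]]), beta_oracle,
               tolerance = 1e-6)
  # a second instance with censoring
  d2 <- data.frame(time = c(2, 3, 5, 7, 11, 13, 17), event = c(1, 0, 1, 1, 0, 1, 1),
                   x = c(0, 1, 1, 0, 1, 0, 1))
  f2 <- fit_cox(survival::Surv(time, event) ~ x, d2)
  expect_equal(unname(f2$coefficients[["x"]]),
               oracle_cox_beta(d2$time, d2$event, d2$x), tolerance = 1e-6)
})

test_that("hazard ratios and Wald intervals are internally consistent", {
  coh <- generate_cohort(cohort_config(n_patients = 300, seed = 6))
  st <- stage_cohort(coh$patients)
  fit <- fit_cox(survival::Surv(time, bcr_event) ~ group, st)
  expect_identical(fit$hazard_ratio, exp(fit$coefficients))
  expect_equal(fit$ci_lower,
               exp(fit$coefficients - stats::qnorm(0.975) * fit$se),
               tolerance = 1e-9)
  expect_equal(fit$ci_upper,
               exp(fit$coefficients + stats::qnorm(0.975) * fit$se),
               tolerance = 1e-9)
  expect_true(all(fit$ci_lower <= fit$hazard_ratio + 1e-12))
  expect_true(all(fit$hazard_ratio <= fit$ci_upper + 1e-12))
  expect_true(fit$c_index >= 0 && fit$c_index <= 1)
  # training-data concordance of a signal fit is at least chance level
  expect_gte(fit$c_index, 0.5 - 1e-9)
  expect_error(fit_cox(survival::Surv(time, bcr_event) ~ group,
                       transform(st, bcr_event = 0)), "no events")
})

test_that("Harrell's C follows the pair-counting conventions", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_c(rep(0.7, 5), c(1, 2, 3, 4, 5), rep(1, 5)), 0.5)
  expect_equal(harrell_c(c(0.9, 0.1, 0.5, 0.2), c(2, 4, 6, 8), c(1, 1, 0, 1)),
               oracle_cindex(c(0.9, 0.1, 0.5, 0.2), c(2, 4, 6, 8),
                             c(1, 1, 0, 1)))
  expect_error(harrell_c(c(1, 2), c(5, 3), c(0, 0)), "no comparable pairs")
})

test_that("Harrell's C equals brute-force enumeration on random data", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    time <- sample(1:6, n, replace = TRUE)      # integer times force ties
    event <- rbinom(n, 1, 0.7)
    risk <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # tied scores too
    o <- oracle_cindex(risk, time, event)
    if (is.na(o)) {
      expect_error(harrell_c(risk, time, event), "no comparable pairs")
    } else {
      expect_equal(harrell_c(risk, time, event), o, tolerance = 1e-12)
    }
  }
})

test_that("Kaplan-Meier matches the product-limit oracle", {
  # worked 4-subject example
  k <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(k$curves$survival, c(0.75, 0.375, 0))
  expect_equal(k$curves$time, c(1, 3, 4))
  # no censoring: equals the empirical survival function
  set.seed(7)
  t5 <- rexp(40)
  k2 <- km_estimate(t5, rep(1, 40))
  emp <- vapply(k2$curves$time, function(s) mean(t5 > s), numeric(1))
  expect_equal(k2$curves$survival, emp, tolerance = 1e-12)
  # random censored instances against the hand product-limit
  for (i in 1:20) {
    n <- sample(5:15, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    k3 <- km_estimate(time, event)
    o <- oracle_km(time, event)
    expect_equal(k3$curves$time, o$time)
    expect_equal(k3$curves$survival, o$survival, tolerance = 1e-12)
  }
  # identical groups: log-rank statistic is zero
  kk <- km_estimate(rep(c(1, 2, 3, 4), 2), rep(c(1, 0, 1, 1), 2),
                    rep(c("a", "b"), each = 4))
  expect_lt(kk$logrank_chisq, 1e-12)
  expect_error(km_estimate(numeric(0), numeric(0)), "input error")
})

test_that("demographic comparisons use the textbook statistics", {
  same <- compare_groups(rep(c(1, 5, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  flat <- compare_groups(rep(c("x", "y"), each = 10),
                         rep(c("g1", "g2"), 10), type = "categorical")
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  # 2x2 table [[30,10],[10,30]]: sum (O-E)^2/E with all E = 20 gives 20
  x <- rep(c("x", "x", "y", "y"), c(30, 10, 10, 30))
  g <- rep(c("g1", "g2", "g1", "g2"), c(30, 10, 10, 30))
  res <- compare_groups(x, g, type = "categorical")
  O <- c(30, 10, 10, 30); E <- rep(20, 4)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_error(compare_groups(c(1, 2, 3), c("a", "b", "c"),
                              type = "continuous"), "two groups")
})

test_that("Wald interval coverage is nominal at true HR 2", {
  rec <- recover_group_hr(500, 200, c(a = 0.5, b = 0.5),
                          c(a = 0, b = log(2)), seed = 77)
  expect_gte(rec$summary$ci_coverage, 0.93)
  expect_lte(rec$summary$ci_coverage, 0.97)
})
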