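test_that("Kaplan-Meier product-limit values match hand computation", {
  # two subjects: event at 5, censoring at 8 -> S(5) = 0.5, median = 5
  km <- km_estimate(c(5, 8), c(1, 0))
  expect_equal(km_surv_at(km, 5), 0.5, tolerance = 1e-6)
  expect_equal(km$median, 5)

  # no events: S(t) = 1 everywhere, median undefined
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))

  # 4 subjects, hand-computed product limit:
  # t=1 (d=1,n=4): 3/4; t=2 censored; t=3 (d=1,n=2): 3/4*1/2 = 3/8
  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_surv_at(km4, c(1, 2, 3)), c(0.75, 0.75, 0.375),
               tolerance = 1e-6)
  expect_equal(km4$median, 3)
})

test_that("KM curve is a non-increasing step function starting at 1", {
  set.seed(42)
  for (rep in 1:5) {
    time <- rexp(50, 0.1); event <- rbinom(50, 1, 0.7)
    km <- km_estimate(time, event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_lte(max(km$surv), 1)
    expect_equal(km_surv_at(km, min(km$time) / 2), 1)
  }
})

test_that("KM median recovers the exponential closed form", {
  set.seed(7)
  lambda <- log(2) / 12
  km <- km_estimate(rexp(5000, lambda), rep(1, 5000))
  expect_equal(km$median, 12, tolerance = 0.05 * 12)
})

test_that("median follow-up uses reverse KM", {
  time <- c(6, 12, 18, 24); event <- c(1, 0, 1, 0)
  # reverse KM treats censorings as events: at t=12 (3 at risk, 1 event)
  # S=2/3; at t=24 (1 at risk, 1 event) S=0 -> first S<=0.5 at t=24
  expect_equal(median_followup(time, event), 24)
})

test_that("log-rank test matches a hand-computed observed-expected table", {
  # 6 patients; A: events at 1, 3, censored 5; B: events at 2, 4, 6
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("A", "B"), each = 3)
  expected_chisq <- oracle_logrank(time, event, group == "A")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, expected_chisq, tolerance = 1e-6)
  expect_equal(lr$p, pchisq(expected_chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # label symmetry
  lr_swap <- logrank_test(time, event, rev(group))
  expect_equal(lr$statistic, lr_swap$statistic, tolerance = 1e-12)

  # identical groups -> statistic 0, p 1
  lr_same <- logrank_test(rep(time, 2), rep(event, 2),
                          rep(c("A", "B"), each = 6))
  expect_equal(lr_same$statistic, 0, tolerance = 1e-12)
  expect_equal(lr_same$p, 1, tolerance = 1e-12)

  # no events anywhere -> flagged, p undefined
  lr_none <- logrank_test(c(1, 2), c(0, 0), c("A", "B"))
  expect_identical(lr_none$flag, "no_events")
  expect_true(is.na(lr_none$p))
})

test_that("log-rank equals the Cox score test on a binary covariate", {
  d <- planted_cohort(seed = 21, n = 120)
  lr <- logrank_test(d$time_months, d$event, d$planted)
  sc <- summary(fit_cox(d, "planted")$fit)$sctest[["test"]]
  expect_equal(lr$statistic, sc, tolerance = 1e-6)
})

test_that("Cox null case: CI covers 1 when the covariate is inert", {
  d <- planted_cohort(seed = 31, n = 1000, hr = 1)
  f <- fit_cox(d, "planted")
  expect_true(f$table$lower95[1] <= 1 && 1 <= f$table$upper95[1])
  expect_identical(f$n_events, sum(d$event))
})

test_that("Cox recovers a planted hazard ratio of 2", {
  d <- planted_cohort(seed = 32, n = 1000)
  f <- fit_cox(d, "planted")
  expect_gt(f$table$HR[1], 1.6)
  expect_lt(f$table$HR[1], 2.5)
  expect_equal(f$table$HR[1], exp(f$table$coef[1]), tolerance = 1e-12)
  expect_true(f$table$lower95[1] < f$table$upper95[1])
})

test_that("Cox HR agrees with the closed-form exponential rate ratio", {
  set.seed(5)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = ifelse(g == 1, 0.2, 0.1))  # true HR = 2
  d <- data.frame(time_months = time, event = 1, g = g)
  f <- fit_cox(d, "g")
  expect_lt(abs(f$table$HR[1] / 2 - 1), 0.1)
})

test_that("dichotomization flags the below-threshold group as at-risk", {
  d <- planted_cohort(seed = 33, n = 600)
  d$marker <- ifelse(d$planted == 1, rnorm(600, 7, 1), rnorm(600, 10, 1))
  f <- fit_cox(d, "marker", dichotomize = c(marker = 8.5))
  expect_gt(f$table$HR[1], 1)  # low marker is adverse
  expect_error(fit_cox(d, "marker", dichotomize = c(nope = 1)),
               "dichotomize")
})

test_that("missing covariate values are dropped and counted", {
  d <- planted_cohort(seed = 34, n = 200)
  d$planted[1:25] <- NA
  f <- fit_cox(d, "planted")
  expect_identical(f$n_dropped, 25L)
  expect_identical(f$n, 175L)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  d <- data.frame(time_months = c(1, 2, 3), event = c(0, 0, 0), x = 1:3)
  expect_error(fit_cox(d, "x"), "no events")
  d2 <- data.frame(time_months = 1:4, event = c(1, 1, 1, 1), x = rep(2, 4))
  expect_error(fit_cox(d2, "x"), "distinct")
  # complete separation: the covariate orders times perfectly
  d3 <- data.frame(time_months = 1:20, event = 1,
                   x = rep(c(1, 0), each = 10))
  f3 <- fit_cox(d3, "x")
  expect_true(length(f3$flags) > 0)
})
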