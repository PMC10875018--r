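test_that("median split: above-median is high, ties go low, missing excluded", {
  s <- median_split(setNames(c(1, 2, 3, 4), paste0("P", 1:4)))
  expect_equal(s$cutoff, 2.5)
  expect_setequal(names(s$group)[s$group == "high"], c("P3", "P4"))
  expect_setequal(names(s$group)[s$group == "low"], c("P1", "P2"))

  s2 <- median_split(setNames(c(1, 2, 2, 5), paste0("P", 1:4)))
  expect_equal(s2$cutoff, 2)
  expect_setequal(names(s2$group)[s2$group == "high"], "P4")
  expect_setequal(names(s2$group)[s2$group == "low"], c("P1", "P2", "P3"))

  s3 <- median_split(setNames(c(1, NA, 3), paste0("P", 1:3)))
  expect_equal(s3$excluded, "P2")
  expect_error(median_split(setNames(c(2, 2, 2), paste0("P", 1:3))),
               "degenerate")

  # ties at the median are the only source of imbalance: with no tied
  # values the split is even to within one, and each tie can shift at most
  # two (one subject plus the seat it vacates)
  set.seed(61)
  for (rep in 1:25) {
    v <- setNames(sample(1:8, 15, replace = TRUE), paste0("P", 1:15))
    if (max(v) == min(v)) next
    s <- median_split(v)
    n_tied <- sum(v == s$cutoff)
    imbalance <- abs(sum(s$group == "high") - sum(s$group == "low"))
    expect_lte(imbalance, if (n_tied == 0) 1 else 2 * n_tied)
  }
})

test_that("Kaplan-Meier matches hand-computed product-limit curves", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$surv[km2$time == 1], 2/3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_equal(km2$n_event[km2$time == 2], 0)  # censoring: no step

  km3 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")

  set.seed(62)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    tm <- sample(1:15, n, replace = TRUE)
    ev <- runif(n) < 0.7
    km <- km_estimate(tm, ev)
    oracle <- km_brute(tm, ev)
    expect_equal(km$surv, oracle$surv[match(km$time, oracle$time)],
                 tolerance = 1e-12)
  }
})

test_that("log-rank: null cases and O-E oracle agreement", {
  tm <- c(1, 2, 3, 1, 2, 3)
  ev <- rep(TRUE, 6)
  grp <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(tm, ev, grp)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # hand-worked 6-subject fixture with distinct group experiences
  tm2 <- c(1, 3, 5, 2, 4, 6)
  ev2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  grp2 <- rep(c("a", "b"), each = 3)
  lr2 <- logrank_test(tm2, ev2, grp2)
  oracle <- logrank_brute(tm2, ev2, grp2)
  expect_equal(lr2$chisq, oracle$chisq, tolerance = 1e-8)
  expect_equal(lr2$p, oracle$p, tolerance = 1e-8)

  set.seed(63)
  for (rep in 1:10) {
    tm <- round(rexp(30, 0.2), 2)
    ev <- runif(30) < 0.8
    grp <- rep(c("a", "b"), 15)
    lr <- logrank_test(tm, ev, grp)
    oracle <- logrank_brute(tm, ev, grp)
    expect_equal(lr$chisq, oracle$chisq, tolerance = 1e-8)
  }
  expect_error(logrank_test(tm, ev, rep("a", 30)), "two groups")
})

test_that("Cox fit: null recovery, Efron ties vs independent maximization, flags", {
  set.seed(64)
  n <- 800
  z <- rep(0:1, n / 2)
  tt <- rexp(n, 0.2)
  cc <- rexp(n, 0.05)
  d <- data.frame(time = pmin(tt, cc), event = tt <= cc, z = z)
  fit <- cox_fit(d, "time", "event", "z")
  expect_true(fit$table$ci_low < 1 && fit$table$ci_high > 1)
  expect_lt(abs(fit$table$beta), 0.2)
  expect_equal(fit$table$hr, exp(fit$table$beta))
  expect_true(fit$table$ci_low < fit$table$hr & fit$table$hr < fit$table$ci_high)

  # tied event times: compare against direct Efron partial-likelihood optimum
  d2 <- data.frame(time = c(1, 1, 1, 2, 2, 3, 3, 4, 5, 5),
                   event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                             TRUE, TRUE, TRUE),
                   z = c(1, 1, 0, 1, 0, 0, 1, 0, 1, 0))
  fit2 <- cox_fit(d2, "time", "event", "z")
  opt <- optimize(function(b) efron_nll(b, d2$time, d2$event, d2$z),
                  interval = c(-5, 5))
  expect_equal(fit2$table$beta, opt$minimum, tolerance = 1e-4)

  # duplicated covariate -> collinearity flag, never silent
  d$z2 <- d$z
  fit3 <- cox_fit(d, "time", "event", c("z", "z2"))
  expect_true(any(fit3$table$flag == "aliased_collinear"))
  expect_true(any(grepl("collinearity", fit3$flags)))

  expect_error(cox_fit(d[1:3, ], "time", "event", c("z", "z2", "time")),
               "too few events")
})

test_that("univariate p < 0.05 selection is strict and drives the multivariate model", {
  expect_equal(select_multivariate(c(a = 0.04, b = 0.06)), "a")
  expect_equal(select_multivariate(c(a = 0.05, b = 0.049999)), "b")
  expect_length(select_multivariate(c(a = 0.5, b = 0.6)), 0)

  set.seed(65)
  n <- 300
  d <- data.frame(strong = rnorm(n), noise = rnorm(n))
  tt <- rexp(n, 0.2 * exp(0.8 * d$strong))
  cc <- rexp(n, 0.05)
  d$time <- pmin(tt, cc); d$event <- tt <= cc
  res <- cox_univariate_multivariate(d, "time", "event", c("strong", "noise"))
  expect_true("strong" %in% res$selected)
  expect_false(is.null(res$multivariate))
  expect_true(all(res$multivariate$table$covariate %in% res$selected))

  set.seed(66)
  d2 <- data.frame(time = rexp(n, 0.2), event = runif(n) < 0.8,
                   pure1 = rnorm(n), pure2 = rnorm(n))
  expect_message(
    res2 <- cox_univariate_multivariate(d2, "time", "event", c("pure1", "pure2")),
    "multivariate model skipped")
  expect_null(res2$multivariate)
})
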