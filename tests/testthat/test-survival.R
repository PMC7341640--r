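test_that("Kaplan-Meier estimate matches the product-limit closed forms", {
  # no events: S(t) = 1 everywhere
  km0 <- kaplan_meier(surv_fixture(c(5, 10, 15), c(0, 0, 0)))
  expect_true(all(km0$surv == 1))

  # n = 2 with events at 1 and 2
  km2 <- kaplan_meier(surv_fixture(c(1, 2), c(1, 1)))
  expect_equal(km2$surv, c(0.5, 0))

  # worked 5-subject example: events at 2 and 4, censored at 3, 5, 6
  km5 <- kaplan_meier(surv_fixture(c(2, 3, 4, 5, 6), c(1, 0, 1, 0, 0)))
  expect_equal(km_survival_at(km5, 2), 0.8)
  expect_equal(km_survival_at(km5, 4), 0.8 * (1 - 1 / 3), tolerance = 1e-12)

  # monotone, starts at 1, equals empirical survival without censoring
  set.seed(31)
  tt <- rexp(40, 0.1)
  km <- kaplan_meier(surv_fixture(tt, rep(1, 40)))
  expect_true(all(diff(km$surv) <= 0))
  expect_lte(max(km$surv), 1)
  expect_equal(km_survival_at(km, median(tt) + 1e-9),
               mean(tt > median(tt) + 1e-9))

  expect_error(survival_table("a", -1, 1), "non-negative")
})

test_that("log-rank test matches a risk-table oracle and is symmetric", {
  s <- surv_fixture(c(1, 3, 5, 7, 2, 4, 6, 8), c(1, 1, 0, 1, 1, 0, 1, 1))
  g <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(s, g)

  # observed-minus-expected accumulation over the combined risk table
  oracle_chisq <- local({
    tt <- s$time; ee <- s$event
    ev_times <- sort(unique(tt[ee == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in ev_times) {
      at_risk <- tt >= t
      n <- sum(at_risk); n1 <- sum(at_risk & g == "A")
      d <- sum(tt == t & ee == 1)
      d1 <- sum(tt == t & ee == 1 & g == "A")
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  })
  expect_equal(lr$chisq, oracle_chisq, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(oracle_chisq, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p = 1
  s2 <- surv_fixture(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1))
  lr2 <- logrank_test(s2, rep(c("A", "B"), each = 3))
  expect_equal(lr2$chisq, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)

  # swapping group labels leaves the statistic unchanged
  g_sw <- ifelse(g == "A", "B", "A")
  expect_equal(logrank_test(s, g_sw)$chisq, lr$chisq)

  expect_error(logrank_test(s, rep("A", 8)), "2 groups")

  # pairwise mode agrees with the two-group test
  g3 <- c("A", "A", "A", "B", "B", "B", "C", "C")
  lr3 <- logrank_test(s, g3, pairwise = TRUE)
  sel <- g3 %in% c("A", "B")
  expect_equal(lr3$pairwise_p["A", "B"],
               logrank_test(s[sel, ], g3[sel])$p)
})

test_that("Cox coefficient matches direct partial-likelihood maximization", {
  # 8 subjects, binary covariate, no tied event times
  tt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ee <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0)
  fit <- suppressWarnings(
    cox_fit(data.frame(x = x), surv_fixture(tt, ee)))
  beta_grid <- optimize(function(b) cox_pl_oracle(b, x, tt, ee),
                        c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$table$coef, beta_grid, tolerance = 1e-3)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(fit$table$hr_lo <= fit$table$hr & fit$table$hr <= fit$table$hr_hi)
})

test_that("Cox fits recover null and non-null generating coefficients", {
  set.seed(32)
  n <- 2000
  x_null <- rnorm(n)
  s_null <- surv_fixture(rexp(n, 0.01), rbinom(n, 1, 0.8))
  fit0 <- cox_fit(data.frame(x = x_null), s_null)
  expect_gt(fit0$table$hr, 0.9)
  expect_lt(fit0$table$hr, 1.1)

  # exponential PH with true log-HR 0.7, ~20% censoring
  x <- rnorm(n)
  ev_t <- rexp(n, 0.01 * exp(0.7 * x))
  cs_t <- rexp(n, 0.0025)
  s1 <- surv_fixture(pmin(ev_t, cs_t), as.integer(ev_t <= cs_t))
  fit1 <- cox_fit(data.frame(x = x), s1)
  expect_lt(abs(fit1$table$coef - 0.7), 0.1)
})

test_that("Cox input contracts: listwise deletion, truncation, small-n warning", {
  set.seed(33)
  n <- 60
  cov <- data.frame(a = rnorm(n), b = rnorm(n))
  cov$a[1:5] <- NA
  s <- surv_fixture(rexp(n, 0.05), rbinom(n, 1, 0.7))
  fit <- cox_fit(cov, s)
  expect_equal(fit$n, n - 5L)
  s8 <- surv_fixture(1:8, rep(1, 8))
  expect_warning(cox_fit(data.frame(x = c(0, 1, 0, 1, 1, 0, 1, 0)), s8),
                 "complete rows")
  # 10-year truncation administratively censors beyond the horizon
  s_long <- surv_fixture(c(60, 200, 90, 300), c(1, 1, 1, 1))
  f <- suppressWarnings(
    cox_fit(data.frame(x = c(1, 0, 0, 1)), s_long, truncate_months = 120))
  expect_equal(f$n_events, 2L)
})

test_that("concordance index equals brute-force pair counting", {
  # perfectly ordered: C = 1
  s <- surv_fixture(c(1, 2, 3), c(1, 1, 1))
  expect_equal(as.numeric(concordance_index(c(3, 2, 1), s)), 1)
  # all risks tied: C = 0.5
  expect_equal(as.numeric(concordance_index(c(1, 1, 1), s)), 0.5)

  # 6-subject mixed censoring case
  tt <- c(2, 4, 4, 6, 8, 10); ee <- c(1, 0, 1, 1, 0, 0)
  rr <- c(5, 4, 4, 2, 1, 3)
  s6 <- surv_fixture(tt, ee)
  expect_equal(as.numeric(concordance_index(rr, s6)),
               cindex_oracle(rr, tt, ee))

  # invariance under strictly increasing transforms; complement identity
  set.seed(34)
  tt <- rexp(30); ee <- rbinom(30, 1, 0.7); rr <- rnorm(30)
  s30 <- surv_fixture(tt, ee)
  c1 <- as.numeric(concordance_index(rr, s30))
  expect_equal(as.numeric(concordance_index(exp(rr), s30)), c1)
  expect_equal(as.numeric(concordance_index(-rr, s30)), 1 - c1)
  # agreement with the survival package on tie-free data
  cs <- survival::concordance(survival::Surv(tt, ee) ~ rr, reverse = TRUE)
  expect_equal(c1, unname(cs$concordance))

  expect_error(concordance_index(c(1, 2), surv_fixture(c(5, 9), c(0, 0))),
               "no admissible pairs")
})

test_that("clinical covariates encode to the documented ordinal scheme", {
  clin <- data.frame(
    age = c(45, 70),
    size_class = c("<2", ">5"),
    grade = c("low", "high"),
    er = c("positive", "negative"),
    her2 = c("negative", "negative"),
    pam50 = c("normal-like", "basal"),
    emat = c("EMAT1", "EMAT4"),
    chemo = c(FALSE, TRUE),
    row.names = c("p1", "p2"))
  cov <- encode_covariates(clin)
  expect_equal(cov$size, c(1, 3))
  expect_equal(cov$grade, c(1, 3))
  expect_equal(cov$ihc, c(1, 4))
  expect_equal(cov$pam50, c(0, 4))
  expect_equal(cov$emat, c(1L, 4L))
  expect_equal(cov$chemo, c(0L, 1L))
})
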