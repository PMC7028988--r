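test_that("percent positive and patient medians match hand counts", {
  cells <- random_cells(100, seed = 51)
  cells$pos_CD8 <- c(rep(TRUE, 5), rep(FALSE, 95))
  pp <- percent_positive(cells, "CD8+")
  expect_equal(pp$pct, 5.0)
  expect_equal(pp$n_cells, 100L)

  expect_equal(patient_density(c(4, 6, 10)), 6)
  expect_error(patient_density(numeric(0)), "no evaluable ROIs")

  # random tables: equals brute-force recount per ROI
  set.seed(52)
  cells2 <- random_cells(300)
  cells2$roi_id <- sample(1:4, 300, replace = TRUE)
  pp2 <- percent_positive(cells2, "PD-1+")
  for (r in 1:4) {
    sub <- cells2[cells2$roi_id == r, ]
    expect_equal(pp2$pct[pp2$roi_id == r],
                 100 * sum(sub$pos_PD1) / nrow(sub))
  }
})

test_that("stratification cuts at the median or mean with ties going low", {
  expect_identical(stratify(c(1, 2, 3, 4), "median"),
                   c("low", "low", "high", "high"))
  expect_identical(stratify(c(0, 0, 10), "mean"), c("low", "low", "high"))
  # value equal to the cut goes low
  expect_identical(stratify(c(1, 2, 3), "median"), c("low", "low", "high"))
  expect_error(stratify(c(2, 2, 2), "median"), "identical")
  expect_error(stratify(1, "median"), ">= 2")
})

test_that("Kaplan-Meier and Greenwood match the hand-computed example", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$var_greenwood[1], (2 / 3)^2 * (1 / (3 * 2)))
  expect_true(is.na(km$var_greenwood[2]))  # undefined once S = 0
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("Kaplan-Meier matches the reference implementation on censored data", {
  set.seed(61)
  for (k in 1:5) {
    n <- 60
    t <- round(rexp(n, 0.05), 1)  # rounding forces ties
    e <- as.integer(runif(n) < 0.7)
    if (sum(e) == 0) e[1] <- 1L
    km <- km_estimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    at_events <- sf$n.event > 0
    expect_equal(km$survival, sf$surv[at_events], tolerance = 1e-10)
    # survfit std.err is the SE of log S; Greenwood SE of S is S * that
    expect_equal(km$se[!is.na(km$se)],
                 (sf$surv * sf$std.err)[at_events][!is.na(km$se)],
                 tolerance = 1e-10)
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(62)
  t <- rexp(40, 0.1)
  km <- km_estimate(t, rep(1L, 40))
  ecdf_surv <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("log-rank is zero for identical groups and detects separation", {
  t <- c(2, 4, 6, 8, 10); e <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # fully separated event times, n = 20 per arm
  lr2 <- logrank_test(c(1:20, 101:120), rep(1L, 40),
                      rep(c("A", "B"), each = 20))
  expect_lt(lr2$p, 0.01)

  # invariant under group relabelling
  set.seed(63)
  tt <- rexp(30, 0.1); ee <- as.integer(runif(30) < 0.7)
  g <- rep(c("A", "B"), 15)
  a <- logrank_test(tt, ee, g)
  b <- logrank_test(tt, ee, ifelse(g == "A", "B", "A"))
  expect_equal(a$statistic, b$statistic)

  expect_error(logrank_test(tt, rep(0L, 30), g), "no events")
  expect_error(logrank_test(tt, ee, rep("A", 30)), "2 non-empty groups")
})

test_that("univariate Cox reports HR with Wald CI and guards degenerate input", {
  set.seed(64)
  g <- rep(c(0, 1), each = 100)
  s <- simulate_survival(log(3) * g, baseline_hazard = 0.01,
                         censoring_rate = 0.2)
  fit <- cox_univariate(s$time_months, s$event, g)
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 5)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
  expect_lt(fit$p, 0.05)
  # CI reproduces from coef +/- 1.96 se
  expect_equal(fit$ci_lower, exp(fit$coef - qnorm(0.975) * fit$se),
               tolerance = 1e-6)

  expect_error(cox_univariate(c(1, 2), c(1, 1), c(0, 0)), "2 non-empty")
  expect_error(cox_univariate(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
               ">= 1 observed event")
})

test_that("Cox HR converges to the true rate ratio without censoring", {
  set.seed(65)
  g <- rep(c(0, 1), each = 500)
  s <- simulate_survival(log(2.5) * g, baseline_hazard = 0.02,
                         censoring_rate = 0)
  fit <- cox_univariate(s$time_months, s$event, g)
  expect_lt(abs(fit$hr - 2.5) / 2.5, 0.1)
})

test_that("complete separation is flagged with an unbounded CI", {
  t <- c(1, 2, 3, 4, 50, 60, 70, 80)
  e <- rep(1L, 8)
  g <- rep(c(1, 0), each = 4)
  fit <- cox_univariate(t, e, g)
  expect_true(fit$separation)
  expect_equal(fit$ci_upper, Inf)
})

test_that("Mann-Whitney gives the exact small-sample p and matches permutations", {
  mw <- mann_whitney(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 1 / 6, tolerance = 1e-12)

  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7), alternative = "less")
  expect_gte(same$p, 0.5)

  # tie-corrected approximation vs a permutation oracle
  set.seed(66)
  a <- round(rnorm(30, 0, 1), 1)
  b <- round(rnorm(30, 0.4, 1), 1)
  mw2 <- mann_whitney(a, b, alternative = "less")
  pooled <- c(a, b)
  stat_obs <- sum(rank(pooled)[seq_along(a)])
  perm <- replicate(20000, {
    idx <- sample(60, 30)
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(perm <= stat_obs)
  expect_lt(abs(mw2$p - p_perm), 0.01)
})

test_that("cohort report tables are complete, deterministic and guarded", {
  set.seed(67)
  n <- 60
  hpv <- rep(c("positive", "negative"), each = n / 2)
  feat <- rnorm(n, 10, 3) + (hpv == "positive") * 3
  s <- simulate_survival(log(2) * (feat > median(feat)),
                         baseline_hazard = 0.01, censoring_rate = 0.3)
  patients <- data.frame(patient_id = 1:n, time_months = s$time_months,
                         event = s$event, hpv_status = hpv, dens = feat)
  rep1 <- run_tables(patients, "dens", cut = "median")
  rep2 <- run_tables(patients, "dens", cut = "median")
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1$cox), 3)  # all / HPV+ / HPV-
  expect_true(all(c("hr", "ci_lower", "ci_upper", "p") %in%
                    names(rep1$cox)))
  expect_equal(nrow(rep1$distribution), 1)
  expect_gt(rep1$n_tests, 0)

  # missing feature is noted, not fatal
  repm <- run_tables(patients, c("dens", "ghost"))
  expect_true(any(grepl("ghost", repm$notes)))

  # single-patient cohort degrades gracefully
  rep0 <- run_tables(patients[1, ], "dens")
  expect_match(rep0$notes, "insufficient")
  expect_equal(rep0$n_tests, 0L)
})
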