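test_that("Kaplan-Meier matches hand-computed product limits", {
  # all censored: flat at 1
  km <- kaplan_meier(c(3, 5, 8), c(FALSE, FALSE, FALSE))
  expect_true(all(km$survival == 1))

  # events at 1, 2, 3 with no censoring: 2/3, 1/3, 0
  km <- kaplan_meier(1:3, rep(TRUE, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)), "must lie in")
})

test_that("Kaplan-Meier equals the brute-force oracle on random small instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    times <- sample(1:8, n, replace = TRUE)
    events <- runif(n) < 0.7
    km <- kaplan_meier(times, events)
    oracle <- km_oracle(times, events)
    expect_equal(km$survival[match(oracle$time, km$time)], oracle$survival,
                 tolerance = 1e-10)
  }
})

test_that("KM curves start at or below 1, stay in [0,1], and never increase", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    km <- kaplan_meier(rexp(n, 0.1), runif(n) < 0.6)
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$survival) <= 1e-12))
  }
})

test_that("log-rank matches the oracle and degenerates sensibly", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 4); e0 <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$df, 1L)

  # tiny worked instance against the hand computation
  times <- c(1, 2, 5, 3, 4, 6)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(times, events, grp)
  oracle <- logrank_oracle(times, events, grp)
  expect_equal(lr$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(lr$p, oracle$p, tolerance = 1e-10)

  # random small instances
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    times <- sample(1:6, n, replace = TRUE)
    events <- runif(n) < 0.8
    grp <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    if (sum(events) == 0) next
    lr <- logrank_test(times, events, grp)
    oracle <- logrank_oracle(times, events, grp)
    expect_equal(lr$chisq, oracle$chisq, tolerance = 1e-8)
  }

  expect_error(logrank_test(1:3, c(TRUE, TRUE, TRUE), rep("a", 3)), "2 non-empty")
})

test_that("log-rank p-values are calibrated under the null", {
  set.seed(202)
  n_rep <- 2000
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    times <- rexp(100, 0.1)
    cens <- runif(100, 0, 15)
    obs <- pmin(times, cens)
    p[i] <- logrank_test(obs, times <= cens, rep(c("a", "b"), each = 50))$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # approximately Uniform(0,1)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("the hazard-ratio estimator recovers known rate ratios", {
  set.seed(303)
  # identical groups: HR near 1
  t0 <- rexp(200, 0.1)
  hr <- hazard_ratio(c(t0, t0), rep(TRUE, 400), rep(0:1, each = 200))
  expect_equal(hr$hr, 1, tolerance = 0.05)

  # exponential groups with rate ratio 2
  times <- c(rexp(500, 0.05), rexp(500, 0.10))
  hr <- hazard_ratio(times, rep(TRUE, 1000), rep(0:1, each = 500))
  expect_gt(hr$hr, 1.8); expect_lt(hr$hr, 2.2)
  expect_true(hr$ci_lower <= hr$hr && hr$hr <= hr$ci_upper)

  # no events in one group: warning + unbounded marker
  expect_warning(
    res <- hazard_ratio(c(rexp(20, 0.1), runif(20, 10, 20)),
                        c(rep(TRUE, 20), rep(FALSE, 20)),
                        rep(0:1, each = 20)),
    "no events")
  expect_true(res$unbounded)
  expect_equal(res$ci_upper, Inf)
})

test_that("HR bias shrinks with sample size on exponential data", {
  set.seed(404)
  est <- function(n) {
    mean(replicate(20, {
      times <- c(rexp(n, 0.05), rexp(n, 0.1))
      log(hazard_ratio(times, rep(TRUE, 2 * n), rep(0:1, each = n))$hr)
    }))
  }
  bias_small <- abs(est(25) - log(2))
  bias_large <- abs(est(400) - log(2))
  expect_lt(bias_large, bias_small + 0.02)
  expect_lt(bias_large, 0.05)
})

test_that("adjusted hazard ratios accept categorical and continuous covariates", {
  set.seed(33)
  sim <- generate_cohort(cohort_config(n_patients = 150, expression = FALSE,
                                       seed = 12))
  cl <- sim$cohort$clinical
  covs <- data.frame(age = cl$age, node = cl$node_positive,
                     rcb = cl$rcb_class == "III")
  hr <- hazard_ratio(cl$dfs_months, cl$dfs_event,
                     cl$patient_id %in% cl$patient_id[1:75], covariates = covs)
  expect_equal(nrow(hr$covariates), 3L)
  expect_true(is.finite(hr$p))
})

test_that("the pooled t test matches its closed form and conventions", {
  x <- c(1.1, 2.3, 3.1, 4.8); y <- c(2.0, 2.2, 3.9)
  res <- t_test2(x, y)
  oracle <- t_oracle(x, y)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)

  expect_equal(t_test2(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  z <- t_test2(c(2, 3, 4), c(2, 3, 4), paired = TRUE)  # all-zero differences
  expect_equal(z$statistic, 0); expect_equal(z$p, 1)
  expect_error(t_test2(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)

  # two groups: F equals the squared pooled t statistic
  x <- c(3.4, 5.2, 1.1, 4.4); y <- c(6.1, 5.9, 7.2)
  a <- one_way_anova(list(x, y))
  expect_equal(a$F, t_test2(x, y)$statistic^2, tolerance = 1e-10)

  groups <- list(c(1.2, 3.1, 2.2), c(4.1, 3.3, 5.0, 4.4), c(2.0, 2.1))
  a <- one_way_anova(groups)
  oracle <- anova_oracle(groups)
  expect_equal(a$F, oracle$F, tolerance = 1e-10)
  expect_equal(a$p, oracle$p, tolerance = 1e-10)

  # identical values: F = 0, p = 1 by convention
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2, 2)))$p, 1)
  expect_error(one_way_anova(list(1:3)))
})

test_that("BH adjustment is correct, dominating, and idempotent", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(9)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(q >= p))          # dominance
  expect_true(all(q <= 1))
  # flat adjusted vectors (the shape BH produces under ties) are fixed points
  expect_equal(bh_fdr(rep(0.04, 6)), rep(0.04, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "must lie in")
})

test_that("Fisher overlap matches exact enumeration and is symmetric", {
  res <- fisher_overlap(1, 2, 1, 2)  # table (1,1;1,1)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)

  res <- fisher_overlap(10, 10, 0, 10)  # extreme table
  expect_equal(res$p, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)

  set.seed(14)
  for (rep in 1:20) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    p1 <- fisher_overlap(a, a + b, c_, c_ + d)$p
    expect_equal(p1, fisher_oracle(a, b, c_, d), tolerance = 1e-10)
    # transposition symmetry
    p2 <- fisher_overlap(a, a + c_, b, b + d)$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  expect_error(fisher_overlap(5, 3, 1, 2), "hits <= totals")
})
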