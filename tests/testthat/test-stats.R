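test_that("the Lilliefors statistic equals the brute-force sup difference", {
  set.seed(1)
  x <- rnorm(30, 5, 2)
  D <- lilliefors_statistic(x)
  # brute force: scan the ECDF-vs-fitted-normal gap at every sample point
  z <- (x - mean(x)) / sd(x)
  gaps <- c()
  for (xi in z) {
    Fn_at <- mean(z <= xi)
    Fn_before <- mean(z < xi)
    gaps <- c(gaps, abs(Fn_at - pnorm(xi)), abs(Fn_before - pnorm(xi)))
  }
  expect_equal(D, max(gaps), tolerance = 1e-12)
  # cross-check against the reference implementation
  skip_if_not_installed("nortest")
  expect_equal(D, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-10)
})

test_that("Lilliefors p-values behave under null and alternative", {
  # seeded standard-normal samples: large p in nearly all runs
  p_null <- vapply(1:40, function(s)
    lilliefors_normality(with_seed(3000 + s, rnorm(50)),
                         n_sim = 2000)$p_value, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.9)
  # exponential samples: small p in most runs
  p_alt <- vapply(1:40, function(s)
    lilliefors_normality(with_seed(4000 + s, rexp(50)),
                         n_sim = 2000)$p_value, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.75)
  # constant sample: non-normal by convention
  expect_equal(lilliefors_normality(rep(1, 10))$p_value, 0)
  expect_error(lilliefors_normality(c(1, 2, 3)), "at least 4")
})

test_that("paired comparison handles degenerate inputs by convention", {
  x <- c(1, 2, 3, 4, 5)
  r <- paired_compare(x, x)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_equal(r$test, "degenerate")
  # constant nonzero differences route to the exact sign test
  r2 <- paired_compare(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$test, "sign")
  expect_equal(r2$p_value, 2 * 0.5^3)
})

test_that("the gate routes normal data to t and skewed data to Wilcoxon", {
  a <- with_seed(11, rnorm(39)); b <- with_seed(12, rnorm(39))
  r <- paired_compare(a, b)
  expect_equal(r$test, "paired_t")
  expect_equal(r$p_value, t.test(a, b, paired = TRUE)$p.value)
  skew_a <- with_seed(13, rexp(39, 0.2)); skew_b <- rep(0, 39)
  r2 <- paired_compare(skew_a, skew_b)
  expect_equal(r2$test, "wilcoxon")
  # rank invariance: doubling both groups leaves the decision unchanged
  r3 <- paired_compare(2 * skew_a, 2 * skew_b)
  expect_equal(r2$p_value, r3$p_value)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("type-I error of the gated procedure is nominal at n = 39", {
  n_trials <- 2000
  rej <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    d <- with_seed(50000 + i, rnorm(39))
    r <- paired_compare(d, rep(0, 39))
    rej[i] <- r$significant
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_trials)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("gated rejection rate under a paired shift matches analytic power", {
  n_trials <- 1000
  rej <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    d <- with_seed(90000 + i, rnorm(39, mean = 0.5, sd = 1))
    rej[i] <- paired_compare(d, rep(0, 39))$significant
  }
  pow <- stats::power.t.test(n = 39, delta = 0.5, sd = 1,
                             type = "one.sample")$power
  expect_lt(abs(mean(rej) - pow), 0.05)
})

test_that("one-way ANOVA matches the brute-force mean-square ratio", {
  g1 <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- one_way_anova(g1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(9)
  groups <- lapply(1:4, function(i) rnorm(sample(5:9, 1), mean = i * 0.3))
  r2 <- one_way_anova(groups)
  all_v <- unlist(groups)
  grand <- mean(all_v)
  k <- length(groups); N <- length(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  Fbf <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(r2$statistic, Fbf, tolerance = 1e-9)
  expect_error(one_way_anova(groups[1:2]), "3 groups")
  expect_error(one_way_anova(list(1, c(1, 2), c(1, 2))), "at least 2")
})
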