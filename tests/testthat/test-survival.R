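test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  set.seed(3)
  t <- rexp(30, 1 / 100)
  km <- km_estimate(t, rep(TRUE, 30))
  emp <- vapply(km$table$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$table$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$table$survival) <= 1e-12))

  # no events: S(t) = 1 everywhere
  km0 <- km_estimate(c(5, 10, 20), rep(FALSE, 3))
  expect_equal(km_survival_at(km0, c(1, 15, 50))$survival, rep(1, 3))

  # one event among four
  km1 <- km_estimate(c(10, 12, 15, 20), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(km_survival_at(km1, 10)$survival, 0.75)
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "finite")
})

test_that("product-limit steps match a hand computation with censoring", {
  # times (6,6,6,7,10), events (1,1,0,1,0):
  # S(6) = 1 - 2/5 = 0.6; at t=7 two at risk, one event: S(7) = 0.6 * 1/2
  km <- km_estimate(c(6, 6, 6, 7, 10), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(km_survival_at(km, 6)$survival, 0.6)
  expect_equal(km_survival_at(km, 7)$survival, 0.3)
  expect_equal(km_survival_at(km, 10)$survival, 0.3)
  expect_true(all(km$table$ci_lower <= km$table$survival + 1e-12 &
                    km$table$survival <= km$table$ci_upper + 1e-12,
                  na.rm = TRUE))
})

test_that("log-rank statistic matches the O-E oracle and degenerates to zero", {
  # identical groups: statistic 0, p 1
  t <- c(5, 8, 12, 20); e <- c(TRUE, TRUE, FALSE, TRUE)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # small hand-worked dataset against a from-scratch O-E/V computation
  time <- c(3, 5, 7, 9, 11, 14, 16, 20)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  group <- rep(c("g1", "g2"), 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi_square, logrank_stat_oracle(time, event, group),
               tolerance = 1e-9)

  expect_error(logrank_test(time, rep(FALSE, 8), group), "zero events")
  expect_error(logrank_test(time, event, rep("g1", 8)), "two")

  # invariant under a common monotone time transformation
  lr_sq <- logrank_test(time^2, event, group)
  expect_equal(lr_sq$chi_square, lr$chi_square, tolerance = 1e-12)
})

test_that("log-rank p agrees with a label-permutation reference", {
  set.seed(14)
  time <- c(rexp(6, 1 / 50), rexp(6, 1 / 120))
  event <- rep(TRUE, 12)
  group <- rep(c("a", "b"), each = 6)
  obs <- logrank_test(time, event, group)
  n_perm <- 1e4
  perm_stats <- vapply(seq_len(n_perm), function(i)
    logrank_stat_oracle(time, event, sample(group)), numeric(1))
  p_perm <- mean(perm_stats >= obs$chi_square - 1e-9)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # chi-square approximation vs exact permutation: agree within Monte-Carlo
  # error plus a small discreteness allowance at n = 12
  expect_lt(abs(obs$p_value - p_perm), 3 * se + 0.025)
})

test_that("logistic regression reproduces the cross-product odds ratio", {
  # 2x2 table (3,7; 9,1): OR = 3*1 / (7*9)
  x <- rep(c(1, 1, 0, 0), c(3, 7, 9, 1))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 7, 9, 1))
  fit <- logistic_fit(y, data.frame(x = x))
  expect_equal(fit$odds_ratio, 3 / 63, tolerance = 1e-6)
  expect_equal(fit$odds_ratio, exp(fit$coefficient), tolerance = 1e-12)
  expect_true(fit$ci95_low < fit$odds_ratio &
                fit$odds_ratio < fit$ci95_high)

  expect_error(logistic_fit(y, data.frame(x = rep(1, 20))), "singular")
  expect_error(logistic_fit(rep(TRUE, 20), data.frame(x = x)),
               "both classes")
  sep <- data.frame(x = as.numeric(y))
  expect_error(logistic_fit(y, sep), "separation")
})

test_that("null logistic Wald p-values are approximately uniform", {
  set.seed(25)
  ps <- vapply(1:150, function(i) {
    x <- rnorm(200)
    y <- runif(200) < 0.4
    logistic_fit(y, data.frame(x = x))$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
  ks <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(ks), 0.15)
})

test_that("Fisher's exact test matches printed statistics and the oracle", {
  # published association of methylation with age at diagnosis
  p062 <- fisher_exact(matrix(c(1, 53, 15, 63), 2, byrow = TRUE))$p_value
  expect_equal(round(p062, 3), 0.002)
  p116 <- fisher_exact(matrix(c(1, 53, 11, 67), 2, byrow = TRUE))$p_value
  expect_equal(round(p116, 3), 0.027)

  # perfectly proportional table: independence, p = 1
  expect_equal(fisher_exact(matrix(c(10, 20, 5, 10), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  # exhaustive-enumeration oracle across random 2x2 tables with N <= 60
  set.seed(8)
  for (i in 1:60) {
    tab <- matrix(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)), 2)
    expect_equal(fisher_exact(tab)$p_value, fisher_2x2_oracle(tab),
                 tolerance = 1e-7)
  }
})

test_that("2x3 Fisher matches brute-force enumeration of fixed-margin tables", {
  tab <- matrix(c(3, 1, 4, 2, 5, 0), nrow = 2)
  # enumerate all 2x3 tables with the observed margins
  rs <- rowSums(tab); cs <- colSums(tab)
  p_obs <- NULL; total <- 0
  prob_table <- function(m) prod(1 / sapply(as.vector(m), factorial))
  p_sum <- 0
  obs_prob <- prob_table(tab)
  for (a in 0:min(rs[1], cs[1])) for (b in 0:(rs[1] - a)) {
    c1 <- rs[1] - a - b
    if (c1 < 0 || b > cs[2] || c1 > cs[3]) next
    m <- rbind(c(a, b, c1), cs - c(a, b, c1))
    if (any(m < 0)) next
    pr <- prob_table(m)
    total <- total + pr
    if (pr <= obs_prob * (1 + 1e-7)) p_sum <- p_sum + pr
  }
  expect_equal(fisher_exact(tab)$p_value, p_sum / total, tolerance = 1e-9)
})

test_that("Freedman log-rank power behaves as the closed form dictates", {
  # no effect: power equals the size of the test
  expect_equal(logrank_power(0.6, 0.6, 50, 50, alpha = 0.05), 0.05,
               tolerance = 1e-9)
  # monotone in sample size
  p1 <- logrank_power(0.8, 0.45, 66, 66)
  p2 <- logrank_power(0.8, 0.45, 132, 132)
  expect_gte(p2, p1)
  # monotone in effect size
  expect_gt(logrank_power(0.8, 0.3, 66, 66), logrank_power(0.8, 0.6, 66, 66))
  # independent evaluation of the same formula
  hr <- log(0.45) / log(0.8)
  d <- 66 * 0.2 + 66 * 0.55
  delta <- abs(hr - 1) * sqrt(d) / (1 + hr)
  expected <- pnorm(delta - qnorm(0.975)) + pnorm(-delta - qnorm(0.975))
  expect_equal(p1, expected, tolerance = 1e-6)
  expect_error(logrank_power(0, 0.5, 10, 10), "strictly")
})
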