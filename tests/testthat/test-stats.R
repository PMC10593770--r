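# Group tests, multiplicity control, Fisher, cohort descriptives and the
# behavioural indices, cross-checked against brute-force oracles.

test_that("two-group tests handle degenerate and separated data", {
  d_same <- data.frame(v = rep(5, 8), g = rep(c("a", "b"), each = 4))
  t_res <- two_group_test(d_same, "v", "g", method = "student_t")
  expect_equal(t_res$statistic, 0)
  expect_equal(t_res$p_value, 1)
  mw <- two_group_test(d_same, "v", "g", method = "mann_whitney")
  expect_equal(mw$p_value, 1)   # mid-rank tie convention
  set.seed(2)
  d_sep <- data.frame(v = c(rnorm(4, 0, 1e-3), rnorm(4, 10, 1e-3)),
                      g = rep(c("a", "b"), each = 4))
  expect_lt(two_group_test(d_sep, "v", "g", "student_t")$p_value, 0.001)
  expect_error(two_group_test(data.frame(v = 1:3, g = c("a", "a", "a")),
                              "v", "g"), "2 levels")
})

test_that("Mann-Whitney U equals the brute-force pair count (mid-ranks)", {
  set.seed(11)
  for (rep in 1:5) {
    x <- sample(0:20, 12, replace = TRUE)   # ties likely
    y <- sample(0:20, 9, replace = TRUE)
    d <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(12, 9)))
    res <- two_group_test(d, "v", "g", "mann_whitney")
    u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(res$statistic, u_oracle)
    # normal-approximation p agrees with a permutation oracle
    perm <- replicate(2000, {
      s <- sample(c(x, y))
      xs <- s[1:12]; ys <- s[13:21]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    })
    p_perm <- mean(abs(perm - 0.5 * 12 * 9) >= abs(u_oracle - 0.5 * 12 * 9))
    expect_lt(abs(res$p_value - p_perm), 0.05)
  }
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- numeric(n); run_min <- Inf
    for (i in seq_len(n)) {
      k <- o[i]
      rank_k <- n - i + 1
      run_min <- min(run_min, n / rank_k * p[k])
      adj[i] <- min(1, run_min)
    }
    adj[ro]
  }
  set.seed(5)
  for (rep in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    expect_true(all(bh_adjust(p) >= p - 1e-12))
  }
})

test_that("Fisher's exact reproduces the cohort sex comparison and oracle", {
  # 2 F / 9 M patients vs 5 F / 11 M controls -> p ~ 0.66
  res <- fisher_exact_test(cohort_sex_table())
  expect_equal(round(res$p_value, 2), 0.66)
  expect_equal(fisher_exact_test(matrix(c(4, 4, 4, 4), 2))$p_value, 1)
  expect_error(fisher_exact_test(matrix(c(1, 2, 3, -1), 2)), "non-negative")
  # full hypergeometric enumeration oracle on random small tables
  fisher_oracle <- function(m) {
    rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
    probs <- vapply(0:min(rs[1], cs[1]), function(a) {
      b <- rs[1] - a; c2 <- cs[1] - a; d2 <- rs[2] - c2
      if (b < 0 || c2 < 0 || d2 < 0) return(NA_real_)
      exp(lchoose(cs[1], a) + lchoose(cs[2], b) - lchoose(n, rs[1]))
    }, numeric(1))
    probs <- probs[!is.na(probs)]
    p_obs <- exp(lchoose(cs[1], m[1, 1]) + lchoose(cs[2], m[1, 2]) -
                   lchoose(sum(m), rs[1]))
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_test(m)$p_value, fisher_oracle(m),
                 tolerance = 1e-7)
  }
})

test_that("t-based cohort descriptives reproduce the patient table", {
  cohort <- patient_cohort()
  expect_identical(nrow(cohort), 11L)
  expect_identical(sum(cohort$sex == "F"), 2L)
  ci <- mean_ci_t(cohort$age_at_death)
  expect_equal(round(ci$ci_lower, 1), 42.8)
  expect_equal(round(ci$ci_upper, 1), 62.3)
  sym <- mean_ci_t(c(-1, 0, 1))
  expect_equal(sym$mean, 0)
  expect_equal(sym$ci_lower, -sym$ci_upper)
  expect_error(mean_ci_t(5), ">= 2")
  # coverage under Gaussian sampling
  set.seed(99)
  hits <- replicate(400, {
    ci <- mean_ci_t(rnorm(10, 3, 2))
    ci$ci_lower <= 3 && 3 <= ci$ci_upper
  })
  expect_gt(mean(hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(hits), 0.95 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("behavioural indices are the documented ratios", {
  expect_equal(discrimination_index(3, 1), 0.5)
  expect_equal(discrimination_index(2, 2), 0)
  expect_equal(discrimination_index(1, 3), -discrimination_index(3, 1))
  expect_error(discrimination_index(0, 0), "> 0")
  expect_equal(open_arm_percentage(5, 5), 50)
  expect_equal(open_arm_percentage(0, 7), 0)
  expect_equal(percent_change(35.8, 28.5), 20.39106, tolerance = 1e-5)
  expect_equal(percent_change(4, 4), 0)
  expect_error(percent_change(0, 1), "nonzero")
  expect_equal(rater_mean_rate(c(10, 14), 10), 1.2)
  expect_equal(rater_mean_rate(7, 10), 0.7)
  expect_equal(rater_mean_rate(c(14, 10), 10), rater_mean_rate(c(10, 14), 10))
})

test_that("multi-group wrappers share the result schema", {
  set.seed(3)
  d <- data.frame(v = c(rnorm(10), rnorm(10, 3), rnorm(10, 6)),
                  g = rep(c("a", "b", "c"), each = 10))
  an <- multi_group_test(d, "v", "g", "anova_tukey")
  expect_lt(an$omnibus$p_value, 0.001)
  expect_identical(nrow(an$pairwise), 3L)
  kw <- multi_group_test(d, "v", "g", "kruskal_dunn")
  expect_lt(kw$omnibus$p_value, 0.001)
  expect_true(all(kw$pairwise$p_adjusted >= kw$pairwise$p_value - 1e-12))
  expect_true(all(kw$pairwise$p_value >= 0 & kw$pairwise$p_value <= 1))
  expect_error(multi_group_test(d[d$g != "c", ], "v", "g"), "two_group_test")
})
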