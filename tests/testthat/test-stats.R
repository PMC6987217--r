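# exact rank-sum, paired t, OLS, Cohen's d, study orchestration

test_that("exact rank-sum enumeration matches hand counts and flags ties", {
  r1 <- wilcoxon_rank_sum_one_tailed(c(4, 5, 6), c(1, 2, 3))
  expect_identical(r1$method, "exact")
  expect_equal(r1$p_one_tailed, 1 / 20, tolerance = 1e-12)
  r2 <- wilcoxon_rank_sum_one_tailed(7:12, 1:6)
  expect_equal(r2$p_one_tailed, 1 / 924, tolerance = 1e-12)
  tied <- wilcoxon_rank_sum_one_tailed(5, 5)
  expect_identical(tied$method, "normal_approx")
  expect_gt(tied$p_one_tailed, 0)
  expect_error(wilcoxon_rank_sum_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum agrees with the reference implementation over random tie-free samples", {
  set.seed(777)
  for (i in 1:150) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(seq_len(50), nx + ny)        # distinct -> tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    mine <- wilcoxon_rank_sum_one_tailed(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = TRUE)$p.value
    expect_identical(mine$method, "exact")
    expect_equal(mine$p_one_tailed, ref, tolerance = 1e-12)
  }
})

test_that("the exact null distribution normalises", {
  # sum over achievable rank sums w of P(W = w) must be 1
  for (nn in list(c(3, 3), c(4, 6), c(6, 6))) {
    nx <- nn[1]; n <- sum(nn)
    sums <- colSums(matrix(utils::combn(n, nx), nrow = nx))
    tab <- table(sums)
    expect_equal(sum(tab) / choose(n, nx), 1, tolerance = 1e-12)
    # one-tailed p at the smallest achievable W is exactly 1
    worst <- wilcoxon_rank_sum_one_tailed(seq_len(nx), nx + seq_len(n - nx))
    expect_equal(worst$p_one_tailed, 1, tolerance = 1e-12)
  }
})

test_that("paired t matches hand computation and the reference implementation", {
  sym <- paired_t(c(-1, 1))
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  expect_error(paired_t(c(2, 2, 2)), "zero variance")
  expect_error(paired_t(1), ">= 2")
  set.seed(55)
  for (i in 1:100) {
    d <- rnorm(sample(3:15, 1))
    mine <- paired_t(d)
    ref <- stats::t.test(d)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    one <- paired_t(d, tail = "one")
    ref1 <- stats::t.test(d, alternative = "greater")
    expect_equal(one$p_value, ref1$p.value, tolerance = 1e-9)
  }
})

test_that("OLS matches lm, handles exact fits, and is affine-invariant in r^2", {
  exact <- linear_regression(1:10, 2 * (1:10) + 1)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  flat <- linear_regression(1:10, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant")
  set.seed(66)
  for (i in 1:50) {
    x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20)
    mine <- linear_regression(x, y)
    ref <- summary(stats::lm(y ~ x))
    expect_equal(mine$slope, unname(ref$coefficients[2, 1]),
                 tolerance = 1e-9)
    expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-9)
    expect_equal(mine$p_slope, unname(ref$coefficients[2, 4]),
                 tolerance = 1e-9)
    # r^2 invariant under affine rescaling of both variables
    resc <- linear_regression(3 * x - 7, -2 * y + 11)
    expect_equal(resc$r_squared, mine$r_squared, tolerance = 1e-9)
  }
})

test_that("a calibrated noise level reproduces a population r^2 of 0.43 at large n", {
  # slope 0.4 with x ~ N(0,1): residual variance 0.4^2 * (1 - R2) / R2
  r2_target <- 0.43
  sigma_e <- sqrt(0.4^2 * (1 - r2_target) / r2_target)
  set.seed(4242)
  x <- rnorm(1e4)
  y <- 0.4 * x + rnorm(1e4, 0, sigma_e)
  fit <- linear_regression(x, y)
  expect_equal(fit$r_squared, r2_target, tolerance = 0.02)
})

test_that("cohens_d implements the unweighted-variance formula with the standard thresholds", {
  expect_equal(cohens_d(5, 2, 5, 3)$d, 0)
  expect_identical(cohens_d(5, 2, 5, 3)$magnitude, "negligible")
  d <- cohens_d(12.5, 2.7^2, 6.2, 2.3^2)
  expect_equal(d$d, 6.3 / sqrt((2.7^2 + 2.3^2) / 2), tolerance = 1e-12)
  expect_identical(d$magnitude, "large")
  # antisymmetry
  expect_equal(cohens_d(6.2, 2.3^2, 12.5, 2.7^2)$d, -d$d, tolerance = 1e-12)
  # magnitude thresholds
  expect_identical(cohens_d(0.2, 1, 0, 1)$magnitude, "small")
  expect_identical(cohens_d(0.5, 1, 0, 1)$magnitude, "medium")
  expect_identical(cohens_d(0.8, 1, 0, 1)$magnitude, "large")
  expect_error(cohens_d(1, 0, 0, 0), "zero")
})

test_that("the unweighted form differs from n-weighted pooling for unequal groups", {
  xj <- c(-1.2, 0.8, 3.1, 4.4)                       # small, high-variance
  xi <- c(0.1, 0.2, -0.1, 0.05, 0.15, -0.2, 0, 0.1,
          -0.05, 0.12, 0.02, -0.08)                  # large, low-variance
  mine <- cohens_d_samples(xj, xi)$d
  pooled_var <- ((length(xj) - 1) * var(xj) + (length(xi) - 1) * var(xi)) /
    (length(xj) + length(xi) - 2)
  d_pooled <- (mean(xj) - mean(xi)) / sqrt(pooled_var)
  expect_equal(mine, (mean(xj) - mean(xi)) / sqrt((var(xj) + var(xi)) / 2),
               tolerance = 1e-12)
  expect_gt(abs(mine - d_pooled), 0.05)   # pins the unweighted form
})

make_summaries <- function(overalls, min_shoe = "neutral",
                           max_shoe = "lateral_post") {
  lapply(seq_along(overalls), function(i) {
    sid <- sprintf("S%02d", i)
    per_shoe <- list(
      neutral = hmp_deviation(sid, "neutral", overalls[i] - 1, 0),
      lateral_post = hmp_deviation(sid, "lateral_post", overalls[i] + 1, 0),
      medial_post = hmp_deviation(sid, "medial_post", overalls[i], 0))
    summarize_subject(per_shoe)
  })
}

make_reductions <- function(n_subj, fun) {
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    do.call(rbind, lapply(c("neutral", "lateral_post", "medial_post"),
                          function(sh) {
      data.frame(subject = sprintf("S%02d", i), condition = sh,
                 region = knee_regions(),
                 pct_reduction = fun(i, sh), stringsAsFactors = FALSE)
    }))
  }))
}

test_that("run_study_analysis wires groups, shoes and regressions together", {
  set.seed(123)
  summaries <- make_summaries(c(1:6, 101:106))
  reds <- make_reductions(12, function(i, sh) {
    base <- if (i > 6) 8 else 3
    base + (sh == "lateral_post") * 2 + rnorm(7, 0, 0.3)
  })
  res <- run_study_analysis(summaries, reds, analysis_config())
  expect_identical(res$groups$high, sprintf("S%02d", 7:12))
  expect_identical(nrow(res$group_tests), 7L)
  expect_true(all(res$group_tests$method == "exact"))
  expect_true(all(res$group_tests$p_value < 0.05))
  expect_true(all(res$group_tests$significant))
  expect_true(all(res$footwear_tests$p_value < 0.05))
  expect_true(all(res$regressions$r_squared > 0.5))
  # subject mismatch is a loud validation error
  expect_error(
    run_study_analysis(summaries, reds[reds$subject != "S03", ]),
    "mismatch.*S03")
})

test_that("identical reductions across shoes make paired tests not-computable, pipeline completes", {
  summaries <- make_summaries(seq(2, 24, by = 2))
  reds <- make_reductions(12, function(i, sh) rep(4 + i / 10, 7))
  res <- run_study_analysis(summaries, reds, analysis_config())
  expect_true(all(is.na(res$footwear_tests$p_value)))
  expect_true(all(grepl("zero variance", res$footwear_tests$note)))
  expect_identical(nrow(res$regressions), 7L)   # battery still completed
})

test_that("holm correction is available but off by default", {
  set.seed(321)
  summaries <- make_summaries(c(1:6, 51:56))
  reds <- make_reductions(12, function(i, sh) {
    (if (i > 6) 6 else 3) + (sh == "lateral_post") + rnorm(7, 0, 0.5)
  })
  plain <- run_study_analysis(summaries, reds, analysis_config())
  expect_false("p_holm" %in% names(plain$group_tests))
  holm <- run_study_analysis(summaries, reds,
                             analysis_config(holm_correction = TRUE))
  expect_true(all(holm$group_tests$p_holm >= holm$group_tests$p_value))
})
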