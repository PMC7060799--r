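# Validation statistics and reference-value procedure.

test_that("Dice handles identity, disjoint and partial overlap, and is symmetric in [0,1]", {
  a <- array(c(1, 1, 0, 0), c(2, 2))
  b <- array(c(1, 0, 0, 0), c(2, 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(dice(array(0, c(2, 2)), array(0, c(2, 2))), 1)
  expect_error(dice(a, array(0, c(3, 3))), "same shape")
  set.seed(14)
  for (i in 1:10) {
    x <- array(stats::runif(64) > 0.5, c(8, 8))
    y <- array(stats::runif(64) > 0.5, c(8, 8))
    d <- dice(x, y)
    expect_identical(d, dice(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("Bland-Altman reports bias, limits of agreement and the paired test", {
  eq <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(eq$bias, 0); expect_equal(eq$loa_low, 0)
  expect_equal(eq$p_vs_zero, 1)

  sh <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(sh$bias, 2); expect_equal(sh$sd_diff, 0)
  expect_equal(sh$p_vs_zero, 0)

  set.seed(15)
  manual <- stats::rnorm(100, 100, 15)
  auto <- manual + stats::rnorm(100, 1.8, 5)
  ba <- bland_altman(auto, manual)
  ci <- ba$bias + c(-1, 1) * 1.96 * ba$sd_diff / sqrt(ba$n)
  expect_true(ci[1] <= 1.8 && 1.8 <= ci[2])
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  # 3-sigma sampling band for an n=100 limit-of-agreement estimate
  expect_lt(abs(ba$loa_high - (1.8 + 9.8)), 2.5)
  expect_lt(abs(ba$loa_low - (1.8 - 9.8)), 2.5)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("error-detection summaries satisfy the balanced-accuracy identity", {
  flags <- c(rep(TRUE, 19), FALSE, rep(FALSE, 75), rep(TRUE, 5))
  truth <- c(rep(TRUE, 20), rep(FALSE, 80))
  s <- error_detection_summary(flags, truth)
  expect_equal(s$tp, 19L); expect_equal(s$fn, 1L)
  expect_equal(s$fp, 5L); expect_equal(s$tn, 75L)
  expect_equal(s$sensitivity, 95)
  expect_equal(s$specificity, 93.75)
  expect_equal(s$bacc, (s$sensitivity + s$specificity) / 2)

  perfect <- error_detection_summary(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$bacc, 100)
  expect_error(error_detection_summary(logical(0), logical(0)), "empty")
})

test_that("the 3-IQR rule removes a planted gross outlier and keeps inliers", {
  suppressWarnings({
    rv <- reference_values(
      data.frame(sex = "M", age = 50, p = c(10, 11, 12, 13, 1000)), "p")
  })
  row <- rv[rv$sex == "M" & rv$age_group == "45-54", ]
  expect_equal(row$n, 4L)
  expect_equal(row$outliers_removed, 1L)
  expect_equal(row$mean, mean(c(10, 11, 12, 13)))

  # quartile arithmetic oracle (type-7): 1000 exceeds Q3 + 3 IQR, 13 does not
  q <- stats::quantile(c(10, 11, 12, 13, 1000), c(0.25, 0.75), type = 7)
  expect_true(1000 > q[2] + 3 * (q[2] - q[1]))
  expect_true(13 <= q[2] + 3 * (q[2] - q[1]))
})

test_that("Gaussian prediction intervals match the closed form and degenerate safely", {
  set.seed(16)
  x <- stats::rnorm(600, 100, 10)
  suppressWarnings({
    rv <- reference_values(data.frame(sex = "F", age = 60, p = x), "p")
  })
  row <- rv[rv$sex == "F" & rv$age_group == "55-64", ]
  expect_lt(abs(row$pi_low - (100 - 19.6)), 1)
  expect_lt(abs(row$pi_high - (100 + 19.6)), 1)

  suppressWarnings({
    rc <- reference_values(data.frame(sex = "M", age = 50, p = rep(7, 30)), "p")
  })
  rowc <- rc[rc$sex == "M" & rc$age_group == "45-54", ]
  expect_equal(rowc$pi_low, 7); expect_equal(rowc$pi_high, 7)

  empty <- rv[rv$sex == "M" & rv$age_group == "45-54", ]
  expect_false(empty$available)
})

test_that("age regression recovers slopes and Bonferroni controls the family-wise error", {
  set.seed(17)
  n <- 500
  age <- stats::runif(n, 45, 75)
  y <- 150 - 0.5 * age + stats::rnorm(n, 0, 5)
  res <- age_regression(data.frame(sex = "M", age = age, p = y), "p")
  se <- 5 / (stats::sd(age) * sqrt(n))
  expect_lt(abs(res$slope - (-0.5)), 3 * se)

  exact <- suppressWarnings(
    age_regression(data.frame(sex = "F", age = age, p = 2 * age + 1), "p"))
  expect_equal(exact$slope, 2, tolerance = 1e-9)
  expect_lt(exact$p_adjusted, 1e-10)

  expect_error(age_regression(data.frame(sex = "M", age = rep(50, 10),
                                         p = stats::rnorm(10)), "p"),
               "constant")

  # family-wise control: 10 pure-noise parameters, 200 replicates
  set.seed(18)
  m <- 10
  hits <- vapply(seq_len(200), function(r) {
    dat <- data.frame(sex = "M", age = stats::runif(120, 45, 75))
    for (j in seq_len(m)) dat[[paste0("p", j)]] <- stats::rnorm(120)
    any(age_regression(dat, paste0("p", seq_len(m)))$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.09)
})

test_that("MAE comparison summarizes groups and detects separated error levels", {
  same <- mae_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  zero <- mae_compare(rep(0, 10), stats::rnorm(10, 5))
  expect_equal(zero$group_a$mean, 0)
  expect_gt(zero$group_b$mean, 0)

  set.seed(19)
  a <- abs(stats::rnorm(50, 4.04, 4))
  b <- abs(stats::rnorm(50, 6.65, 5.9))
  cmp <- mae_compare(a, b, paired = TRUE)
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$method, "paired t-test")
})
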