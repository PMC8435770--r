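test_that("Lin's CCC matches closed-form evaluations", {
  x <- c(2.3, 5.1, 7.8, 9.0, 11.4, 4.2)
  expect_equal(lin_ccc(x, x)$est, 1)

  # constant shift with equal variances: ccc = 2 s^2 / (2 s^2 + delta^2)
  set.seed(30)
  x <- rnorm(200)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # n-denominator sd = 1
  y <- x + 10
  expect_equal(lin_ccc(x, y)$est, 2 / (2 + 100), tolerance = 1e-10)

  # degenerate inputs are refused
  expect_error(lin_ccc(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(lin_ccc(rnorm(2), rnorm(2)), "at least 3")
})

test_that("CCC from summary moments reproduces the 2017-cohort arithmetic", {
  cc <- ccc_from_moments(8.9, 7.4, 3.0, 3.5, 0.71, n = 197)
  expect_equal(round(cc$est, 2), 0.63)
  expect_true(cc$sd > 0 && cc$sd < 0.2)
})

test_that("CCC never exceeds the Pearson correlation and is symmetric", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    x <- rnorm(n, 10, 2)
    y <- 0.5 * x + rnorm(n, sample(c(0, 3), 1), 1.5)
    ccc <- lin_ccc(x, y)$est
    r <- cor(x, y)
    expect_lte(abs(ccc), abs(r) + 1e-12)
    expect_lte(abs(ccc), 1)
    # invariant to relabelling the two methods
    expect_equal(ccc, lin_ccc(y, x)$est, tolerance = 1e-12)
  }
  # equality exactly when means and variances agree
  x <- rnorm(50)
  y <- 2 * x  # then standardise to equal moments
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)
  expect_equal(lin_ccc(x, y)$est, cor(x, y), tolerance = 1e-12)
})

test_that("rmsep matches hand arithmetic and its algebraic identity", {
  expect_equal(rmsep(c(2, 4), c(1, 3)), 1)
  expect_equal(rmsep(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmsep(1:5, 1:5), 0)

  # rmsep^2 = (mx - my)^2 + sx~^2 + sy~^2 - 2 sxy~ with n-denominator moments
  set.seed(32)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 5, 3); y <- rnorm(n, 4, 2)
    mx <- mean(x); my <- mean(y)
    rhs <- (mx - my)^2 + mean((x - mx)^2) + mean((y - my)^2) -
      2 * mean((x - mx) * (y - my))
    expect_equal(rmsep(x, y)^2, rhs, tolerance = 1e-10)
  }
})

test_that("coefficient of variation matches printed-table arithmetic", {
  expect_equal(cv_percent(rep(7, 10)), 0)
  expect_equal(round(cv_from_moments(8.9, 3.0), 1), 33.7)
  expect_equal(cv_from_moments(7.4, 3.5), 100 * 3.5 / 7.4)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("paired test reports bias and handles degenerate differences", {
  x <- c(4.1, 6.3, 8.2, 9.9, 12.0)
  pb <- paired_bias(x, x)
  expect_equal(pb$t, 0)
  expect_equal(pb$relative_bias, 0)

  # constant-shift differences: degenerate branch, p = 0 convention
  pb2 <- paired_bias(c(1, 2, 3), c(0, 1, 2))
  expect_true(pb2$degenerate)
  expect_equal(pb2$p_value, 0)
  expect_equal(pb2$mean_diff, 1)

  # cohort-level underestimation from the printed means
  pb3 <- paired_bias(c(9, 9), c(6.4, 6.4))
  expect_equal(round(pb3$relative_bias, 1), 28.9)

  # agrees with stats::t.test in the regular case
  set.seed(33)
  y <- x - rnorm(5, 1, 0.3)
  tt <- t.test(x, y, paired = TRUE)
  pb4 <- paired_bias(x, y)
  expect_equal(pb4$t, unname(tt$statistic))
  expect_equal(pb4$p_value, tt$p.value)
})

test_that("averaging variance reduction follows the closed form", {
  expect_equal(averaging_variance_reduction(1, 7), 0)
  expect_equal(averaging_variance_reduction(0.3, 1), 0)
  expect_equal(averaging_variance_reduction(0.56, 4), 33)
  expect_error(averaging_variance_reduction(1.2, 4))
})

test_that("Fisher z test detects departures from a hypothesised correlation", {
  out <- fisher_r_test(0.67, 313, rho0 = 1)
  expect_equal(out$p_value, 0)
  out2 <- fisher_r_test(0.5, 100, rho0 = 0.5)
  expect_equal(out2$z, 0)
  out3 <- fisher_r_test(0.8, 200, rho0 = 0)
  expect_lt(out3$p_value, 1e-10)
})

test_that("body-weight diagnostic recovers injected slopes and stays null-calibrated", {
  # noiseless linear size-dependence: slope recovered exactly (no sampling
  # test applies to a zero-residual fit)
  w <- seq(200, 500, length.out = 40)
  d <- 0.01 * w
  out <- bias_vs_bodyweight(x = d, y = rep(0, 40), bodyweight = w)
  expect_equal(out$slope, 0.01, tolerance = 1e-10)
  expect_true(is.na(out$p_value))

  # constant difference: zero slope
  out0 <- bias_vs_bodyweight(x = rep(2, 40), y = rep(0, 40), bodyweight = w)
  expect_equal(out0$slope, 0, tolerance = 1e-10)

  expect_error(bias_vs_bodyweight(d, d, rep(300, 40)), "constant body weight")

  # under a size-independent bias the slope is non-significant in >= 90%
  set.seed(34)
  reject <- vapply(1:200, function(i) {
    w <- rnorm(80, 350, 60)
    x <- rnorm(80, 9, 2.8)
    y <- x - rnorm(80, 2, 1)
    bias_vs_bodyweight(x, y, w)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.10)
})

test_that("agreement report reproduces per-group and pooled statistics", {
  set.seed(35)
  n <- 120
  cohort <- rep(c("C1", "C2"), each = n / 2)
  x <- rnorm(n, 9, 2.8)
  y <- 0.8 * x + rnorm(n, -1, 1.5)
  phen <- dplyr::bind_rows(
    single_trait_phen(sprintf("f%03d", 1:n), x, trait = "lipid_ref", cohort = cohort),
    single_trait_phen(sprintf("f%03d", 1:n), y, trait = "lipid_ds_mean", cohort = cohort)
  )
  rep_tbl <- agreement_report(phen, "lipid_ref", "lipid_ds_mean", group = "cohort")
  expect_equal(rep_tbl$group, c("C1", "C2", "pooled"))

  pooled <- rep_tbl[rep_tbl$group == "pooled", ]
  expect_equal(pooled$n, n)
  expect_equal(pooled$mean_x, mean(x))
  expect_equal(pooled$cv_y, cv_percent(y))
  expect_equal(pooled$pearson_r, cor(x, y))
  expect_equal(pooled$ccc, lin_ccc(x, y)$est)
  expect_equal(pooled$rmsep, rmsep(x, y))
  expect_equal(pooled$relative_bias, 100 * (mean(x) - mean(y)) / mean(x))

  g1 <- rep_tbl[rep_tbl$group == "C1", ]
  expect_equal(g1$ccc, lin_ccc(x[cohort == "C1"], y[cohort == "C1"])$est)

  # repeated-record traits must be summarised before pairing
  dup <- dplyr::bind_rows(phen,
                          single_trait_phen("f001", 1, trait = "lipid_ds_mean"))
  expect_error(agreement_report(dup, "lipid_ref", "lipid_ds_mean"),
               "multiple records")
})
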