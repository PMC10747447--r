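test_that("two-way mean squares conserve the total sum of squares", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, 10, 3), n, k) + rnorm(n)
    ms <- two_way_mean_squares(tab)
    expect_equal(ms$SSR + ms$SSC + ms$SSE, ms$SST,
                 tolerance = 1e-9)
    # independent route: stats::aov on the long format
    ora <- aov_mean_squares(tab)
    expect_equal(ms$MSR, ora$MSR, tolerance = 1e-9)
    expect_equal(ms$MSC, ora$MSC, tolerance = 1e-9)
    expect_equal(ms$MSE, ora$MSE, tolerance = 1e-9)
  }
})

test_that("identical raters give zero rater and residual mean squares", {
  ms <- two_way_mean_squares(cbind(1:3, 1:3))
  expect_equal(ms$MSC, 0)
  expect_equal(ms$MSE, 0)
  expect_error(two_way_mean_squares(matrix(1:3, ncol = 1)), "2 x 2")
  expect_error(two_way_mean_squares(cbind(c(1, NA), c(2, 3))), "finite")
})

test_that("worked 4x2 table reproduces the hand-computed decomposition", {
  tab <- rbind(c(1, 2), c(3, 5), c(6, 6), c(2, 2))
  ms <- two_way_mean_squares(tab)
  # grand mean 3.375; row means 1.5, 4, 6, 2; column means 3, 3.75
  expect_equal(ms$SSR, 25.375)
  expect_equal(ms$SSC, 1.125)
  expect_equal(ms$SSE, 1.375)
  expect_equal(ms$MSR, 25.375 / 3)
  expect_equal(ms$MSE, 1.375 / 3)
})

test_that("ICC forms match the closed-form estimates and reference CI", {
  tab <- rbind(c(1, 2), c(3, 5), c(6, 6), c(2, 2))
  i21 <- icc(tab, "ICC21")
  i31 <- icc(tab, "ICC31")
  i3k <- icc(tab, "ICC3k")
  expect_equal(i21$estimate, 8 / 9.25, tolerance = 1e-12)
  expect_equal(i31$estimate, 0.897196261682243, tolerance = 1e-9)
  expect_equal(i3k$estimate, 0.945812807881773, tolerance = 1e-9)
  # ICC(2,1) CI frozen from an independent reference implementation
  expect_equal(i21$lower, 0.1536295947418427, tolerance = 1e-9)
  expect_equal(i21$upper, 0.9903816702804742, tolerance = 1e-9)
  expect_true(i21$lower <= i21$estimate && i21$estimate <= i21$upper)
})

test_that("perfect agreement gives ICC 1; flat tables are undefined", {
  tab <- cbind(c(1, 4, 2, 6), c(1, 4, 2, 6))
  for (form in c("ICC21", "ICC31", "ICC3k")) {
    expect_equal(icc(tab, form)$estimate, 1)
  }
  expect_error(icc(matrix(5, 4, 2), "ICC21"), "undefined")
})

test_that("a rater offset lowers absolute agreement but not consistency", {
  set.seed(4)
  x <- rnorm(60, 20, 5)
  tab0 <- cbind(x, x + rnorm(60, 0, 0.5))
  tab_off <- tab0
  tab_off[, 2] <- tab_off[, 2] + 4
  expect_equal(icc(tab_off, "ICC31")$estimate,
               icc(tab0, "ICC31")$estimate, tolerance = 1e-12)
  expect_lt(icc(tab_off, "ICC21")$estimate, icc(tab0, "ICC21")$estimate)
})

test_that("joint affine maps leave every ICC form unchanged", {
  set.seed(6)
  tab <- cbind(rnorm(40, 10, 4), rnorm(40, 10, 4) + rnorm(40, 0, 1))
  for (form in c("ICC21", "ICC31", "ICC3k")) {
    a <- icc(tab, form)$estimate
    b <- icc(2.5 * tab - 7, form)$estimate
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("form ordering ICC21 <= ICC31 <= ICC3k holds when MSC >= MSE", {
  set.seed(31)
  tried <- 0
  for (i in 1:200) {
    tab <- cbind(rnorm(20, 10, 3), rnorm(20, 10, 3))
    tab[, 2] <- tab[, 1] + rnorm(20, runif(1, -2, 2), runif(1, 0.2, 2))
    ms <- two_way_mean_squares(tab)
    if (ms$MSR <= ms$MSE || ms$MSC < ms$MSE) next
    tried <- tried + 1
    e <- vapply(c("ICC21", "ICC31", "ICC3k"),
                function(f) icc(tab, f)$estimate, numeric(1))
    expect_true(e[1] <= e[2] + 1e-12 && e[2] <= e[3] + 1e-12)
  }
  expect_gt(tried, 50)
})

test_that("method-error CV matches hand evaluation and its invariances", {
  x1 <- c(10, 12, 14); x2 <- c(11, 13, 13)
  sdd <- sd(x1 - x2) # 2/sqrt(3)
  expect_equal(as.numeric(cv_method_error(x1, x2, "dahlberg")),
               100 * (sdd / sqrt(2)) / ((mean(x1) + mean(x2)) / 2))
  expect_equal(as.numeric(cv_method_error(x1, x2, "literal")),
               100 * sdd / (mean(x1) + mean(x2)))
  expect_equal(attr(cv_method_error(x1, x2), "variant"), "dahlberg")

  expect_equal(as.numeric(cv_method_error(x1, x1)), 0)
  # scale invariance
  expect_equal(as.numeric(cv_method_error(3.7 * x1, 3.7 * x2)),
               as.numeric(cv_method_error(x1, x2)), tolerance = 1e-12)
  expect_error(cv_method_error(x1, x2[1:2]), "lengths")
  expect_error(cv_method_error(c(1, -1), c(-1, 1)), "undefined")
})

test_that("SEM follows SD * sqrt(1 - ICC) with the literal variant on a flag", {
  expect_equal(sem_measurement(10, 1), 0)
  expect_equal(sem_measurement(0, 0.3), 0)
  # Table-style inputs: SD 11.27 deg at ICC 0.895
  expect_equal(sem_measurement(11.27, 0.895), 11.27 * sqrt(0.105))
  expect_equal(sem_measurement(11.27, 0.895, "literal"), 11.27 * 0.105)
  expect_error(sem_measurement(10, 1.2), "icc")
})

test_that("MDC95 is the constant 1.96*sqrt(2) multiple of SEM", {
  expect_equal(mdc95(0), 0)
  expect_equal(mdc95(1), qnorm(0.975) * sqrt(2))
  s <- runif(20, 0.1, 30)
  expect_equal(mdc95(s) / s, rep(qnorm(0.975) * sqrt(2), 20))
  expect_error(mdc95(-1), ">= 0")
})

test_that("ICC bands follow the reporting scheme with upper-bound ties", {
  expect_identical(classify_icc(c(0.895, 0.5, 0.39)),
                   c("very good", "normal", "poor"))
  expect_identical(classify_icc(0.75), "very good")
  expect_identical(classify_icc(c(0.49, 0.75, 0.9, 0.95), "methods"),
                   c("poor", "good", "high", "high"))
  expect_error(classify_icc(1.2), "exceed")
})

test_that("the report reproduces a zero-noise session and negation invariance", {
  prof <- motion_profile("side_dip_left")
  lo <- generate_angle_profile(prof)
  hi <- generate_angle_profile(prof, rate_hz = 100)
  pr <- pair_traces(lo, hi)
  rep1 <- reliability_report(pr)
  expect_identical(names(rep1),
                   c("participant", "task", "side", "n", "M", "SD",
                     "icc_form", "ICC", "ci_lower", "ci_upper", "band",
                     "CV_pct", "SEM", "MDC95"))
  expect_gt(rep1$ICC, 0.9999) # only interpolation error separates the two
  expect_lt(rep1$SEM, 0.05)
  expect_equal(rep1$MDC95, qnorm(0.975) * sqrt(2) * rep1$SEM)

  # negated (right side dip) pair: M flips, ICC unchanged
  neg <- pr
  neg$test <- -neg$test
  neg$reference <- -neg$reference
  rep2 <- reliability_report(list(pr, neg))
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$M[2], -rep2$M[1])
  expect_equal(rep2$ICC[2], rep2$ICC[1], tolerance = 1e-12)
})
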