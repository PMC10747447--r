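mk_trace <- function(vals, rate = 12, task = "side_dip_left", ...) {
  angle_trace(vals, rate_hz = rate, task = task, ...)
}

test_that("section extraction spans the two global extremes in time order", {
  w <- extract_section(mk_trace(c(0, 1, 2, 3, 2, 1)))
  expect_identical(c(w$start, w$end), c(0L, 3L)) # min first, max at 3
  expect_false(w$max_first)

  w2 <- extract_section(mk_trace(c(3, 2, 1, 0, 1, 2)))
  expect_identical(c(w2$start, w2$end), c(0L, 3L)) # max first
  expect_true(w2$max_first)

  # ties resolve to the earliest index
  w3 <- extract_section(mk_trace(c(0, 2, 2, 0, 1)))
  expect_identical(c(w3$start, w3$end), c(0L, 1L))

  expect_error(extract_section(mk_trace(c(5, 5, 5))), "no motion")
  expect_error(extract_section(mk_trace(5)), ">= 2 samples")
})

test_that("resampling interpolates linearly and preserves endpoints", {
  out <- resample_to_n(mk_trace(c(0, 1, 2)), 5)
  expect_equal(out$angle_deg, c(0, 0.5, 1, 1.5, 2))

  tr <- generate_angle_profile(motion_profile("side_dip_left"))
  out2 <- resample_to_n(tr, 100)
  expect_length(out2$angle_deg, 100L)
  expect_identical(out2$angle_deg[1], tr$angle_deg[1])
  expect_identical(out2$angle_deg[100], tr$angle_deg[61])

  # identity on the native grid
  v <- cumsum(runif(40))
  tr40 <- mk_trace(v)
  expect_identical(resample_to_n(tr40, 40)$angle_deg, v)
})

test_that("resampling is idempotent at n = 100 and preserves monotonicity", {
  set.seed(3)
  v <- cumsum(runif(37))
  once <- resample_to_n(mk_trace(v), 100)
  twice <- resample_to_n(once, 100)
  expect_identical(once$angle_deg, twice$angle_deg)
  expect_true(all(diff(once$angle_deg) >= 0))
})

test_that("interior gaps are bridged with a warning; hopeless traces error", {
  v <- c(0, 1, NA, 3, 4)
  expect_warning(out <- resample_to_n(mk_trace(v), 5), "bridging")
  expect_equal(out$angle_deg, c(0, 1, 2, 3, 4))
  expect_error(resample_to_n(mk_trace(c(NA_real_, NA_real_)), 5),
               "missing")
  expect_error(resample_to_n(mk_trace(c(NA, 1, 2)), 5), "endpoints")
})

test_that("sign harmonisation negates an opposite-convention reference", {
  test <- mk_trace(c(0, 10, 20))
  ref <- mk_trace(c(-10, -20), convention = "right_positive")
  out <- harmonize_signs(test, ref)
  expect_equal(out$reference$angle_deg, c(10, 20))
  expect_identical(out$reference$convention, "left_positive")

  same <- harmonize_signs(test, mk_trace(c(1, 2)))
  expect_equal(same$reference$angle_deg, c(1, 2))

  expect_error(harmonize_signs(test, mk_trace(c(1, 2),
                                              task = "ybt_hip_extension",
                                              convention = "unsigned_0_180")),
               "task mismatch")
})

test_that("paired traces land on the exact 100-frame grid", {
  prof <- motion_profile("side_dip_left")
  lo <- generate_angle_profile(prof)
  hi <- generate_angle_profile(prof, rate_hz = 100)
  for (strategy in c("test", "each")) {
    pr <- pair_traces(lo, hi, window_from = strategy)
    expect_length(pr$test, 100L)
    expect_length(pr$reference, 100L)
    expect_identical(pr$convention, "left_positive")
  }
})

test_that("same motion at 12 vs 100 Hz pairs within the interpolation bound", {
  # raised-cosine rise over T_r seconds: max curvature peak/2 * (pi/T_r)^2;
  # linear interpolation error bound: curvature * h^2 / 8 at h = 1/12 s
  peak <- 40; dur <- 5; hold <- 0.2
  ramp <- (1 - hold) * dur / 2
  bound <- (peak / 2) * (pi / ramp)^2 * (1 / 12)^2 / 8
  prof <- motion_profile("side_dip_left", peak, dur, 12, hold)
  lo <- generate_angle_profile(prof)
  hi <- generate_angle_profile(prof, rate_hz = 100)
  for (strategy in c("test", "each")) {
    pr <- pair_traces(lo, hi, window_from = strategy)
    expect_lt(max(abs(pr$test - pr$reference)), bound)
  }
})

test_that("pairing commutes with joint sign negation", {
  set.seed(8)
  v12 <- generate_angle_profile(motion_profile("side_dip_left"))$angle_deg +
    rnorm(61, 0, 0.3)
  v100 <- generate_angle_profile(motion_profile("side_dip_left"),
                                 rate_hz = 100)$angle_deg + rnorm(501, 0, 0.3)
  for (strategy in c("test", "each")) {
    p_pos <- pair_traces(mk_trace(v12), mk_trace(v100, rate = 100),
                         window_from = strategy)
    p_neg <- pair_traces(mk_trace(-v12), mk_trace(-v100, rate = 100),
                         window_from = strategy)
    expect_equal(p_neg$test, -p_pos$test, tolerance = 1e-12)
    expect_equal(p_neg$reference, -p_pos$reference, tolerance = 1e-12)
  }
})

test_that("a constant reference trips the no-motion error", {
  lo <- generate_angle_profile(motion_profile("side_dip_left"))
  for (strategy in c("test", "each")) {
    expect_error(pair_traces(lo, mk_trace(rep(1, 50), rate = 100),
                             window_from = strategy), "no motion")
  }
})
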