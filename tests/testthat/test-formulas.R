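base_inputs <- list(cv2_int = 0.2, cv2_x = 0.2, cv2_z = 0.4,
                    gamma_x = 1 / 3, gamma_y = 1, gamma_z = 5,
                    gain = 0.5, k_z = 1, ybar = 100, zbar = 100)

test_that("open-loop noise time-averages the disturbance", {
  i <- base_inputs
  i$gamma_x <- 1
  expect_equal(cv2_open_loop(i)$total, 0.2 + 0.1)
  i$gamma_x <- 1e-9    # slow disturbance passes through fully
  expect_equal(cv2_open_loop(i)$total, 0.4, tolerance = 1e-8)
  i$gamma_x <- 1e9     # fast disturbance averages away
  expect_equal(cv2_open_loop(i)$total, 0.2, tolerance = 1e-8)
  i$cv2_x <- 0
  expect_equal(cv2_open_loop(i)$external, 0)
})

test_that("proportional noise reduces to the open loop at zero gain", {
  i <- base_inputs
  i$gain <- 0
  p <- cv2_proportional(i)
  o <- cv2_open_loop(i)
  expect_equal(p$intrinsic, o$intrinsic, tolerance = 1e-12)
  expect_equal(p$external, o$external, tolerance = 1e-12)
  expect_equal(p$controller, 0)
})

test_that("strong proportional feedback hits the documented limits", {
  i <- base_inputs
  i$gain <- 1e8
  p <- cv2_proportional(i)
  # intrinsic floor gamma_y/(gamma_y + gamma_z) * cv2_int
  expect_equal(p$intrinsic, 1 / 6 * 0.2, tolerance = 1e-6)
  expect_equal(p$external, 0, tolerance = 1e-8)
  expect_gt(p$controller, 1e6)   # sensor noise grows without bound
})

test_that("fast-sensor limit approximates the full proportional form", {
  i <- base_inputs
  i$gamma_z <- 1e5; i$gamma_x <- 1e-4; i$gain <- 2
  full <- cv2_proportional(i)
  fast <- cv2_proportional_fast_sensor(i)
  expect_equal(fast$intrinsic, full$intrinsic, tolerance = 1e-3)
  expect_equal(fast$external, full$external, tolerance = 1e-3)
  # external part decays one order in f faster than the intrinsic part
  expect_equal(fast$external / fast$intrinsic, i$cv2_x / i$cv2_int / (1 + 2),
               tolerance = 1e-12)
})

test_that("optimal proportional gains minimize the fast-sensor noise", {
  # asymptotic regime f* >> 1; closed forms hold to ~1%
  i <- list(cv2_int = 0, cv2_x = 0.2, cv2_z = 1e-4, gamma_y = 1,
            gamma_z = 1e3)
  opt <- optimal_gain_proportional(i, "external_only")
  num <- stats::optimize(function(f) {
    j <- i; j$gain <- f; cv2_proportional_fast_sensor(j)$total
  }, c(1, 1e5), tol = 1e-12)
  expect_equal(opt$gain, num$minimum, tolerance = 0.02)
  expect_equal(opt$min_cv2, num$objective, tolerance = 0.02)

  i2 <- list(cv2_int = 0.2, cv2_x = 0, cv2_z = 1e-4, gamma_y = 1,
             gamma_z = 1e3)
  opt2 <- optimal_gain_proportional(i2, "intrinsic_only")
  num2 <- stats::optimize(function(f) {
    j <- i2; j$gain <- f; cv2_proportional_fast_sensor(j)$total
  }, c(1, 1e5), tol = 1e-12)
  expect_equal(opt2$gain, num2$minimum, tolerance = 0.02)
  expect_equal(opt2$min_cv2, num2$objective, tolerance = 0.02)
  expect_error(optimal_gain_proportional(list(cv2_int = 1, cv2_z = 0,
                                              gamma_y = 1, gamma_z = 1)),
               "cv2_z")
})

test_that("the noise floor counts burst events of both genes", {
  # N_y = N_z = 100 burst events per target lifetime: floor = 2/100
  expect_equal(noise_floor_burst_events(ybar = 1000, by_mean = 10,
                                        zbar = 500, bz_mean = 10,
                                        gamma_y = 1, gamma_z = 2),
               0.02)
  # quadrupling both event counts quarters the floor (1/sqrt(Ny*Nz))
  expect_equal(noise_floor_burst_events(4000, 10, 2000, 10, 1, 2), 0.005)
  # consistency with the intrinsic-only optimum under geometric bursts
  ybar <- 400; by <- 10; zbar <- 300; bz <- 5; gy <- 1; gz <- 5
  opt <- optimal_gain_proportional(
    list(cv2_int = by / ybar, cv2_x = 0, cv2_z = bz / zbar,
         gamma_y = gy, gamma_z = gz), "intrinsic_only")
  expect_equal(opt$min_cv2,
               noise_floor_burst_events(ybar, by, zbar, bz, gy, gz),
               tolerance = 1e-12)
})

test_that("integral feedback leaves the intrinsic noise untouched", {
  for (f in c(0.1, 0.5, 2, 10)) {
    i <- base_inputs; i$gain <- f
    expect_equal(cv2_integral(i)$intrinsic, i$cv2_int)
    # the integrator noise is exactly linear in the gain
    expect_equal(cv2_integral(i)$controller, f * i$cv2_z)
  }
})

test_that("integral disturbance transmission peaks at the closed-form rate", {
  i <- base_inputs
  ext <- function(gx) { j <- i; j$gamma_x <- gx; cv2_integral(j)$external }
  num <- stats::optimize(ext, c(1e-4, 1e3), maximum = TRUE, tol = 1e-12)
  expect_equal(integral_peak_disturbance_rate(i), num$maximum,
               tolerance = 1e-6)
  # slow and fast disturbances are both rejected
  expect_lt(ext(1e-8), ext(num$maximum))
  expect_lt(ext(1e8), ext(num$maximum))
  # quadrupling the gain doubles the peak rate
  i4 <- i; i4$gain <- 4 * i$gain
  expect_equal(integral_peak_disturbance_rate(i4),
               2 * integral_peak_disturbance_rate(i), tolerance = 1e-12)
})

test_that("optimal integral gain minimizes the slow-disturbance noise", {
  i <- base_inputs
  i$gamma_x <- 0.01
  slow <- function(f) i$zbar * i$gamma_x / (i$ybar * f * i$k_z) * i$cv2_x +
    f * i$cv2_z + i$cv2_int
  num <- stats::optimize(slow, c(1e-5, 1e3), tol = 1e-14)
  opt <- optimal_gain_integral(i)
  expect_equal(opt$gain, num$minimum, tolerance = 1e-6)
  expect_equal(opt$min_cv2, num$objective, tolerance = 1e-10)
  # the minimal excess noise is linear in CV_X
  i4 <- i; i4$cv2_x <- 4 * i$cv2_x
  expect_equal(optimal_gain_integral(i4)$min_cv2 - i$cv2_int,
               2 * (opt$min_cv2 - i$cv2_int), tolerance = 1e-12)
})

test_that("derivative noise reduces to the open loop at zero gain", {
  i <- base_inputs; i$gain <- 0
  d <- cv2_derivative(i)
  o <- cv2_open_loop(i)
  expect_equal(d$intrinsic, o$intrinsic, tolerance = 1e-12)
  expect_equal(d$external, o$external, tolerance = 1e-12)
  expect_equal(d$controller, 0)
})

test_that("derivative control cannot reject slow disturbances", {
  i <- base_inputs
  i$gamma_x <- 1e-10
  for (f in c(0.2, 1, 5)) {
    i$gain <- f
    expect_equal(cv2_derivative(i)$external, i$cv2_x, tolerance = 1e-6)
  }
  # intrinsic part decreases and sensor part increases with the gain
  tot <- sapply(c(0.1, 0.5, 2, 8), function(f) {
    i$gain <- f; d <- cv2_derivative(i); c(d$intrinsic, d$controller)
  })
  expect_true(all(diff(tot[1, ]) < 0))
  expect_true(all(diff(tot[2, ]) > 0))
})

test_that("noise input records are validated", {
  expect_error(cv2_open_loop(list(cv2_int = -1, gamma_y = 1)),
               "non-negative")
  expect_error(cv2_proportional(utils::modifyList(base_inputs,
                                                  list(gain = -1))),
               "gain")
})
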