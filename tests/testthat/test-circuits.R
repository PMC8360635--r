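test_that("constructors validate their inputs", {
  expect_error(species_params(-1, 1, geo(2)), "non-negative")
  expect_error(species_params(1, 0, geo(2)), "positive")
  expect_error(regulation_spec("hill_repression", z_c = -1, h = 2), "z_c")
  expect_error(regulation_spec("zero_order_integral", z_c = 1, h = 1),
               "y_set")
  expect_error(disturbance_spec("none", xbar = 0), "positive")
  # topology/regulation variants must match
  tg <- species_params(1, 1, geo(2)); sn <- species_params(1, 1, geo(2))
  expect_error(circuit_proportional(tg, sn, regulation_spec("ratio_derivative",
                                                            h = 1)),
               "hill_repression")
  expect_error(circuit_derivative(tg, sn,
                                  regulation_spec("hill_repression",
                                                  z_c = 1, h = 1)),
               "ratio_derivative")
})

test_that("regulation multiplier honors the documented conventions", {
  rp <- regulation_spec("hill_repression", z_c = 50, h = 2)
  expect_equal(regulation_value(rp, z = 0), 1)
  expect_equal(regulation_value(rp, z = 50), 0.5)
  expect_equal(regulation_value(rp, z = 100), 1 / (1 + 4))
  rd <- regulation_spec("ratio_derivative", h = 2)
  expect_equal(regulation_value(rd, y = 30, z = 30), 1)
  # the y = 0 convention (z / max(y, 1))^h keeps propensities finite
  expect_equal(regulation_value(rd, y = 0, z = 3), 9)
  expect_equal(regulation_value(regulation_spec("open_loop"), y = 5, z = 7), 1)
})

test_that("open-loop and derivative steady means match the closed forms", {
  co <- circuit_open(species_params(2, 0.2, geo(20)))
  expect_equal(solve_steady_means(co)$ybar, 200)
  # derivative: ybar = (k_y <B_y>/gamma_y) * (k_z <B_z>/gamma_z)^h
  m5 <- solve_steady_means(fixture_circuit("fig5"))
  expect_equal(m5$ybar, 200)
  expect_equal(m5$zbar, 200)
})

test_that("proportional steady mean is the unique bracketed root", {
  cp <- fixture_circuit("fig2b")
  m <- solve_steady_means(cp)
  # residual of the stationary mean equation, at machine precision
  g <- regulation_value(cp$regulation, z = m$zbar)
  resid <- cp$target$k * g * 20 - cp$target$gamma * m$ybar
  expect_lt(abs(resid), 1e-10 * cp$target$gamma * m$ybar)
  # the root is independent of the bracket: re-solve from two distinct
  # brackets of the (strictly decreasing) stationary equation
  cc <- m$zbar / m$ybar
  f <- function(y) cp$target$k * regulation_value(cp$regulation, z = cc * y) *
    20 - cp$target$gamma * y
  y_open <- cp$target$k * 20 / cp$target$gamma
  r1 <- stats::uniroot(f, c(0, y_open), tol = 1e-13 * y_open)$root
  r2 <- stats::uniroot(f, c(0.5 * m$ybar, y_open), tol = 1e-13 * y_open)$root
  expect_lt(abs(r1 - r2) / r1, 1e-10)
  expect_lt(abs(m$ybar - r1) / r1, 1e-10)
  # documented working point of the fixture
  expect_equal(m$ybar, 100, tolerance = 1e-10)
  expect_equal(m$zbar, 50, tolerance = 1e-10)
})

test_that("integral steady means hit the set point exactly", {
  ci <- fixture_circuit("fig3b")
  m <- solve_steady_means(ci)
  expect_identical(m$ybar, 100)
  expect_equal(m$zbar, 100)   # z_c = 100, g(zbar) = 1/2 at this working point
  # unreachable set point: y_set above the open-loop mean
  bad <- ci
  bad$regulation$y_set <- 300  # open-loop mean is 200
  expect_error(solve_steady_means(bad), "unreachable")
})

test_that("feedback gains match their closed forms and bounds", {
  # Hill repression at zbar = z_c, h = 2: f = h * (1 - 1/2) = 1
  tg <- species_params(20, 1, geo(10))           # y_open = 200, g0 = 1/2
  sn <- species_params(0.2, 1, geo(10))          # zbar = 2 * ybar
  cp <- circuit_proportional(tg, sn,
                             regulation_spec("hill_repression",
                                             z_c = 200, h = 2))
  m <- solve_steady_means(cp)
  expect_equal(m$ybar, 100, tolerance = 1e-10)
  expect_equal(m$zbar, 200, tolerance = 1e-10)
  expect_equal(feedback_gain(cp), 1, tolerance = 1e-10)
  # derivative: f_d = h * gamma_y / gamma_z
  cd <- fixture_circuit("fig5")
  cd$sensor$gamma <- 1; cd$target$gamma <- 0.2
  expect_equal(feedback_gain(cd), 0.2)
  expect_equal(feedback_gain(circuit_open(tg)), 0)
  # property: the Hill-repression gain is bounded strictly below h
  set.seed(11)
  for (i in 1:20) {
    ci <- rand_circuit("proportional", disturbed = FALSE)
    expect_lt(feedback_gain(ci), ci$regulation$h)
    expect_gt(feedback_gain(ci), 0)
  }
})

test_that("static sensitivity matches the analytic values by topology", {
  expect_equal(static_sensitivity(circuit_open(species_params(2, 0.2,
                                                              geo(20)))),
               1, tolerance = 1e-9)
  expect_equal(static_sensitivity(fixture_circuit("fig3b")), 0,
               tolerance = 1e-9)
  expect_equal(static_sensitivity(fixture_circuit("fig5")), 1,
               tolerance = 1e-9)
  # property: proportional sensitivity equals 1/(1 + f_p)
  set.seed(12)
  for (i in 1:10) {
    ci <- rand_circuit("proportional", disturbed = FALSE)
    s <- static_sensitivity(ci)
    expect_equal(s, 1 / (1 + feedback_gain(ci)), tolerance = 1e-6)
  }
})

test_that("noise inputs reproduce the documented working points", {
  inp <- noise_inputs(fixture_circuit("fig2b"))
  expect_equal(inp$cv2_int, 0.2)
  expect_equal(inp$cv2_x, 0.2)
  expect_equal(inp$cv2_z, 0.4, tolerance = 1e-10)
  expect_equal(inp$gain, 0.5, tolerance = 1e-10)
  expect_equal(inp$gamma_z, 5)
  expect_equal(inp$gamma_x, 1 / 3)
  # frozen disturbance: no external noise channel
  inp0 <- noise_inputs(circuit_open(species_params(2, 0.2, geo(20))))
  expect_identical(inp0$cv2_x, 0)
  expect_identical(inp0$gamma_x, Inf)
})
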