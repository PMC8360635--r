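test_that("linearized burst frequency has the documented coefficients", {
  cp <- fixture_circuit("fig2b")
  lin <- linearize(cp)
  # base rate satisfies stationarity: b <B_y> = gamma_y * ybar
  m <- solve_steady_means(cp)
  expect_equal(lin$base_rate * 20, cp$target$gamma * m$ybar,
               tolerance = 1e-12)
  expect_equal(lin$coeffs[["x"]], 1)
  expect_equal(lin$coeffs[["z"]], -feedback_gain(cp), tolerance = 1e-12)

  cd <- fixture_circuit("fig5")
  ld <- linearize(cd)
  expect_equal(ld$coeffs[["y"]], -1)   # h = 1
  expect_equal(ld$coeffs[["z"]], 1)
  expect_false("x" %in% names(ld$coeffs))  # frozen disturbance

  ca <- rand_circuit("integral", design = "autocatalytic")
  # the autocatalytic integrator inverts the error sign: Z activates Y
  expect_gt(linearize(ca)$coeffs[["z"]], 0)
})

test_that("open-loop moment dynamics match the hand-derived system", {
  # k_y = 2, gamma_y = 0.2, geometric <B> = 20 (m2 = 780), no disturbance:
  #   d<y>/dt   = 40 - 0.2 <y>
  #   d<y^2>/dt = 1560 + (2*2*20 + 0.2) <y> - 0.4 <y^2>
  co <- circuit_open(species_params(2, 0.2, geo(20)))
  sys <- assemble_moment_system(co)
  expect_identical(sys$labels, c("y", "yy"))
  expect_equal(unname(sys$a), c(40, 1560))
  expect_equal(unname(sys$A),
               matrix(c(-0.2, 80.2, 0, -0.4), 2, 2), tolerance = 1e-14)
  mu <- steady_state_moments(sys)
  expect_equal(mu[["y"]], 200)
  # stationary CV2 equals <B_y>/ybar for geometric bursts
  expect_equal((mu[["yy"]] - mu[["y"]]^2) / mu[["y"]]^2, 0.1,
               tolerance = 1e-12)
})

test_that("stationary moments null the assembled dynamics", {
  set.seed(21)
  for (topo in c("open", "proportional", "integral", "derivative")) {
    ci <- rand_circuit(topo)
    sys <- assemble_moment_system(ci)
    mu <- steady_state_moments(sys)
    resid <- sys$a + sys$A %*% mu
    expect_lt(max(abs(resid)) / max(abs(sys$a)), 1e-9)
    # first moments agree with the deterministic steady means
    m <- solve_steady_means(ci)
    expect_equal(mu[["y"]], m$ybar, tolerance = 1e-8)
    if ("z" %in% sys$species) expect_equal(mu[["z"]], m$zbar,
                                           tolerance = 1e-8)
  }
})

test_that("non-Hurwitz and inconsistent systems are rejected", {
  sys <- structure(list(labels = c("y", "yy"), a = c(1, 1),
                        A = diag(2), species = "y", means = NULL),
                   class = "moment_system")
  expect_error(steady_state_moments(sys), "Hurwitz")
})

test_that("noise decomposition is additive with non-negative components", {
  set.seed(22)
  for (topo in c("open", "proportional", "integral", "derivative")) {
    ci <- rand_circuit(topo)
    dec <- decompose_noise(ci)
    expect_gte(dec$intrinsic, 0)
    expect_gte(dec$external, 0)
    expect_gte(dec$controller, -1e-12 * dec$total)
    # the total of the decomposition is the CV2 of the full moment solve
    full <- steady_state_moments(assemble_moment_system(ci))
    cv2_full <- (full[["yy"]] - full[["y"]]^2) / full[["y"]]^2
    expect_equal(dec$total, cv2_full, tolerance = 1e-10)
  }
})

test_that("silencing the disturbance removes exactly the external part", {
  ci <- fixture_circuit("fig2b")
  dec <- decompose_noise(ci)
  frozen <- ci
  frozen$disturbance <- disturbance_spec("none")
  dec0 <- decompose_noise(frozen)
  expect_equal(dec0$external, 0)
  expect_equal(dec0$intrinsic + dec0$controller,
               dec$intrinsic + dec$controller, tolerance = 1e-10)
})

test_that("moment systems export as a stable text dump", {
  sys <- assemble_moment_system(circuit_open(species_params(2, 0.2, geo(20))))
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  export_moment_system(sys, f)
  lines <- readLines(f)
  expect_identical(lines[1], "labels: y yy")
  expect_identical(lines[3], "A:")
  expect_length(lines, 3 + length(sys$labels))
})

test_that("degenerate regulating means are rejected at linearization", {
  cp <- fixture_circuit("fig2b")
  cp$sensor$k <- 0   # zbar = 0: the log-sensitivity gain is undefined
  expect_error(linearize(cp), "degenerate")
})
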