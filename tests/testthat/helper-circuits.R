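# Shared helpers: compact constructors and random circuit generators used by
# the property and oracle-equivalence tests. All draws use the caller's RNG
# stream; tests seed it explicitly.

geo <- function(m) burst_dist("shifted_geometric", m)

rand_disturbance <- function() {
  gx <- 10^stats::runif(1, -1, 1)
  bx <- stats::runif(1, 1, 25)
  xbar <- stats::runif(1, 100, 2000)
  disturbance_spec("bursty",
                   params = species_params(xbar * gx / bx, gx, geo(bx)))
}

# Random circuit at a controlled working point: decay rates over two decades,
# geometric bursts with means in [1, 25], stationary means in [100, 2000]
# (small-noise regime where every analytic route applies), Hill repression
# level g(zbar) in (0.15, 0.85), Hill coefficient in [0.5, 4].
rand_circuit <- function(topology, disturbed = TRUE, design = "zero_order") {
  dist <- if (disturbed) rand_disturbance() else disturbance_spec("none")
  gy <- 10^stats::runif(1, -1, 1)
  by <- stats::runif(1, 1, 25)
  ybar <- stats::runif(1, 100, 2000)
  if (topology == "open") {
    return(circuit_open(species_params(gy * ybar / by, gy, geo(by)), dist))
  }
  gz <- 10^stats::runif(1, -1, 1)
  bz <- stats::runif(1, 1, 25)
  zbar <- stats::runif(1, 100, 2000)
  h <- stats::runif(1, 0.5, 4)
  g0 <- stats::runif(1, 0.15, 0.85)
  zc <- zbar * ((1 - g0) / g0)^(-1 / h)
  if (topology == "proportional") {
    circuit_proportional(
      species_params(gy * ybar / (g0 * by), gy, geo(by)),
      species_params(zbar * gz / (bz * ybar), gz, geo(bz)),
      regulation_spec("hill_repression", z_c = zc, h = h),
      dist)
  } else if (topology == "integral") {
    kz <- 10^stats::runif(1, -1, 1)
    if (design == "autocatalytic") kz <- kz / ybar  # 1/(molecules * time)
    circuit_integral(
      species_params(gy * ybar / (g0 * by), gy, geo(by)),
      species_params(kz, gz, geo(bz)),
      regulation_spec("zero_order_integral", z_c = zc, h = h, y_set = ybar),
      dist, design = design)
  } else {
    ratio <- zbar / ybar               # = k_z <B_z>/gamma_z
    circuit_derivative(
      species_params(gy * ybar / (by * ratio^h), gy, geo(by)),
      species_params(ratio * gz / bz, gz, geo(bz)),
      regulation_spec("ratio_derivative", h = h),
      dist)
  }
}

# Closed-form prediction matching the circuit's topology (same dispatch the
# sweep engine uses), via the exported formula layer.
closed_form_for <- function(circuit) {
  inp <- noise_inputs(circuit)
  switch(circuit$topology,
    open = cv2_open_loop(inp),
    proportional = cv2_proportional(inp),
    integral = cv2_integral(inp, design = circuit$design),
    derivative = cv2_derivative(inp))
}

# State of y sampled on a regular time grid from a recorded trajectory
# (right-continuous step interpolation).
sample_states <- function(tr, from, by) {
  ts <- seq(from, tr$t_end, by = by)
  tr$y[findInterval(ts, tr$time)]
}
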