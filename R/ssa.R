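# run code with a private, restored RNG state so simulations are reproducible
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

default_burn_in <- function(circuit) {
  rates <- circuit$target$gamma
  if (circuit$disturbance$mode == "bursty")
    rates <- c(rates, circuit$disturbance$params$gamma)
  if (!is.null(circuit$sensor) && circuit$topology != "integral")
    rates <- c(rates, circuit$sensor$gamma)
  10 / min(rates)
}

kernel_args <- function(circuit, means, init) {
  kind_code <- function(b) if (b$kind == "deterministic") 0L else 1L
  has_x <- circuit$disturbance$mode == "bursty"
  xp <- circuit$disturbance$params
  sn <- circuit$sensor
  reg <- circuit$regulation
  topo <- match(circuit$topology,
                c("open", "proportional", "integral", "derivative")) - 1L
  if (identical(circuit$design, "autocatalytic"))
    stop("the autocatalytic integrator design is analysis-only; ",
         "simulate the zero-order design instead", call. = FALSE)
  state0 <- if (init == "means") {
    c(if (has_x) round(means$xbar) else means$xbar,
      round(means$ybar),
      if (is.null(sn)) 0 else round(means$zbar))
  } else {
    c(if (has_x) 0 else means$xbar, 0, 0)
  }
  list(topology = topo,
       has_x = has_x,
       k_x = if (has_x) xp$k else 0,
       g_x = if (has_x) xp$gamma else 0,
       bx_kind = if (has_x) kind_code(xp$burst) else 0L,
       bx_mean = if (has_x) xp$burst$mean_size else 1,
       xbar = means$xbar,
       k_y = circuit$target$k,
       g_y = circuit$target$gamma,
       by_kind = kind_code(circuit$target$burst),
       by_mean = circuit$target$burst$mean_size,
       has_z = !is.null(sn),
       k_z = if (is.null(sn)) 0 else sn$k,
       g_z = if (is.null(sn)) 0 else sn$gamma,
       bz_kind = if (is.null(sn)) 0L else kind_code(sn$burst),
       bz_mean = if (is.null(sn)) 1 else sn$burst$mean_size,
       z_c = if (is.null(reg$z_c)) 1 else reg$z_c,
       hill_h = if (is.null(reg$h)) 1 else reg$h,
       y_set = if (is.null(reg$y_set)) 0 else reg$y_set,
       x0 = state0[1], y0 = state0[2], z0 = state0[3])
}

#' Exact stochastic simulation of a circuit
#'
#' Direct-method SSA of the full nonlinear jump process (no linearization):
#' inter-event times are exponential in the total propensity, the event is
#' chosen proportionally to the channel propensities, burst events add a
#' freshly sampled burst size, death events decrement by one, and all
#' propensities are recomputed after every event. Identical
#' `(circuit, t_end, seed)` give bit-identical trajectories.
#'
#' @param circuit A [circuit_model()] (the autocatalytic integrator design is
#'   analysis-only and cannot be simulated).
#' @param t_end Simulation horizon (time), positive.
#' @param seed Integer seed (applied to a private RNG scope).
#' @param burn_in Time discarded before accumulating the built-in stationary
#'   summaries (default 0 for raw trajectories).
#' @param record Keep the full event-level trajectory (`TRUE`) or only the
#'   time-weighted summaries (`FALSE`, constant memory).
#' @param init Initial state: `"means"` (rounded deterministic steady means,
#'   shortens burn-in) or `"zeros"`.
#' @param hist_max If positive, also accumulate a time-weighted histogram of
#'   y over `0:hist_max`.
#' @param max_pop Per-species population cap; exceeding it raises a runaway
#'   error with diagnostics.
#' @param max_events Event budget guard.
#' @return Object of class `trajectory`: `time`, `x`, `y`, `z` vectors when
#'   recorded, plus summary fields (`mean_y`, `m2_y`, `weight`, ...), the
#'   seed, horizon and burn-in used.
#' @export
ssa_simulate <- function(circuit, t_end, seed = NULL, burn_in = 0,
                         record = TRUE, init = c("means", "zeros"),
                         hist_max = 0, max_pop = 1e6, max_events = 5e7) {
  stopifnot(inherits(circuit, "circuit_model"), t_end > 0, burn_in >= 0)
  init <- match.arg(init)
  means <- solve_steady_means(circuit)
  ka <- kernel_args(circuit, means, init)
  res <- with_seed(seed, do.call(.ssa_kernel, c(ka, list(
    t_end = t_end, burn_in = burn_in, record = record,
    hist_max = as.integer(hist_max), max_pop = max_pop,
    max_events = max_events))))
  res$t_end <- t_end
  res$burn_in <- burn_in
  res$seed <- seed
  res$recorded <- record
  res$topology <- circuit$topology
  structure(res, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s circuit, t_end=%g, %g events%s\n",
              x$topology, x$t_end, x$n_events,
              if (x$recorded) " (recorded)" else " (summaries only)"))
  invisible(x)
}

#' Trajectory export as a tidy data frame
#'
#' @param x A recorded [ssa_simulate()] trajectory.
#' @param ... Unused.
#' @return `data.frame` with columns `time`, `x`, `y`, `z`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  if (!isTRUE(x$recorded))
    stop("trajectory was simulated with record = FALSE", call. = FALSE)
  data.frame(time = x$time, x = x$x, y = x$y, z = x$z)
}

# time-weighted sums of y over [burn_in, t_end] from a recorded trajectory
tw_sums <- function(tr, burn_in) {
  t <- c(tr$time, tr$t_end)
  w <- pmax(pmin(t[-1], tr$t_end), burn_in) - pmin(pmax(t[-length(t)], burn_in), tr$t_end)
  w <- pmax(w, 0)
  y <- tr$y
  c(w = sum(w), y = sum(w * y), y2 = sum(w * y^2))
}

pooled_cv2 <- function(sums) {
  w <- sum(sums[, "w"]); m <- sum(sums[, "y"]) / w
  m2 <- sum(sums[, "y2"]) / w
  c(mean = m, cv2 = (m2 - m^2) / m^2)
}

#' Stationary summary statistics from replicate trajectories
#'
#' Time-weighted stationary mean and CV2 of the target protein, pooled across
#' replicates after discarding `burn_in` from each. Standard errors come from
#' a replicate-level jackknife of the pooled estimators (time-correlated
#' samples within a trajectory make naive i.i.d. errors invalid).
#'
#' @param trajectories A list of recorded [ssa_simulate()] trajectories (a
#'   single trajectory is accepted).
#' @param burn_in Time discarded at the start of every replicate; must be
#'   below every `t_end`.
#' @return Object of class `summary_stats`: list with `mean_y`, `cv2_y`,
#'   `se_mean`, `se_cv2`, `n_replicates`, `burn_in`.
#' @export
stationary_stats <- function(trajectories, burn_in = 0) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1,
            all(vapply(trajectories, inherits, TRUE, "trajectory")))
  if (any(vapply(trajectories, function(tr) burn_in >= tr$t_end, TRUE)))
    stop("invalid window: burn_in must be smaller than every t_end",
         call. = FALSE)
  sums <- t(vapply(trajectories, tw_sums, numeric(3), burn_in = burn_in))
  est <- pooled_cv2(sums)
  n <- nrow(sums)
  if (n > 1) {
    jk <- t(vapply(seq_len(n), function(i) pooled_cv2(sums[-i, , drop = FALSE]),
                   numeric(2)))
    se <- sqrt((n - 1) / n * colSums(sweep(jk, 2, colMeans(jk))^2))
  } else {
    se <- c(mean = NA_real_, cv2 = NA_real_)
  }
  structure(list(mean_y = est[["mean"]], cv2_y = est[["cv2"]],
                 se_mean = se[["mean"]], se_cv2 = se[["cv2"]],
                 n_replicates = n, burn_in = burn_in),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> mean_y = %.4g +/- %.3g, cv2_y = %.4g +/- %.3g (%d replicates)\n",
    x$mean_y, x$se_mean, x$cv2_y, x$se_cv2, x$n_replicates))
  invisible(x)
}

# replicate summaries without storing trajectories (constant memory)
ssa_rep_sums <- function(circuit, n_reps, t_end, burn_in, seed,
                         init = "means", max_events = 5e7) {
  seeds <- seed + seq_len(n_reps) - 1L
  t(vapply(seeds, function(s) {
    tr <- ssa_simulate(circuit, t_end = t_end, seed = s, burn_in = burn_in,
                       record = FALSE, init = init, max_events = max_events)
    c(w = tr$weight, y = tr$mean_y * tr$weight, y2 = tr$m2_y * tr$weight)
  }, numeric(3)))
}

closed_form_cv2 <- function(circuit) {
  inp <- noise_inputs(circuit)
  switch(circuit$topology,
    open = cv2_open_loop(inp),
    proportional = cv2_proportional(inp),
    integral = cv2_integral(inp, design = circuit$design %||% "zero_order"),
    derivative = cv2_derivative(inp)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the closed-form noise against exact simulation
#'
#' Runs `n_reps` independent SSA replicates of the circuit, estimates the
#' stationary CV2 of Y with a jackknife standard error, evaluates the
#' matching closed-form prediction (open-loop, proportional, integral or
#' derivative decomposition), and reports the z-score of the discrepancy.
#' Intended for small-noise regimes (total CV2 of roughly 0.5 or less) where
#' the linear noise approximation holds.
#'
#' @param circuit A [circuit_model()].
#' @param n_reps Number of replicates.
#' @param t_end Horizon per replicate.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param burn_in Discarded initial time (default: ten times the slowest
#'   relaxation timescale of the circuit).
#' @param flag_z Absolute z-score above which the comparison is flagged.
#' @return Object of class `lna_comparison`: list with the simulated and
#'   predicted CV2, standard errors, z-score and flag.
#' @export
validate_against_lna <- function(circuit, n_reps = 8, t_end, seed = 1,
                                 burn_in = default_burn_in(circuit),
                                 flag_z = 3) {
  stopifnot(t_end > burn_in)
  sums <- ssa_rep_sums(circuit, n_reps, t_end, burn_in, seed)
  est <- pooled_cv2(sums)
  jk <- t(vapply(seq_len(n_reps),
                 function(i) pooled_cv2(sums[-i, , drop = FALSE]), numeric(2)))
  se <- sqrt((n_reps - 1) / n_reps * colSums(sweep(jk, 2, colMeans(jk))^2))
  pred <- closed_form_cv2(circuit)
  zsc <- (est[["cv2"]] - pred$total) / se[["cv2"]]
  structure(list(cv2_sim = est[["cv2"]], se_cv2 = se[["cv2"]],
                 mean_sim = est[["mean"]], se_mean = se[["mean"]],
                 cv2_pred = pred$total, prediction = pred,
                 z = zsc, flagged = abs(zsc) > flag_z,
                 n_reps = n_reps, t_end = t_end, burn_in = burn_in,
                 seed = seed),
            class = "lna_comparison")
}

#' @export
print.lna_comparison <- function(x, ...) {
  cat(sprintf(
    "<lna_comparison> simulated CV2 = %.5g +/- %.3g, predicted %.5g, z = %.2f%s\n",
    x$cv2_sim, x$se_cv2, x$cv2_pred, x$z,
    if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}
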