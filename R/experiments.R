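# --- sweep plumbing ----------------------------------------------------------

# Rebuild a circuit at a requested feedback gain, preserving the working point
# (steady means and all CV2 inputs). For Hill repression the value g(zbar) is
# held at its base value while h carries the gain: h = f/(1 - g(zbar)) and z_c
# is re-placed so that (zbar/z_c)^h stays constant. For the derivative
# topology h = f * gamma_z / gamma_y directly (means are invariant when
# k_z <B_z>/gamma_z = 1, and are re-solved regardless).
circuit_at_gain <- function(circuit, gain) {
  stopifnot(gain >= 0)
  c2 <- circuit
  if (circuit$topology == "derivative") {
    c2$regulation$h <- max(gain, 1e-9) * circuit$sensor$gamma /
      circuit$target$gamma
    return(c2)
  }
  if (circuit$topology == "open")
    stop("open-loop circuits have no feedback gain to sweep", call. = FALSE)
  means <- solve_steady_means(circuit)
  g0 <- hill_g(circuit$regulation, means$zbar)
  h <- max(gain, 1e-9) / (1 - g0)
  c2$regulation$h <- h
  c2$regulation$z_c <- means$zbar * ((1 - g0) / g0)^(-1 / h)
  c2
}

# Rebuild a circuit at a new disturbance or sensor timescale, holding the
# stationary means (hence the CV2 inputs) fixed by co-scaling the burst rate.
circuit_at_rate <- function(circuit, variable, value) {
  stopifnot(value > 0)
  c2 <- circuit
  if (variable == "gamma_x") {
    if (circuit$disturbance$mode != "bursty")
      stop("no bursty disturbance to re-time", call. = FALSE)
    sc <- value / circuit$disturbance$params$gamma
    c2$disturbance$params$gamma <- value
    c2$disturbance$params$k <- circuit$disturbance$params$k * sc
    c2$disturbance$xbar <- disturbance_spec("bursty",
                                            params = c2$disturbance$params)$xbar
  } else if (variable == "gamma_z") {
    sc <- value / circuit$sensor$gamma
    c2$sensor$gamma <- value
    c2$sensor$k <- circuit$sensor$k * sc
  } else if (variable == "zbar") {
    if (circuit$topology == "integral") {
      means <- solve_steady_means(circuit)
      c2$regulation$z_c <- circuit$regulation$z_c * value / means$zbar
    } else {
      means <- solve_steady_means(circuit)
      c2$sensor$k <- circuit$sensor$k * value / means$zbar
    }
  } else stop("unknown sweep variable `", variable, "`", call. = FALSE)
  c2
}

#' Configure a parameter sweep
#'
#' @param circuit A [circuit_model()] or fixture name (see
#'   [fixture_circuit()]).
#' @param variable Swept quantity: `"gain"` (feedback gain, driven through the
#'   Hill coefficient at a fixed working point), `"gamma_x"` or `"gamma_z"`
#'   (timescales, burst rates co-scaled so means stay fixed), or `"zbar"`.
#' @param grid Strictly increasing, non-empty numeric grid.
#' @param engines Subset of `"formulas"` (closed forms), `"lna"`
#'   (generator-assembled moment solver) and `"ssa"` (exact simulation).
#' @param normalization `"none"`, or `"open_loop_total"`/`"zero_gain_total"`
#'   (all components divided by the open-loop total noise of the working
#'   point, i.e. the total at zero gain, as in the figure captions).
#' @param ssa List of SSA settings `n_reps`, `t_end`, `burn_in` (NULL for the
#'   default), `seed`.
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(circuit,
                         variable = c("gain", "gamma_x", "gamma_z", "zbar"),
                         grid,
                         engines = c("formulas", "lna"),
                         normalization = c("none", "open_loop_total",
                                           "zero_gain_total"),
                         ssa = list(n_reps = 8, t_end = NULL, burn_in = NULL,
                                    seed = 1)) {
  if (is.character(circuit)) circuit <- fixture_circuit(circuit)
  stopifnot(inherits(circuit, "circuit_model"))
  variable <- match.arg(variable)
  normalization <- match.arg(normalization)
  engines <- match.arg(engines, c("formulas", "lna", "ssa"), several.ok = TRUE)
  if (length(grid) == 0 || any(diff(grid) <= 0))
    stop("`grid` must be non-empty and strictly increasing", call. = FALSE)
  structure(list(circuit = circuit, variable = variable, grid = grid,
                 engines = engines, normalization = normalization, ssa = ssa),
            class = "sweep_config")
}

eval_engine <- function(circuit, engine, ssa_opts) {
  if (engine == "formulas") {
    dec <- closed_form_cv2(circuit)
    c(intrinsic = dec$intrinsic, external = dec$external,
      controller = dec$controller, total = dec$total, se = NA_real_)
  } else if (engine == "lna") {
    dec <- decompose_noise(circuit)
    c(intrinsic = dec$intrinsic, external = dec$external,
      controller = dec$controller, total = dec$total, se = NA_real_)
  } else {
    bi <- ssa_opts$burn_in %||% default_burn_in(circuit)
    te <- ssa_opts$t_end %||% (bi + 100 / circuit$target$gamma)
    cmp <- validate_against_lna(circuit, n_reps = ssa_opts$n_reps %||% 8,
                                t_end = te, seed = ssa_opts$seed %||% 1,
                                burn_in = bi)
    c(intrinsic = NA_real_, external = NA_real_, controller = NA_real_,
      total = cmp$cv2_sim, se = cmp$se_cv2)
  }
}

#' Run a parameter sweep
#'
#' Evaluates the requested engines at every grid point. Gain sweeps vary the
#' Hill coefficient with the working point (means and CV2 inputs) held fixed,
#' the paper-style primary knob; timescale sweeps co-scale burst rates so the
#' means are unchanged; means are re-solved at every point regardless.
#' Engine failures flag the row (`ok = FALSE`) and the sweep continues.
#' Normalization (by the zero-gain/open-loop total of the working point) is
#' applied last.
#'
#' @param config A [sweep_config()].
#' @return Object of class `sweep_result`: a `data.frame` with one row per
#'   (grid point x engine): `value`, `engine`, `intrinsic`, `external`,
#'   `controller`, `total`, `se`, `ok`; attributes `normalization`,
#'   `reference` (the normalizing total), `variable`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  base <- config$circuit
  ref <- 1
  if (config$normalization != "none") {
    ref <- cv2_open_loop(noise_inputs(base))$total
  }
  rows <- list()
  seed0 <- config$ssa$seed %||% 1
  for (i in seq_along(config$grid)) {
    v <- config$grid[i]
    ci <- tryCatch(
      if (config$variable == "gain") circuit_at_gain(base, v)
      else circuit_at_rate(base, config$variable, v),
      error = function(e) e)
    for (eng in config$engines) {
      opts <- config$ssa
      opts$seed <- seed0 + (i - 1L) * (opts$n_reps %||% 8)
      res <- if (inherits(ci, "error")) ci else
        tryCatch(eval_engine(ci, eng, opts), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          value = v, engine = eng, intrinsic = NA_real_, external = NA_real_,
          controller = NA_real_, total = NA_real_, se = NA_real_, ok = FALSE)
        warning(sprintf("engine `%s` failed at %s = %g: %s", eng,
                        config$variable, v, conditionMessage(res)),
                call. = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          value = v, engine = eng,
          intrinsic = res[["intrinsic"]] / ref,
          external = res[["external"]] / ref,
          controller = res[["controller"]] / ref,
          total = res[["total"]] / ref, se = res[["se"]] / ref, ok = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "normalization") <- config$normalization
  attr(out, "reference") <- ref
  attr(out, "variable") <- config$variable
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Reproduce the derivative-controller SSA validation sweep
#'
#' For the derivative validation circuit (no external disturbance, h = 1,
#' \eqn{k_z = \gamma_z}; see `fixture_circuit("fig5")`), sweeps the sensor
#' timescale \eqn{\gamma_z} (hence the gain \eqn{f_d = \gamma_y/\gamma_z}),
#' estimates the stationary CV2 of Y by exact simulation at every point, and
#' compares with the closed-form derivative-controller prediction. A point is
#' flagged when |z| exceeds `flag_z`.
#'
#' @param gamma_z Grid of sensor decay rates (the circuit's `k_z` tracks it).
#' @param n_reps Replicates per grid point.
#' @param t_end Horizon per replicate (time); default gives roughly 400
#'   target lifetimes of averaging after burn-in.
#' @param seed Base seed; grid point i uses `seed + (i-1)*n_reps`.
#' @param flag_z Flagging threshold on |z|.
#' @param circuit The validation circuit (defaults to the bundled fixture).
#' @return `data.frame` with one row per grid point: `gamma_z`, `f_d`,
#'   `cv2_sim`, `se`, `cv2_pred`, `z`, `flagged`; attribute `n_flagged`.
#' @export
reproduce_fig5 <- function(gamma_z = c(0.2, 0.5, 1, 2, 5, 10),
                           n_reps = 12, t_end = NULL, seed = 1, flag_z = 3,
                           circuit = fixture_circuit("fig5")) {
  rows <- lapply(seq_along(gamma_z), function(i) {
    gz <- gamma_z[i]
    ci <- circuit
    ci$sensor$gamma <- gz
    ci$sensor$k <- gz          # k_z = gamma_z per the validation design
    bi <- default_burn_in(ci)
    te <- t_end %||% (bi + 400 / ci$target$gamma)
    cmp <- validate_against_lna(ci, n_reps = n_reps, t_end = te,
                                seed = seed + (i - 1L) * n_reps,
                                burn_in = bi, flag_z = flag_z)
    data.frame(gamma_z = gz,
               f_d = feedback_gain(ci),
               cv2_sim = cmp$cv2_sim, se = cmp$se_cv2,
               cv2_pred = cmp$cv2_pred, z = cmp$z, flagged = cmp$flagged)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_flagged") <- sum(out$flagged)
  out
}
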