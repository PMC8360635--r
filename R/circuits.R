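#' Species kinetic parameters
#'
#' A bursty birth-death species: bursts arrive at Poisson rate `k`, each adds
#' a sampled burst size, and each molecule decays independently at rate
#' `gamma`.
#'
#' @param k Burst frequency (1/time), non-negative (zero gives a silent gene,
#'   useful as a degenerate control).
#' @param gamma First-order decay rate (1/time), strictly positive.
#' @param burst A [burst_dist()].
#' @return An object of class `species_params`.
#' @export
species_params <- function(k, gamma, burst) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("`k` must be a single non-negative rate", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive rate", call. = FALSE)
  stopifnot(inherits(burst, "burst_dist"))
  structure(list(k = as.numeric(k), gamma = as.numeric(gamma), burst = burst),
            class = "species_params")
}

#' External disturbance specification
#'
#' The upstream disturbance species X modulates the target's burst frequency
#' multiplicatively as \eqn{x(t)/\bar{x}}. With `mode = "none"` the
#' disturbance is frozen at a constant \eqn{x \equiv \bar{x}} (no external
#' noise); with `mode = "bursty"` X follows its own bursty birth-death
#' process with stationary mean \eqn{\bar{x} = k_x \langle B_x\rangle/\gamma_x}.
#'
#' @param mode `"none"` or `"bursty"`.
#' @param params A [species_params()] for X (required when `mode = "bursty"`).
#' @param xbar Constant level when `mode = "none"` (default 1; it cancels from
#'   every normalized burst frequency).
#' @return An object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(mode = c("none", "bursty"), params = NULL,
                             xbar = 1) {
  mode <- match.arg(mode)
  if (mode == "bursty") {
    stopifnot(inherits(params, "species_params"))
    xbar <- params$k * burst_moments(params$burst)[["m1"]] / params$gamma
  } else {
    params <- NULL
    if (!is.numeric(xbar) || xbar <= 0) stop("`xbar` must be positive", call. = FALSE)
  }
  structure(list(mode = mode, params = params, xbar = as.numeric(xbar)),
            class = "disturbance_spec")
}

#' Regulation of the target's burst frequency
#'
#' The burst-frequency multiplier implementing the feedback nonlinearity:
#' * `open_loop`: constant 1 (no regulation);
#' * `hill_repression`: repressing Hill function
#'   \eqn{g(z) = 1/(1 + (z/z_c)^h)} (proportional and integral controllers);
#' * `ratio_derivative`: \eqn{(z/y)^h}, the incoherent feedforward form that
#'   arises from a product of Z-activation and Y-self-repression Hill
#'   functions in the strong-Y-binding, weak-Z-binding limit with equal Hill
#'   coefficients (derivative controller).
#'
#' @param variant One of `"open_loop"`, `"hill_repression"`,
#'   `"zero_order_integral"`, `"ratio_derivative"`. `"zero_order_integral"`
#'   is Hill repression paired with the integrator reaction scheme; it also
#'   carries the set point `y_set`.
#' @param z_c Half-maximal repression level (molecules), positive.
#' @param h Hill coefficient, positive.
#' @param y_set Target set point (molecules), `zero_order_integral` only.
#' @return An object of class `regulation_spec`.
#' @export
regulation_spec <- function(variant = c("open_loop", "hill_repression",
                                        "zero_order_integral",
                                        "ratio_derivative"),
                            z_c = NULL, h = NULL, y_set = NULL) {
  variant <- match.arg(variant)
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    as.numeric(v)
  }
  if (variant %in% c("hill_repression", "zero_order_integral")) {
    z_c <- chk_pos(z_c, "z_c"); h <- chk_pos(h, "h")
  }
  if (variant == "ratio_derivative") h <- chk_pos(h, "h")
  if (variant == "zero_order_integral") y_set <- chk_pos(y_set, "y_set")
  structure(list(variant = variant, z_c = z_c, h = h, y_set = y_set),
            class = "regulation_spec")
}

#' Evaluate the burst-frequency multiplier at a state
#'
#' Total on the non-negative orthant. For `ratio_derivative` the propensity
#' \eqn{(z/y)^h} is undefined at `y = 0`; the simulator convention
#' \eqn{(z/\max(y, 1))^h} is used so that propensities stay finite (invisible
#' in the small-noise regime where the analysis holds).
#'
#' @param reg A [regulation_spec()].
#' @param y,z Molecule counts (non-negative).
#' @return Non-negative multiplier.
#' @export
regulation_value <- function(reg, y = 0, z = 0) {
  stopifnot(inherits(reg, "regulation_spec"), y >= 0, z >= 0)
  switch(reg$variant,
    open_loop = rep(1, length(z)),
    hill_repression = ,
    zero_order_integral = 1 / (1 + (z / reg$z_c)^reg$h),
    ratio_derivative = (z / pmax(y, 1))^reg$h
  )
}

# derivative of the Hill repression g(z) (analytic, used by the Newton
# polish and the feedback gain)
hill_g <- function(reg, z) 1 / (1 + (z / reg$z_c)^reg$h)
hill_gprime <- function(reg, z) {
  u <- (z / reg$z_c)^reg$h
  -reg$h * u / (z * (1 + u)^2)
}

#' Circuit models
#'
#' A `circuit_model` fully specifies the disturbance species X, the target
#' protein Y, the controller species Z (absent in open loop), and the
#' feedback topology. Constructors:
#'
#' * `circuit_open()`: no controller; Y bursts at \eqn{k_y x/\bar{x}}.
#' * `circuit_proportional()`: noisy sensor Z with birth frequency
#'   \eqn{k_z y} (burst size \eqn{B_z}) and first-order decay; Y bursts at
#'   \eqn{k_y g(z) x/\bar{x}} with Hill repression g.
#' * `circuit_integral()`: integrator Z with birth frequency
#'   \eqn{k_z y/\langle B_z\rangle} (burst size \eqn{B_z}) and zero-order
#'   decay at constant propensity \eqn{k_z y_{set}} (suppressed at z = 0 to
#'   keep counts non-negative); Y bursts as in the proportional circuit. The
#'   net drift of z is \eqn{k_z (y - y_{set})}: a stochastic integrator of
#'   the set-point error. `design = "autocatalytic"` selects the alternative
#'   self-activating integrator (analysis only; see [cv2_integral()]).
#' * `circuit_derivative()`: sensor Z as in the proportional circuit, but Y
#'   bursts at \eqn{k_y (x/\bar{x}) (z/y)^h}: delayed activation by Z plus
#'   self-repression, an incoherent feedforward loop acting as an approximate
#'   derivative controller.
#'
#' @param disturbance A [disturbance_spec()] (default: none).
#' @param target A [species_params()] for Y.
#' @param sensor A [species_params()] for Z. For the integral topology
#'   `sensor$gamma` is unused by the reaction scheme (decay is zero-order);
#'   it is retained only as a nominal timescale.
#' @param regulation A [regulation_spec()] of the matching variant.
#' @param design Integrator realization, `"zero_order"` (default, simulable)
#'   or `"autocatalytic"` (moment analysis and closed forms only).
#' @return An object of class `circuit_model` with fields `topology`,
#'   `disturbance`, `target`, `sensor`, `regulation`.
#' @name circuit_model
NULL

new_circuit <- function(topology, disturbance, target, sensor, regulation,
                        design = NULL) {
  stopifnot(inherits(disturbance, "disturbance_spec"),
            inherits(target, "species_params"),
            is.null(sensor) || inherits(sensor, "species_params"),
            inherits(regulation, "regulation_spec"))
  structure(list(topology = topology, disturbance = disturbance,
                 target = target, sensor = sensor, regulation = regulation,
                 design = design),
            class = "circuit_model")
}

#' @rdname circuit_model
#' @export
circuit_open <- function(target, disturbance = disturbance_spec("none")) {
  new_circuit("open", disturbance, target, NULL, regulation_spec("open_loop"))
}

#' @rdname circuit_model
#' @export
circuit_proportional <- function(target, sensor, regulation,
                                 disturbance = disturbance_spec("none")) {
  if (regulation$variant != "hill_repression")
    stop("proportional circuits use `hill_repression` regulation", call. = FALSE)
  new_circuit("proportional", disturbance, target, sensor, regulation)
}

#' @rdname circuit_model
#' @export
circuit_integral <- function(target, sensor, regulation,
                             disturbance = disturbance_spec("none"),
                             design = c("zero_order", "autocatalytic")) {
  design <- match.arg(design)
  if (regulation$variant != "zero_order_integral")
    stop("integral circuits use `zero_order_integral` regulation", call. = FALSE)
  new_circuit("integral", disturbance, target, sensor, regulation, design)
}

#' @rdname circuit_model
#' @export
circuit_derivative <- function(target, sensor, regulation,
                               disturbance = disturbance_spec("none")) {
  if (regulation$variant != "ratio_derivative")
    stop("derivative circuits use `ratio_derivative` regulation", call. = FALSE)
  new_circuit("derivative", disturbance, target, sensor, regulation)
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("<circuit_model> topology: %s\n", x$topology))
  bm <- function(sp) sprintf("k=%g, gamma=%g, <B>=%g (%s)",
                             sp$k, sp$gamma, sp$burst$mean_size, sp$burst$kind)
  cat("  target Y:", bm(x$target), "\n")
  if (!is.null(x$sensor)) cat("  sensor Z:", bm(x$sensor), "\n")
  if (x$disturbance$mode == "bursty") {
    cat("  disturbance X:", bm(x$disturbance$params), "\n")
  } else {
    cat(sprintf("  disturbance: none (x = %g constant)\n", x$disturbance$xbar))
  }
  r <- x$regulation
  cat(sprintf("  regulation: %s%s\n", r$variant,
              switch(r$variant,
                     open_loop = "",
                     ratio_derivative = sprintf(" (h=%g)", r$h),
                     sprintf(" (z_c=%g, h=%g%s)", r$z_c, r$h,
                             if (is.null(r$y_set)) "" else
                               sprintf(", y_set=%g", r$y_set)))))
  invisible(x)
}

#' Deterministic steady-state means
#'
#' Solves the stationary mean equations for the circuit:
#' open loop \eqn{\bar{y} = k_y\langle B_y\rangle/\gamma_y}; proportional
#' \eqn{\bar{y}} is the unique root of
#' \eqn{k_y\, g(k_z\langle B_z\rangle \bar{y}/\gamma_z)\,\langle B_y\rangle = \gamma_y \bar{y}}
#' (bracketed on \eqn{[0, k_y\langle B_y\rangle/\gamma_y]} since
#' \eqn{g \le 1}, then Newton-polished to ~1e-14 relative); integral
#' \eqn{\bar{y} = y_{set}} with \eqn{\bar{z}} given by inverting the Hill
#' repression; derivative
#' \eqn{\bar{y} = (k_y\langle B_y\rangle/\gamma_y)(k_z\langle B_z\rangle/\gamma_z)^h}.
#'
#' @param circuit A [circuit_model()].
#' @return Object of class `steady_means`: list with `xbar`, `ybar`, `zbar`
#'   (NA when the species is absent).
#' @export
solve_steady_means <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_model"))
  tg <- circuit$target
  by1 <- burst_moments(tg$burst)[["m1"]]
  xbar <- circuit$disturbance$xbar
  y_open <- tg$k * by1 / tg$gamma
  reg <- circuit$regulation

  out <- switch(circuit$topology,
    open = list(ybar = y_open, zbar = NA_real_),
    proportional = {
      sn <- circuit$sensor
      cc <- sn$k * burst_moments(sn$burst)[["m1"]] / sn$gamma  # zbar = cc*ybar
      if (cc == 0) return(structure(list(xbar = xbar, ybar = y_open, zbar = 0),
                                    class = "steady_means"))
      f <- function(y) tg$k * hill_g(reg, cc * y) * by1 - tg$gamma * y
      # f(0) > 0, f(y_open) <= 0: guaranteed bracket
      root <- stats::uniroot(f, c(0, y_open), tol = 1e-12 * y_open)$root
      # Newton polish with analytic derivative
      for (i in 1:4) {
        fp <- tg$k * by1 * hill_gprime(reg, cc * root) * cc - tg$gamma
        step <- f(root) / fp
        root <- root - step
        if (abs(step) < 1e-15 * root) break
      }
      list(ybar = root, zbar = cc * root)
    },
    integral = {
      v <- tg$gamma * reg$y_set / (tg$k * by1)  # required g(zbar)
      if (v >= 1)
        stop("set point unreachable: y_set must be below the open-loop mean ",
             "k_y<B_y>/gamma_y", call. = FALSE)
      zbar <- reg$z_c * ((1 - v) / v)^(1 / reg$h)
      list(ybar = reg$y_set, zbar = zbar)
    },
    derivative = {
      sn <- circuit$sensor
      ratio <- sn$k * burst_moments(sn$burst)[["m1"]] / sn$gamma
      ybar <- y_open * ratio^reg$h
      list(ybar = ybar, zbar = ratio * ybar)
    }
  )
  structure(list(xbar = xbar, ybar = out$ybar, zbar = out$zbar),
            class = "steady_means")
}

#' @export
print.steady_means <- function(x, ...) {
  cat(sprintf("<steady_means> xbar=%g, ybar=%g, zbar=%s\n",
              x$xbar, x$ybar,
              if (is.na(x$zbar)) "-" else format(x$zbar)))
  invisible(x)
}

#' Feedback gain of a circuit
#'
#' The dimensionless feedback strength entering the linearized burst
#' frequency: for Hill repression (proportional and integral controllers) the
#' log sensitivity
#' \eqn{f = -\bar{z} g'(\bar{z})/g(\bar{z}) = h\,(1 - 1/(1 + (\bar{z}/z_c)^h))},
#' bounded strictly below the Hill coefficient for finite \eqn{\bar{z}};
#' for the derivative controller \eqn{f_d = h\,\gamma_y/\gamma_z}. Open loop
#' has gain 0.
#'
#' @param circuit A [circuit_model()].
#' @param means Optional [solve_steady_means()] result (recomputed if missing).
#' @return Non-negative scalar gain.
#' @export
feedback_gain <- function(circuit, means = solve_steady_means(circuit)) {
  stopifnot(inherits(circuit, "circuit_model"))
  reg <- circuit$regulation
  switch(circuit$topology,
    open = 0,
    proportional = ,
    integral = reg$h * (1 - hill_g(reg, means$zbar)),
    derivative = reg$h * circuit$target$gamma / circuit$sensor$gamma
  )
}

#' Static input-output sensitivity
#'
#' The normalized sensitivity of the closed-loop steady-state mean to the
#' environmental input rate \eqn{k_y}:
#' \eqn{S = (k_y/\bar{y})\, d\bar{y}/d k_y}, computed by a centered finite
#' difference of \eqn{\log \bar{y}} over two [solve_steady_means()] calls at
#' \eqn{k_y(1 \pm \epsilon)}. Analytically S equals 1 for the open-loop and
#' derivative circuits, \eqn{1/(1+f_p)} for proportional feedback, and 0 for
#' integral feedback (perfect adaptation).
#'
#' @param circuit A [circuit_model()].
#' @param rel_step Relative finite-difference step \eqn{\epsilon}.
#' @return Scalar sensitivity.
#' @export
static_sensitivity <- function(circuit, rel_step = 1e-4) {
  stopifnot(inherits(circuit, "circuit_model"))
  perturb <- function(fac) {
    c2 <- circuit
    c2$target$k <- circuit$target$k * fac
    solve_steady_means(c2)$ybar
  }
  yp <- perturb(1 + rel_step)
  ym <- perturb(1 - rel_step)
  (log(yp) - log(ym)) / (log(1 + rel_step) - log(1 - rel_step))
}

#' Noise inputs implied by a circuit
#'
#' Collects the quantities the closed-form noise expressions take as inputs:
#' intrinsic noise \eqn{CV^2_{int} = (\langle B_y\rangle + \langle B_y^2\rangle)/(2\langle B_y\rangle\bar{y})},
#' disturbance noise \eqn{CV^2_X} (0 when the disturbance is frozen),
#' controller noise \eqn{CV^2_Z = (\langle B_z\rangle + \langle B_z^2\rangle)/(2\langle B_z\rangle\bar{z})},
#' the decay rates, \eqn{k_z}, the feedback gain, and the means.
#'
#' @param circuit A [circuit_model()].
#' @param means Optional precomputed [solve_steady_means()] result.
#' @return Object of class `noise_inputs` (a named list).
#' @export
noise_inputs <- function(circuit, means = solve_steady_means(circuit)) {
  stopifnot(inherits(circuit, "circuit_model"))
  cv2_of <- function(burst, mean_level) {
    m <- burst_moments(burst)
    (m[["m1"]] + m[["m2"]]) / (2 * m[["m1"]] * mean_level)
  }
  d <- circuit$disturbance
  inp <- list(
    cv2_int = cv2_of(circuit$target$burst, means$ybar),
    cv2_x = if (d$mode == "bursty") cv2_of(d$params$burst, means$xbar) else 0,
    cv2_z = if (!is.null(circuit$sensor)) cv2_of(circuit$sensor$burst, means$zbar) else 0,
    gamma_x = if (d$mode == "bursty") d$params$gamma else Inf,
    gamma_y = circuit$target$gamma,
    gamma_z = if (!is.null(circuit$sensor)) circuit$sensor$gamma else NA_real_,
    k_z = if (!is.null(circuit$sensor)) circuit$sensor$k else NA_real_,
    gain = feedback_gain(circuit, means),
    ybar = means$ybar,
    zbar = means$zbar
  )
  structure(inp, class = "noise_inputs")
}
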