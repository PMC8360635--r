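#' Closed-form stationary noise: open loop
#'
#' \deqn{CV^2_Y = CV^2_{int} + \frac{\gamma_y}{\gamma_y + \gamma_x} CV^2_X.}
#' The ratio \eqn{\gamma_y/(\gamma_y+\gamma_x)} quantifies time-averaging of
#' the upstream fluctuations: it vanishes for fast disturbances
#' (\eqn{\gamma_x \to \infty}) and approaches 1 for slow ones.
#'
#' @param inputs A [noise_inputs()] object or named list with the fields used
#'   by the formula (`cv2_int`, `cv2_x`, `gamma_x`, `gamma_y`, and for the
#'   feedback forms `gamma_z`, `cv2_z`, `gain`, `k_z`, `ybar`, `zbar`).
#' @return A [noise_decomposition()].
#' @export
cv2_open_loop <- function(inputs) {
  i <- as_noise_inputs(inputs)
  ext <- if (i$cv2_x > 0) i$gamma_y / (i$gamma_y + i$gamma_x) * i$cv2_x else 0
  noise_decomposition(intrinsic = i$cv2_int, external = ext, controller = 0)
}

#' Closed-form stationary noise: proportional controller
#'
#' Three-component decomposition at feedback gain \eqn{f_p}:
#' \deqn{CV^2_Y =
#'  \frac{\gamma_y + f_p\gamma_y + \gamma_z}{(f_p+1)(\gamma_y+\gamma_z)} CV^2_{int}
#'  + \frac{\gamma_y\left((\gamma_z+\gamma_y)(\gamma_x+\gamma_z) + \gamma_x\gamma_y f_p\right)}
#'         {(1+f_p)(\gamma_y+\gamma_z)\left((\gamma_x+\gamma_y)(\gamma_x+\gamma_z) + \gamma_y\gamma_z f_p\right)} CV^2_X
#'  + \frac{f_p^2\,\gamma_y}{(f_p+1)(\gamma_y+\gamma_z)} CV^2_Z.}
#' At \eqn{f_p = 0} this reduces to the open-loop split; as
#' \eqn{f_p \to \infty} the intrinsic part approaches the floor
#' \eqn{\gamma_y CV^2_{int}/(\gamma_y+\gamma_z)}, the external part vanishes,
#' and the sensor part grows without bound.
#'
#' @inheritParams cv2_open_loop
#' @export
cv2_proportional <- function(inputs) {
  i <- as_noise_inputs(inputs)
  f <- i$gain; gy <- i$gamma_y; gz <- i$gamma_z; gx <- i$gamma_x
  intr <- (gy + f * gy + gz) / ((f + 1) * (gy + gz)) * i$cv2_int
  ext <- if (i$cv2_x > 0) {
    gy * ((gz + gy) * (gx + gz) + gx * gy * f) /
      ((1 + f) * (gy + gz) * ((gx + gy) * (gx + gz) + gy * gz * f)) * i$cv2_x
  } else 0
  ctrl <- f^2 * gy / ((f + 1) * (gy + gz)) * i$cv2_z
  noise_decomposition(intr, ext, ctrl)
}

#' Closed-form stationary noise: proportional controller, fast-sensor limit
#'
#' Limit \eqn{\gamma_z \gg \gamma_y} (fast sensor) and
#' \eqn{\gamma_x \ll \gamma_y} (slow disturbance):
#' \deqn{CV^2_Y = \frac{CV^2_{int}}{1+f_p} + \frac{CV^2_X}{(1+f_p)^2}
#'  + \frac{f_p^2\,\gamma_y}{(f_p+1)\gamma_z} CV^2_Z.}
#' The external part decays as \eqn{1/f_p^2} against \eqn{1/f_p} for the
#' intrinsic part: proportional feedback buffers upstream disturbances more
#' effectively than shot noise.
#'
#' @inheritParams cv2_open_loop
#' @export
cv2_proportional_fast_sensor <- function(inputs) {
  i <- as_noise_inputs(inputs)
  f <- i$gain
  noise_decomposition(
    intrinsic = i$cv2_int / (1 + f),
    external = i$cv2_x / (1 + f)^2,
    controller = f^2 * i$gamma_y * i$cv2_z / ((f + 1) * i$gamma_z))
}

#' Optimal proportional gain in the strong-feedback regime
#'
#' Minimizes the fast-sensor noise over \eqn{f_p \gg 1}. Derived by elementary
#' calculus from the two-term asymptote of the fast-sensor expression:
#' * `external_only` (\eqn{CV^2_{int} = 0}): minimize
#'   \eqn{CV^2_X/f^2 + f\gamma_y CV^2_Z/\gamma_z}, giving
#'   \eqn{f_p = (2 CV^2_X \gamma_z/(CV^2_Z\gamma_y))^{1/3}} and minimum
#'   \eqn{3\,(CV_X CV^2_Z \gamma_y/(2\gamma_z))^{2/3}}; the minimal noise
#'   scales as \eqn{CV_X^{2/3}}.
#' * `intrinsic_only` (\eqn{CV^2_X = 0}): minimize
#'   \eqn{CV^2_{int}/f + f\gamma_y CV^2_Z/\gamma_z}, giving
#'   \eqn{f_p = (CV_{int}/CV_Z)\sqrt{\gamma_z/\gamma_y}} and minimum
#'   \eqn{2\, CV_{int} CV_Z \sqrt{\gamma_y/\gamma_z}}.
#'
#' @inheritParams cv2_open_loop
#' @param mode Which noise source is present besides the sensor.
#' @return List with `gain` and `min_cv2`.
#' @export
optimal_gain_proportional <- function(inputs,
                                      mode = c("external_only",
                                               "intrinsic_only")) {
  i <- as_noise_inputs(inputs)
  mode <- match.arg(mode)
  if (i$cv2_z <= 0)
    stop("no interior minimum: sensor noise cv2_z must be positive",
         call. = FALSE)
  r <- i$gamma_z / i$gamma_y
  if (mode == "external_only") {
    gain <- (2 * i$cv2_x * r / i$cv2_z)^(1 / 3)
    min_cv2 <- 3 * (sqrt(i$cv2_x) * i$cv2_z / (2 * r))^(2 / 3)
  } else {
    gain <- sqrt(i$cv2_int / i$cv2_z * r)
    min_cv2 <- 2 * sqrt(i$cv2_int * i$cv2_z / r)
  }
  list(gain = gain, min_cv2 = min_cv2)
}

#' Noise floor in units of burst events
#'
#' The minimal achievable proportional-feedback noise without external
#' disturbance, rewritten for geometric bursts in terms of the average number
#' of burst events per target lifetime \eqn{1/\gamma_y}:
#' \deqn{CV^2_Y = 2\sqrt{\frac{1}{N_y N_z}}, \quad
#'  N_y = \bar{y}/\langle B_y\rangle,\;
#'  N_z = \gamma_z\bar{z}/(\gamma_y\langle B_z\rangle).}
#' The floor decays as the square root of the number of burst events of both
#' the target and the controller gene.
#'
#' @param ybar,zbar Stationary means (molecules).
#' @param by_mean,bz_mean Mean burst sizes.
#' @param gamma_y,gamma_z Decay rates (1/time).
#' @return Dimensionless CV2 floor.
#' @export
noise_floor_burst_events <- function(ybar, by_mean, zbar, bz_mean,
                                     gamma_y, gamma_z) {
  n_y <- ybar / by_mean
  n_z <- gamma_z * zbar / (gamma_y * bz_mean)
  2 * sqrt(1 / (n_y * n_z))
}

#' Closed-form stationary noise: integral controller
#'
#' Zero-order-decay integrator design (`"zero_order"`, gain \eqn{f_i}):
#' \deqn{CV^2_Y =
#'  \frac{\bar{z}\gamma_x\gamma_y}{\bar{y} f_i k_z \gamma_y + \bar{z}(\gamma_y\gamma_x + \gamma_x^2)} CV^2_X
#'  + f_i\, CV^2_Z + CV^2_{int}.}
#' The intrinsic part is untouched by integral feedback; the integrator part
#' grows linearly in \eqn{f_i}; the external part is non-monotone in the
#' disturbance timescale \eqn{\gamma_x} (see
#' [integral_peak_disturbance_rate()]). The `"autocatalytic"` design (Z
#' self-activation, first-order removal of Z by Y) differs only in
#' proportionality constants of the external term:
#' \deqn{\frac{\gamma_x\gamma_y}{\bar{y} f_i k_z \gamma_y + \gamma_y\gamma_x + \gamma_x^2} CV^2_X}
#' (there \eqn{k_z} carries units 1/(molecules x time)).
#'
#' @inheritParams cv2_open_loop
#' @param design Integrator realization.
#' @export
cv2_integral <- function(inputs, design = c("zero_order", "autocatalytic")) {
  i <- as_noise_inputs(inputs)
  design <- match.arg(design)
  f <- i$gain; gy <- i$gamma_y; gx <- i$gamma_x
  ext <- if (i$cv2_x > 0) {
    if (design == "zero_order") {
      i$zbar * gx * gy /
        (i$ybar * f * i$k_z * gy + i$zbar * (gy * gx + gx^2)) * i$cv2_x
    } else {
      gx * gy / (i$ybar * f * i$k_z * gy + gy * gx + gx^2) * i$cv2_x
    }
  } else 0
  noise_decomposition(intrinsic = i$cv2_int, external = ext,
                      controller = f * i$cv2_z)
}

#' Disturbance timescale of peak noise transmission under integral feedback
#'
#' The external component of the integral-feedback noise is maximal at
#' \deqn{\gamma_x = \sqrt{k_z f_i \bar{y}\gamma_y/\bar{z}},}
#' the exact argmax over \eqn{\gamma_x} of the external term (obtained by
#' differentiating \eqn{\gamma_x/(c + \bar{z}(\gamma_y\gamma_x+\gamma_x^2))}
#' with \eqn{c = \bar{y} f_i k_z \gamma_y}). Integral feedback rejects slow
#' disturbances (adaptation) and time-averages fast ones, so transmission
#' peaks at an intermediate frequency.
#'
#' @inheritParams cv2_open_loop
#' @return Rate (1/time).
#' @export
integral_peak_disturbance_rate <- function(inputs) {
  i <- as_noise_inputs(inputs)
  if (i$gain <= 0) return(0)
  sqrt(i$k_z * i$gain * i$ybar * i$gamma_y / i$zbar)
}

#' Optimal integral gain for slow disturbances
#'
#' In the slow-disturbance limit \eqn{\gamma_x \to 0} the noise reduces to
#' \deqn{CV^2_Y = \frac{\bar{z}\gamma_x}{\bar{y} f_i k_z} CV^2_X
#'   + f_i CV^2_Z + CV^2_{int},}
#' minimized (elementary calculus) at
#' \eqn{f_i = (CV_X/CV_Z)\sqrt{\bar{z}\gamma_x/(\bar{y}k_z)}} with minimum
#' \deqn{CV^2_Y = 2\sqrt{\bar{z}\gamma_x/(\bar{y}k_z)}\; CV_X CV_Z + CV^2_{int}.}
#' The minimal excess noise is linear in \eqn{CV_X} and can be made
#' arbitrarily small by increasing \eqn{k_z}.
#'
#' @inheritParams cv2_open_loop
#' @return List with `gain` and `min_cv2` (total, including the intrinsic
#'   part).
#' @export
optimal_gain_integral <- function(inputs) {
  i <- as_noise_inputs(inputs)
  if (i$cv2_z <= 0)
    stop("no interior minimum: integrator noise cv2_z must be positive",
         call. = FALSE)
  s <- sqrt(i$zbar * i$gamma_x / (i$ybar * i$k_z))
  list(gain = sqrt(i$cv2_x / i$cv2_z) * s,
       min_cv2 = 2 * s * sqrt(i$cv2_x * i$cv2_z) + i$cv2_int)
}

#' Closed-form stationary noise: derivative controller
#'
#' Incoherent-feedforward derivative controller at gain
#' \eqn{f_d = h\gamma_y/\gamma_z}:
#' \deqn{CV^2_Y =
#'  \frac{\gamma_y+\gamma_z}{\gamma_y + \gamma_z f_d + \gamma_z} CV^2_{int}
#'  + \frac{\gamma_y\left(\gamma_y(\gamma_x+\gamma_z) + \gamma_z(\gamma_x+\gamma_z+\gamma_z f_d)\right)}
#'         {(\gamma_y+\gamma_z f_d+\gamma_z)\left(\gamma_y(\gamma_x+\gamma_z) + \gamma_x(\gamma_x+\gamma_z f_d+\gamma_z)\right)} CV^2_X
#'  + \frac{f_d^2 \gamma_z^2}{\gamma_y(\gamma_y+\gamma_z f_d+\gamma_z)} CV^2_Z.}
#' At \eqn{f_d = 0} the open-loop split is recovered. For slow disturbances
#' (\eqn{\gamma_x \ll \gamma_y, \gamma_z}) the external part tends to
#' \eqn{CV^2_X} independently of \eqn{f_d}: derivative control cannot reject
#' low-frequency disturbances.
#'
#' @inheritParams cv2_open_loop
#' @export
cv2_derivative <- function(inputs) {
  i <- as_noise_inputs(inputs)
  f <- i$gain; gy <- i$gamma_y; gz <- i$gamma_z; gx <- i$gamma_x
  den <- gy + gz * f + gz
  intr <- (gy + gz) / den * i$cv2_int
  ext <- if (i$cv2_x > 0) {
    gy * (gy * (gx + gz) + gz * (gx + gz + gz * f)) /
      (den * (gy * (gx + gz) + gx * (gx + gz * f + gz))) * i$cv2_x
  } else 0
  ctrl <- f^2 * gz^2 / (gy * den) * i$cv2_z
  noise_decomposition(intr, ext, ctrl)
}

# coerce/validate plain lists into noise inputs; pure functions over this
# record keep the formula layer total and property-testable
as_noise_inputs <- function(inputs) {
  if (inherits(inputs, "noise_inputs")) return(inputs)
  stopifnot(is.list(inputs))
  defaults <- list(cv2_int = 0, cv2_x = 0, cv2_z = 0, gamma_x = Inf,
                   gamma_y = NA_real_, gamma_z = NA_real_, k_z = NA_real_,
                   gain = 0, ybar = NA_real_, zbar = NA_real_)
  out <- utils::modifyList(defaults, inputs[names(inputs) %in% names(defaults)])
  with(out, {
    if (cv2_int < 0 || cv2_x < 0 || cv2_z < 0)
      stop("CV2 inputs must be non-negative", call. = FALSE)
    if (gain < 0) stop("`gain` must be non-negative", call. = FALSE)
  })
  structure(out, class = "noise_inputs")
}

#' @export
print.noise_inputs <- function(x, ...) {
  cat("<noise_inputs>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}
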