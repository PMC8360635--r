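#' Linearize the target's burst frequency about the steady means
#'
#' The linear noise approximation replaces the nonlinear burst frequency of Y
#' by its first-order Taylor expansion around the stationary means, written in
#' normalized deviations \eqn{\delta_s = s/\bar{s} - 1}:
#' \deqn{rate(x, y, z) \approx b\,(1 + c_x \delta_x + c_y \delta_y + c_z \delta_z).}
#' The base rate \eqn{b} satisfies \eqn{b\,\langle B_y\rangle = \gamma_y \bar{y}}
#' (stationarity). Coefficients by topology: open loop \eqn{c_x = +1};
#' proportional/integral add \eqn{c_z = -f} with \eqn{f} the log-sensitivity
#' gain; derivative has \eqn{c_x = +1}, \eqn{c_z = +f_d\gamma_z/\gamma_y = h},
#' \eqn{c_y = -h}. When the disturbance is frozen the x coefficient is absent.
#'
#' @param circuit A [circuit_model()].
#' @param means A [solve_steady_means()] result.
#' @return Object of class `linearized_rates`: list with `base_rate` and
#'   named coefficient vector `coeffs` (subset of `x`, `y`, `z`).
#' @export
linearize <- function(circuit, means = solve_steady_means(circuit)) {
  stopifnot(inherits(circuit, "circuit_model"))
  reg <- circuit$regulation
  has_x <- circuit$disturbance$mode == "bursty"
  if (!is.null(circuit$sensor) && (!is.finite(means$zbar) || means$zbar <= 0))
    stop("degenerate linearization: regulating species has zero mean",
         call. = FALSE)
  gain <- feedback_gain(circuit, means)
  co <- if (has_x) c(x = 1) else c()
  base <- switch(circuit$topology,
    open = circuit$target$k,
    proportional = ,
    integral = circuit$target$k * hill_g(reg, means$zbar),
    derivative = circuit$target$k * (means$zbar / means$ybar)^reg$h
  )
  co <- switch(circuit$topology,
    open = co,
    proportional = ,
    # the autocatalytic integrator (dz = kz*z*(ybar - y)) inverts the error
    # sign, so its loop is negative only when Z activates Y: coefficient +f_i
    integral = c(co, z = if (identical(circuit$design, "autocatalytic"))
      gain else -gain),
    derivative = c(co, y = -reg$h, z = reg$h)  # h = f_d * gamma_z / gamma_y
  )
  structure(list(base_rate = base, coeffs = co), class = "linearized_rates")
}

# --- event tables -----------------------------------------------------------
# Each stochastic event is affine in the state after linearization:
#   rate(s) = rate0 + sum_k rc[k] * s_k,
# and changes a single species `sp` by a random jump with first/second moments
# (m1, m2). `shot` = FALSE drops the jump-variance contribution to second
# moments, turning the event into a deterministic drift (used for noise-source
# silencing in decompose_noise()).
circuit_events <- function(circuit, lin, means,
                           silence_x = FALSE, silence_z_shot = FALSE) {
  has_x <- circuit$disturbance$mode == "bursty" && !silence_x
  has_z <- !is.null(circuit$sensor)
  species <- c(if (has_x) "x", "y", if (has_z) "z")
  ev <- list()
  add <- function(rate0, rc, sp, m1, m2, shot = TRUE) {
    ev[[length(ev) + 1L]] <<- list(rate0 = rate0, rc = rc, sp = sp,
                                   m1 = m1, m2 = m2, shot = shot)
  }
  if (has_x) {
    xp <- circuit$disturbance$params
    bx <- burst_moments(xp$burst)
    add(xp$k, c(), "x", bx[["m1"]], bx[["m2"]])
    add(0, c(x = xp$gamma), "x", -1, 1)
  }
  # target bursts: base*(1 + sum c_k (s_k/sbar_k - 1)), with silenced species
  # pinned at their means (deviation identically zero)
  co <- lin$coeffs[names(lin$coeffs) %in% species]
  sbar <- c(x = means$xbar, y = means$ybar, z = means$zbar)
  by <- burst_moments(circuit$target$burst)
  add(lin$base_rate * (1 - sum(co)),
      if (length(co)) lin$base_rate * co / sbar[names(co)] else c(),
      "y", by[["m1"]], by[["m2"]])
  add(0, c(y = circuit$target$gamma), "y", -1, 1)
  if (has_z) {
    sn <- circuit$sensor
    bz <- burst_moments(sn$burst)
    if (circuit$topology %in% c("proportional", "derivative")) {
      add(0, c(y = sn$k), "z", bz[["m1"]], bz[["m2"]], shot = !silence_z_shot)
      add(0, c(z = sn$gamma), "z", -1, 1, shot = !silence_z_shot)
    } else if (identical(circuit$design, "autocatalytic")) {
      # z self-activates in bursts at rate kz*ybar*z/<Bz>; y degrades z with
      # propensity kz*z*y, linearized about the means
      ys <- circuit$regulation$y_set
      add(0, c(z = sn$k * ys / bz[["m1"]]), "z", bz[["m1"]], bz[["m2"]],
          shot = !silence_z_shot)
      add(-sn$k * means$zbar * means$ybar,
          c(y = sn$k * means$zbar, z = sn$k * means$ybar), "z", -1, 1,
          shot = !silence_z_shot)
    } else {
      # zero-order integrator: bursty births at kz*y/<Bz>, constant decay
      add(0, c(y = sn$k / bz[["m1"]]), "z", bz[["m1"]], bz[["m2"]],
          shot = !silence_z_shot)
      add(sn$k * circuit$regulation$y_set, c(), "z", -1, 1,
          shot = !silence_z_shot)
    }
  }
  list(species = species, events = ev)
}

#' Assemble the linear moment dynamics from the infinitesimal generator
#'
#' Builds the exact first- and second-order moment equations
#' \eqn{\dot{\mu} = \hat{a} + A\mu} of the linearized jump process by the
#' generator expansion: every event contributes, for each tracked monomial,
#' (rate) x (expected change of the monomial). With affine rates and
#' single-species jumps the system closes exactly at second order. Moment
#' ordering is means first, then second moments in lexicographic species
#' order.
#'
#' @param circuit A [circuit_model()].
#' @param lin A [linearize()] result.
#' @param means A [solve_steady_means()] result.
#' @param silence_x Freeze the disturbance at its mean (drop x events).
#' @param silence_z_shot Drop the jump variance of controller-species events
#'   (z follows a deterministic flow conditioned on the other species).
#' @return Object of class `moment_system`: list with `labels`, drift vector
#'   `a`, matrix `A`, plus the `species` and `means` used.
#' @export
assemble_moment_system <- function(circuit, lin = linearize(circuit, means),
                                   means = solve_steady_means(circuit),
                                   silence_x = FALSE, silence_z_shot = FALSE) {
  ce <- circuit_events(circuit, lin, means, silence_x, silence_z_shot)
  sp <- ce$species
  n1 <- length(sp)
  pairs <- list()
  for (i in seq_len(n1)) for (j in i:n1)
    pairs[[length(pairs) + 1L]] <- c(sp[i], sp[j])
  labels <- c(sp, vapply(pairs, paste0, "", collapse = ""))
  n <- length(labels)
  idx <- function(a, b = NULL) {
    lab <- if (is.null(b)) a else paste0(sort(c(a, b))[1], sort(c(a, b))[2])
    match(lab, labels)
  }
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  a <- stats::setNames(numeric(n), labels)

  for (e in ce$events) {
    k <- e$sp
    rc <- e$rc
    # d<k>/dt += m1 * <rate>
    a[idx(k)] <- a[idx(k)] + e$m1 * e$rate0
    for (s in names(rc))
      A[idx(k), idx(s)] <- A[idx(k), idx(s)] + e$m1 * rc[[s]]
    # d<k^2>/dt += 2 m1 <rate * k> + shot * m2 * <rate>
    kk <- idx(k, k)
    A[kk, idx(k)] <- A[kk, idx(k)] + 2 * e$m1 * e$rate0
    for (s in names(rc))
      A[kk, idx(s, k)] <- A[kk, idx(s, k)] + 2 * e$m1 * rc[[s]]
    if (e$shot) {
      a[kk] <- a[kk] + e$m2 * e$rate0
      for (s in names(rc))
        A[kk, idx(s)] <- A[kk, idx(s)] + e$m2 * rc[[s]]
    }
    # cross moments d<k o>/dt += m1 <rate * o>
    for (o in setdiff(sp, k)) {
      ko <- idx(k, o)
      A[ko, idx(o)] <- A[ko, idx(o)] + e$m1 * e$rate0
      for (s in names(rc))
        A[ko, idx(s, o)] <- A[ko, idx(s, o)] + e$m1 * rc[[s]]
    }
  }
  structure(list(labels = labels, a = a, A = A, species = sp, means = means),
            class = "moment_system")
}

#' @export
print.moment_system <- function(x, ...) {
  cat(sprintf("<moment_system> %d moments: %s\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Export a moment system as a plain-text matrix dump
#'
#' Writes the moment labels, drift vector and dense dynamics matrix in a
#' stable text layout for debugging and cross-language checks.
#'
#' @param sys A [assemble_moment_system()] result.
#' @param file Path or connection (default: stdout).
#' @export
export_moment_system <- function(sys, file = stdout()) {
  stopifnot(inherits(sys, "moment_system"))
  lines <- c(paste("labels:", paste(sys$labels, collapse = " ")),
             paste("a:", paste(format(sys$a, digits = 17), collapse = " ")),
             "A:",
             apply(sys$A, 1, function(r)
               paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, file)
  invisible(sys)
}

#' Stationary moments of a linear moment system
#'
#' Solves \eqn{A\bar{\mu} = -\hat{a}} after checking that `A` is Hurwitz
#' (all eigenvalues with real part below `-tol` relative to the spectral
#' radius); borderline or unstable systems are rejected. Implied variances
#' must be non-negative beyond round-off.
#'
#' @param sys A [assemble_moment_system()] result.
#' @param tol Relative stability tolerance on eigenvalue real parts.
#' @return Named stationary moment vector.
#' @export
steady_state_moments <- function(sys, tol = 1e-9) {
  stopifnot(inherits(sys, "moment_system"))
  ev <- eigen(sys$A, only.values = TRUE)$values
  lim <- -tol * max(abs(ev))
  if (any(Re(ev) > lim)) {
    stop(sprintf(
      "moment dynamics not Hurwitz: eigenvalue with real part %.3e",
      max(Re(ev))), call. = FALSE)
  }
  mu <- solve(sys$A, -sys$a)
  names(mu) <- sys$labels
  for (s in sys$species) {
    v <- mu[paste0(s, s)] - mu[s]^2
    scale <- max(mu[paste0(s, s)], 1)
    if (v < -1e-8 * scale)
      stop(sprintf("negative implied variance for %s: %.3e (conditioning)",
                   s, v), call. = FALSE)
  }
  mu
}

cv2_from_moments <- function(mu, s = "y") {
  (mu[[paste0(s, s)]] - mu[[s]]^2) / mu[[s]]^2
}

#' Decompose the stationary target noise by source silencing
#'
#' Computes the stationary \eqn{CV^2} of Y from three moment solves: (i) the
#' full system; (ii) the disturbance frozen at \eqn{\bar{x}}; (iii)
#' additionally the controller species' jump noise removed (z reduced to a
#' deterministic flow conditioned on the state). Because the stationary
#' covariance is linear in the per-event jump-variance sources, differencing
#' attributes the noise exactly and additively:
#' external = (i)-(ii), controller = (ii)-(iii), intrinsic = (iii).
#'
#' @param circuit A [circuit_model()].
#' @return Object of class `noise_decomposition`: list with `intrinsic`,
#'   `external`, `controller`, `total`.
#' @export
decompose_noise <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_model"))
  means <- solve_steady_means(circuit)
  lin <- linearize(circuit, means)
  solve_cv2 <- function(...) {
    sys <- assemble_moment_system(circuit, lin, means, ...)
    cv2_from_moments(steady_state_moments(sys))
  }
  total <- solve_cv2()
  no_x <- if (circuit$disturbance$mode == "bursty")
    solve_cv2(silence_x = TRUE) else total
  intrinsic <- if (!is.null(circuit$sensor))
    solve_cv2(silence_x = TRUE, silence_z_shot = TRUE) else no_x
  noise_decomposition(intrinsic = intrinsic,
                      external = total - no_x,
                      controller = no_x - intrinsic)
}

#' Construct a noise decomposition
#'
#' Container for the additive split of the stationary target noise
#' \eqn{CV^2_Y} into intrinsic (bursty expression of Y), external
#' (upstream disturbance) and controller (sensor/integrator expression)
#' components; `total` is their sum.
#'
#' @param intrinsic,external,controller Non-negative CV2 components.
#' @return Object of class `noise_decomposition`.
#' @export
noise_decomposition <- function(intrinsic, external, controller) {
  structure(list(intrinsic = as.numeric(intrinsic),
                 external = as.numeric(external),
                 controller = as.numeric(controller),
                 total = as.numeric(intrinsic + external + controller)),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("<noise_decomposition> CV2 of Y\n")
  cat(sprintf("  intrinsic:  %.6g\n  external:   %.6g\n  controller: %.6g\n  total:      %.6g\n",
              x$intrinsic, x$external, x$controller, x$total))
  invisible(x)
}
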