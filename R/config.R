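#' Read and write circuit definitions as YAML
#'
#' Circuits are serialized as a structured config with keys `topology`,
#' `disturbance`, `target`, `sensor`, `regulation` (plus `design` for the
#' integral topology). Species entries have `k`, `gamma` and
#' `burst: {kind, mean}`; the disturbance has `mode: none` with `xbar`, or
#' `mode: bursty` with the species fields.
#'
#' @param path File path (`read_circuit` also accepts an already-parsed list).
#' @return `read_circuit()` returns a [circuit_model()];
#'   `write_circuit()` invisibly returns `path`.
#' @export
read_circuit <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  need <- function(x, nm) {
    if (is.null(x[[nm]])) stop("circuit config missing field `", nm, "`",
                               call. = FALSE)
    x[[nm]]
  }
  parse_species <- function(s) {
    b <- need(s, "burst")
    species_params(need(s, "k"), need(s, "gamma"),
                   burst_dist(need(b, "kind"), need(b, "mean")))
  }
  d <- need(cfg, "disturbance")
  dist <- if (identical(d$mode, "bursty")) {
    disturbance_spec("bursty", params = parse_species(d))
  } else {
    disturbance_spec("none", xbar = d$xbar %||% 1)
  }
  target <- parse_species(need(cfg, "target"))
  topo <- need(cfg, "topology")
  r <- cfg$regulation
  switch(topo,
    open = circuit_open(target, dist),
    proportional = circuit_proportional(
      target, parse_species(need(cfg, "sensor")),
      regulation_spec("hill_repression", z_c = need(r, "z_c"),
                      h = need(r, "h")), dist),
    integral = circuit_integral(
      target, parse_species(need(cfg, "sensor")),
      regulation_spec("zero_order_integral", z_c = need(r, "z_c"),
                      h = need(r, "h"), y_set = need(r, "y_set")),
      dist, design = cfg$design %||% "zero_order"),
    derivative = circuit_derivative(
      target, parse_species(need(cfg, "sensor")),
      regulation_spec("ratio_derivative", h = need(r, "h")), dist),
    stop("unknown topology `", topo, "`", call. = FALSE)
  )
}

#' @rdname read_circuit
#' @param circuit A [circuit_model()] to serialize.
#' @export
write_circuit <- function(circuit, path) {
  stopifnot(inherits(circuit, "circuit_model"))
  sp_list <- function(sp) list(k = sp$k, gamma = sp$gamma,
                               burst = list(kind = sp$burst$kind,
                                            mean = sp$burst$mean_size))
  d <- circuit$disturbance
  cfg <- list(
    topology = circuit$topology,
    disturbance = if (d$mode == "bursty") c(list(mode = "bursty"),
                                            sp_list(d$params))
                  else list(mode = "none", xbar = d$xbar),
    target = sp_list(circuit$target))
  if (!is.null(circuit$sensor)) cfg$sensor <- sp_list(circuit$sensor)
  r <- circuit$regulation
  cfg$regulation <- Filter(Negate(is.null),
                           list(variant = r$variant, z_c = r$z_c, h = r$h,
                                y_set = r$y_set))
  if (!is.null(circuit$design)) cfg$design <- circuit$design
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' Bundled figure-caption parameter sets
#'
#' Named circuit fixtures encoding the printed parameter sets of the noise
#' figures: `"fig2b"` (proportional controller working point with
#' \eqn{CV^2_Z = 0.4}, \eqn{CV^2_{int} = CV^2_X = 0.2},
#' \eqn{\gamma_z = 5\gamma_y = 15\gamma_x}), `"fig3b"` (integral controller,
#' \eqn{CV^2_X = 0.5}, \eqn{k_z = \gamma_y}, \eqn{\bar{z}/\bar{y} = 1},
#' \eqn{\gamma_y = 3\gamma_x}, \eqn{CV^2_{int} = 0.2}), `"fig4b"` (derivative
#' controller, \eqn{CV^2_{int} = 0.25}, \eqn{CV^2_Z = 0.1},
#' \eqn{CV^2_X = 0.7}, \eqn{\gamma_z = 3\gamma_y}), and `"fig5"` (derivative
#' validation circuit: \eqn{k_y = 2}, \eqn{\gamma_y = 0.2},
#' \eqn{\langle B_y\rangle = 20}, \eqn{\langle B_z\rangle = 1},
#' \eqn{k_z = \gamma_z}, \eqn{h = 1}, no external disturbance).
#'
#' @param name Fixture name.
#' @return A [circuit_model()] for `fixture_circuit()`; a character vector of
#'   available names for `list_fixtures()`.
#' @export
fixture_circuit <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "pidnoise")
  if (!nzchar(path))
    stop("unknown fixture `", name, "`; see list_fixtures()", call. = FALSE)
  read_circuit(path)
}

#' @rdname fixture_circuit
#' @export
list_fixtures <- function() {
  sub("\\.yaml$", "",
      dir(system.file("extdata", package = "pidnoise"), pattern = "\\.yaml$"))
}
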