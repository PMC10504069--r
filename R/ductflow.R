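#' Channel geometry of one rectangular flow channel
#'
#' Describes a single flow channel of the fluidic plate as a rectangular duct
#' of width `w`, height `h` and length `L`. The device default is one channel
#' of the 96-well plate: 6.0 mm wide, 0.5 mm high and 125.77 mm long, treated
#' as fully developed flow over its whole length (the short inlet/outlet
#' narrowings are not modelled).
#'
#' @param width_m channel width w in metres (transverse, along which the
#'   shear profile varies slowly).
#' @param height_m channel height h in metres (the small dimension; cells sit
#'   on the bottom wall z = 0).
#' @param length_m channel length L in metres, used for the pressure drop.
#' @return an object of class `channel_geometry`.
#' @examples
#' channel_geometry()            # device default, 6.0 x 0.5 x 125.77 mm
#' channel_geometry(1e-3, 1e-4, 0.02)
#' @export
channel_geometry <- function(width_m = 6.0e-3, height_m = 0.5e-3,
                             length_m = 125.77e-3) {
  stopifnot(is.numeric(width_m), is.numeric(height_m), is.numeric(length_m))
  if (!is.finite(width_m) || width_m <= 0 ||
      !is.finite(height_m) || height_m <= 0 ||
      !is.finite(length_m) || length_m <= 0) {
    stop("invalid channel geometry: width, height and length must be finite and > 0",
         call. = FALSE)
  }
  structure(list(w = width_m, h = height_m, L = length_m),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %.2f x %.2f x %.2f mm (w x h x L), aspect %.1f\n",
              x$w * 1e3, x$h * 1e3, x$L * 1e3, x$w / x$h))
  invisible(x)
}

#' Working-fluid properties
#'
#' Dynamic viscosity and density of the perfusion medium. The default
#' viscosity is 0.75 mPa.s: culture medium at 37 C is slightly less viscous
#' than room-temperature water, and this value makes the plate formula
#' tau = 6 mu Q / (w h^2) reproduce the device operating point of
#' 14 mL/min at 0.7 Pa exactly. Density defaults to water, 1000 kg/m^3.
#'
#' @param viscosity_pas dynamic viscosity mu in Pa.s.
#' @param density_kg_m3 density rho in kg/m^3.
#' @return an object of class `fluid_props`.
#' @export
fluid_props <- function(viscosity_pas = 0.75e-3, density_kg_m3 = 1000) {
  if (!is.finite(viscosity_pas) || viscosity_pas <= 0 ||
      !is.finite(density_kg_m3) || density_kg_m3 <= 0) {
    stop("invalid fluid properties: viscosity and density must be finite and > 0",
         call. = FALSE)
  }
  structure(list(mu = viscosity_pas, rho = density_kg_m3),
            class = "fluid_props")
}

#' @export
print.fluid_props <- function(x, ...) {
  cat(sprintf("<fluid_props> mu = %.3g mPa.s, rho = %g kg/m^3\n",
              x$mu * 1e3, x$rho))
  invisible(x)
}

check_geom <- function(geom) {
  if (!inherits(geom, "channel_geometry"))
    stop("`geom` must be a channel_geometry()", call. = FALSE)
  geom
}
check_fluid <- function(fluid) {
  if (!inherits(fluid, "fluid_props"))
    stop("`fluid` must be a fluid_props()", call. = FALSE)
  fluid
}

#' Bottom-wall shear stress from flow rate (parallel-plate formula)
#'
#' For a wide, shallow channel the fully developed laminar flow is locally
#' plane-Poiseuille and the shear stress on the bottom wall away from the
#' side walls is `tau = 6 mu Q / (w h^2)`. This is the headline design
#' quantity of a parallel-plate flow chamber: at the device geometry and the
#' default medium viscosity, 14 mL/min gives 0.70 Pa (7 dyn/cm^2).
#'
#' @param q_m3_s volumetric flow rate Q in m^3/s (>= 0).
#' @param geom [channel_geometry()].
#' @param fluid [fluid_props()].
#' @return wall shear stress in Pa; linear in both Q and mu.
#' @seealso [shear_to_flowrate()] for the inverse, [wall_shear_profile()] for
#'   the transverse variation the plate formula ignores.
#' @examples
#' plate_wall_shear(ml_min_to_m3_s(14), channel_geometry(), fluid_props())
#' @export
plate_wall_shear <- function(q_m3_s, geom = channel_geometry(),
                             fluid = fluid_props()) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(q_m3_s), all(q_m3_s >= 0))
  6 * fluid$mu * q_m3_s / (geom$w * geom$h^2)
}

#' Flow rate needed for a target wall shear stress
#'
#' Inverts [plate_wall_shear()]: `Q = tau w h^2 / (6 mu)`.
#'
#' @param tau_pa target bottom-wall shear stress in Pa (>= 0).
#' @inheritParams plate_wall_shear
#' @return volumetric flow rate in m^3/s.
#' @export
shear_to_flowrate <- function(tau_pa, geom = channel_geometry(),
                              fluid = fluid_props()) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(tau_pa), all(tau_pa >= 0))
  tau_pa * geom$w * geom$h^2 / (6 * fluid$mu)
}

#' Mean axial velocity
#'
#' `U = Q / (w h)`, the cross-section-averaged axial velocity. At the device
#' operating point (14 mL/min through 6.0 x 0.5 mm) this is 0.0778 m/s.
#'
#' @inheritParams plate_wall_shear
#' @return mean velocity in m/s.
#' @export
mean_velocity <- function(q_m3_s, geom = channel_geometry()) {
  check_geom(geom)
  stopifnot(is.numeric(q_m3_s), all(q_m3_s >= 0))
  q_m3_s / (geom$w * geom$h)
}

#' Reynolds number of the channel flow
#'
#' `Re = rho U D_h / mu` with the hydraulic diameter `D_h = 2 w h / (w + h)`.
#' Values below 2000 are flagged laminar; the device operates around Re ~ 100.
#'
#' @inheritParams plate_wall_shear
#' @return a tibble with columns `reynolds` and `laminar` (Re < 2000).
#' @export
reynolds_number <- function(q_m3_s, geom = channel_geometry(),
                            fluid = fluid_props()) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(q_m3_s), all(q_m3_s >= 0))
  dh <- 2 * geom$w * geom$h / (geom$w + geom$h)
  re <- fluid$rho * mean_velocity(q_m3_s, geom) * dh / fluid$mu
  tibble::tibble(reynolds = re, laminar = re < 2000)
}

# Stable cosh(a)/cosh(b) for 0 <= a <= b (both can be huge).
cosh_ratio <- function(a, b) {
  exp(a - b) * (1 + exp(-2 * a)) / (1 + exp(-2 * b))
}

odd_terms <- function(n_terms) {
  if (!is.numeric(n_terms) || length(n_terms) != 1 || n_terms < 1)
    stop("n_terms must be a positive integer", call. = FALSE)
  seq(1, by = 2, length.out = as.integer(n_terms))
}

#' Axial velocity in a rectangular duct (Fourier-series solution)
#'
#' Evaluates the classical series solution of fully developed laminar flow in
#' a rectangular duct driven by a constant axial pressure gradient G = -dp/dx,
#' with no-slip on all four walls:
#' \deqn{u(y,z) = \frac{4 G h^2}{\pi^3 \mu} \sum_{n\ odd}
#'   \frac{1}{n^3}\left[1 - \frac{\cosh(n\pi (y - w/2)/h)}{\cosh(n\pi w/(2h))}\right]
#'   \sin(n\pi z/h)}
#' Coordinates: y in [0, w] across the width, z in [0, h] across the height.
#'
#' @param y,z positions in metres; recycled against each other elementwise.
#' @param g_pa_m axial pressure gradient G in Pa/m (>= 0).
#' @param n_terms number of odd series terms (default 51; the series
#'   converges like 1/n^3).
#' @inheritParams plate_wall_shear
#' @return axial velocity u(y, z) in m/s.
#' @export
duct_velocity_series <- function(y, z, g_pa_m, geom = channel_geometry(),
                                 fluid = fluid_props(), n_terms = 51) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(y), is.numeric(z), is.numeric(g_pa_m), g_pa_m >= 0)
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  eps <- 1e-12 * max(geom$w, geom$h)
  if (any(y < -eps | y > geom$w + eps | z < -eps | z > geom$h + eps))
    stop("point outside the channel cross-section", call. = FALSE)
  w <- geom$w; h <- geom$h
  ns <- odd_terms(n_terms)
  u <- numeric(n)
  half <- ns * pi * w / (2 * h)
  for (i in seq_along(ns)) {
    k <- ns[i]
    bracket <- 1 - cosh_ratio(abs(y - w / 2) * k * pi / h, half[i])
    u <- u + bracket * sin(k * pi * z / h) / k^3
  }
  4 * g_pa_m * h^2 / (pi^3 * fluid$mu) * u
}

#' Flow rate through a rectangular duct for a given pressure gradient
#'
#' Integrates the series solution over the cross-section:
#' \deqn{Q = \frac{G w h^3}{12 \mu} F(w/h), \quad
#'   F = 1 - \sum_{n\ odd} \frac{192 h}{\pi^5 n^5 w} \tanh\!\left(\frac{n\pi w}{2h}\right)}
#' `F` is the finite-aspect correction factor, strictly between 0 and 1 and
#' tending to 1 (the plane-Poiseuille limit) as w/h grows.
#'
#' @inheritParams duct_velocity_series
#' @return a list with `q_m3_s` and the correction factor `f_aspect`.
#' @export
duct_flowrate <- function(g_pa_m, geom = channel_geometry(),
                          fluid = fluid_props(), n_terms = 51) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(g_pa_m), g_pa_m >= 0)
  w <- geom$w; h <- geom$h
  ns <- odd_terms(n_terms)
  f <- 1 - sum(192 * h / (pi^5 * ns^5 * w) * tanh(ns * pi * w / (2 * h)))
  list(q_m3_s = g_pa_m * w * h^3 / (12 * fluid$mu) * f, f_aspect = f)
}

#' Pressure gradient that drives a given flow rate
#'
#' Inverts [duct_flowrate()] (the relation is linear in G).
#'
#' @inheritParams duct_flowrate
#' @param q_m3_s volumetric flow rate in m^3/s.
#' @return pressure gradient G in Pa/m.
#' @export
flowrate_to_gradient <- function(q_m3_s, geom = channel_geometry(),
                                 fluid = fluid_props(), n_terms = 51) {
  unit <- duct_flowrate(1, geom, fluid, n_terms)$q_m3_s
  q_m3_s / unit
}

#' Bottom-wall shear stress profile across the channel width
#'
#' Differentiates the duct series term-wise in z and evaluates
#' `tau(y) = mu du/dz` on (or near) the bottom wall:
#' \deqn{\tau(y, z) = \frac{4 G h}{\pi^2} \sum_{n\ odd}
#'   \frac{1}{n^2}\left[1 - \frac{\cosh(n\pi (y - w/2)/h)}{\cosh(n\pi w/(2h))}\right]
#'   \cos(n\pi z/h)}
#' The profile is flat over the central part of a high-aspect channel, drops
#' to zero at the side walls, and is symmetric about the midline. `z_eval_m`
#' lets you evaluate mu du/dz at a plane above the wall (e.g. 10 um) instead
#' of at z = 0.
#'
#' @inheritParams duct_velocity_series
#' @param y_m transverse positions in [0, w]; default a 241-point grid.
#' @param z_eval_m evaluation height in [0, h]; 0 (the wall) by default.
#' @return a tibble of class `shear_profile` with columns `y_m`, `tau_pa`,
#'   and attributes `z_eval_m`, `g_pa_m`.
#' @export
wall_shear_profile <- function(g_pa_m, geom = channel_geometry(),
                               fluid = fluid_props(),
                               y_m = seq(0, geom$w, length.out = 241),
                               z_eval_m = 0, n_terms = 51) {
  check_geom(geom); check_fluid(fluid)
  w <- geom$w; h <- geom$h
  if (any(y_m < -1e-15 | y_m > w * (1 + 1e-12)))
    stop("y grid outside [0, w]", call. = FALSE)
  if (z_eval_m < 0 || z_eval_m > h)
    stop("z_eval_m outside [0, h]", call. = FALSE)
  ns <- odd_terms(n_terms)
  half <- ns * pi * w / (2 * h)
  tau <- numeric(length(y_m))
  for (i in seq_along(ns)) {
    k <- ns[i]
    bracket <- 1 - cosh_ratio(abs(y_m - w / 2) * k * pi / h, half[i])
    tau <- tau + bracket * cos(k * pi * z_eval_m / h) / k^2
  }
  out <- tibble::tibble(y_m = y_m, tau_pa = 4 * g_pa_m * h / pi^2 * tau)
  attr(out, "z_eval_m") <- z_eval_m
  attr(out, "g_pa_m") <- g_pa_m
  class(out) <- c("shear_profile", class(out))
  out
}

#' Pressure drop over the channel length
#'
#' `dP = G L`, with G obtained by inverting the duct flow-rate relation.
#' `method = "plate"` uses the parallel-plate gradient `G = 12 mu Q/(w h^3)`
#' (no side-wall correction); `"series"` divides by the aspect factor F and
#' is a few percent larger.
#'
#' @inheritParams plate_wall_shear
#' @param method `"series"` (default) or `"plate"`.
#' @param n_terms series terms for the F factor.
#' @return pressure drop in Pa.
#' @export
pressure_drop <- function(q_m3_s, geom = channel_geometry(),
                          fluid = fluid_props(),
                          method = c("series", "plate"), n_terms = 51) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(q_m3_s), all(q_m3_s >= 0))
  method <- match.arg(method)
  g <- switch(method,
    plate = 12 * fluid$mu * q_m3_s / (geom$w * geom$h^3),
    series = flowrate_to_gradient(q_m3_s, geom, fluid, n_terms))
  g * geom$L
}

#' Operating-point summary for a channel
#'
#' One-call design table: given exactly one of flow rate, mean velocity or
#' target wall shear, derives the rest (plate shear, series centerline shear,
#' pressure drop, Reynolds number). This is the tabular interface to the duct
#' model: pipe the result onward or serialize it as the run report does.
#'
#' @param flow_ml_min,velocity_m_s,shear_dyn_cm2 exactly one must be non-NULL.
#' @inheritParams plate_wall_shear
#' @param n_terms series terms for duct quantities.
#' @return a one-row tibble with columns `q_ml_min`, `u_m_s`, `tau_plate_pa`,
#'   `tau_plate_dyn_cm2`, `tau_center_pa`, `dp_pa`, `reynolds`, `laminar`.
#' @examples
#' flow_design(flow_ml_min = 14)
#' @export
flow_design <- function(flow_ml_min = NULL, velocity_m_s = NULL,
                        shear_dyn_cm2 = NULL, geom = channel_geometry(),
                        fluid = fluid_props(), n_terms = 51) {
  given <- !c(is.null(flow_ml_min), is.null(velocity_m_s), is.null(shear_dyn_cm2))
  if (sum(given) != 1)
    stop("specify exactly one of flow_ml_min, velocity_m_s, shear_dyn_cm2",
         call. = FALSE)
  q <- if (!is.null(flow_ml_min)) {
    ml_min_to_m3_s(flow_ml_min)
  } else if (!is.null(velocity_m_s)) {
    velocity_m_s * geom$w * geom$h
  } else {
    shear_to_flowrate(dyn_cm2_to_pa(shear_dyn_cm2), geom, fluid)
  }
  tau_plate <- plate_wall_shear(q, geom, fluid)
  g <- flowrate_to_gradient(q, geom, fluid, n_terms)
  tau_center <- wall_shear_profile(g, geom, fluid, y_m = geom$w / 2,
                                   n_terms = n_terms)$tau_pa
  re <- reynolds_number(q, geom, fluid)
  tibble::tibble(
    q_ml_min = m3_s_to_ml_min(q),
    u_m_s = mean_velocity(q, geom),
    tau_plate_pa = tau_plate,
    tau_plate_dyn_cm2 = pa_to_dyn_cm2(tau_plate),
    tau_center_pa = tau_center,
    dp_pa = pressure_drop(q, geom, fluid, n_terms = n_terms),
    reynolds = re$reynolds,
    laminar = re$laminar
  )
}
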