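#' Finite-difference solution of the duct cross-section
#'
#' Solves the Poisson problem of fully developed laminar duct flow,
#' `d2u/dy2 + d2u/dz2 = -G/mu` with `u = 0` on all four walls, by a 5-point
#' finite-difference discretisation and a direct sparse solve. It serves as
#' an independent numerical check of [duct_velocity_series()] — the two
#' routes share no code beyond the problem statement.
#'
#' @inheritParams duct_velocity_series
#' @param ny,nz number of grid points across the width and height,
#'   boundaries included (default 241 x 21; at the device aspect ratio this
#'   matches the series to a fraction of a percent).
#' @return an object of class `velocity_field`: list with `u` (ny x nz
#'   matrix, m/s), `y_m`, `z_m` grid vectors, `geom`, `fluid`, `g_pa_m`.
#' @export
solve_crosssection_fd <- function(g_pa_m, geom = channel_geometry(),
                                  fluid = fluid_props(), ny = 241, nz = 21) {
  check_geom(geom); check_fluid(fluid)
  stopifnot(is.numeric(g_pa_m), g_pa_m >= 0)
  if (ny < 8 || nz < 8)
    stop("grid must have at least 8 points per dimension", call. = FALSE)
  y <- seq(0, geom$w, length.out = ny)
  z <- seq(0, geom$h, length.out = nz)
  u <- matrix(0, ny, nz)
  if (g_pa_m > 0) {
    dy <- y[2] - y[1]; dz <- z[2] - z[1]
    niy <- ny - 2; niz <- nz - 2
    idx <- function(i, j) (j - 1) * niy + i   # interior (i in 1..niy, j in 1..niz)
    ii <- rep(seq_len(niy), niz)
    jj <- rep(seq_len(niz), each = niy)
    p <- idx(ii, jj)
    ay <- 1 / dy^2; az <- 1 / dz^2
    rows <- c(p,
              p[ii > 1], p[ii < niy],
              p[jj > 1], p[jj < niz])
    cols <- c(p,
              idx(ii[ii > 1] - 1, jj[ii > 1]),
              idx(ii[ii < niy] + 1, jj[ii < niy]),
              idx(ii[jj > 1], jj[jj > 1] - 1),
              idx(ii[jj < niz], jj[jj < niz] + 1))
    vals <- c(rep(-2 * (ay + az), length(p)),
              rep(ay, sum(ii > 1) + sum(ii < niy)),
              rep(az, sum(jj > 1) + sum(jj < niz)))
    a <- Matrix::sparseMatrix(i = rows, j = cols, x = vals)
    rhs <- rep(-g_pa_m / fluid$mu, length(p))
    sol <- as.numeric(Matrix::solve(a, rhs))
    u[2:(ny - 1), 2:(nz - 1)] <- matrix(sol, niy, niz)
  }
  structure(list(u = u, y_m = y, z_m = z, geom = geom, fluid = fluid,
                 g_pa_m = g_pa_m),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d grid, u_max = %.4g m/s\n",
              length(x$y_m), length(x$z_m), max(x$u)))
  invisible(x)
}

#' Tidy a finite-difference velocity field
#'
#' Long-format tibble (y, z, u) for plotting or CSV export.
#'
#' @param x a `velocity_field` from [solve_crosssection_fd()].
#' @param ... unused.
#' @return a tibble with columns `y_m`, `z_m`, `u_m_s`.
#' @method tidy velocity_field
#' @export
tidy.velocity_field <- function(x, ...) {
  tibble::tibble(
    y_m = rep(x$y_m, times = length(x$z_m)),
    z_m = rep(x$z_m, each = length(x$y_m)),
    u_m_s = as.vector(x$u)
  )
}

#' Integrate a velocity field to a flow rate
#'
#' Trapezoidal integration of u(y, z) over the cross-section; used to check
#' conservation against the Q that generated the field.
#'
#' @param field a `velocity_field`.
#' @return volumetric flow rate in m^3/s.
#' @export
integrate_flowrate <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  trap_w <- function(g) {
    d <- diff(g)
    c(d / 2, 0) + c(0, d / 2)
  }
  wy <- trap_w(field$y_m); wz <- trap_w(field$z_m)
  as.numeric(wy %*% field$u %*% wz)
}

#' Bottom-wall shear from a finite-difference field
#'
#' One-sided derivative `mu du/dz` at z = 0 per transverse position, using
#' the curvature known exactly at the wall: since u = 0 along the wall,
#' `u_zz(0) = -G/mu` there, which upgrades the two-point stencil to third
#' order: `u_z(0) = (8 u_1 - u_2 + 2 dz^2 G/mu) / (6 dz)`.
#'
#' @param field a `velocity_field`.
#' @return a tibble with `y_m`, `tau_pa`.
#' @export
fd_wall_shear <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  dz <- field$z_m[2] - field$z_m[1]
  mu <- field$fluid$mu
  tau <- mu * (8 * field$u[, 2] - field$u[, 3] +
                 2 * dz^2 * field$g_pa_m / mu) / (6 * dz)
  tibble::tibble(y_m = field$y_m, tau_pa = tau)
}
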