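test_that("operating-point conversions reproduce the device design values", {
  q14 <- ml_min_to_m3_s(14)
  expect_equal(plate_wall_shear(q14), 0.70, tolerance = 1e-12)
  expect_equal(pa_to_dyn_cm2(plate_wall_shear(q14)), 7)
  expect_equal(plate_wall_shear(0), 0)
  expect_equal(plate_wall_shear(2 * q14), 1.40, tolerance = 1e-12)
  expect_equal(mean_velocity(q14), 0.077778, tolerance = 1e-4)
  expect_equal(round(mean_velocity(q14), 2), 0.08)
  expect_equal(mean_velocity(0), 0)
  expect_equal(mean_velocity(2 * q14), 2 * mean_velocity(q14))
  expect_equal(m3_s_to_ml_min(shear_to_flowrate(0.70)), 14, tolerance = 1e-12)
  expect_equal(shear_to_flowrate(0), 0)
})

test_that("shear <-> flow rate round trip is exact and linear", {
  withr::with_seed(11, {
    taus <- stats::runif(20, 0.01, 5)
    expect_equal(plate_wall_shear(shear_to_flowrate(taus)), taus,
                 tolerance = 1e-14)
    # linear in Q and in mu
    q <- stats::runif(1, 1e-8, 1e-5)
    k <- stats::runif(1, 0.5, 3)
    expect_equal(plate_wall_shear(k * q), k * plate_wall_shear(q))
    mu2 <- fluid_props(viscosity_pas = k * 0.75e-3)
    expect_equal(plate_wall_shear(q, fluid = mu2), k * plate_wall_shear(q))
  })
})

test_that("invalid geometry and fluid inputs error", {
  expect_error(channel_geometry(width_m = 0), "invalid channel geometry")
  expect_error(channel_geometry(height_m = -1), "invalid channel geometry")
  expect_error(fluid_props(viscosity_pas = 0), "invalid fluid")
  expect_error(plate_wall_shear(1e-6, geom = list(w = 1)), "channel_geometry")
})

test_that("duct series obeys no-slip walls and the plane-Poiseuille limits", {
  g <- 1000
  geom <- channel_geometry()
  # all four walls
  expect_equal(duct_velocity_series(c(0, geom$w, 1e-3, 1e-3),
                                    c(1e-4, 1e-4, 0, geom$h), g, geom),
               rep(0, 4), tolerance = 1e-12)
  expect_error(duct_velocity_series(-1e-3, 1e-4, g, geom), "outside")
  # quasi-parallel-plate centre velocity -> G h^2 / (8 mu)
  wide <- channel_geometry(width_m = 1, height_m = 1e-3, length_m = 0.1)
  u_c <- duct_velocity_series(0.5, 0.5e-3, g, wide)
  expect_equal(u_c, g * (1e-3)^2 / (8 * 0.75e-3), tolerance = 1e-3)
  # flow-rate correction factor: 0 < F < 1, F -> 1 as w/h grows
  f1 <- duct_flowrate(g, channel_geometry(1e-3, 1e-3, 0.1))$f_aspect
  f12 <- duct_flowrate(g, geom)$f_aspect
  f_wide <- duct_flowrate(g, wide)$f_aspect
  expect_true(f1 > 0 && f1 < f12 && f12 < f_wide && f_wide < 1)
  expect_equal(f_wide, 1, tolerance = 1e-3)
  # series truncation converged at the default term count
  u51 <- duct_velocity_series(3e-3, 0.25e-3, g, geom, n_terms = 51)
  u201 <- duct_velocity_series(3e-3, 0.25e-3, g, geom, n_terms = 201)
  expect_equal(u51, u201, tolerance = 1e-6)
  expect_error(duct_flowrate(g, geom, n_terms = 0), "n_terms")
})

test_that("square-duct flow factor matches finite-difference integration", {
  g <- 1000
  sq <- channel_geometry(1e-3, 1e-3, 0.1)
  fd <- solve_crosssection_fd(g, sq, ny = 121, nz = 121)
  f_fd <- integrate_flowrate(fd) /
    (g * sq$w * sq$h^3 / (12 * fluid_props()$mu))
  expect_equal(duct_flowrate(g, sq)$f_aspect, f_fd, tolerance = 2e-3)
})

test_that("wall shear profile is symmetric, vanishes at side walls, and has a flat plateau", {
  g <- 2955
  geom <- channel_geometry()
  prof <- wall_shear_profile(g, geom)
  expect_true(all(prof$tau_pa >= -1e-12))
  expect_equal(prof$tau_pa, rev(prof$tau_pa), tolerance = 1e-10)
  expect_equal(prof$tau_pa[1], 0, tolerance = 1e-12)
  expect_equal(prof$tau_pa[nrow(prof)], 0, tolerance = 1e-12)
  central <- prof$tau_pa[prof$y_m >= 0.1 * geom$w & prof$y_m <= 0.9 * geom$w]
  expect_lt(diff(range(central)) / max(central), 0.02)
  # centreline wall shear for w/h = 100 within 1% of the plate formula
  wide <- channel_geometry(0.1, 1e-3, 0.1)
  q <- duct_flowrate(g, wide)$q_m3_s
  tau_c <- wall_shear_profile(g, wide, y_m = 0.05)$tau_pa
  expect_equal(tau_c / plate_wall_shear(q, wide), 1, tolerance = 0.01)
  # plate limit at the centreline: tau -> G h / 2
  expect_equal(tau_c, g * wide$h / 2, tolerance = 5e-3)
  expect_error(wall_shear_profile(g, geom, z_eval_m = 1), "z_eval")
  # evaluation 10 um above the wall is slightly below the wall value
  tau10 <- wall_shear_profile(g, geom, y_m = geom$w / 2, z_eval_m = 10e-6)$tau_pa
  tau0 <- wall_shear_profile(g, geom, y_m = geom$w / 2)$tau_pa
  expect_true(tau10 < tau0 && tau10 > 0.9 * tau0)
})

test_that("pressure drop follows the duct model and the plate hand value", {
  q14 <- ml_min_to_m3_s(14)
  expect_equal(pressure_drop(0), 0)
  expect_equal(pressure_drop(q14, method = "plate"), 352.16, tolerance = 1e-4)
  expect_gt(pressure_drop(q14), pressure_drop(q14, method = "plate"))
  qs <- seq(0, 5, length.out = 7) * 1e-7
  expect_true(all(diff(pressure_drop(qs)) > 0))
})

test_that("Reynolds number flags the laminar operating regime", {
  q14 <- ml_min_to_m3_s(14)
  re <- reynolds_number(q14)
  expect_equal(re$reynolds, 95.7, tolerance = 0.01)
  expect_true(re$laminar)
  expect_equal(reynolds_number(0)$reynolds, 0)
  expect_equal(reynolds_number(3 * q14)$reynolds, 3 * re$reynolds)
})

test_that("finite-difference field is zero at G = 0, symmetric, and conservative", {
  geom <- channel_geometry()
  expect_true(all(solve_crosssection_fd(0, geom)$u == 0))
  fd <- solve_crosssection_fd(1000, geom)
  expect_true(all(fd$u[1, ] == 0) && all(fd$u[, 1] == 0) &&
                all(fd$u[nrow(fd$u), ] == 0) && all(fd$u[, ncol(fd$u)] == 0))
  expect_true(all(fd$u >= 0))
  # mirror symmetry under y -> w - y and z -> h - z
  expect_equal(fd$u, fd$u[rev(seq_len(nrow(fd$u))), ], tolerance = 1e-12)
  expect_equal(fd$u, fd$u[, rev(seq_len(ncol(fd$u)))], tolerance = 1e-12)
  # integrating the field recovers the duct-model flow rate
  expect_equal(integrate_flowrate(fd),
               duct_flowrate(1000, geom)$q_m3_s, tolerance = 0.01)
  expect_error(solve_crosssection_fd(1000, geom, ny = 4), "at least 8")
})

test_that("series and finite-difference solutions cross-validate across aspect ratios", {
  g <- 1000
  cases <- list(c(1, 61, 61), c(4, 121, 31), c(12, 241, 21))
  for (cs in cases) {
    gm <- channel_geometry(cs[1] * 1e-3, 1e-3, 0.1)
    fd <- solve_crosssection_fd(g, gm, ny = cs[2], nz = cs[3])
    cen_y <- fd$y_m >= 0.1 * gm$w & fd$y_m <= 0.9 * gm$w
    cen_z <- fd$z_m >= 0.1 * gm$h & fd$z_m <= 0.9 * gm$h
    us <- outer(fd$y_m[cen_y], fd$z_m[cen_z],
                function(y, z) duct_velocity_series(y, z, g, gm))
    rel <- max(abs(us - fd$u[cen_y, cen_z]) / fd$u[cen_y, cen_z])
    expect_lt(rel, 0.005)
  }
})

test_that("duct outputs scale linearly in Q and 1/mu", {
  withr::with_seed(21, {
    geom <- channel_geometry()
    q <- stats::runif(1, 1e-8, 1e-6)
    k <- stats::runif(1, 0.3, 4)
    expect_equal(pressure_drop(k * q, geom), k * pressure_drop(q, geom))
    mu_k <- fluid_props(viscosity_pas = k * 0.75e-3)
    expect_equal(pressure_drop(q, geom, mu_k), k * pressure_drop(q, geom))
    g <- flowrate_to_gradient(q, geom)
    expect_equal(flowrate_to_gradient(k * q, geom), k * g)
    prof <- wall_shear_profile(g, geom)
    prof_k <- wall_shear_profile(k * g, geom)
    expect_equal(prof_k$tau_pa, k * prof$tau_pa)
  })
})

test_that("flow_design derives a consistent operating table from any single input", {
  by_q <- flow_design(flow_ml_min = 14)
  by_tau <- flow_design(shear_dyn_cm2 = 7)
  by_u <- flow_design(velocity_m_s = by_q$u_m_s)
  expect_equal(by_q$tau_plate_pa, 0.70, tolerance = 1e-12)
  expect_equal(by_tau$q_ml_min, 14, tolerance = 1e-10)
  expect_equal(by_u$q_ml_min, 14, tolerance = 1e-10)
  # side walls raise the centre shear a few percent above the plate value
  ratio <- by_q$tau_center_pa / by_q$tau_plate_pa
  expect_true(ratio > 1.02 && ratio < 1.10)
  expect_error(flow_design(), "exactly one")
  expect_error(flow_design(flow_ml_min = 14, velocity_m_s = 0.1), "exactly one")
})

test_that("centre wall shear at the device aspect ratio matches the FD oracle", {
  geom <- channel_geometry()
  q14 <- ml_min_to_m3_s(14)
  g <- flowrate_to_gradient(q14, geom)
  fd <- solve_crosssection_fd(g, geom)
  tau_fd_c <- fd_wall_shear(fd)$tau_pa[(nrow(fd$u) + 1) / 2]
  tau_series_c <- wall_shear_profile(g, geom, y_m = geom$w / 2)$tau_pa
  expect_equal(tau_series_c, tau_fd_c, tolerance = 0.005)
  # a few percent above the plate formula at fixed Q
  expect_true(tau_fd_c / plate_wall_shear(q14, geom) > 1.02)
})
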