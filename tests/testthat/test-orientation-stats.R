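test_that("angle doubling maps axial data onto the full circle", {
  expect_equal(double_angles(45), 90)
  expect_equal(double_angles(179.5), 359)
  # axial identification: alpha and alpha + 180 are the same axis
  expect_equal(double_angles(10), double_angles(190))
  expect_equal(double_angles(c(0, 90, 135)), c(0, 180, 270))
})

test_that("circular mean and resultant length match hand-computed values", {
  m <- circular_mean_resultant(c(30, 30, 30))
  expect_equal(m$r, 1)
  expect_equal(m$mean_deg, 30)
  expect_equal(circular_mean_resultant(c(0, 180))$r, 0, tolerance = 1e-12)
  m3 <- circular_mean_resultant(c(0, 0, 180))
  expect_equal(m3$r, 1 / 3, tolerance = 1e-12)
  expect_equal(m3$mean_deg, 0, tolerance = 1e-9)
  expect_true(is.na(circular_mean_resultant(c(0, 90, 180, 270))$mean_deg))
  expect_error(circular_mean_resultant(numeric(0)), "empty")
})

test_that("axial summaries reproduce the worked polarity-index values", {
  s <- axial_summary(c(45, 45, 45))
  expect_equal(s$pi_index, 1)
  expect_equal(s$mean_deg, 45)
  expect_equal(axial_summary(c(0, 90))$pi_index, 0, tolerance = 1e-12)
  s3 <- axial_summary(c(0, 0, 90))
  expect_equal(s3$pi_index, 1 / 3, tolerance = 1e-12)
  expect_equal(s3$mean_deg, 0, tolerance = 1e-9)
  td <- tidy(s3)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$pi_index, 1 / 3, tolerance = 1e-12)
  expect_identical(glance(s3), td)
})

test_that("PI is 1 exactly when all axial angles coincide mod 180", {
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- stats::runif(1, 0, 180)
      n <- sample(2:50, 1)
      same <- rep(a, n) + 180 * stats::rbinom(n, 1, 0.5)
      expect_equal(axial_summary(same)$pi_index, 1, tolerance = 1e-9)
      spread <- a + stats::rnorm(n, 0, 20)
      if (stats::sd(spread %% 180) > 1e-6)
        expect_lt(axial_summary(spread)$pi_index, 1)
    }
  })
})

test_that("rotating all angles shifts the mean and preserves PI", {
  withr::with_seed(8, {
    for (i in 1:10) {
      a <- sample_axial_angles(200, stats::runif(1, 0, 180),
                               stats::runif(1, 0.5, 4))
      delta <- stats::runif(1, -180, 180)
      s0 <- axial_summary(a)
      s1 <- axial_summary(a + delta)
      expect_equal(s1$pi_index, s0$pi_index, tolerance = 1e-12)
      expect_equal(((s1$mean_deg - s0$mean_deg - delta) + 90) %% 180 - 90, 0,
                   tolerance = 1e-6)
    }
  })
})

test_that("uniform axial samples calibrate to a vanishing polarity index", {
  withr::with_seed(13, {
    reps <- 500
    n <- 1000
    alpha <- matrix(stats::runif(reps * n, 0, 180), n, reps)
    theta <- 2 * alpha * pi / 180
    pi_hat <- sqrt(colMeans(cos(theta))^2 + colMeans(sin(theta))^2)
    expect_lt(mean(pi_hat), 0.05)   # E[PI] = O(1/sqrt(N))
    expect_gt(mean(pi_hat), 0.01)
  })
})

test_that("sampled axial angles recover the Bessel-ratio resultant length", {
  n <- 2e4
  for (kappa in c(0.5, 1, 2, 4)) {
    a <- sample_axial_angles(n, 30, kappa, seed = 1000 + kappa * 10)
    target <- von_mises_resultant(kappa)
    # 2 SE of the doubled-angle resultant plus the O(1/sqrt(n)) null bias
    a2 <- von_mises_resultant(kappa) # A1
    se <- sqrt((1 - a2^2) / n)
    tol <- 2 * se + sqrt(pi / (4 * n))
    expect_lt(abs(axial_summary(a)$pi_index - target), tol)
  }
  # degenerate cases
  expect_lte(axial_summary(sample_axial_angles(1e5, 0, 0, seed = 2))$pi_index,
             0.02)
  tight <- sample_axial_angles(1000, 77, 1e6, seed = 3)
  expect_lt(max(axial_abs_err(tight, 77)), 0.2)
  expect_error(sample_axial_angles(10, 0, -1))
})

test_that("polarity-angle sampler matches its closed-form resultant", {
  a <- sample_polarity_angles(1e5, 180, 1, seed = 4)
  r <- circular_mean_resultant(a)$r
  expect_equal(r, von_mises_resultant(1), tolerance = 0.01)
  expect_lt(circular_mean_resultant(
    sample_polarity_angles(1e5, 0, 0, seed = 5))$r, 0.02)
  # strongly concentrated against flow: signed index -> -1
  fpi <- mean(cos(sample_polarity_angles(1000, 180, 1e6, seed = 6) * pi / 180))
  expect_equal(fpi, -1, tolerance = 1e-4)
})

test_that("Rayleigh p-values match a Monte-Carlo null oracle", {
  # evenly spaced angles: no concentration
  expect_gt(rayleigh_test(seq(0, 350, by = 10))$p_value, 0.9)
  # strong concentration: decisive
  a <- sample_polarity_angles(100, 0, 2, seed = 9)
  expect_lt(rayleigh_test(a)$p_value, 1e-6)
  # moderate case at N = 20: series correction within 10% of simulation
  theta <- seq(0, 342, by = 18) + 25 * cos(seq(0, 342, by = 18) * pi / 180)
  p_series <- rayleigh_test(theta)$p_value
  p_mc <- mc_rayleigh_p(theta)
  expect_gt(p_series, 0.01)  # genuinely moderate
  expect_lt(abs(p_series - p_mc) / p_mc, 0.10)
  expect_error(rayleigh_test(5), "at least 2")
})

test_that("angular histograms conserve counts and honour the axial period", {
  withr::with_seed(30, {
    a <- stats::runif(12, 0, 180)
    h <- angular_histogram(a, n_bins = 9, axial = TRUE)
    expect_equal(sum(h$count), 12)
    expect_true(all(h$bin_start_deg >= 0 & h$bin_end_deg <= 180))
  })
  h0 <- angular_histogram(numeric(0), n_bins = 12)
  expect_true(all(h0$count == 0))
  hu <- angular_histogram(seq(-179.5, 179.5, by = 1), n_bins = 36)
  expect_true(all(hu$count == 10))
  expect_s3_class(autoplot(hu), "ggplot")
})

test_that("moment-based ellipse fits recover orientation of known shapes", {
  # 20 x 10 axis-aligned rectangle: long axis along x
  rect <- expand.grid(row = 1:10, col = 1:20)
  f <- fit_region_ellipse(rect$row, rect$col)
  expect_equal(f$orientation_deg, 0, tolerance = 1e-9)
  ft <- fit_region_ellipse(rect$col, rect$row)   # transposed
  expect_equal(ft$orientation_deg, 90, tolerance = 1e-9)
  # translation invariance
  f2 <- fit_region_ellipse(rect$row + 57, rect$col + 13)
  expect_equal(f2$orientation_deg, f$orientation_deg)
  expect_equal(f2$major_px, f$major_px)
  # rendered ellipse rotated 30 degrees
  grid <- expand.grid(row = 1:101, col = 1:101)
  u <- (cos(pi / 6) * (grid$col - 51) + sin(pi / 6) * -(grid$row - 51)) / 30
  v <- (-sin(pi / 6) * (grid$col - 51) + cos(pi / 6) * -(grid$row - 51)) / 12
  inside <- u^2 + v^2 <= 1
  f30 <- fit_region_ellipse(grid$row[inside], grid$col[inside])
  expect_lt(axial_abs_err(f30$orientation_deg, 30), 1)
  expect_equal(f30$major_px / 2, 30, tolerance = 0.02)
  # degenerate objects are flagged, not fitted
  expect_false(fit_region_ellipse(5, 5)$orientation_ok)
  disc <- grid[(grid$row - 51)^2 + (grid$col - 51)^2 <= 20^2, ]
  expect_false(fit_region_ellipse(disc$row, disc$col)$orientation_ok)
})

test_that("region_shapes tabulates every labelled object with border flags", {
  lab <- matrix(0L, 40, 40)
  lab[5:10, 5:20] <- 1L    # interior, elongated along x
  lab[30:40, 30:35] <- 2L  # touches the border
  sh <- region_shapes(lab)
  expect_equal(nrow(sh), 2)
  expect_equal(sh$orientation_deg[1], 0, tolerance = 1e-6)
  expect_identical(sh$border, c(FALSE, TRUE))
  expect_equal(sh$area_px, c(6L * 16L, 11L * 6L))
  expect_equal(nrow(region_shapes(matrix(0L, 5, 5))), 0)
})

test_that("summarise_orientation groups and drops undefined orientations", {
  df <- tibble::tibble(
    orientation_deg = c(10, 20, NA, 100, 110, 120),
    condition = c("a", "a", "a", "b", "b", "b"))
  s <- summarise_orientation(df, condition = condition)
  expect_equal(nrow(s), 2)
  expect_equal(s$n, c(2L, 3L))
  expect_equal(s$mean_deg[2], 110, tolerance = 1e-9)
})
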