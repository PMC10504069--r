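nuc_tbl <- function(...) {
  m <- matrix(c(numeric(0), ...), ncol = 2, byrow = TRUE)
  tibble::tibble(id = seq_len(nrow(m)), row = m[, 1], col = m[, 2])
}

test_that("pairing handles the worked single- and two-pair examples", {
  p <- pair_organelles(nuc_tbl(0, 0), nuc_tbl(3, 4))
  expect_equal(nrow(p), 1)
  expect_equal(p$distance_px, 5)
  # two nuclei, two Golgi: straight matching total 2 beats crossing total 18
  p2 <- pair_organelles(nuc_tbl(0, 0, 0, 10), nuc_tbl(0, 1, 0, 9))
  expect_equal(p2$golgi_id[p2$nucleus_id == 1], 1)
  expect_equal(p2$golgi_id[p2$nucleus_id == 2], 2)
  expect_equal(sum(p2$distance_px), 2)
  # distance gate discards remote partners
  pg <- pair_organelles(nuc_tbl(0, 0), nuc_tbl(0, 1000), max_distance = 50)
  expect_equal(nrow(pg), 0)
  expect_equal(attr(pg, "unmatched_nuclei"), 1)
  expect_equal(attr(pg, "unmatched_golgi"), 1)
  # empty inputs
  expect_equal(nrow(pair_organelles(nuc_tbl(), nuc_tbl(1, 1))), 0)
})

test_that("optimal assignment equals brute-force enumeration on random instances", {
  withr::with_seed(1234, {
    for (i in 1:200) {
      n <- sample(1:6, 1); m <- sample(1:6, 1)
      nuclei <- tibble::tibble(id = seq_len(n), row = stats::runif(n, 0, 100),
                               col = stats::runif(n, 0, 100))
      golgi <- tibble::tibble(id = seq_len(m), row = stats::runif(m, 0, 100),
                              col = stats::runif(m, 0, 100))
      p <- pair_organelles(nuclei, golgi)
      cost <- outer(seq_len(n), seq_len(m), function(a, b)
        sqrt((nuclei$row[a] - golgi$row[b])^2 +
               (nuclei$col[a] - golgi$col[b])^2))
      expect_equal(sum(p$distance_px), brute_force_min_cost(cost),
                   tolerance = 1e-9)
    }
  })
})

test_that("pairing is invariant to input order", {
  withr::with_seed(55, {
    n <- 8
    nuclei <- tibble::tibble(id = 1:n, row = stats::runif(n, 0, 50),
                             col = stats::runif(n, 0, 50))
    golgi <- tibble::tibble(id = 1:n, row = nuclei$row + stats::rnorm(n, 0, 2),
                            col = nuclei$col + stats::rnorm(n, 0, 2))
    p1 <- pair_organelles(nuclei, golgi)
    perm_n <- sample(n); perm_g <- sample(n)
    p2 <- pair_organelles(nuclei[perm_n, ], golgi[perm_g, ])
    key <- function(p) {
      o <- order(p$nucleus_id)
      paste(p$nucleus_id[o], p$golgi_id[o])
    }
    expect_identical(key(p1), key(p2))
  })
})

test_that("greedy pairing is offered but can be beaten by the optimal matching", {
  # classic trap: greedy grabs the globally shared closest partner
  nuclei <- nuc_tbl(0, 0, 0, 3)
  golgi <- nuc_tbl(0, 2, 0, 10)
  g <- pair_organelles(nuclei, golgi, method = "greedy")
  o <- pair_organelles(nuclei, golgi, method = "optimal")
  expect_gte(sum(g$distance_px), sum(o$distance_px))
  expect_equal(o$golgi_id[o$nucleus_id == 1], 1)
})

test_that("polarity angle follows the signed flow-relative convention", {
  # flow right-to-left: Golgi displaced leftward of nucleus -> 0 degrees
  expect_equal(polarity_angle(5, 5, 5, 2), 0)
  expect_equal(abs(polarity_angle(5, 5, 5, 8)), 180)
  # left of the flow direction (facing -x, left is -y i.e. larger row): +90
  expect_equal(polarity_angle(5, 5, 6, 5), 90)
  expect_equal(polarity_angle(5, 5, 4, 5), -90)
  expect_true(is.na(polarity_angle(5, 5, 5, 5)))
  # equivariance: rotating flow vector and displacement together
  withr::with_seed(77, {
    for (i in 1:10) {
      phi <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
      d <- stats::runif(2, -5, 5)
      f <- c(-1, 0)
      a0 <- polarity_angle(0, 0, -d[2], d[1], f)
      dr <- rot %*% d; fr <- rot %*% f
      a1 <- polarity_angle(0, 0, -dr[2], dr[1], as.vector(fr))
      expect_equal(((a1 - a0 + 180) %% 360) - 180, 0, tolerance = 1e-9)
    }
  })
})

test_that("polarity summaries match hand-computed values and bounds", {
  s <- polarity_summary(c(180, 180, 180))
  expect_equal(s$fpi, -1)
  expect_equal(s$r, 1)
  s3 <- polarity_summary(c(0, 0, 180))
  expect_equal(s3$fpi, 1 / 3, tolerance = 1e-12)
  expect_equal(s3$r, 1 / 3, tolerance = 1e-12)
  u <- polarity_summary(seq(-179, 180, by = 1))
  expect_lt(u$r, 0.01)
  expect_lt(abs(u$fpi), 0.01)
  expect_error(polarity_summary(NA_real_), "empty")
  # |FPI| <= R <= 1 on random samples
  withr::with_seed(88, {
    for (i in 1:20) {
      th <- sample_polarity_angles(50, stats::runif(1, -180, 180),
                                   stats::runif(1, 0, 3))
      s <- polarity_summary(th)
      expect_lte(abs(s$fpi), s$r + 1e-12)
      expect_lte(s$r, 1)
    }
  })
  td <- tidy(s3)
  expect_equal(td$fpi, 1 / 3, tolerance = 1e-12)
})

test_that("pipeline recovers ground-truth flow polarity on a rendered monolayer", {
  mono <- small_flow_mono()
  res <- analyze_monolayer(mono$images, flow_axis = mono$spec$flow_axis,
                           condition = "flow")
  fpi_pipe <- res$summary$fpi[res$summary$readout == "polarity"]
  fpi_truth <- polarity_summary(mono$truth$polarity_true_deg)$fpi
  expect_lt(fpi_pipe, 0)                      # against the flow vector
  expect_lt(abs(fpi_pipe - fpi_truth), 0.05)  # parameter recovery
})
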