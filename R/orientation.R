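#' Double axial angles to unimodal angles
#'
#' A cell's long axis has no front or back: orientation angles are axial
#' data, defined modulo 180 degrees (alpha and alpha + 180 are the same
#' axis). The standard device for analysing axial data is to double every
#' angle, `theta_i = 2 alpha_i`, which maps the half-circle onto the full
#' circle and makes the sample unimodal; all circular machinery then applies.
#' Out-of-range inputs are first wrapped into [0, 180).
#'
#' @param alpha_deg axial angles in degrees.
#' @return doubled angles in [0, 360).
#' @export
double_angles <- function(alpha_deg) {
  stopifnot(is.numeric(alpha_deg))
  wrap_360(2 * wrap_180(alpha_deg))
}

#' Circular mean direction and resultant length
#'
#' For unimodal angles theta_i the mean resultant vector is
#' `(C, S) = (mean(cos theta), mean(sin theta))`; its length
#' `R = sqrt(C^2 + S^2)` lies in [0, 1] (0 = uniform, 1 = perfectly
#' concentrated) and its direction `atan2(S, C)` is the circular mean.
#' When R falls below `tol` the mean direction is undefined (any direction
#' fits equally well) and is returned as NA.
#'
#' @param theta_deg angles in degrees (unimodal, i.e. full-circle data).
#' @param tol resultant length below which the mean direction is flagged
#'   undefined.
#' @return a list with `mean_deg` (in (-180, 180], possibly NA) and `r`.
#' @export
circular_mean_resultant <- function(theta_deg, tol = 1e-9) {
  if (length(theta_deg) == 0) stop("empty angle sample", call. = FALSE)
  stopifnot(is.numeric(theta_deg), all(is.finite(theta_deg)))
  th <- deg2rad(theta_deg)
  cc <- mean(cos(th)); ss <- mean(sin(th))
  r <- sqrt(cc^2 + ss^2)
  mean_deg <- if (r < tol) NA_real_ else wrap_signed(rad2deg(atan2(ss, cc)))
  list(mean_deg = mean_deg, r = min(r, 1))
}

#' Summarise an axial orientation sample
#'
#' The orientation readout for a monolayer: doubles the axial angles,
#' takes the circular mean of the doubled sample, and reports
#' * the polarity index `PI = R(2 alpha)` — the length of the mean resultant
#'   vector of the doubled angles, 0 for random orientation and 1 when every
#'   cell lies along the same axis;
#' * the mean direction `alpha_bar = theta_bar / 2`, mapped into [0, 180);
#' * the Rayleigh uniformity p-value of the doubled sample.
#'
#' @param alpha_deg axial angles in degrees (wrapped into [0, 180)).
#' @return an object of class `axial_summary`; see [tidy.axial_summary()].
#' @examples
#' s <- axial_summary(c(0, 0, 90))
#' s$pi_index   # 1/3
#' @export
axial_summary <- function(alpha_deg) {
  theta <- double_angles(alpha_deg)
  m <- circular_mean_resultant(theta)
  structure(list(
    n = length(alpha_deg),
    pi_index = m$r,
    mean_deg = if (is.na(m$mean_deg)) NA_real_ else wrap_180(m$mean_deg / 2),
    doubled_mean_deg = m$mean_deg,
    p_uniform = if (length(theta) >= 2) rayleigh_test(theta)$p_value else NA_real_
  ), class = "axial_summary")
}

#' @export
print.axial_summary <- function(x, ...) {
  cat(sprintf("<axial_summary> N = %d, PI = %.3f, mean = %s deg, Rayleigh p = %.3g\n",
              x$n, x$pi_index,
              if (is.na(x$mean_deg)) "NA" else sprintf("%.1f", x$mean_deg),
              x$p_uniform))
  invisible(x)
}

#' @rdname axial_summary
#' @param x an `axial_summary`.
#' @param ... unused.
#' @method tidy axial_summary
#' @export
tidy.axial_summary <- function(x, ...) {
  tibble::tibble(n = x$n, pi_index = x$pi_index, mean_deg = x$mean_deg,
                 doubled_mean_deg = x$doubled_mean_deg, p_uniform = x$p_uniform)
}

#' @rdname axial_summary
#' @method glance axial_summary
#' @export
glance.axial_summary <- function(x, ...) tidy.axial_summary(x)

#' Rayleigh test of circular uniformity
#'
#' Tests H0: angles are uniform on the circle against a unimodal
#' alternative. The statistic is `Z = N R^2`; the p-value uses the standard
#' finite-N series correction
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4N) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288N^2)]`.
#' For axial data apply it to the doubled angles (as [axial_summary()] does).
#'
#' @param theta_deg angles in degrees, N >= 2.
#' @return a tibble with `n`, `r`, `statistic` (Z) and `p_value` (clamped to
#'   [1e-300, 1]).
#' @export
rayleigh_test <- function(theta_deg) {
  n <- length(theta_deg)
  if (n < 2) stop("Rayleigh test needs at least 2 angles", call. = FALSE)
  r <- circular_mean_resultant(theta_deg)$r
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  tibble::tibble(n = n, r = r, statistic = z,
                 p_value = min(max(p, 1e-300), 1))
}

#' Angular histogram
#'
#' Bins angles for rose-diagram display. Axial samples are binned on
#' [0, 180), vectorial samples on (-180, 180]; counts always sum to N.
#'
#' @param angles_deg angles in degrees.
#' @param n_bins number of bins (>= 2).
#' @param axial if TRUE treat the data as axial (period 180).
#' @return a tibble of class `angular_histogram` with `bin_start_deg`,
#'   `bin_end_deg`, `bin_mid_deg`, `count`.
#' @export
angular_histogram <- function(angles_deg, n_bins = 36, axial = FALSE) {
  stopifnot(n_bins >= 2)
  period <- if (axial) 180 else 360
  offset <- if (axial) 0 else -180
  edges <- seq(0, period, length.out = n_bins + 1)
  x <- if (length(angles_deg)) (angles_deg - offset) %% period else numeric(0)
  idx <- pmin(floor(x / (period / n_bins)) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin_start_deg = edges[-(n_bins + 1)] + offset,
    bin_end_deg = edges[-1] + offset,
    bin_mid_deg = (edges[-(n_bins + 1)] + edges[-1]) / 2 + offset,
    count = counts
  )
  attr(out, "axial") <- axial
  class(out) <- c("angular_histogram", class(out))
  out
}

#' Rose diagram of an angular histogram
#'
#' @param object an `angular_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot angular_histogram
#' @export
autoplot.angular_histogram <- function(object, ...) {
  axial <- isTRUE(attr(object, "axial"))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid_deg, y = .data$count)) +
    ggplot2::geom_col(width = (object$bin_end_deg[1] - object$bin_start_deg[1]),
                      fill = "steelblue", colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(
      limits = if (axial) c(0, 180) else c(-180, 180),
      breaks = if (axial) seq(0, 150, 30) else seq(-180, 150, 45)) +
    ggplot2::labs(x = if (axial) "orientation (deg, axial)" else "angle (deg)",
                  y = "cells") +
    ggplot2::theme_minimal()
}

#' Fit an ellipse to a pixel mask by second central moments
#'
#' The orientation of a segmented object is read off the major principal
#' axis of its pixel distribution: with central moments mu20, mu02, mu11,
#' `alpha = 0.5 * atan2(2 mu11, mu20 - mu02)` mapped into [0, 180). Angles
#' follow the mathematical convention (counter-clockwise from +x with y
#' pointing up), so image rows are flipped internally; alpha = 0 means
#' aligned with the image x-axis, i.e. the flow axis in the default layout.
#' Near-circular objects (eccentricity below `min_eccentricity`) have no
#' meaningful axis and get `orientation_ok = FALSE`.
#'
#' @param rows,cols pixel coordinates of the object (1-based image indices).
#' @param min_eccentricity below this the orientation is flagged undefined.
#' @return a one-row tibble: centroid (`row`, `col`), `major_px`, `minor_px`
#'   (full axis lengths), `orientation_deg`, `eccentricity`, `area_px`,
#'   `orientation_ok`.
#' @export
fit_region_ellipse <- function(rows, cols, min_eccentricity = 0.05) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1)
  x <- cols
  y <- -rows                      # flip to mathematical orientation
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2) + 1 / 12   # pixel-patch correction
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  ok <- length(rows) > 1 && ecc >= min_eccentricity
  alpha <- if (ok) wrap_180(rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))) else NA_real_
  tibble::tibble(
    row = mean(rows), col = mean(cols),
    major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(pmax(l2, 0)),
    orientation_deg = alpha, eccentricity = ecc,
    area_px = length(rows), orientation_ok = ok
  )
}

#' Per-object ellipse fits for a label map
#'
#' Runs [fit_region_ellipse()] on every labelled object of an integer label
#' map (0 = background) and returns one row per object.
#'
#' @param labels integer matrix label map.
#' @param min_eccentricity passed to [fit_region_ellipse()].
#' @return a tibble with a leading `id` column plus the ellipse columns,
#'   including `border` (object touches the image border).
#' @export
region_shapes <- function(labels, min_eccentricity = 0.05) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(tibble::tibble(id = integer(), row = double(), col = double(),
                          major_px = double(), minor_px = double(),
                          orientation_deg = double(), eccentricity = double(),
                          area_px = integer(), orientation_ok = logical(),
                          border = logical()))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  pix <- which(labels > 0)
  rr <- ((pix - 1) %% nr) + 1
  cc <- ((pix - 1) %/% nr) + 1
  lab <- labels[pix]
  purrr::map_dfr(ids, function(k) {
    sel <- lab == k
    fit <- fit_region_ellipse(rr[sel], cc[sel], min_eccentricity)
    fit$border <- any(rr[sel] == 1 | rr[sel] == nr | cc[sel] == 1 | cc[sel] == nc)
    fit
  }) |>
    dplyr::mutate(id = as.integer(ids), .before = 1)
}

#' Orientation summary for a table of per-object angles
#'
#' Data-frame-first wrapper: takes a per-object table (e.g. from
#' [region_shapes()]), drops rows with undefined orientation, and returns one
#' summary row per group.
#'
#' @param data a data frame with an orientation column in degrees.
#' @param angle bare column name of the axial angle (default
#'   `orientation_deg`).
#' @param ... grouping columns (bare names), e.g. `condition`.
#' @return a tibble with one row per group: `n`, `pi_index`, `mean_deg`,
#'   `doubled_mean_deg`, `p_uniform`.
#' @export
summarise_orientation <- function(data, angle = orientation_deg, ...) {
  data |>
    dplyr::filter(!is.na({{ angle }})) |>
    dplyr::group_by(...) |>
    dplyr::group_modify(~ tidy(axial_summary(dplyr::pull(.x, {{ angle }})))) |>
    dplyr::ungroup()
}
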