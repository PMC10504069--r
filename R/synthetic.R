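# Synthetic confluent-monolayer generator. Cells are drawn as a seeded
# anisotropic Voronoi mosaic so that each region's fitted long axis tracks a
# known orientation; nuclei, Golgi and a nuclear marker channel are rendered
# on top with per-cell ground truth, which is what makes the whole image
# pipeline testable without real microscopy data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample axial orientation angles
#'
#' Draws axial (180-degree-periodic) angles whose *doubled* values follow a
#' von Mises distribution — the exact inverse of the doubling construction
#' used in the analysis: theta ~ VM(2 mean, kappa), alpha = theta/2 mod 180.
#' The population polarity index of such a sample is the Bessel ratio
#' `I1(kappa)/I0(kappa)` ([von_mises_resultant()]), so recovery is checkable
#' in closed form. `kappa = 0` gives a uniform axial sample (PI -> 0).
#'
#' @param n number of angles.
#' @param mean_deg mean axis direction in degrees (0 = along the image
#'   x-axis, i.e. the flow axis in the default layout).
#' @param kappa concentration of the doubled distribution (>= 0).
#' @param seed optional seed for a reproducible draw (RNG state restored).
#' @return axial angles in [0, 180).
#' @export
sample_axial_angles <- function(n, mean_deg = 0, kappa = 3, seed = NULL) {
  stopifnot(n >= 0, kappa >= 0)
  draw <- function() wrap_180(rvonmises_deg(n, 2 * mean_deg, kappa) / 2)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample front-rear polarity angles
#'
#' Plain (non-doubled) von Mises draw for vectorial data such as the
#' nucleus-to-Golgi polarity angle relative to the flow axis. A mean of 180
#' degrees with positive kappa emulates a population polarized against the
#' flow vector.
#'
#' @inheritParams sample_axial_angles
#' @param mean_deg mean polarity angle in degrees relative to the flow axis.
#' @return angles in (-180, 180].
#' @export
sample_polarity_angles <- function(n, mean_deg = 180, kappa = 2, seed = NULL) {
  stopifnot(n >= 0, kappa >= 0)
  if (is.null(seed)) rvonmises_deg(n, mean_deg, kappa)
  else with_seed(seed, rvonmises_deg(n, mean_deg, kappa))
}

#' Specification of a synthetic monolayer image
#'
#' Collects every tunable of the generator. Defaults emulate a confluent
#' HUVEC monolayer after 4 h of laminar flow imaged at ~1 um/px: a few
#' hundred elongated cells aligned with the flow axis (kappa_axial = 3,
#' elongation 2.5), nuclei correlated with the cell axis (wrapped-normal
#' jitter, sd 15 deg), Golgi offset ~6 um from the nucleus at angles
#' concentrated against the flow vector (mean 180 deg, kappa_pol = 2), a
#' nuclear marker whose mean intensity depends on condition, and shot +
#' Gaussian read noise. Flow axis (-1, 0): flow runs right to left.
#'
#' @param image_px image size, `c(rows, cols)` or a scalar for square.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param n_cells target cell count (the jittered lattice realises a count
#'   close to it; the truth table has one row per rendered cell).
#' @param orientation_mean_deg,kappa_axial axial orientation distribution of
#'   the cell long axes (doubled-von-Mises; see [sample_axial_angles()]).
#' @param elongation anisotropy of each cell's assignment metric (>= 1;
#'   1 = isotropic cells with no orientation signal). The fitted major/minor
#'   ratio of rendered cells comes out somewhat larger than this factor
#'   (roughly twice it at 2.5) because the metric is applied area-preserving.
#' @param nucleus_scale nucleus equivalent radius as a fraction of the cell
#'   equivalent radius.
#' @param nucleus_elongation,nucleus_jitter_sd_deg nucleus aspect ratio and
#'   the sd (deg) of the wrapped-normal jitter coupling nucleus to cell axis.
#' @param golgi_offset_um nucleus-centroid-to-Golgi distance in um.
#' @param polarity_mean_deg,kappa_pol polarity-angle distribution relative to
#'   the flow axis (von Mises; 180 deg = against flow).
#' @param marker_mean,marker_sd per-cell nuclear marker intensity (16-bit
#'   counts), Normal(mean, sd) across cells.
#' @param noise_sd Gaussian read-noise sd (counts); `shot_noise` adds
#'   Poisson noise with the pixel's mean as its rate.
#' @param shot_noise logical.
#' @param flow_axis flow direction as a unit-ish vector `c(x, y)` in
#'   mathematical coordinates (x right, y up).
#' @param condition condition label carried into every table.
#' @param seed RNG seed; same spec + seed gives byte-identical output.
#' @return an object of class `monolayer_spec` (a validated list).
#' @export
monolayer_spec <- function(image_px = c(600, 600), pixel_size_um = 1.0,
                           n_cells = 300, orientation_mean_deg = 0,
                           kappa_axial = 3, elongation = 2.5,
                           nucleus_scale = 0.4, nucleus_elongation = 1.8,
                           nucleus_jitter_sd_deg = 15, golgi_offset_um = 6,
                           polarity_mean_deg = 180, kappa_pol = 2,
                           marker_mean = 8000, marker_sd = 800,
                           noise_sd = 100, shot_noise = TRUE,
                           flow_axis = c(-1, 0), condition = "flow",
                           seed = 1) {
  if (length(image_px) == 1) image_px <- c(image_px, image_px)
  stopifnot(length(image_px) == 2, all(image_px >= 64),
            pixel_size_um > 0, n_cells >= 1,
            kappa_axial >= 0, kappa_pol >= 0, elongation >= 1,
            nucleus_scale > 0, nucleus_scale < 1, nucleus_elongation >= 1,
            nucleus_jitter_sd_deg >= 0, golgi_offset_um >= 0,
            marker_mean > 0, marker_sd >= 0, noise_sd >= 0,
            length(flow_axis) == 2, any(flow_axis != 0))
  structure(list(
    image_px = as.integer(image_px), pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    orientation_mean_deg = orientation_mean_deg, kappa_axial = kappa_axial,
    elongation = elongation, nucleus_scale = nucleus_scale,
    nucleus_elongation = nucleus_elongation,
    nucleus_jitter_sd_deg = nucleus_jitter_sd_deg,
    golgi_offset_um = golgi_offset_um,
    polarity_mean_deg = polarity_mean_deg, kappa_pol = kappa_pol,
    marker_mean = marker_mean, marker_sd = marker_sd,
    noise_sd = noise_sd, shot_noise = isTRUE(shot_noise),
    flow_axis = flow_axis / sqrt(sum(flow_axis^2)),
    condition = condition, seed = as.integer(seed)
  ), class = "monolayer_spec")
}

#' @export
print.monolayer_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<monolayer_spec> %d x %d px (%.2g um/px), ~%d cells, condition '%s'\n",
    "  orientation: mean %.0f deg, kappa %.2g, elongation %.2g\n",
    "  polarity: mean %.0f deg, kappa %.2g, Golgi offset %.2g um; seed %d\n"),
    x$image_px[1], x$image_px[2], x$pixel_size_um, x$n_cells, x$condition,
    x$orientation_mean_deg, x$kappa_axial, x$elongation,
    x$polarity_mean_deg, x$kappa_pol, x$golgi_offset_um, x$seed))
  invisible(x)
}

# intensity scales (16-bit counts)
.render_levels <- list(
  junction_peak = 30000, cytoplasm = 1500,
  nucleus_mean = 20000, nucleus_cell_sd = 2000,
  golgi_peak = 25000, background = 400
)

# Anisotropic nearest-seed label map. Per-seed metric contracts coordinates
# along the cell axis by the elongation factor and expands them across it by
# the same factor (area-preserving), so regions stretch along their own axis
# strongly enough that the fitted ellipse orientation tracks the sampled
# angle even under neighbour competition.
aniso_voronoi <- function(nr, nc, seed_row, seed_col, alpha_deg, elongation) {
  n <- length(seed_row)
  best <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  spacing <- sqrt(nr * nc / n)
  margin <- ceiling(1.6 * spacing * max(1, elongation)) + 2L
  ca <- cos(deg2rad(alpha_deg)); sa <- sin(deg2rad(alpha_deg))
  for (k in seq_len(n)) {
    r0 <- max(1L, floor(seed_row[k] - margin)); r1 <- min(nr, ceiling(seed_row[k] + margin))
    c0 <- max(1L, floor(seed_col[k] - margin)); c1 <- min(nc, ceiling(seed_col[k] + margin))
    rw <- r0:r1; cw <- c0:c1
    dx <- matrix(rep(cw - seed_col[k], each = length(rw)), length(rw))
    dy <- matrix(rep(-(rw - seed_row[k]), times = length(cw)), length(rw))
    u <- (ca[k] * dx + sa[k] * dy) / elongation
    v <- (-sa[k] * dx + ca[k] * dy) * elongation
    d2 <- u * u + v * v
    sub_b <- best[rw, cw, drop = FALSE]
    upd <- d2 < sub_b
    sub_b[upd] <- d2[upd]
    best[rw, cw] <- sub_b
    sub_l <- lab[rw, cw, drop = FALSE]
    sub_l[upd] <- k
    lab[rw, cw] <- sub_l
  }
  # exact cleanup for any pixel outside every window (rare)
  miss <- which(lab == 0L)
  if (length(miss)) {
    mr <- ((miss - 1) %% nr) + 1
    mc <- ((miss - 1) %/% nr) + 1
    for (j in seq_along(miss)) {
      dx <- mc[j] - seed_col; dy <- -(mr[j] - seed_row)
      u <- (ca * dx + sa * dy) / elongation
      v <- (-sa * dx + ca * dy) * elongation
      lab[miss[j]] <- which.min(u * u + v * v)
    }
  }
  lab
}

# filled rotated ellipse, returned as linear pixel indices within the image
ellipse_pixels <- function(nr, nc, row0, col0, a, b, alpha_deg) {
  m <- ceiling(max(a, b)) + 1L
  rw <- max(1L, floor(row0 - m)):min(nr, ceiling(row0 + m))
  cw <- max(1L, floor(col0 - m)):min(nc, ceiling(col0 + m))
  dx <- matrix(rep(cw - col0, each = length(rw)), length(rw))
  dy <- matrix(rep(-(rw - row0), times = length(cw)), length(rw))
  ca <- cos(deg2rad(alpha_deg)); sa <- sin(deg2rad(alpha_deg))
  u <- (ca * dx + sa * dy) / a
  v <- (-sa * dx + ca * dy) / b
  inside <- which(u * u + v * v <= 1)
  rr <- rw[((inside - 1) %% length(rw)) + 1]
  cc <- cw[((inside - 1) %/% length(rw)) + 1]
  (cc - 1L) * nr + rr
}

#' Render a synthetic monolayer image stack with ground truth
#'
#' Generates the four staining channels of the acquisition this package
#' analyses — junction marker (cell outlines), nuclear stain, Golgi marker
#' and a nuclear transcription-factor marker — as 16-bit images, together
#' with a per-cell ground-truth table and the cell/nucleus label maps.
#'
#' Cells tile the frame as a seeded anisotropic Voronoi mosaic: seed points
#' sit on a jittered lattice and each seed's metric is contracted along its
#' sampled orientation axis by the elongation factor, so the fitted long
#' axis of each region tracks its true angle. Nuclei are filled ellipses at
#' region centres with orientation coupled to the cell axis; the Golgi is a
#' Gaussian blob displaced from the nucleus centroid along the sampled
#' polarity angle (clipped to stay inside the cell); the marker channel
#' fills nuclear pixels at a per-cell Normal(condition mean, sd) level.
#' Poisson shot noise and Gaussian read noise are applied last. The truth
#' table stores the realised (post-clipping) polarity angle, recomputed from
#' the stored centroids, so truth is self-consistent by construction.
#'
#' @param spec a [monolayer_spec()].
#' @return an object of class `monolayer`: list with
#'   * `images`: named list of integer matrices (`junction`, `nuclei`,
#'     `golgi`, `marker`), 16-bit range;
#'   * `truth`: tibble, one row per rendered cell (centroids, true angles,
#'     marker level, border flag);
#'   * `labels`: cell label map (anisotropic Voronoi regions);
#'   * `nucleus_labels`: rendered-nucleus label map (same ids);
#'   * `spec`: the input spec.
#' @export
render_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_px[1]; nc <- spec$image_px[2]
    # equal lattice spacing in both axes: unequal spacings would imprint a
    # spurious global orientation on an isotropic mosaic
    s0 <- sqrt(nr * nc / spec$n_cells)
    nx <- max(1L, round(nc / s0))
    ny <- max(1L, round(nr / s0))
    sx <- nc / nx; sy <- nr / ny
    seed_col <- rep((seq_len(nx) - 0.5) * sx, each = ny) +
      stats::runif(nx * ny, -0.35 * sx, 0.35 * sx)
    seed_row <- rep((seq_len(ny) - 0.5) * sy, times = nx) +
      stats::runif(nx * ny, -0.35 * sy, 0.35 * sy)
    n <- nx * ny
    alpha <- sample_axial_angles(n, spec$orientation_mean_deg, spec$kappa_axial)

    labels <- aniso_voronoi(nr, nc, seed_row, seed_col, alpha, spec$elongation)

    # region centroids, areas, border flags
    pix <- seq_len(nr * nc)
    rr <- ((pix - 1L) %% nr) + 1L
    cc <- ((pix - 1L) %/% nr) + 1L
    lab <- as.vector(labels)
    area <- tabulate(lab, nbins = n)
    if (any(area == 0))
      stop("degenerate mosaic: a lattice seed captured no pixels", call. = FALSE)
    cen_row <- tapply(rr, lab, mean)
    cen_col <- tapply(cc, lab, mean)
    on_border <- rr == 1L | rr == nr | cc == 1L | cc == nc
    border <- tabulate(lab[on_border], nbins = n) > 0

    # junction = pixels whose 4-neighbourhood crosses a region boundary
    bnd <- matrix(FALSE, nr, nc)
    bnd[-nr, ] <- bnd[-nr, ] | labels[-nr, ] != labels[-1, ]
    bnd[-1, ] <- bnd[-1, ] | labels[-1, ] != labels[-nr, ]
    bnd[, -nc] <- bnd[, -nc] | labels[, -nc] != labels[, -1]
    bnd[, -1] <- bnd[, -1] | labels[, -1] != labels[, -nc]

    # nuclei: ellipse at region centre, orientation = cell axis + jitter,
    # clipped to the cell region (junction line keeps neighbours separate)
    nuc_alpha <- wrap_180(alpha + stats::rnorm(n, 0, spec$nucleus_jitter_sd_deg))
    b_nuc <- spec$nucleus_scale * sqrt(area / pi) / sqrt(spec$nucleus_elongation)
    a_nuc <- b_nuc * spec$nucleus_elongation
    nucleus_labels <- matrix(0L, nr, nc)
    nuc_row <- nuc_col <- numeric(n)
    min_nuc_px <- 20L
    for (k in seq_len(n)) {
      # narrow or border-truncated cells can clip the first candidate away;
      # shrink and align with the cell axis before giving up
      px <- integer(0)
      r0 <- cen_row[k]; c0 <- cen_col[k]
      ri <- min(max(round(r0), 1L), nr); ci <- min(max(round(c0), 1L), nc)
      if (labels[ri, ci] != k) {
        # centroid fell outside a concave/truncated region: start from the
        # region pixel closest to it
        kp <- pix[lab == k]
        kr <- ((kp - 1L) %% nr) + 1L
        kc <- ((kp - 1L) %/% nr) + 1L
        j <- which.min((kr - r0)^2 + (kc - c0)^2)
        r0 <- kr[j]; c0 <- kc[j]
      }
      for (attempt in 0:5) {
        shrink <- 0.85^attempt
        ang <- if (attempt < 2) nuc_alpha[k] else alpha[k]
        px <- ellipse_pixels(nr, nc, r0, c0, shrink * a_nuc[k],
                             shrink * b_nuc[k], ang)
        px <- px[labels[px] == k & !bnd[px]]
        if (length(px) >= min_nuc_px) break
        if (length(px) > 0) {
          # recentre on what survived the clip
          r0 <- mean(((px - 1L) %% nr) + 1L)
          c0 <- mean(((px - 1L) %/% nr) + 1L)
        }
      }
      if (length(px) < min_nuc_px)
        stop(sprintf(paste0("cells too dense to render distinct nuclei: ",
                            "cell %d nucleus has %d px (area %d px^2); ",
                            "reduce n_cells or nucleus_scale"),
                     k, length(px), area[k]), call. = FALSE)
      nucleus_labels[px] <- k
      nuc_row[k] <- mean(((px - 1L) %% nr) + 1L)
      nuc_col[k] <- mean(((px - 1L) %/% nr) + 1L)
    }

    # Golgi: displaced from the nucleus centroid along the sampled polarity
    # angle (relative to the flow axis), pulled inward until inside the cell
    theta_pol <- rvonmises_deg(n, spec$polarity_mean_deg, spec$kappa_pol)
    flow_ang <- rad2deg(atan2(spec$flow_axis[2], spec$flow_axis[1]))
    dir_ang <- deg2rad(flow_ang + theta_pol)
    d_px <- spec$golgi_offset_um / spec$pixel_size_um
    gol_row <- gol_col <- numeric(n)
    for (k in seq_len(n)) {
      d <- d_px
      repeat {
        gr <- nuc_row[k] - d * sin(dir_ang[k])
        gc <- nuc_col[k] + d * cos(dir_ang[k])
        ri <- min(max(round(gr), 1L), nr); ci <- min(max(round(gc), 1L), nc)
        if (labels[ri, ci] == k || d < 1) break
        d <- d * 0.85
      }
      gol_row[k] <- gr; gol_col[k] <- gc
    }
    pol_true <- wrap_signed(rad2deg(atan2(-(gol_row - nuc_row), gol_col - nuc_col)) -
                              flow_ang)
    pol_true[abs(gol_row - nuc_row) + abs(gol_col - nuc_col) < 1e-9] <- NA_real_

    # channels (clean signal first, noise last)
    marker_true <- stats::rnorm(n, spec$marker_mean, spec$marker_sd)
    marker_true <- pmax(marker_true, 0.05 * spec$marker_mean)
    nuc_bright <- stats::rnorm(n, .render_levels$nucleus_mean,
                               .render_levels$nucleus_cell_sd)
    bg <- .render_levels$background
    junction <- matrix(.render_levels$cytoplasm, nr, nc)
    junction[bnd] <- .render_levels$junction_peak
    nuclei <- matrix(bg, nr, nc)
    inn <- nucleus_labels > 0
    nuclei[inn] <- nuc_bright[nucleus_labels[inn]]
    marker <- matrix(bg, nr, nc)
    marker[inn] <- marker_true[nucleus_labels[inn]]
    golgi <- matrix(bg, nr, nc)
    sigma_g <- max(1.5, 2 / spec$pixel_size_um)
    for (k in seq_len(n)) {
      m <- ceiling(3 * sigma_g)
      rw <- max(1L, floor(gol_row[k] - m)):min(nr, ceiling(gol_row[k] + m))
      cw <- max(1L, floor(gol_col[k] - m)):min(nc, ceiling(gol_col[k] + m))
      dr <- matrix(rep(rw - gol_row[k], times = length(cw)), length(rw))
      dc <- matrix(rep(cw - gol_col[k], each = length(rw)), length(rw))
      golgi[rw, cw] <- golgi[rw, cw] +
        .render_levels$golgi_peak * exp(-(dr^2 + dc^2) / (2 * sigma_g^2))
    }

    add_noise <- function(img) {
      x <- img
      if (spec$shot_noise) x <- stats::rpois(length(x), pmax(x, 0))
      if (spec$noise_sd > 0) x <- x + stats::rnorm(length(x), 0, spec$noise_sd)
      matrix(as.integer(pmin(pmax(round(x), 0), 65535)), nr, nc)
    }
    images <- list(junction = add_noise(junction), nuclei = add_noise(nuclei),
                   golgi = add_noise(golgi), marker = add_noise(marker))

    truth <- tibble::tibble(
      cell = seq_len(n),
      row = as.numeric(cen_row), col = as.numeric(cen_col),
      area_px = as.integer(area),
      orientation_true_deg = alpha,
      nucleus_row = nuc_row, nucleus_col = nuc_col,
      nucleus_orientation_deg = nuc_alpha,
      golgi_row = gol_row, golgi_col = gol_col,
      polarity_true_deg = pol_true,
      marker_true = marker_true,
      border = as.vector(border),
      condition = spec$condition
    )
    structure(list(images = images, truth = truth, labels = labels,
                   nucleus_labels = nucleus_labels, spec = spec),
              class = "monolayer")
  })
}

#' @export
print.monolayer <- function(x, ...) {
  cat(sprintf("<monolayer> %d x %d px, %d cells, condition '%s', seed %d\n",
              nrow(x$labels), ncol(x$labels), nrow(x$truth),
              x$spec$condition, x$spec$seed))
  invisible(x)
}
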