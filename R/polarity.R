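#' Pair nuclei with Golgi by globally optimal assignment
#'
#' Matches each nucleus to at most one Golgi so that the total Euclidean
#' distance over all matched pairs is minimal (linear sum assignment, solved
#' by the Hungarian method). Pairs farther apart than `max_distance` are
#' discarded after the solve; a greedy nearest-first variant is available
#' for comparison but is not globally optimal.
#'
#' @param nuclei,golgi data frames with columns `id`, `row`, `col`
#'   (centroids in pixels); lengths may differ.
#' @param max_distance gate in pixels; matched pairs farther apart are
#'   dropped (default Inf).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return a tibble of class `polarity_pairs`: `nucleus_id`, `golgi_id`,
#'   `nucleus_row`, `nucleus_col`, `golgi_row`, `golgi_col`, `distance_px`.
#'   Attributes `unmatched_nuclei` and `unmatched_golgi` list leftover ids.
#' @export
pair_organelles <- function(nuclei, golgi, max_distance = Inf,
                            method = c("optimal", "greedy")) {
  method <- match.arg(method)
  empty <- tibble::tibble(nucleus_id = integer(), golgi_id = integer(),
                          nucleus_row = double(), nucleus_col = double(),
                          golgi_row = double(), golgi_col = double(),
                          distance_px = double())
  finish <- function(out) {
    attr(out, "unmatched_nuclei") <- setdiff(nuclei$id, out$nucleus_id)
    attr(out, "unmatched_golgi") <- setdiff(golgi$id, out$golgi_id)
    class(out) <- c("polarity_pairs", class(out))
    out
  }
  if (nrow(nuclei) == 0 || nrow(golgi) == 0) return(finish(empty))
  cost <- outer(seq_len(nrow(nuclei)), seq_len(nrow(golgi)),
                function(i, j) sqrt((nuclei$row[i] - golgi$row[j])^2 +
                                      (nuclei$col[i] - golgi$col[j])^2))
  pairs <- if (method == "optimal") {
    if (nrow(cost) <= ncol(cost)) {
      sol <- clue::solve_LSAP(cost)
      cbind(seq_len(nrow(cost)), as.integer(sol))
    } else {
      sol <- clue::solve_LSAP(t(cost))
      cbind(as.integer(sol), seq_len(ncol(cost)))
    }
  } else {
    taken_i <- logical(nrow(cost)); taken_j <- logical(ncol(cost))
    acc <- matrix(integer(0), ncol = 2)
    for (s in seq_len(min(dim(cost)))) {
      masked <- cost
      masked[taken_i, ] <- Inf; masked[, taken_j] <- Inf
      best <- arrayInd(which.min(masked), dim(masked))
      if (!is.finite(masked[best])) break
      acc <- rbind(acc, best)
      taken_i[best[1]] <- TRUE; taken_j[best[2]] <- TRUE
    }
    acc
  }
  d <- cost[pairs]
  keep <- d <= max_distance
  out <- tibble::tibble(
    nucleus_id = nuclei$id[pairs[keep, 1]],
    golgi_id = golgi$id[pairs[keep, 2]],
    nucleus_row = nuclei$row[pairs[keep, 1]],
    nucleus_col = nuclei$col[pairs[keep, 1]],
    golgi_row = golgi$row[pairs[keep, 2]],
    golgi_col = golgi$col[pairs[keep, 2]],
    distance_px = d[keep]
  )
  finish(out)
}

#' Signed polarity angle of nucleus-to-Golgi vectors
#'
#' The front-rear polarity of a cell is the signed angle between the vector
#' from its nucleus centroid to its Golgi centroid and the flow vector, in
#' (-180, 180]. 0 means the Golgi sits downstream of the nucleus (polarized
#' with the flow), 180 upstream (against the flow, the typical endothelial
#' response), +90 to the left of the flow direction. Pixel coordinates are
#' row/col; the row axis is flipped internally so angles follow the
#' mathematical convention.
#'
#' @param nucleus_row,nucleus_col,golgi_row,golgi_col centroid coordinates
#'   (vectors, recycled).
#' @param flow_axis flow direction `c(x, y)` in mathematical coordinates
#'   (default `c(-1, 0)`: flow right to left).
#' @return signed angles in degrees; NA where the centroids coincide.
#' @export
polarity_angle <- function(nucleus_row, nucleus_col, golgi_row, golgi_col,
                           flow_axis = c(-1, 0)) {
  stopifnot(length(flow_axis) == 2, any(flow_axis != 0))
  dx <- golgi_col - nucleus_col
  dy <- -(golgi_row - nucleus_row)
  fx <- flow_axis[1]; fy <- flow_axis[2]
  ang <- wrap_signed(rad2deg(atan2(fx * dy - fy * dx, fx * dx + fy * dy)))
  ang[abs(dx) + abs(dy) < 1e-12] <- NA_real_
  ang
}

#' Add polarity angles to a table of nucleus-Golgi pairs
#'
#' @param pairs output of [pair_organelles()] (or any data frame with the
#'   four centroid columns).
#' @param flow_axis see [polarity_angle()].
#' @return `pairs` with a `polarity_deg` column appended.
#' @export
polarity_angles <- function(pairs, flow_axis = c(-1, 0)) {
  dplyr::mutate(pairs, polarity_deg = polarity_angle(
    .data$nucleus_row, .data$nucleus_col,
    .data$golgi_row, .data$golgi_col, flow_axis))
}

#' Summarise front-rear polarity of a monolayer
#'
#' Vectorial circular summary (no doubling): the mean polarity direction,
#' the resultant length R in [0, 1], and the signed flow-polarity index
#' `FPI = mean(cos theta)` — positive when the population points with the
#' flow vector, negative against it, with |FPI| <= R always.
#'
#' @param theta_deg polarity angles in degrees (NAs dropped).
#' @return an object of class `polarity_summary`.
#' @examples
#' polarity_summary(c(0, 0, 180))  # FPI = 1/3, R = 1/3
#' @export
polarity_summary <- function(theta_deg) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (length(theta_deg) == 0) stop("empty polarity sample", call. = FALSE)
  m <- circular_mean_resultant(theta_deg)
  structure(list(
    n = length(theta_deg),
    mean_deg = m$mean_deg,
    r = m$r,
    fpi = mean(cos(deg2rad(theta_deg)))
  ), class = "polarity_summary")
}

#' @export
print.polarity_summary <- function(x, ...) {
  cat(sprintf("<polarity_summary> N = %d, R = %.3f, FPI = %+.3f, mean = %s deg\n",
              x$n, x$r, x$fpi,
              if (is.na(x$mean_deg)) "NA" else sprintf("%.1f", x$mean_deg)))
  invisible(x)
}

#' @rdname polarity_summary
#' @param x a `polarity_summary`.
#' @param ... unused.
#' @method tidy polarity_summary
#' @export
tidy.polarity_summary <- function(x, ...) {
  tibble::tibble(n = x$n, mean_deg = x$mean_deg, r = x$r, fpi = x$fpi)
}

#' @rdname polarity_summary
#' @method glance polarity_summary
#' @export
glance.polarity_summary <- function(x, ...) tidy.polarity_summary(x)

#' Polarity summary for a table of angles, by group
#'
#' @param data data frame with a polarity-angle column in degrees.
#' @param angle bare column name (default `polarity_deg`).
#' @param ... grouping columns.
#' @return one summary row per group: `n`, `mean_deg`, `r`, `fpi`.
#' @export
summarise_polarity <- function(data, angle = polarity_deg, ...) {
  data |>
    dplyr::filter(!is.na({{ angle }})) |>
    dplyr::group_by(...) |>
    dplyr::group_modify(~ tidy(polarity_summary(dplyr::pull(.x, {{ angle }})))) |>
    dplyr::ungroup()
}
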