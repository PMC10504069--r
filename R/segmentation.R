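# Classical segmentation of the staining channels. The statistics downstream
# are agnostic to the segmenter, so any externally produced label map can be
# passed straight to region_shapes()/nuclear_marker_intensity(); these
# functions are a self-contained classical pipeline (threshold, watershed,
# seeded propagation) built on EBImage primitives.

as_ebi <- function(m) EBImage::Image(t(m / 65535))
from_ebi_labels <- function(im) {
  x <- t(EBImage::imageData(im))
  matrix(as.integer(round(x)), nrow(x), ncol(x))
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum across slices, the standard flattening step before 2D
#' analysis of confocal stacks.
#'
#' @param stack a list of equally sized matrices, or a 3D array with the
#'   slice index last.
#' @return a single matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) == 0)
    stop("stack must be a nonempty list of matrices or a 3D array", call. = FALSE)
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(s) identical(dim(s), d), logical(1))))
    stop("all slices must have the same shape", call. = FALSE)
  Reduce(pmax, stack)
}

#' Relabel a label map to contiguous ids 1..K
#'
#' @param labels integer label map (0 = background).
#' @return the same map with object ids remapped to 1..K in increasing
#'   order of the original ids.
#' @export
relabel_contiguous <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  out
}

auto_threshold <- function(img) {
  if (diff(range(img)) == 0) return(Inf)  # blank image: nothing above threshold
  EBImage::otsu(as_ebi(img)) * 65535
}

#' Segment nuclei from a nuclear-stain image
#'
#' Global automatic (Otsu) threshold, hole filling, minimum-area filter and
#' a distance-transform watershed to split touching nuclei. A blank image
#' yields an empty label map, not an error.
#'
#' @param img 2D intensity matrix (16-bit counts).
#' @param min_area_px discard objects smaller than this (default 30 px^2).
#' @param threshold intensity threshold; `NULL` (default) for Otsu.
#' @param split_touching run the watershed split (default TRUE).
#' @return integer label map (0 background, labels contiguous 1..K).
#' @export
segment_nuclei <- function(img, min_area_px = 30, threshold = NULL,
                           split_touching = TRUE) {
  stopifnot(is.matrix(img))
  thr <- if (is.null(threshold)) auto_threshold(img) else threshold
  bw <- img > thr
  if (!any(bw)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- EBImage::fillHull(EBImage::Image(t(bw)))
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  out <- from_ebi_labels(lab)
  area <- tabulate(out[out > 0])
  small <- which(area < min_area_px)
  if (length(small)) out[out %in% small] <- 0L
  relabel_contiguous(out)
}

#' Segment cells from a junction image using nucleus seeds
#'
#' Seeded propagation on the junction channel: bright junction ridges (above
#' an automatic threshold) are masked out and every remaining pixel is
#' assigned to the geodesically nearest nucleus seed, so regions partition
#' the non-ridge foreground, one region per seed, separated by cell-cell
#' junctions. Output labels keep the seed (nucleus) ids so cell and nucleus
#' tables join directly; border-touching cells can be dropped to avoid
#' truncated-shape bias in orientation statistics.
#'
#' @param junction 2D junction-marker matrix (16-bit counts).
#' @param seeds integer label map of nucleus seeds (e.g. from
#'   [segment_nuclei()]).
#' @param exclude_border drop regions touching the image border
#'   (default TRUE).
#' @param ridge_threshold junction intensity above which pixels count as
#'   boundary; `NULL` (default) for Otsu.
#' @return integer label map; labels are seed ids (use
#'   [relabel_contiguous()] if 1..K contiguity is needed).
#' @export
segment_cells <- function(junction, seeds, exclude_border = TRUE,
                          ridge_threshold = NULL) {
  stopifnot(is.matrix(junction), is.matrix(seeds),
            identical(dim(junction), dim(seeds)))
  if (!any(seeds > 0)) return(matrix(0L, nrow(junction), ncol(junction)))
  thr <- if (is.null(ridge_threshold)) auto_threshold(junction) else ridge_threshold
  mask <- EBImage::Image(t(junction < thr))
  lab <- EBImage::propagate(as_ebi(junction), EBImage::Image(t(seeds)),
                            mask = mask)
  out <- from_ebi_labels(lab)
  if (exclude_border) {
    nr <- nrow(out); nc <- ncol(out)
    edge <- unique(c(out[1, ], out[nr, ], out[, 1], out[, nc]))
    out[out %in% edge[edge > 0]] <- 0L
  }
  out
}

#' Segment Golgi blobs and return intensity-weighted centroids
#'
#' Threshold, connected components (8-connectivity), minimum-area filter,
#' then per-object intensity-weighted centroids — appropriate for compact
#' blob-like organelle signals.
#'
#' @param img 2D Golgi-marker matrix.
#' @param min_area_px discard components smaller than this (default 5).
#' @param threshold intensity threshold; `NULL` for Otsu.
#' @return a tibble with `id`, `row`, `col` (weighted centroid), `area_px`,
#'   `total_intensity`; zero rows for a blank image.
#' @export
segment_golgi <- function(img, min_area_px = 5, threshold = NULL) {
  stopifnot(is.matrix(img))
  thr <- if (is.null(threshold)) auto_threshold(img) else threshold
  bw <- img > thr
  empty <- tibble::tibble(id = integer(), row = double(), col = double(),
                          area_px = integer(), total_intensity = double())
  if (!any(bw)) return(empty)
  lab <- from_ebi_labels(EBImage::bwlabel(EBImage::Image(t(bw))))
  pix <- which(lab > 0)
  nr <- nrow(img)
  d <- tibble::tibble(
    id = lab[pix],
    row = ((pix - 1) %% nr) + 1,
    col = ((pix - 1) %/% nr) + 1,
    w = pmax(as.numeric(img[pix]), 0)
  )
  out <- d |>
    dplyr::summarise(row = sum(row * w) / sum(w), col = sum(col * w) / sum(w),
                     area_px = dplyr::n(), total_intensity = sum(w),
                     .by = "id") |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::arrange(.data$id)
  out$id <- seq_len(nrow(out))
  out
}
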