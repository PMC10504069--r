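# End-to-end orchestration: simulate -> segment -> quantify -> summarise,
# with on-disk artifacts (16-bit TIFFs, per-object CSVs, report.json) laid
# out per run so every summary is traceable to a per-object table.

#' Write / read a multi-channel image stack as 16-bit TIFFs
#'
#' One TIFF per channel, named `<prefix><channel>.tif`. Intensities are
#' integer counts in [0, 65535]; the round trip is exact.
#'
#' @param images named list of integer matrices.
#' @param dir directory (created if needed).
#' @param prefix filename prefix, e.g. `"flow_"`.
#' @return (write) invisibly, the written paths; (read) a named list of
#'   integer matrices.
#' @export
write_image_stack <- function(images, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(images), function(ch) {
    p <- file.path(dir, paste0(prefix, ch, ".tif"))
    tiff::writeTIFF(images[[ch]] / 65535, p, bits.per.sample = 16,
                    compression = "none")
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_image_stack
#' @param channels channel names to read (default the four staining
#'   channels).
#' @export
read_image_stack <- function(dir, prefix = "",
                             channels = c("junction", "nuclei", "golgi",
                                          "marker")) {
  out <- lapply(channels, function(ch) {
    p <- file.path(dir, paste0(prefix, ch, ".tif"))
    if (!file.exists(p)) stop(sprintf("missing channel image: %s", p),
                              call. = FALSE)
    x <- tiff::readTIFF(p)
    matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
  })
  names(out) <- channels
  out
}

#' Analyse one multi-channel monolayer image
#'
#' The full image pipeline on an in-memory stack: segment nuclei from the
#' DNA stain, cells by seeded propagation on the junction channel, Golgi
#' blobs from the Golgi channel; fit per-object ellipses; pair nuclei with
#' Golgi (optimal assignment, gated at 1.5x the median nucleus major axis)
#' and compute polarity angles against the flow axis; measure per-nucleus
#' marker intensity; summarise cell orientation, nucleus orientation and
#' polarity.
#'
#' @param images named list with matrices `junction`, `nuclei`, `golgi`,
#'   `marker` (marker optional).
#' @param flow_axis flow direction in mathematical coordinates.
#' @param condition condition label stamped into all tables.
#' @param max_pair_factor polarity gate as a multiple of the median nucleus
#'   major-axis length.
#' @return a list of tibbles: `cells`, `nuclei`, `pairs`, `intensity`,
#'   `summary` (one row per readout: cell orientation, nucleus orientation,
#'   polarity), plus `counts`.
#' @export
analyze_monolayer <- function(images, flow_axis = c(-1, 0),
                              condition = NA_character_,
                              max_pair_factor = 1.5) {
  stopifnot(all(c("junction", "nuclei", "golgi") %in% names(images)))
  nucleus_labels <- segment_nuclei(images$nuclei)
  cell_labels <- segment_cells(images$junction, nucleus_labels)
  cells <- region_shapes(cell_labels) |>
    dplyr::mutate(condition = condition)
  nuclei <- region_shapes(nucleus_labels) |>
    dplyr::mutate(condition = condition)
  golgi <- segment_golgi(images$golgi)
  gate <- max_pair_factor * stats::median(nuclei$major_px)
  pairs <- pair_organelles(
    dplyr::select(nuclei, "id", "row", "col"), golgi,
    max_distance = if (is.finite(gate)) gate else Inf) |>
    polarity_angles(flow_axis) |>
    dplyr::mutate(condition = condition)
  intensity <- if (!is.null(images$marker)) {
    nuclear_marker_intensity(nucleus_labels, images$marker, condition)
  } else {
    NULL
  }
  interior_nuclei <- dplyr::filter(nuclei, !.data$border)
  summ <- dplyr::bind_rows(
    dplyr::mutate(summarise_orientation(cells), readout = "cell_orientation"),
    dplyr::mutate(summarise_orientation(interior_nuclei),
                  readout = "nucleus_orientation"),
    dplyr::mutate(
      tidy(polarity_summary(pairs$polarity_deg[pairs$nucleus_id %in%
                                                 interior_nuclei$id])),
      readout = "polarity")
  ) |>
    dplyr::mutate(condition = condition) |>
    dplyr::relocate("readout", "condition")
  list(cells = cells, nuclei = nuclei, pairs = pairs, intensity = intensity,
       summary = summ,
       counts = tibble::tibble(condition = condition,
                               cells = nrow(cells), nuclei = nrow(nuclei),
                               golgi = nrow(golgi), pairs = nrow(pairs)))
}

default_conditions <- function() {
  list(
    static = list(kappa_axial = 0, kappa_pol = 0, elongation = 1.4,
                  marker_mean = 4000),
    flow = list(kappa_axial = 3, kappa_pol = 2, elongation = 2.5,
                marker_mean = 8000)
  )
}

#' Configuration for a pipeline run
#'
#' @param mode `"simulate"` (render synthetic conditions, write images,
#'   analyse them), `"analyze"` (analyse images already on disk), or
#'   `"flow-design"` (channel operating-point table only).
#' @param out_dir output directory for artifacts.
#' @param seed master seed; condition i is rendered at `seed + i - 1`.
#' @param conditions named list of [monolayer_spec()] overrides per
#'   condition (simulate mode). Defaults emulate static vs flow.
#' @param flow_axis flow direction for polarity angles.
#' @param images_dir directory with `<condition>_<channel>.tif` files
#'   (analyze mode).
#' @param geom,fluid,flow_ml_min duct-model inputs (flow-design mode).
#' @param qpcr include a simulated qPCR plate and its fold changes in
#'   simulate mode (default TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "analyze", "flow-design"),
                       out_dir = tempfile("endoshear_run_"), seed = 1,
                       conditions = default_conditions(),
                       flow_axis = c(-1, 0), images_dir = NULL,
                       geom = channel_geometry(), fluid = fluid_props(),
                       flow_ml_min = 14, qpcr = TRUE) {
  mode <- match.arg(mode)
  if (mode == "analyze" && is.null(images_dir))
    stop("analyze mode needs images_dir", call. = FALSE)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 conditions = conditions, flow_axis = flow_axis,
                 images_dir = images_dir, geom = geom, fluid = fluid,
                 flow_ml_min = flow_ml_min, qpcr = isTRUE(qpcr)),
            class = "run_config")
}

write_csv_quiet <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
}

#' Run the pipeline end to end
#'
#' Executes the configured mode and writes a `run/` layout under
#' `config$out_dir`: `config.json`, `images/*.tif` (simulate),
#' `tables/*.csv` (per-object tables and summaries), `histograms/*.csv`
#' (angular histogram bins), `report.json`. Identical config + seed gives
#' an identical report.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report` (a list mirroring report.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(
    seed = config$seed,
    mode = config$mode,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("endoshear"))
  )
  report <- if (config$mode == "flow-design") {
    list(flow_design = flow_design(flow_ml_min = config$flow_ml_min,
                                   geom = config$geom, fluid = config$fluid))
  } else {
    stacks <- if (config$mode == "simulate") {
      conds <- names(config$conditions)
      for (i in seq_along(conds)) {
        spec <- do.call(monolayer_spec, c(
          config$conditions[[i]],
          list(condition = conds[i], seed = config$seed + i - 1)))
        mono <- render_monolayer(spec)
        write_image_stack(mono$images, file.path(config$out_dir, "images"),
                          prefix = paste0(conds[i], "_"))
        write_csv_quiet(mono$truth,
                        file.path(config$out_dir, "tables",
                                  paste0(conds[i], "_truth.csv")))
      }
      stats::setNames(lapply(conds, function(cd) {
        read_image_stack(file.path(config$out_dir, "images"),
                         prefix = paste0(cd, "_"))
      }), conds)
    } else {
      conds <- names(config$conditions)
      stats::setNames(lapply(conds, function(cd) {
        read_image_stack(config$images_dir, prefix = paste0(cd, "_"))
      }), conds)
    }
    results <- lapply(names(stacks), function(cd) {
      res <- analyze_monolayer(stacks[[cd]], config$flow_axis, condition = cd)
      write_csv_quiet(res$cells,
                      file.path(config$out_dir, "tables",
                                paste0(cd, "_cells.csv")))
      write_csv_quiet(res$nuclei,
                      file.path(config$out_dir, "tables",
                                paste0(cd, "_nuclei.csv")))
      write_csv_quiet(res$pairs,
                      file.path(config$out_dir, "tables",
                                paste0(cd, "_pairs.csv")))
      if (!is.null(res$intensity))
        write_csv_quiet(res$intensity,
                        file.path(config$out_dir, "tables",
                                  paste0(cd, "_intensity.csv")))
      hist_cells <- angular_histogram(
        res$cells$orientation_deg[!is.na(res$cells$orientation_deg)],
        n_bins = 18, axial = TRUE)
      write_csv_quiet(hist_cells,
                      file.path(config$out_dir, "histograms",
                                paste0(cd, "_cell_orientation.csv")))
      hist_pol <- angular_histogram(
        res$pairs$polarity_deg[!is.na(res$pairs$polarity_deg)],
        n_bins = 36, axial = FALSE)
      write_csv_quiet(hist_pol,
                      file.path(config$out_dir, "histograms",
                                paste0(cd, "_polarity.csv")))
      res
    })
    names(results) <- names(stacks)
    out <- list(
      summary = dplyr::bind_rows(lapply(results, `[[`, "summary")),
      counts = dplyr::bind_rows(lapply(results, `[[`, "counts")),
      intensity_stats = {
        itab <- dplyr::bind_rows(lapply(results, `[[`, "intensity"))
        if (nrow(itab) && length(unique(itab$condition)) == 2) {
          dplyr::bind_cols(
            itab |>
              dplyr::summarise(mean_intensity = mean(.data$mean_intensity),
                               n = dplyr::n(), .by = "condition") |>
              tidyr::pivot_wider(names_from = "condition",
                                 values_from = c("mean_intensity", "n")),
            compare_groups(itab, mean_intensity, condition,
                           method = "wilcox")["p_value"])
        } else {
          NULL
        }
      }
    )
    if (config$mode == "simulate" && config$qpcr) {
      cq <- simulate_cq_table(seed = config$seed)
      write_csv_quiet(cq, file.path(config$out_dir, "tables", "cq.csv"))
      out$qpcr <- qpcr_fold_changes(cq, reference = "GAPDH",
                                    control = "static")
    }
    out
  }
  report$provenance <- provenance
  jsonlite::write_json(
    lapply(report, function(x) if (inherits(x, "data.frame")) x else x),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  cfg <- config
  cfg$geom <- unclass(cfg$geom); cfg$fluid <- unclass(cfg$fluid)
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$flow_design)) print(x$flow_design)
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$qpcr)) print(x$qpcr)
  invisible(x)
}
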