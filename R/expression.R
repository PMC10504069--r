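#' Per-nucleus mean marker intensity
#'
#' The nuclear-marker readout (e.g. a shear-responsive transcription factor
#' such as KLF4): nuclei segmented from the DNA stain define the regions of
#' interest, and the mean marker intensity is taken over each nucleus's
#' pixels.
#'
#' @param nucleus_labels integer label map of nuclei (0 = background).
#' @param marker 2D marker-channel matrix, same shape.
#' @param condition condition label recycled into the output.
#' @param min_area_px drop nuclei smaller than this (default 30).
#' @return a tibble: `id`, `area_px`, `mean_intensity`, `condition`.
#' @export
nuclear_marker_intensity <- function(nucleus_labels, marker,
                                     condition = NA_character_,
                                     min_area_px = 30) {
  stopifnot(is.matrix(nucleus_labels), is.matrix(marker))
  if (!identical(dim(nucleus_labels), dim(marker)))
    stop("label map and marker image must have the same shape", call. = FALSE)
  pix <- which(nucleus_labels > 0)
  if (length(pix) == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          mean_intensity = double(),
                          condition = character()))
  }
  tibble::tibble(id = nucleus_labels[pix],
                 value = as.numeric(marker[pix])) |>
    dplyr::summarise(area_px = dplyr::n(),
                     mean_intensity = mean(.data$value), .by = "id") |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::arrange(.data$id) |>
    dplyr::mutate(condition = condition)
}

#' Relative expression by the 2^-ddCq (Livak) method, scalar form
#'
#' `ddCq = (Cq_target,sample - Cq_ref,sample) - (Cq_target,control -
#' Cq_ref,control)`; fold change = `2^-ddCq`. Each argument may be a vector
#' of replicate Cq values; replicates are aggregated (mean by default)
#' before differencing.
#'
#' @param cq_target_sample,cq_ref_sample,cq_target_control,cq_ref_control
#'   Cq values (replicate vectors allowed), all finite.
#' @param aggregate `"mean"` (default) or `"median"` replicate aggregation.
#' @return fold change (numeric scalar).
#' @examples
#' livak_fold_change(20, 18, 22, 18)  # ddCq = -2, fold change 4
#' @export
livak_fold_change <- function(cq_target_sample, cq_ref_sample,
                              cq_target_control, cq_ref_control,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  vals <- list(cq_target_sample, cq_ref_sample, cq_target_control,
               cq_ref_control)
  if (!all(vapply(vals, function(v) length(v) > 0 && all(is.finite(v)),
                  logical(1))))
    stop("all Cq inputs must be nonempty and finite", call. = FALSE)
  m <- vapply(vals, agg, numeric(1))
  ddcq <- (m[1] - m[2]) - (m[3] - m[4])
  2^(-ddcq)
}

#' Relative expression for a tidy Cq table
#'
#' Data-frame-first ddCq analysis: aggregates replicate Cq per gene and
#' sample, normalises every gene to the reference gene within each sample
#' (dCq), references each gene to the control sample (ddCq), and reports
#' `2^-ddCq`.
#'
#' @param data data frame of a qPCR plate with one row per well.
#' @param gene,sample,cq bare column names for gene, sample/condition and Cq.
#' @param reference reference (housekeeping) gene name, e.g. `"GAPDH"`.
#' @param control control sample/condition name (fold change 1 by
#'   construction).
#' @param aggregate replicate aggregation, `"mean"` (default) or `"median"`.
#' @return a tibble: `gene`, `sample`, `cq`, `dcq`, `ddcq`, `fold_change`
#'   (reference gene excluded).
#' @export
qpcr_fold_changes <- function(data, gene = gene, sample = sample, cq = cq,
                              reference = "GAPDH", control,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  tab <- data |>
    dplyr::transmute(gene = {{ gene }}, sample = {{ sample }}, cq = {{ cq }}) |>
    dplyr::summarise(cq = agg(.data$cq), .by = c("gene", "sample"))
  if (any(!is.finite(tab$cq)) || any(tab$cq <= 0))
    stop("Cq values must be finite and positive", call. = FALSE)
  if (!control %in% tab$sample)
    stop(sprintf("control sample '%s' not present", control), call. = FALSE)
  ref <- dplyr::filter(tab, .data$gene == reference)
  missing_ref <- setdiff(unique(tab$sample), ref$sample)
  if (length(missing_ref))
    stop(sprintf("no reference-gene ('%s') Cq for sample(s): %s", reference,
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  out <- tab |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::left_join(dplyr::select(ref, "sample", ref_cq = "cq"),
                     by = "sample") |>
    dplyr::mutate(dcq = .data$cq - .data$ref_cq)
  ctrl <- out |>
    dplyr::filter(.data$sample == control) |>
    dplyr::select("gene", dcq_control = "dcq")
  out |>
    dplyr::left_join(ctrl, by = "gene") |>
    dplyr::mutate(ddcq = .data$dcq - .data$dcq_control,
                  fold_change = 2^(-.data$ddcq)) |>
    dplyr::select("gene", "sample", "cq", "dcq", "ddcq", "fold_change")
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of mean Cq against log10(dilution factor). The slope in
#' cycles per decade gives the amplification efficiency
#' `E = 10^(-1/slope) - 1`; perfect doubling chemistry has slope
#' -log2(10) = -3.3219 and E = 100%. A non-negative slope is flagged invalid
#' (efficiency undefined).
#'
#' @param dilution dilution factors (e.g. `c(1/10, 1/25, 1/50)`), at least
#'   two distinct values.
#' @param cq mean Cq per dilution, same length.
#' @return an object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `valid`, `n`.
#' @examples
#' standard_curve_fit(c(1, 0.1), c(20, 23.3219))   # E = 100%
#' @export
standard_curve_fit <- function(dilution, cq) {
  stopifnot(length(dilution) == length(cq), length(dilution) >= 2,
            all(dilution > 0), all(is.finite(cq)))
  if (length(unique(dilution)) < 2)
    stop("degenerate design: need at least two distinct dilution factors",
         call. = FALSE)
  fit <- stats::lm(cq ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  valid <- is.finite(slope) && slope < 0
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
    valid = valid,
    n = length(cq)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f cycles/decade, E = %s, R^2 = %.4f%s\n",
              x$slope,
              if (x$valid) sprintf("%.1f%%", 100 * x$efficiency) else "NA",
              x$r_squared, if (x$valid) "" else " [invalid: slope >= 0]"))
  invisible(x)
}

#' @rdname standard_curve_fit
#' @param x a `standard_curve`.
#' @param ... unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 valid = x$valid, n = x$n)
}

#' @rdname standard_curve_fit
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) tidy.standard_curve(x)

#' Group comparison wrappers
#'
#' Thin wrappers over the standard tests used for monolayer readouts:
#' two-sided Wilcoxon rank-sum, Welch t-test, or one-way ANOVA with Tukey
#' correction for more than two groups. These delegate entirely to the
#' stats package; they exist so pipeline reports carry a uniform table.
#'
#' @param data data frame.
#' @param value,group bare column names of the measurement and the grouping
#'   factor.
#' @param method `"wilcox"`, `"t"`, or `"anova_tukey"`.
#' @return a tibble with `comparison`, `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(data, value, group,
                           method = c("wilcox", "t", "anova_tukey")) {
  method <- match.arg(method)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (method == "anova_tukey") {
    fit <- stats::aov(v ~ g)
    tk <- stats::TukeyHSD(fit)$g
    return(tibble::tibble(comparison = rownames(tk),
                          statistic = tk[, "diff"],
                          p_value = tk[, "p adj"],
                          method = "one-way ANOVA + Tukey"))
  }
  if (nlevels(g) != 2)
    stop("two-group test needs exactly two groups", call. = FALSE)
  ht <- if (method == "wilcox") stats::wilcox.test(v ~ g, exact = FALSE)
        else stats::t.test(v ~ g)
  tibble::tibble(comparison = paste(levels(g), collapse = " vs "),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = ht$method)
}

#' Simulate a tidy qPCR Cq table
#'
#' Generates a plate with a reference gene at a common baseline and target
#' genes whose true fold changes versus a control condition are specified;
#' replicate Cq values get Gaussian noise (default sd 0.15 cycles, typical
#' well-to-well scatter). Useful for exercising [qpcr_fold_changes()] with
#' known truth.
#'
#' @param fold_changes named list: `fold_changes[[gene]][[condition]]` =
#'   true fold change vs control (control itself defaults to 1).
#' @param conditions character vector of conditions; the first is the
#'   control unless `control` is given.
#' @param control control condition name.
#' @param reference reference gene name (default "GAPDH").
#' @param n_replicates technical replicates per well (default 2).
#' @param baseline_cq reference-gene Cq and target-gene control Cq.
#' @param noise_sd replicate noise sd in cycles.
#' @param seed RNG seed.
#' @return tibble: `gene`, `sample`, `replicate`, `cq`.
#' @export
simulate_cq_table <- function(fold_changes = list(KLF2 = c(flow = 4),
                                                  KLF4 = c(flow = 3)),
                              conditions = c("static", "flow"),
                              control = conditions[1], reference = "GAPDH",
                              n_replicates = 2, baseline_cq = 22,
                              noise_sd = 0.15, seed = 1) {
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = reference, sample = cond,
        replicate = seq_len(n_replicates),
        cq = baseline_cq + stats::rnorm(n_replicates, 0, noise_sd))
      for (g in names(fold_changes)) {
        fc <- if (cond == control) 1 else unname(fold_changes[[g]][[cond]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = g, sample = cond,
          replicate = seq_len(n_replicates),
          cq = baseline_cq - log2(fc) + stats::rnorm(n_replicates, 0, noise_sd))
      }
    }
    dplyr::bind_rows(rows)
  })
}
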