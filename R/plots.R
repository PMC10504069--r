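#' Plot a transverse wall-shear profile
#'
#' @param object a `shear_profile` from [wall_shear_profile()].
#' @param ... unused.
#' @return a ggplot of tau(y) across the channel width.
#' @method autoplot shear_profile
#' @export
autoplot.shear_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y_m * 1e3,
                                       y = .data$tau_pa)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "transverse position y (mm)",
                  y = "wall shear stress (Pa)",
                  subtitle = sprintf("evaluated at z = %g um",
                                     attr(object, "z_eval_m") * 1e6)) +
    ggplot2::theme_minimal()
}

#' Plot a duct velocity field
#'
#' @param object a `velocity_field` from [solve_crosssection_fd()].
#' @param ... unused.
#' @return a ggplot raster of u(y, z) over the cross-section.
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$y_m * 1e3, y = .data$z_m * 1e3,
                               fill = .data$u_m_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "u (m/s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "y (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}

#' Quick-look rendering of a synthetic monolayer channel
#'
#' @param x a `monolayer` from [render_monolayer()].
#' @param channel which channel to show.
#' @param ... unused.
#' @return a ggplot raster.
#' @export
plot_monolayer <- function(x, channel = c("junction", "nuclei", "golgi",
                                          "marker"), ...) {
  stopifnot(inherits(x, "monolayer"))
  channel <- match.arg(channel)
  img <- x$images[[channel]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = channel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
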