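#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-displacement curve
#'
#' Reaction force in the displacement direction versus enforced master
#' displacement, annotated with the cumulative fractured volume.
#'
#' @param object A `fd_curve` from [run_micro_simulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fd_curve
#' @export
autoplot.fd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$displacement_um,
                                       y = .data$force_mN)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$deleted_volume_um3),
                        alpha = 0.7) +
    ggplot2::scale_size_continuous(name = expression("fractured volume (" * mu * m^3 * ")")) +
    ggplot2::labs(x = expression("master displacement (" * mu * "m)"),
                  y = "reaction force (mN)",
                  title = sprintf("Unit-cell response, gap %g nm",
                                  attr(object, "gap_nm") %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot a removal-torque curve
#'
#' @param object A `torque_curve` from [combine_torque()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot torque_curve
#' @export
autoplot.torque_curve <- function(object, ...) {
  pk <- peak_torque(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rotation_deg,
                                       y = .data$torque_Ncm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "red") +
    ggplot2::labs(x = "rotation (degrees)", y = "removal torque (N cm)",
                  title = sprintf("Removal torque, gap %g nm (peak %.3g N cm)",
                                  attr(object, "gap_nm") %||% NA,
                                  pk$torque_Ncm)) +
    ggplot2::theme_minimal()
}

#' Plot a height map
#'
#' @param object A `height_map`.
#' @param ... Unused.
#' @return A ggplot raster of the surface heights.
#' @method autoplot height_map
#' @export
autoplot.height_map <- function(object, ...) {
  df <- expand.grid(x = (seq_len(nrow(object$z)) - 0.5) * object$dx_nm * 1e-3,
                    y = (seq_len(ncol(object$z)) - 0.5) * object$dy_nm * 1e-3)
  df$z <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ "(" * mu * "m)"),
                  y = expression(y ~ "(" * mu * "m)")) +
    ggplot2::theme_minimal()
}

#' Per-layer force contributions over rotation
#'
#' Visualises the fracture progression down the implant: each line is one
#' macro layer's (area-upscaled) force contribution; the top layer peaks and
#' lets go first, the bottom last.
#'
#' @param tc A `torque_curve` from [combine_torque()].
#' @return A ggplot.
#' @export
plot_layer_contributions <- function(tc) {
  f <- attr(tc, "layer_forces_mN")
  if (is.null(f)) stop("torque curve carries no layer contributions")
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(rotation_deg = tc$rotation_deg),
                     tibble::as_tibble(`colnames<-`(f, seq_len(ncol(f))))),
    -"rotation_deg", names_to = "layer", values_to = "force_mN")
  df$layer <- factor(as.integer(df$layer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rotation_deg, y = .data$force_mN,
                                   colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_d(name = "layer (1 = top)") +
    ggplot2::labs(x = "rotation (degrees)",
                  y = "layer force contribution (mN)") +
    ggplot2::theme_minimal()
}
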