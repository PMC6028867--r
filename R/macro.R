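#' Macroscopic torsion layer model
#'
#' Analytic description of the embedded implant cylinder used to scale the
#' unit-cell response up to removal torque: a cylinder of the given diameter
#' embedded over `embedded_depth_mm` in the polymer block, divided into
#' axial layers. Under an applied top rotation with the bottom of the
#' cylinder fixed, the twist varies linearly with height, so each layer sees
#' a tangential surface displacement proportional to its height above the
#' bottom; the layer value is taken at the layer's mean height.
#'
#' @param diameter_mm Cylinder diameter, mm.
#' @param embedded_depth_mm Embedded length, mm.
#' @param n_layers Number of axial layers.
#' @param layer_height_mm Layer height, mm; `n_layers * layer_height_mm`
#'   must equal the embedded depth.
#' @param cell_area_um2 Projected area of the micro unit cell, square
#'   micrometres (sets the area upscaling of the micro reaction force).
#' @param block_mm Block dimensions (w, l, h), mm; recorded for provenance.
#' @return An object of class `macro_model`.
#' @examples
#' macro_model()  # the bench geometry
#' @export
macro_model <- function(diameter_mm = 3, embedded_depth_mm = 9, n_layers = 20,
                        layer_height_mm = embedded_depth_mm / n_layers,
                        cell_area_um2 = 3.15 * 6.3,
                        block_mm = c(15, 15, 10)) {
  stopifnot(diameter_mm > 0, embedded_depth_mm > 0, n_layers >= 1,
            cell_area_um2 > 0)
  if (abs(n_layers * layer_height_mm - embedded_depth_mm) > 1e-9)
    stop("layer count times layer height must equal the embedded depth")
  structure(list(diameter_mm = diameter_mm,
                 embedded_depth_mm = embedded_depth_mm,
                 n_layers = as.integer(n_layers),
                 layer_height_mm = layer_height_mm,
                 cell_area_um2 = cell_area_um2, block_mm = block_mm),
            class = "macro_model")
}

#' @export
print.macro_model <- function(x, ...) {
  cat(sprintf("<macro_model> d = %g mm, embedded %g mm, %d layers x %g mm\n",
              x$diameter_mm, x$embedded_depth_mm, x$n_layers,
              x$layer_height_mm))
  invisible(x)
}

#' Per-layer tangential displacements under an applied rotation
#'
#' Tangential surface displacement `u = r * theta(z)` of each layer, with the
#' twist `theta(z)` linear from the full applied rotation at the top of the
#' embedded length to zero at the fixed bottom, evaluated at the layer's mean
#' height. Layer 1 is the top layer (where the torque is applied).
#'
#' @param model A [macro_model()].
#' @param rotation_deg Applied top rotation, degrees (>= 0).
#' @return A tibble with `layer`, `z_mid_mm` (height of the layer midpoint
#'   above the fixed bottom) and `displacement_um`.
#' @examples
#' layer_displacements(macro_model(), 0.1)
#' @export
layer_displacements <- function(model, rotation_deg) {
  stopifnot(inherits(model, "macro_model"))
  if (rotation_deg < 0) stop("rotation must be non-negative")
  L <- model$embedded_depth_mm
  z_mid <- L - (seq_len(model$n_layers) - 0.5) * model$layer_height_mm
  r <- model$diameter_mm / 2
  theta <- rotation_deg * pi / 180
  tibble::tibble(layer = seq_len(model$n_layers), z_mid_mm = z_mid,
                 displacement_um = r * theta * (z_mid / L) * 1e3)
}

#' Tangential surface displacement at a given height
#'
#' @param model A [macro_model()].
#' @param rotation_deg Applied top rotation, degrees.
#' @param z_mm Height above the fixed bottom, mm (default: top of the
#'   embedded length).
#' @return Displacement in micrometres.
#' @export
surface_displacement <- function(model, rotation_deg, z_mm = model$embedded_depth_mm) {
  r <- model$diameter_mm / 2
  r * (rotation_deg * pi / 180) * (z_mm / model$embedded_depth_mm) * 1e3
}

#' Interpolate the micro reaction force at a displacement
#'
#' Piecewise-linear interpolation of the recorded force-displacement curve;
#' beyond the last recorded sample the last force value is held (with a
#' one-time warning), since the periodic micro response repeats after one
#' texture period and the post-fracture force level is the relevant tail.
#'
#' @param curve A `fd_curve` (or any data frame with `displacement_um` and
#'   `force_mN`).
#' @param displacement_um Displacement(s) to evaluate, micrometres (>= 0).
#' @param warn Warn when clamping beyond the recorded range.
#' @return Force(s) in millinewtons.
#' @export
micro_force_at <- function(curve, displacement_um, warn = TRUE) {
  stopifnot(all(displacement_um >= 0))
  if (warn && any(displacement_um > max(curve$displacement_um) + 1e-12))
    warning("displacement beyond the recorded curve; holding the last force value")
  stats::approx(curve$displacement_um, curve$force_mN, xout = displacement_um,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Combine the micro response into a removal-torque curve
#'
#' Layer-wise summation of the micro reaction forces: for each rotation, each
#' layer's tangential displacement (with its linear delay from the twist
#' profile) is looked up in the micro force-displacement curve, upscaled by
#' the ratio of the layer's lateral area (`pi * d * h_layer`) to the unit
#' cell area, and converted to torque with the cylinder radius as the moment
#' arm.
#'
#' @param curve A `fd_curve` from [run_micro_simulation()].
#' @param model A [macro_model()].
#' @param rotations_deg Rotation grid, degrees, starting at 0 (default 0-1
#'   degrees in 0.001-degree increments; the top layer moves about 0.26 um
#'   per 0.01 degrees, so a finer grid is needed to resolve the micro-curve
#'   features it sweeps through).
#' @return A `torque_curve`: tibble with `rotation_deg`, `torque_Nmm`,
#'   `torque_Ncm`; the per-layer force contributions (mN, rotations in rows,
#'   layers in columns) are attached as attribute `"layer_forces_mN"`.
#' @export
combine_torque <- function(curve, model, rotations_deg = seq(0, 1, by = 0.001)) {
  stopifnot(inherits(model, "macro_model"), all(rotations_deg >= 0),
            !is.unsorted(rotations_deg, strictly = TRUE))
  if (model$cell_area_um2 <= 0) stop("unit-cell area must be positive")
  r_mm <- model$diameter_mm / 2
  layer_area_mm2 <- pi * model$diameter_mm * model$layer_height_mm
  area_ratio <- layer_area_mm2 / (model$cell_area_um2 * 1e-6)  # mm^2 / mm^2
  ld0 <- layer_displacements(model, 1)  # displacements scale linearly in theta
  u <- outer(rotations_deg, ld0$displacement_um)               # n_rot x n_layers
  f <- matrix(micro_force_at(curve, as.vector(u), warn = FALSE),
              nrow = length(rotations_deg))
  layer_torque_Nmm <- r_mm * area_ratio * f * 1e-3             # mN -> N
  out <- tibble::tibble(rotation_deg = rotations_deg,
                        torque_Nmm = rowSums(layer_torque_Nmm),
                        torque_Ncm = rowSums(layer_torque_Nmm) / 10)
  attr(out, "layer_forces_mN") <- f
  attr(out, "model") <- model
  attr(out, "gap_nm") <- attr(curve, "gap_nm")
  class(out) <- c("torque_curve", class(out))
  out
}

#' Peak of a removal-torque curve
#'
#' The simulated removal torque: rotation and value of the global maximum of
#' the torque curve (ties broken towards the smallest rotation).
#'
#' @param tc A `torque_curve` (or any data frame with `rotation_deg` and
#'   `torque_Nmm`).
#' @return A one-row tibble with `rotation_deg`, `torque_Nmm`, `torque_Ncm`.
#' @export
peak_torque <- function(tc) {
  if (nrow(tc) == 0) stop("empty torque curve")
  i <- which.max(tc$torque_Nmm)
  tibble::tibble(rotation_deg = tc$rotation_deg[i],
                 torque_Nmm = tc$torque_Nmm[i],
                 torque_Ncm = tc$torque_Nmm[i] / 10)
}

#' @rdname peak_torque
#' @param x A `torque_curve`.
#' @param ... Unused.
#' @method glance torque_curve
#' @export
glance.torque_curve <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(gap_nm = attr(x, "gap_nm") %||% NA_real_),
                   peak_torque(x))
}

#' Fracture progression across layers
#'
#' For each layer, the rotation at which its force contribution peaks and
#' the first rotation at which the contribution has dropped below the peak
#' (the layer has "let go"). Because the top layer sees the largest
#' displacement, loosening progresses from the top of the implant to the
#' bottom.
#'
#' @param tc A `torque_curve` from [combine_torque()].
#' @return A tibble with `layer`, `peak_rotation_deg`, `peak_force_mN`,
#'   `past_peak_rotation_deg` (NA if the layer never passes its peak on the
#'   grid).
#' @export
layer_progression <- function(tc) {
  f <- attr(tc, "layer_forces_mN")
  if (is.null(f)) stop("torque curve carries no layer contributions")
  purrr::map_dfr(seq_len(ncol(f)), function(j) {
    v <- f[, j]
    ip <- which.max(v)
    past <- which(seq_along(v) > ip & v < v[ip] - 1e-12)
    tibble::tibble(layer = j, peak_rotation_deg = tc$rotation_deg[ip],
                   peak_force_mN = v[ip],
                   past_peak_rotation_deg =
                     if (length(past)) tc$rotation_deg[past[1]] else NA_real_)
  })
}

#' Write a torque curve as CSV
#'
#' Columns: rotation, torque in N mm and N cm, and one force column per
#' layer.
#'
#' @param tc A `torque_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_torque_curve <- function(tc, path) {
  f <- attr(tc, "layer_forces_mN")
  df <- as.data.frame(tc)
  if (!is.null(f)) {
    colnames(f) <- sprintf("layer%02d_force_mN", seq_len(ncol(f)))
    df <- cbind(df, f)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# retorq torque curve, gap_nm: %g",
                     attr(tc, "gap_nm") %||% NA), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
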