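#' Areal roughness targets for the implant surface
#'
#' Bundles the three areal surface-texture parameters used to characterise the
#' acid-etched titanium surface: `Sa`, the arithmetic mean deviation of the
#' surface from its mean plane (nm); `Sdq`, the root-mean-square slope of the
#' surface expressed as the corresponding angle (degrees, i.e. the arctangent
#' of the RMS gradient); and `Sdr`, the developed interfacial area ratio (%,
#' the excess of true over projected area).
#'
#' @param sa_nm Arithmetic mean deviation, nm (>= 0).
#' @param sdq_deg RMS slope angle, degrees (0 <= sdq < 90).
#' @param sdr_pct Developed area ratio, percent (>= 0).
#' @return An object of class `roughness_spec`.
#' @examples
#' acid_etched <- roughness_spec(849, 50, 40)
#' @export
roughness_spec <- function(sa_nm, sdq_deg, sdr_pct) {
  stopifnot(is.numeric(sa_nm), length(sa_nm) == 1, sa_nm >= 0,
            is.numeric(sdq_deg), length(sdq_deg) == 1, sdq_deg >= 0, sdq_deg < 90,
            is.numeric(sdr_pct), length(sdr_pct) == 1, sdr_pct >= 0)
  structure(list(sa_nm = sa_nm, sdq_deg = sdq_deg, sdr_pct = sdr_pct),
            class = "roughness_spec")
}

#' @export
print.roughness_spec <- function(x, ...) {
  cat(sprintf("<roughness_spec> Sa = %g nm, Sdq = %g deg, Sdr = %g %%\n",
              x$sa_nm, x$sdq_deg, x$sdr_pct))
  invisible(x)
}

#' Micro unit cell of the implant surface
#'
#' The small periodic patch of implant surface whose simulated interfacial
#' response is scaled up to the whole implant. `width_um` is the extent along
#' the enforced tangential (x) direction, `length_um` the transverse (y)
#' extent, and `substrate_depth_um` the depth of embedding polymer below the
#' interface plane retained in the finite-element model.
#'
#' @param width_um,length_um Footprint dimensions, micrometres.
#' @param substrate_depth_um Polymer depth below the interface plane,
#'   micrometres.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(width_um = 3.15, length_um = 6.3, substrate_depth_um = 6) {
  stopifnot(width_um > 0, length_um > 0, substrate_depth_um > 0)
  structure(list(width_um = width_um, length_um = length_um,
                 substrate_depth_um = substrate_depth_um,
                 area_um2 = width_um * length_um),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %g x %g um footprint, substrate depth %g um\n",
              x$width_um, x$length_um, x$substrate_depth_um))
  invisible(x)
}

#' Conical surface feature
#'
#' A single cone standing on the otherwise flat interface plane, the
#' parametric model of one acid-etched surface asperity. The apex sits at
#' `apex_um` in the cell footprint (cell centre by default). The base circle
#' may overlap the cell boundary: because the topography is tiled
#' periodically with the cell period, the cell-restricted cone is exactly one
#' period of a uniform lattice of identical, possibly interpenetrating cones.
#'
#' @param base_radius_um Base radius, micrometres (> 0 unless height is 0).
#' @param height_um Height, micrometres (>= 0).
#' @param apex_um Length-2 apex position (x, y) in the cell, micrometres, or
#'   `NULL` for the cell centre (resolved when a cell is supplied).
#' @return An object of class `cone_feature`.
#' @export
cone_feature <- function(base_radius_um, height_um, apex_um = NULL) {
  stopifnot(is.numeric(base_radius_um), base_radius_um >= 0,
            is.numeric(height_um), height_um >= 0)
  if (height_um > 0 && base_radius_um <= 0)
    stop("a cone with positive height needs a positive base radius")
  if (!is.null(apex_um)) stopifnot(is.numeric(apex_um), length(apex_um) == 2)
  structure(list(base_radius_um = base_radius_um, height_um = height_um,
                 apex_um = apex_um),
            class = "cone_feature")
}

#' @export
print.cone_feature <- function(x, ...) {
  cat(sprintf("<cone_feature> base radius %g um, height %g um, flank angle %.2f deg\n",
              x$base_radius_um, x$height_um,
              if (x$base_radius_um > 0) atan(x$height_um / x$base_radius_um) * 180 / pi else 0))
  invisible(x)
}

cone_apex <- function(cone, cell) {
  if (is.null(cone$apex_um)) c(cell$width_um / 2, cell$length_um / 2) else cone$apex_um
}

check_cone_in_cell <- function(cone, cell) {
  d1 <- cell$width_um / 2
  d2 <- cell$length_um / 2
  rc <- sqrt(d1^2 + d2^2)
  if (cone$base_radius_um > rc + 1e-12)
    stop(sprintf(paste0("cone base radius %.4g um exceeds the half cell diagonal ",
                        "%.4g um: the feature does not fit the periodic cell"),
                 cone$base_radius_um, rc))
  apex <- cone_apex(cone, cell)
  ctr <- c(cell$width_um / 2, cell$length_um / 2)
  if (max(abs(apex - ctr)) > 1e-9)
    stop("closed-form roughness requires the apex at the cell centre")
  invisible(TRUE)
}

# ---- closed-form clipped-disc integrals ------------------------------------
# The cell-centred cone clipped by the cell edges is one period of the uniform
# lattice of cones (nearest-apex/Voronoi argument), so all surface integrals
# reduce to integrals over the intersection of the base disc with the cell
# rectangle. With d1 = w/2, d2 = l/2 and rho <= sqrt(d1^2 + d2^2):
#   S(rho) = area of disc(rho) within the rectangle
#   Q(rho) = integral of r over the same region
# Both have elementary antiderivatives via circular-segment terms.
clip_segment_terms <- function(rho, d) {
  ok <- rho > d
  r <- pmax(rho, d)
  S <- ifelse(ok, 2 * r^2 * acos(d / r) - 2 * d * sqrt(pmax(r^2 - d^2, 0)), 0)
  Q <- ifelse(ok,
              4 * ((r^3 / 3) * acos(d / r) -
                   (d / 3) * ((r / 2) * sqrt(pmax(r^2 - d^2, 0)) +
                              (d^2 / 2) * acosh(pmax(r / d, 1)))),
              0)
  list(S = S, Q = Q)
}

clip_area <- function(rho, d1, d2) {
  e1 <- clip_segment_terms(rho, d1)
  e2 <- clip_segment_terms(rho, d2)
  pi * rho^2 - e1$S - e2$S
}

clip_first_moment <- function(rho, d1, d2) {
  e1 <- clip_segment_terms(rho, d1)
  e2 <- clip_segment_terms(rho, d2)
  2 * pi * rho^3 / 3 - e1$Q - e2$Q
}

# Vectorised over (a, h); internal workhorse in micrometres. Returns a list of
# sa (um), rms gradient (dimensionless), sdr (fraction).
cone_roughness_core <- function(a, h, w, l) {
  A <- w * l
  d1 <- w / 2
  d2 <- l / 2
  flat <- h <= 0 | a <= 0
  a <- pmax(a, 1e-300)
  h_safe <- pmax(h, 1e-300)
  S_a <- clip_area(a, d1, d2)
  Q_a <- clip_first_moment(a, d1, d2)
  Mz_a <- h_safe * (S_a - Q_a / a)          # integral of z over the cell
  zbar <- Mz_a / A
  f <- S_a / A                              # covered area fraction
  rstar <- a * (1 - zbar / h_safe)          # radius where the cone crosses the mean plane
  S_r <- clip_area(rstar, d1, d2)
  Q_r <- clip_first_moment(rstar, d1, d2)
  Mz_r <- h_safe * (S_r - Q_r / a)
  sa <- 2 * (Mz_r - zbar * S_r) / A         # |z - zbar| integral splits at rstar
  slope <- h_safe / a
  rms <- sqrt(f) * slope
  sdr <- f * (sqrt(1 + slope^2) - 1)
  sa[flat] <- 0; rms[flat] <- 0; sdr[flat] <- 0
  list(sa_um = sa, rms = rms, sdr = sdr)
}

#' Closed-form areal roughness of a conical feature
#'
#' Exact Sa, Sdq and Sdr for a single cone centred in the unit cell, i.e. for
#' one period of the uniform lattice of identical cones. Sa comes from the
#' area integral of `|z - mean(z)|` split at the radius where the flank
#' crosses the mean plane, Sdq from the area-weighted RMS of the surface
#' gradient (slope h/a on the covered fraction, zero elsewhere) and Sdr from
#' the lateral-versus-projected area excess. Clipping of the base disc by the
#' cell edges is handled analytically through circular-segment terms.
#'
#' @param cone A [cone_feature()].
#' @param cell A [unit_cell()].
#' @return A one-row tibble with columns `sa_nm`, `sdq_deg`, `sdr_pct`.
#' @examples
#' cone_roughness(cone_feature(1, 1), unit_cell())
#' @export
cone_roughness <- function(cone, cell) {
  check_cone_in_cell(cone, cell)
  v <- cone_roughness_core(cone$base_radius_um, cone$height_um,
                           cell$width_um, cell$length_um)
  tibble::tibble(sa_nm = v$sa_um * 1e3,
                 sdq_deg = atan(v$rms) * 180 / pi,
                 sdr_pct = v$sdr * 100)
}

# ---- height maps -----------------------------------------------------------

#' Discrete height map of the unit-cell surface
#'
#' A rectangular grid of surface heights (nm) over the cell footprint at
#' regular, possibly anisotropic, spacing. Heights are measured from the flat
#' interface plane (reference 0).
#'
#' @param z Numeric matrix of heights, nm; rows advance along x, columns
#'   along y.
#' @param dx_nm,dy_nm Grid spacing along x and y, nm.
#' @return An object of class `height_map`.
#' @export
height_map <- function(z, dx_nm, dy_nm = dx_nm) {
  stopifnot(is.matrix(z), is.numeric(z), nrow(z) >= 1, ncol(z) >= 1,
            !anyNA(z), dx_nm > 0, dy_nm > 0)
  structure(list(z = z, dx_nm = dx_nm, dy_nm = dy_nm), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d samples, spacing %.4g x %.4g nm, range [%.4g, %.4g] nm\n",
              nrow(x$z), ncol(x$z), x$dx_nm, x$dy_nm, min(x$z), max(x$z)))
  invisible(x)
}

#' Sample the conical surface onto a height map
#'
#' Evaluates `z = max(0, h (1 - r / a))` at cell-centred grid points (pixel
#' centres), so the map integrates the surface by the midpoint rule. Exact on
#' the flat region and on the flank away from the base circle.
#'
#' @param cone A [cone_feature()].
#' @param cell A [unit_cell()].
#' @param resolution Samples per axis (>= 2); the same count is used along x
#'   and y, so spacing differs on a non-square cell.
#' @return A [height_map()] with heights in nm.
#' @export
render_height_map <- function(cone, cell, resolution = 512) {
  stopifnot(resolution >= 2)
  apex <- cone_apex(cone, cell)
  dx <- cell$width_um / resolution
  dy <- cell$length_um / resolution
  x <- (seq_len(resolution) - 0.5) * dx - apex[1]
  y <- (seq_len(resolution) - 0.5) * dy - apex[2]
  a <- cone$base_radius_um
  h <- cone$height_um
  z <- if (h <= 0) {
    matrix(0, resolution, resolution)
  } else {
    r <- sqrt(outer(x^2, y^2, `+`))
    zz <- h * (1 - r / a)
    zz[zz < 0] <- 0
    zz
  }
  height_map(z * 1e3, dx_nm = dx * 1e3, dy_nm = dy * 1e3)
}

#' Areal roughness parameters of a height map
#'
#' Numerical counterparts of [cone_roughness()] on a sampled surface:
#' Sa is the mean absolute deviation from the mean height; Sdq is the
#' arctangent of the RMS surface gradient estimated by central differences in
#' the interior and one-sided differences at the borders; Sdr is the excess
#' of the developed area, obtained by splitting every grid cell into two
#' triangular facets, over the projected area.
#'
#' @param hm A [height_map()] with at least 2 x 2 samples.
#' @return A one-row tibble with columns `sa_nm`, `sdq_deg`, `sdr_pct`.
#' @export
roughness_from_height_map <- function(hm) {
  stopifnot(inherits(hm, "height_map"))
  z <- hm$z
  nx <- nrow(z); ny <- ncol(z)
  if (nx < 2 || ny < 2) stop("height map must be at least 2 x 2")
  dx <- hm$dx_nm; dy <- hm$dy_nm
  sa <- mean(abs(z - mean(z)))

  gx <- z; gy <- z
  gx[2:(nx - 1), ] <- (z[3:nx, ] - z[1:(nx - 2), ]) / (2 * dx)
  gx[1, ] <- (z[2, ] - z[1, ]) / dx
  gx[nx, ] <- (z[nx, ] - z[nx - 1, ]) / dx
  gy[, 2:(ny - 1)] <- (z[, 3:ny] - z[, 1:(ny - 2)]) / (2 * dy)
  gy[, 1] <- (z[, 2] - z[, 1]) / dy
  gy[, ny] <- (z[, ny] - z[, ny - 1]) / dy
  rms <- sqrt(mean(gx^2 + gy^2))

  # developed area by facet triangulation: diagonal split of each grid cell
  z00 <- z[-nx, -ny]; z10 <- z[-1, -ny]; z01 <- z[-nx, -1]; z11 <- z[-1, -1]
  tri_area <- function(dza_x, dza_y, dzb_x, dzb_y, dza, dzb) {
    # area of triangle spanned by edge vectors (dza_x, dza_y, dza), (dzb_x, dzb_y, dzb)
    cx <- dza_y * dzb - dza * dzb_y
    cy <- dza * dzb_x - dza_x * dzb
    cz <- dza_x * dzb_y - dza_y * dzb_x
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  dev <- tri_area(dx, 0, 0, dy, z10 - z00, z01 - z00) +
         tri_area(-dx, 0, 0, -dy, z01 - z11, z10 - z11)
  proj <- (nx - 1) * (ny - 1) * dx * dy
  sdr <- (sum(dev) - proj) / proj

  tibble::tibble(sa_nm = sa, sdq_deg = atan(rms) * 180 / pi, sdr_pct = sdr * 100)
}

#' Write/read a height map as a commented CSV matrix
#'
#' Plain-text, row-major matrix with `#`-prefixed header lines carrying the
#' grid spacing and units.
#'
#' @param hm A [height_map()].
#' @param path File path.
#' @return `write_height_map()` returns `path` invisibly; `read_height_map()`
#'   returns a [height_map()].
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# retorq height map",
               "# units: nm",
               sprintf("# dx_nm: %.17g", hm$dx_nm),
               sprintf("# dy_nm: %.17g", hm$dy_nm)), con)
  utils::write.table(hm$z, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1) stop("height map header missing '", key, "'")
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  z <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  height_map(z, dx_nm = get_num("dx_nm"), dy_nm = get_num("dy_nm"))
}

# ---- cone fitting ----------------------------------------------------------

fit_cone_modes <- c("sa+sdq", "sdq+sdr", "least-squares-all")

# height enforcing the Sdq target exactly at base radius a (clipped geometry):
# rms = sqrt(f(a)) * h/a = tan(sdq)
height_for_sdq <- function(a, sdq_deg, w, l) {
  f <- clip_area(a, w / 2, l / 2) / (w * l)
  tan(sdq_deg * pi / 180) * a / sqrt(f)
}

#' Fit the conical feature to roughness targets
#'
#' Determines base radius and height of the cone so that its closed-form
#' roughness matches the targets. Two-constraint modes (`"sa+sdq"`, the
#' default, and `"sdq+sdr"`) solve the two named parameters exactly when a
#' solution exists in the admissible radius range (base radius up to the half
#' cell diagonal). A single cone cannot reproduce every roughness triple: when
#' the named pair has no exact solution, the fit minimises the summed squared
#' relative error of the pair and warns (set `on_infeasible = "error"` to fail
#' instead, with the violated bound named). `"least-squares-all"` minimises
#' the summed squared relative error over all three parameters. The achieved
#' triple is always reported alongside the cone.
#'
#' @param spec A [roughness_spec()] with the targets.
#' @param cell A [unit_cell()].
#' @param mode One of `"sa+sdq"`, `"sdq+sdr"`, `"least-squares-all"`.
#' @param on_infeasible `"least-squares"` (default) or `"error"`; behaviour of
#'   the two-constraint modes when no exact solution exists.
#' @param tol Relative tolerance for the exact two-constraint solve.
#' @return An object of class `cone_fit` with elements `cone`, `cell`,
#'   `mode`, `exact` (logical), `target` and `achieved` (one-row tibbles).
#' @examples
#' fit <- fit_cone(roughness_spec(300, 30, 10), unit_cell())
#' tidy(fit)
#' @export
fit_cone <- function(spec, cell, mode = c("sa+sdq", "sdq+sdr", "least-squares-all"),
                     on_infeasible = c("least-squares", "error"), tol = 1e-9) {
  stopifnot(inherits(spec, "roughness_spec"), inherits(cell, "unit_cell"))
  mode <- match.arg(mode)
  on_infeasible <- match.arg(on_infeasible)
  w <- cell$width_um; l <- cell$length_um
  amax <- sqrt((w / 2)^2 + (l / 2)^2) * (1 - 1e-9)
  target <- tibble::tibble(sa_nm = spec$sa_nm, sdq_deg = spec$sdq_deg,
                           sdr_pct = spec$sdr_pct)

  finish <- function(a, h, exact) {
    cone <- cone_feature(a, h)
    structure(list(cone = cone, cell = cell, mode = mode, exact = exact,
                   target = target, achieved = cone_roughness(cone, cell)),
              class = "cone_fit")
  }

  if (spec$sa_nm == 0 && spec$sdq_deg == 0 && spec$sdr_pct == 0)
    return(finish(min(w, l) / 4, 0, TRUE))

  achieved_at <- function(a) {
    h <- height_for_sdq(a, spec$sdq_deg, w, l)
    v <- cone_roughness_core(a, h, w, l)
    list(h = h, sa_nm = v$sa_um * 1e3, sdr_pct = v$sdr * 100)
  }

  if (mode %in% c("sa+sdq", "sdq+sdr")) {
    key <- if (mode == "sa+sdq") "sa_nm" else "sdr_pct"
    tgt <- target[[key]]
    residual <- function(a) achieved_at(a)[[key]] - tgt
    grid <- seq(amax * 1e-4, amax, length.out = 400)
    vals <- vapply(grid, residual, numeric(1))
    sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
    if (spec$sdq_deg > 0 && length(sgn) > 0) {
      i <- sgn[1]  # smallest root: the most compact feature matching the pair
      root <- stats::uniroot(residual, c(grid[i], grid[i + 1]), tol = amax * tol)
      a <- root$root
      return(finish(a, achieved_at(a)$h, TRUE))
    }
    msg <- sprintf(paste0("no cone with base radius in (0, %.4g] um matches ",
                          "%s exactly at Sdq = %g deg (best achievable %s: %.4g); "),
                   amax, key, spec$sdq_deg,
                   key, if (length(vals)) vals[which.min(abs(vals))] + tgt else NA)
    if (on_infeasible == "error")
      stop(msg, "the named pair is infeasible for a single cone in this cell")
    warning(msg, "falling back to a least-squares fit of the pair")
    pair <- if (mode == "sa+sdq") c("sa_nm", "sdq_deg") else c("sdq_deg", "sdr_pct")
    ls <- ls_fit_cone(target, w, l, amax, pair)
    return(finish(ls[1], ls[2], FALSE))
  }

  ls <- ls_fit_cone(target, w, l, amax, c("sa_nm", "sdq_deg", "sdr_pct"))
  finish(ls[1], ls[2], FALSE)
}

# least-squares over selected parameters; multi-start L-BFGS-B on (a, h)
ls_fit_cone <- function(target, w, l, amax, params) {
  obj <- function(p) {
    v <- cone_roughness_core(p[1], p[2], w, l)
    ach <- c(sa_nm = v$sa_um * 1e3, sdq_deg = atan(v$rms) * 180 / pi,
             sdr_pct = v$sdr * 100)
    sum(((ach[params] - unlist(target[params])) /
           pmax(unlist(target[params]), 1e-12))^2)
  }
  starts <- expand.grid(a = amax * c(0.2, 0.5, 0.8, 0.95),
                        h = c(0.5, 1.5, 3, 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                      lower = c(amax * 1e-4, 1e-6), upper = c(amax, 50),
                      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

#' @export
print.cone_fit <- function(x, ...) {
  cat(sprintf("<cone_fit> mode %s (%s)\n", x$mode,
              if (x$exact) "exact" else "least squares"))
  print(x$cone)
  cat("target:  "); cat(sprintf("Sa %g nm, Sdq %g deg, Sdr %g %%\n",
                                x$target$sa_nm, x$target$sdq_deg, x$target$sdr_pct))
  cat("achieved:"); cat(sprintf(" Sa %.4g nm, Sdq %.4g deg, Sdr %.4g %%\n",
                                x$achieved$sa_nm, x$achieved$sdq_deg, x$achieved$sdr_pct))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cone fit
#'
#' @param x A `cone_fit`.
#' @param ... Unused.
#' @return A tibble with one row per roughness parameter: target, achieved
#'   value and relative error.
#' @method tidy cone_fit
#' @export
tidy.cone_fit <- function(x, ...) {
  tibble::tibble(parameter = c("sa_nm", "sdq_deg", "sdr_pct"),
                 target = unlist(x$target, use.names = FALSE),
                 achieved = unlist(x$achieved, use.names = FALSE)) |>
    dplyr::mutate(rel_error = (.data$achieved - .data$target) /
                    ifelse(.data$target == 0, 1, .data$target))
}

#' @rdname tidy.cone_fit
#' @method glance cone_fit
#' @export
glance.cone_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, exact = x$exact,
                 base_radius_um = x$cone$base_radius_um,
                 height_um = x$cone$height_um,
                 flank_angle_deg = if (x$cone$base_radius_um > 0)
                   atan(x$cone$height_um / x$cone$base_radius_um) * 180 / pi else 0)
}

# ---- rigid master contact surface ------------------------------------------

#' Gap-offset rigid contact surface
#'
#' Builds the rigid master surface for the contact solver: the titanium
#' feature (base plane plus cone, periodic along the enforced x direction with
#' the cell width as period) shrunk by the interfacial gap along its outward
#' normal, giving a uniform clearance between feature and polymer imprint.
#' The returned object carries a signed-distance evaluator: positive on the
#' polymer side, zero on the offset surface, with unit outward normals.
#'
#' @param cone A [cone_feature()].
#' @param cell A [unit_cell()]; fixes the apex position and the x period.
#' @param gap_nm Uniform clearance, nm (>= 0).
#' @param periodic_x Tile the feature along x with the cell width (default
#'   `TRUE`, matching the tied lateral boundary conditions).
#' @return An object of class `contact_surface` with fields `cone`, `cell`,
#'   `gap_nm` and `sdf(points_um, shift_um = 0)`, where `points_um` is an
#'   n x 3 matrix (x, y, depth z into the polymer) and `shift_um` a rigid
#'   translation of the master along +x. `sdf` returns `list(d_um, normal)`.
#' @export
offset_surface <- function(cone, cell, gap_nm = 0, periodic_x = TRUE) {
  stopifnot(inherits(cone, "cone_feature"), inherits(cell, "unit_cell"),
            gap_nm >= 0)
  a <- cone$base_radius_um
  h <- cone$height_um
  gap_um <- gap_nm * 1e-3
  if (h > 0) {
    inradius <- (a + h - sqrt(a^2 + h^2)) / 2
    if (gap_um >= inradius)
      stop(sprintf("gap %.4g nm >= cone inradius %.4g nm: offset cone degenerates",
                   gap_nm, inradius * 1e3))
  }
  apex <- cone_apex(cone, cell)
  period <- if (periodic_x) cell$width_um else Inf

  sdf <- function(points_um, shift_um = 0) {
    p <- as.matrix(points_um)
    stopifnot(ncol(p) == 3)
    n_pts <- nrow(p)
    # base half-space z <= 0 (titanium below the interface plane)
    d <- p[, 3]
    nrm <- matrix(rep(c(0, 0, 1), each = n_pts), ncol = 3)
    if (h > 0) {
      dx <- p[, 1] - (apex[1] + shift_um)
      if (is.finite(period)) dx <- dx - period * round(dx / period)
      dy <- p[, 2] - apex[2]
      ks <- if (is.finite(period)) -1:1 else 0L
      for (k in ks) {
        dxa <- if (k == 0) dx else dx - k * period
        rho <- sqrt(dxa^2 + dy^2)
        sc <- cone_sdf_2d(rho, p[, 3], a, h)
        better <- sc$d < d
        if (any(better)) {
          # map the 2d (rho, z) gradient back to 3d
          safe_rho <- pmax(rho, 1e-300)
          ex <- dxa / safe_rho
          ey <- dy / safe_rho
          nrm[better, 1] <- sc$g_rho[better] * ex[better]
          nrm[better, 2] <- sc$g_rho[better] * ey[better]
          nrm[better, 3] <- sc$g_z[better]
          d[better] <- sc$d[better]
        }
      }
    }
    list(d_um = d + gap_um, normal = nrm)
  }

  structure(list(cone = cone, cell = cell, gap_nm = gap_nm,
                 periodic_x = periodic_x, sdf = sdf),
            class = "contact_surface")
}

#' @export
print.contact_surface <- function(x, ...) {
  cat(sprintf("<contact_surface> gap %g nm, %s\n", x$gap_nm,
              if (x$periodic_x) "periodic along x" else "single feature"))
  invisible(x)
}

# signed distance (and gradient) to the solid finite cone in the (rho, z)
# half-plane: distance to the flank segment from (a, 0) to (0, h), negative
# inside. The cone's base disc is interior to the union with the base
# half-space, so only the flank acts as a boundary; this keeps interface
# nodes at z = 0 correctly detected when the sliding feature overlaps them
# laterally.
cone_sdf_2d <- function(rho, z, a, h) {
  ex <- -a; ez <- h            # segment direction (a,0) -> (0,h)
  len2 <- a^2 + h^2
  t <- pmin(pmax(((rho - a) * ex + z * ez) / len2, 0), 1)
  qr <- a + t * ex
  qz <- t * ez
  dr <- rho - qr
  dz <- z - qz
  dseg <- sqrt(dr^2 + dz^2)
  inside <- z >= 0 & z <= h & rho <= a * (1 - z / h)
  d <- ifelse(inside, -dseg, dseg)
  safe <- pmax(dseg, 1e-300)
  g_rho <- ifelse(inside, -dr / safe, dr / safe)
  g_z <- ifelse(inside, -dz / safe, dz / safe)
  list(d = d, g_rho = g_rho, g_z = g_z)
}
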