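#' Default run configuration ("acid_etched_bench")
#'
#' The packaged baseline profile: the acid-etched bench model with all
#' defaults at the bench-model values — roughness targets Sa 849 nm,
#' Sdq 50 deg, Sdr 40 %; 3.15 x 6.3 um unit cell; polymer E = 3.76 GPa,
#' nu = 0.34, yield 40 MPa (titanium grade IV constants retained for the
#' deformable-feature option); gap sweep 10/50/100/150 nm; 3 mm cylinder
#' embedded 9 mm, 20 layers of 0.45 mm. The displacement schedule defaults
#' to 30 increments of 0.02 um (0.6 um total): increments resolve the
#' fracture transient of every gap in the sweep and the total spans the
#' tangential engagement of the largest gap plus the force decay; the
#' six-increment schedule remains available via `micro.n_steps`.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    roughness = list(sa_nm = 849, sdq_deg = 50, sdr_pct = 40),
    fit_mode = "sa+sdq",
    cell = list(width_um = 3.15, length_um = 6.3, substrate_depth_um = 6),
    mesh = list(target_elem_size_um = 0.4),
    material = list(
      polymer = list(elastic_modulus_gpa = 3.76, poisson_ratio = 0.34,
                     yield_strength_mpa = 40),
      titanium = list(elastic_modulus_gpa = 113, poisson_ratio = 0.32)),
    contact = list(penalty_scale = 100, penetration_tol_rel = 1e-3),
    micro = list(gaps_nm = c(10, 50, 100, 150), n_steps = 30,
                 total_displacement_um = 0.6, max_passes = 30,
                 stress_sampling = "mean"),
    macro = list(diameter_mm = 3, embedded_depth_mm = 9, n_layers = 20,
                 layer_height_mm = 0.45, block_mm = c(15, 15, 10)),
    rotation = list(max_deg = 1, step_deg = 0.001)),
    class = "run_config")
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: '", here, "'")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key '", here, "' must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[key] <- list(user[[key]])
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  # constructors enforce the module invariants
  roughness_spec(cfg$roughness$sa_nm, cfg$roughness$sdq_deg, cfg$roughness$sdr_pct)
  cell <- do.call(unit_cell, cfg$cell)
  material(cfg$material$polymer$elastic_modulus_gpa,
           cfg$material$polymer$poisson_ratio,
           cfg$material$polymer$yield_strength_mpa)
  do.call(macro_model, c(cfg$macro[c("diameter_mm", "embedded_depth_mm",
                                     "n_layers", "layer_height_mm")],
                         list(cell_area_um2 = cell$area_um2)))
  chk(cfg$fit_mode %in% fit_cone_modes,
      paste("fit_mode must be one of", paste(fit_cone_modes, collapse = ", ")))
  chk(all(cfg$micro$gaps_nm >= 0), "gaps must be non-negative")
  chk(cfg$micro$n_steps >= 1, "micro.n_steps must be at least 1")
  chk(is.null(cfg$micro$total_displacement_um) ||
        cfg$micro$total_displacement_um > 0,
      "micro.total_displacement_um must be positive when given")
  chk(cfg$mesh$target_elem_size_um > 0, "mesh.target_elem_size_um must be positive")
  chk(cfg$contact$penalty_scale > 0, "contact.penalty_scale must be positive")
  chk(cfg$rotation$max_deg > 0 && cfg$rotation$step_deg > 0,
      "rotation grid must be positive")
  chk(cfg$micro$stress_sampling %in% c("mean", "max"),
      "micro.stress_sampling must be 'mean' or 'max'")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, applies it over the packaged defaults
#' ([default_config()]), rejects unknown keys and validates every module
#' invariant. An empty (or `NULL`) file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("configuration must be a YAML mapping")
      cfg <- merge_config(unclass(cfg), user)
      class(cfg) <- "run_config"
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_objects <- function(cfg) {
  cell <- do.call(unit_cell, cfg$cell)
  list(
    spec = roughness_spec(cfg$roughness$sa_nm, cfg$roughness$sdq_deg,
                          cfg$roughness$sdr_pct),
    cell = cell,
    polymer = material(cfg$material$polymer$elastic_modulus_gpa,
                       cfg$material$polymer$poisson_ratio,
                       cfg$material$polymer$yield_strength_mpa),
    macro = do.call(macro_model,
                    c(cfg$macro[c("diameter_mm", "embedded_depth_mm",
                                  "n_layers", "layer_height_mm")],
                      list(cell_area_um2 = cell$area_um2,
                           block_mm = cfg$macro$block_mm))),
    rotations = seq(0, cfg$rotation$max_deg, by = cfg$rotation$step_deg))
}

#' Full removal-torque pipeline
#'
#' Fits the conical feature to the roughness targets, meshes the unit cell,
#' runs the micro fracture simulation for every gap size and combines each
#' force-displacement curve into a removal-torque curve. When `out_dir` is
#' given, all artifacts are written there: the resolved configuration (for
#' provenance), the roughness report, per-gap curve CSVs, torque CSVs and a
#' JSON summary.
#'
#' @param cfg A `run_config` (default: [default_config()]).
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return A list of class `retorq_run`: `fit` (the `cone_fit`), `curves`
#'   (per-gap `fd_curve`s), `torques` (per-gap `torque_curve`s) and
#'   `summary` (tibble: gap, peak torque and rotation, fractured volume).
#' @export
run_removal_torque <- function(cfg = default_config(), out_dir = NULL,
                               quiet = FALSE) {
  validate_config(cfg)
  ob <- config_objects(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))

  t0 <- proc.time()[3]
  say("[fit] fitting cone to roughness targets (mode %s)", cfg$fit_mode)
  fit <- fit_cone(ob$spec, ob$cell, mode = cfg$fit_mode)

  say("[mesh] building unit-cell mesh (target element size %g um)",
      cfg$mesh$target_elem_size_um)
  mesh_set <- build_unit_cell_mesh(fit$cone, ob$cell,
                                   cfg$mesh$target_elem_size_um)
  say("[mesh] %d elements, %d nodes", nrow(mesh_set$mesh$elems),
      nrow(mesh_set$mesh$nodes))

  curves <- list()
  torques <- list()
  for (g in cfg$micro$gaps_nm) {
    say("[micro] gap %g nm", g)
    curves[[paste0("gap_", g, "nm")]] <-
      run_micro_simulation(fit$cone, ob$cell, ob$polymer, gap_nm = g,
                           n_steps = cfg$micro$n_steps,
                           total_displacement_um = cfg$micro$total_displacement_um,
                           mesh_set = mesh_set,
                           penalty_scale = cfg$contact$penalty_scale,
                           penetration_tol_rel = cfg$contact$penetration_tol_rel,
                           max_passes = cfg$micro$max_passes,
                           sampling = cfg$micro$stress_sampling)
    torques[[paste0("gap_", g, "nm")]] <-
      combine_torque(curves[[paste0("gap_", g, "nm")]], ob$macro, ob$rotations)
  }
  summary <- purrr::map_dfr(torques, glance) |>
    dplyr::mutate(fractured_volume_um3 =
                    purrr::map_dbl(curves, ~ max(.x$deleted_volume_um3)))
  say("[done] %.1f s elapsed", proc.time()[3] - t0)

  run <- structure(list(fit = fit, curves = curves, torques = torques,
                        summary = summary, config = cfg),
                   class = "retorq_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.retorq_run <- function(x, ...) {
  cat("<retorq_run>\n")
  print(x$fit)
  print(x$summary)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(run$config, file.path(out_dir, "config_echo.yml"))
  rr <- dplyr::bind_cols(tibble::tibble(mode = run$fit$mode), run$fit$achieved,
                         tibble::tibble(base_radius_um = run$fit$cone$base_radius_um,
                                        height_um = run$fit$cone$height_um))
  utils::write.csv(rr, file.path(out_dir, "roughness_report.csv"),
                   row.names = FALSE)
  for (nm in names(run$curves))
    write_fd_curve(run$curves[[nm]], file.path(out_dir, paste0("curve_", nm, ".csv")))
  for (nm in names(run$torques))
    write_torque_curve(run$torques[[nm]], file.path(out_dir, paste0("torque_", nm, ".csv")))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Generate canonical test inputs
#'
#' Writes the fixture inputs used by the verification suite: the canonical
#' meshes (`"meshes"`: single element, 2 x 2 x 2 block, cantilever, VTK and
#' MSH), flat and conical height maps (`"height_maps"`, commented CSV) and
#' synthetic linear force-displacement curves (`"linear_curves"`, CSV).
#'
#' @param kind One of `"meshes"`, `"height_maps"`, `"linear_curves"`.
#' @param destination Output directory (created if missing).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("meshes", "height_maps", "linear_curves"),
                              destination) {
  kind <- match.arg(kind)
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination)) stop("cannot create destination: ", destination)
  paths <- character()
  if (kind == "meshes") {
    specs <- list(single_element = build_fixture_mesh("single_element"),
                  block = build_fixture_mesh("block", c(2, 2, 2), c(2, 2, 2)),
                  cantilever = build_fixture_mesh("cantilever", c(10, 1, 1),
                                                  c(40, 4, 4)))
    for (nm in names(specs)) {
      p1 <- file.path(destination, paste0(nm, ".vtk"))
      p2 <- file.path(destination, paste0(nm, ".msh"))
      write_vtk(specs[[nm]]$mesh, p1)
      write_msh(specs[[nm]]$mesh, p2)
      paths <- c(paths, p1, p2)
    }
  } else if (kind == "height_maps") {
    flat <- height_map(matrix(0, 32, 32), dx_nm = 100)
    cone <- render_height_map(cone_feature(1, 1.2), unit_cell(), resolution = 64)
    p1 <- file.path(destination, "flat.csv")
    p2 <- file.path(destination, "cone.csv")
    write_height_map(flat, p1)
    write_height_map(cone, p2)
    paths <- c(p1, p2)
  } else {
    u <- seq(0, 3, by = 0.5)
    for (k in c(0.05, 0.2)) {
      df <- data.frame(step = seq_along(u) - 1, displacement_um = u,
                       force_mN = k * u, deleted_elements = 0L,
                       deleted_volume_um3 = 0)
      p <- file.path(destination, sprintf("linear_k%03.0f.csv", k * 1000))
      utils::write.csv(df, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  paths
}
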