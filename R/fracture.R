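#' Delete elements whose von Mises stress reached yield
#'
#' Fracture of the embedding polymer is modelled as element death: every
#' active element whose von Mises equivalent stress has reached the yield
#' strength is deactivated (criterion `>=`, simultaneous deletion of all
#' offending elements in one pass).
#'
#' @param mesh A [hex_mesh()].
#' @param vm_mpa Per-element von Mises stress, MPa (`NA` for inactive
#'   elements, as returned by [von_mises_field()]).
#' @param yield_mpa Deletion threshold, MPa.
#' @return A list with `mesh` (updated activity), `deleted` (indices
#'   deactivated in this pass) and `n_deleted`.
#' @export
delete_yielded_elements <- function(mesh, vm_mpa, yield_mpa) {
  stopifnot(inherits(mesh, "hex_mesh"), length(vm_mpa) == nrow(mesh$elems),
            yield_mpa > 0)
  del <- which(mesh$active & !is.na(vm_mpa) & vm_mpa >= yield_mpa)
  list(mesh = deactivate_elements(mesh, del), deleted = del,
       n_deleted = length(del))
}

#' Volume removed by fracture
#'
#' Initial volume minus current active volume of the mesh.
#'
#' @param mesh A [hex_mesh()].
#' @return Fractured volume, cubic micrometres.
#' @export
fractured_volume <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  sum(mesh$elem_vol[!mesh$active])
}

#' Generic stepped loading with element death
#'
#' The inner engine shared by the micro contact simulation and the
#' verification fixtures: the load is raised in `n_steps` equal increments;
#' after each solve, elements at or above the yield stress are deleted and
#' the same load level is re-solved until a pass deletes nothing (fracture
#' equilibrium) or `max_passes` is hit.
#'
#' @param sys A [fem_system()].
#' @param solver Function `(sys, fraction)` returning a `solve_state` at the
#'   given load fraction (0, 1].
#' @param n_steps Number of outer load increments.
#' @param yield_mpa Deletion threshold, MPa (defaults to the system
#'   material's yield strength).
#' @param max_passes Inner fracture-loop cap per step.
#' @param sampling Stress sampling for the criterion, see
#'   [von_mises_field()].
#' @param record Function `(sys, state, fraction)` returning a named list of
#'   extra columns to record per step (optional).
#' @return A tibble with one row per step (plus the zero-load row): `step`,
#'   `fraction`, `force_mN` (reaction along +x), `deleted_elements`
#'   (cumulative), `deleted_volume_um3`, `max_vm_mpa`,
#'   `fracture_converged`, plus any `record` columns. The final system is
#'   attached as attribute `"sys"`.
#' @export
run_fracture_steps <- function(sys, solver, n_steps = 6, yield_mpa = NULL,
                               max_passes = 30, sampling = "mean",
                               record = NULL) {
  stopifnot(inherits(sys, "fem_system"), n_steps >= 1)
  if (is.null(yield_mpa)) yield_mpa <- sys$material$yield_strength_mpa
  rows <- vector("list", n_steps + 1)
  rows[[1]] <- tibble::tibble(step = 0L, fraction = 0, force_mN = 0,
                              deleted_elements = sum(!sys$mesh$active),
                              deleted_volume_um3 = fractured_volume(sys$mesh),
                              max_vm_mpa = 0, fracture_converged = TRUE)
  for (s in seq_len(n_steps)) {
    frac <- s / n_steps
    conv <- FALSE
    for (pass in seq_len(max_passes)) {
      state <- solver(sys, frac)
      vm <- von_mises_field(state, sys, sampling = sampling)
      res <- delete_yielded_elements(sys$mesh, vm, yield_mpa)
      if (res$n_deleted == 0) { conv <- TRUE; break }
      sys$mesh <- res$mesh
      sys <- rebuild_dofmap(sys)
    }
    if (!conv)
      warning(sprintf("fracture loop cap (%d passes) reached at step %d", max_passes, s))
    row <- tibble::tibble(step = s, fraction = frac,
                          force_mN = reaction_force(state, c(1, 0, 0)),
                          deleted_elements = sum(!sys$mesh$active),
                          deleted_volume_um3 = fractured_volume(sys$mesh),
                          max_vm_mpa = max(c(vm[sys$mesh$active], 0), na.rm = TRUE),
                          fracture_converged = conv)
    if (!is.null(record))
      row <- dplyr::bind_cols(row, tibble::as_tibble(record(sys, state, frac)))
    rows[[s + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sys") <- sys
  out
}

#' Micro unit-cell simulation for one gap size
#'
#' Drives the unit-cell fracture simulation: the rigid implant surface
#' feature, offset by the interfacial gap, is displaced parallel to the
#' interface in equal increments; at each increment the frictionless contact
#' problem is solved, yielded elements are deleted and the step re-solved
#' until no further fractures occur, and the post-fracture reaction force in
#' the displacement direction is recorded together with the removed volume.
#'
#' @param cone A [cone_feature()] (typically from [fit_cone()]).
#' @param cell A [unit_cell()].
#' @param mat A [material()] for the embedding polymer.
#' @param gap_nm Interfacial gap, nm.
#' @param n_steps Number of displacement increments (default 30; increments
#'   should stay below the element size so fracture progresses gradually).
#' @param total_displacement_um Total master displacement, micrometres
#'   (default 0.6: spans the tangential engagement `gap / sin(flank angle)`
#'   of the largest bench gap plus the fracture transient).
#' @param target_elem_size_um Mesh resolution passed to
#'   [build_unit_cell_mesh()].
#' @param mesh_set Optionally a prebuilt `list(mesh, sets)` to reuse across
#'   gap sizes.
#' @param penalty_scale,penetration_tol_rel,max_passes,sampling Solver
#'   controls, see [solve_contact()] and [run_fracture_steps()].
#' @return A `fd_curve`: tibble with columns `step`, `displacement_um`,
#'   `force_mN`, `deleted_elements`, `deleted_volume_um3`, `max_vm_mpa`,
#'   `fracture_converged`; attributes `gap_nm`, `cone`, `cell` and the final
#'   `sys`.
#' @examples
#' \donttest{
#' cone <- cone_feature(1.2, 1.5)
#' curve <- run_micro_simulation(cone, unit_cell(substrate_depth_um = 3),
#'                               material(), gap_nm = 10,
#'                               target_elem_size_um = 0.8)
#' }
#' @export
run_micro_simulation <- function(cone, cell, mat, gap_nm,
                                 n_steps = 30, total_displacement_um = 0.6,
                                 target_elem_size_um = 0.4, mesh_set = NULL,
                                 penalty_scale = 100,
                                 penetration_tol_rel = 1e-3,
                                 max_passes = 30, sampling = "mean") {
  stopifnot(gap_nm >= 0)
  if (is.null(total_displacement_um)) total_displacement_um <- 0.6
  stopifnot(total_displacement_um > 0)
  if (is.null(mesh_set))
    mesh_set <- build_unit_cell_mesh(cone, cell, target_elem_size_um)
  surface <- offset_surface(cone, cell, gap_nm = gap_nm)
  bc <- bc_unit_cell(mesh_set$mesh, mesh_set$sets)
  sys <- fem_system(mesh_set$mesh, mat, bc)

  solver <- function(sys, fraction) {
    solve_contact(sys, surface, master_displacement_um =
                    fraction * total_displacement_um,
                  penalty_scale = penalty_scale,
                  penetration_tol_rel = penetration_tol_rel)
  }
  out <- run_fracture_steps(sys, solver, n_steps = n_steps,
                            yield_mpa = mat$yield_strength_mpa,
                            max_passes = max_passes, sampling = sampling)
  out$displacement_um <- out$fraction * total_displacement_um
  out <- dplyr::relocate(out, "step", "displacement_um")
  attr(out, "gap_nm") <- gap_nm
  attr(out, "cone") <- cone
  attr(out, "cell") <- cell
  class(out) <- c("fd_curve", class(out))
  out
}

#' Micro simulations over a gap sweep
#'
#' Runs [run_micro_simulation()] for each gap size, reusing one mesh; the
#' interfacial gap only enters through the offset of the rigid master
#' surface.
#'
#' @inheritParams run_micro_simulation
#' @param gaps_nm Gap sizes, nm (default the bench sweep 10, 50, 100,
#'   150 nm).
#' @return A named list of `fd_curve` objects, one per gap.
#' @export
run_gap_sweep <- function(cone, cell, mat, gaps_nm = c(10, 50, 100, 150),
                          n_steps = 30, total_displacement_um = 0.6,
                          target_elem_size_um = 0.4, ...) {
  mesh_set <- build_unit_cell_mesh(cone, cell, target_elem_size_um)
  curves <- lapply(gaps_nm, function(g)
    run_micro_simulation(cone, cell, mat, gap_nm = g, n_steps = n_steps,
                         total_displacement_um = total_displacement_um,
                         mesh_set = mesh_set, ...))
  names(curves) <- paste0("gap_", gaps_nm, "nm")
  curves
}

#' Summaries of a force-displacement curve
#'
#' @param x A `fd_curve` from [run_micro_simulation()].
#' @param ... Unused.
#' @return One-row tibble: gap, peak force and its displacement, final
#'   deleted volume and element count.
#' @method glance fd_curve
#' @export
glance.fd_curve <- function(x, ...) {
  i <- which.max(x$force_mN)
  tibble::tibble(gap_nm = attr(x, "gap_nm"),
                 peak_force_mN = x$force_mN[i],
                 peak_displacement_um = x$displacement_um[i],
                 deleted_volume_um3 = max(x$deleted_volume_um3),
                 deleted_elements = max(x$deleted_elements))
}

#' Write a force-displacement curve as CSV
#'
#' Unit-bearing column headers; the gap size is recorded in a `#` comment
#' line.
#'
#' @param curve A `fd_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fd_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# retorq force-displacement curve, gap_nm: %g",
                     attr(curve, "gap_nm") %||% NA), con)
  utils::write.csv(as.data.frame(curve)[, c("step", "displacement_um",
                                            "force_mN", "deleted_elements",
                                            "deleted_volume_um3")],
                   con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
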