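pmat <- material()

test_that("the deletion criterion is 'reached' (>=) and acts per pass", {
  blk <- build_fixture_mesh("block", c(2, 2, 2), c(2, 2, 2))$mesh
  res <- delete_yielded_elements(blk, rep(30, 8), 40)
  expect_equal(res$n_deleted, 0L)
  res <- delete_yielded_elements(blk, rep(50, 8), 40)
  expect_equal(res$n_deleted, 8L)
  m3 <- build_fixture_mesh("block", c(3, 1, 1), c(3, 1, 1))$mesh
  res <- delete_yielded_elements(m3, c(39.9, 40.0, 40.1), 40)
  expect_equal(res$n_deleted, 2L)
  expect_setequal(res$deleted, c(2L, 3L))
  # already-inactive elements are not deleted again
  res2 <- delete_yielded_elements(res$mesh, c(50, 50, 50), 40)
  expect_equal(res2$deleted, 1L)
})

test_that("stepped uniaxial stretching deletes the element when E*eps reaches yield", {
  # 6 steps to 1.8 % strain: E*eps crosses 40 MPa at step 4 (1.2 % -> 45.12)
  fx <- build_fixture_mesh("single_element")
  n <- fx$mesh$nodes
  presc <- rbind(
    data.frame(node = which(n[, 1] == 0), comp = 1, value_um = 0),
    data.frame(node = which(n[, 1] == 1), comp = 1, value_um = 0.018),
    data.frame(node = which(n[, 2] == 0), comp = 2, value_um = 0),
    data.frame(node = which(n[, 3] == 0), comp = 3, value_um = 0))
  sys <- fem_system(fx$mesh, pmat, bc_spec(prescribed = presc))
  axial_dofs <- 3 * (which(n[, 1] == 1) - 1) + 1
  out <- run_fracture_steps(
    sys, function(s, f) solve_displacement(s, scale = f), n_steps = 6,
    record = function(s, st, f) list(axial_mN = sum(st$fint[axial_dofs]) * 1e3))
  expect_equal(out$deleted_elements, c(0, 0, 0, 0, 1, 1, 1))
  # Hooke's law before deletion: F = E * eps * A (1 um^2 cross-section);
  # the zero-load row carries no recorded extras
  eps <- 0.018 * out$fraction[2:4]
  expect_equal(out$axial_mN[2:4], 3.76e9 * eps * 1e-12 * 1e3, tolerance = 1e-9)
  expect_equal(out$axial_mN[5:7], rep(0, 3))
  expect_equal(out$deleted_volume_um3[7], 1)
})

micro_fixture <- function() {
  cell <- unit_cell(substrate_depth_um = 4)
  cone <- cone_feature(1.3, 1.8)
  list(cell = cell, cone = cone,
       ms = build_unit_cell_mesh(cone, cell, 0.65))
}

test_that("element removal never stiffens the structure (softening)", {
  fx <- micro_fixture()
  surf <- offset_surface(fx$cone, fx$cell, gap_nm = 10)
  sys <- fem_system(fx$ms$mesh, pmat, bc_unit_cell(fx$ms$mesh, fx$ms$sets))
  st <- solve_contact(sys, surf, 0.08)
  f_before <- reaction_force(st)
  vm <- von_mises_field(st, sys)
  res <- delete_yielded_elements(sys$mesh, vm, pmat$yield_strength_mpa)
  expect_gt(res$n_deleted, 0)
  sys$mesh <- res$mesh
  sys <- retorq:::rebuild_dofmap(sys)
  f_after <- reaction_force(solve_contact(sys, surf, 0.08))
  expect_lte(f_after, f_before + 1e-9)
})

test_that("first deletions localise at the contact flank", {
  fx <- micro_fixture()
  surf <- offset_surface(fx$cone, fx$cell, gap_nm = 10)
  sys <- fem_system(fx$ms$mesh, pmat, bc_unit_cell(fx$ms$mesh, fx$ms$sets))
  st <- solve_contact(sys, surf, 0.08)
  vm <- von_mises_field(st, sys)
  res <- delete_yielded_elements(sys$mesh, vm, pmat$yield_strength_mpa)
  centroid_d <- vapply(seq_len(nrow(sys$mesh$elems)), function(e) {
    surf$sdf(rbind(colMeans(sys$mesh$nodes[sys$mesh$elems[e, ], ])),
             shift_um = 0.08)$d_um
  }, numeric(1))
  # every first-pass deletion lies within the nearest-to-surface third
  expect_lte(max(centroid_d[res$deleted]),
             stats::quantile(centroid_d, 1 / 3))
})

test_that("micro simulation curves satisfy their invariants deterministically", {
  fx <- micro_fixture()
  run <- function() run_micro_simulation(fx$cone, fx$cell, pmat, gap_nm = 20,
                                         n_steps = 5,
                                         total_displacement_um = 0.25,
                                         mesh_set = fx$ms)
  cv <- run()
  expect_true(all(diff(cv$displacement_um) > 0))
  expect_equal(cv$displacement_um[1], 0)
  expect_equal(cv$force_mN[1], 0)
  expect_true(all(diff(cv$deleted_elements) >= 0))
  expect_true(all(diff(cv$deleted_volume_um3) >= 0))
  expect_gt(max(cv$deleted_elements), 0)
  sys <- attr(cv, "sys")
  expect_equal(fractured_volume(sys$mesh),
               mesh_volume(sys$mesh, active_only = FALSE) -
                 mesh_volume(sys$mesh),
               tolerance = 1e-12)
  # no randomness anywhere in the pipeline: repeat runs are bit-identical
  cv2 <- run()
  expect_identical(cv$force_mN, cv2$force_mN)
  expect_identical(cv$deleted_volume_um3, cv2$deleted_volume_um3)
})

test_that("curves survive the CSV round trip with their gap annotation", {
  fx <- micro_fixture()
  cv <- run_micro_simulation(fx$cone, fx$cell, pmat, gap_nm = 20, n_steps = 2,
                             total_displacement_um = 0.1, mesh_set = fx$ms)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fd_curve(cv, path)
  expect_match(readLines(path, n = 1), "gap_nm: 20")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$force_mN, cv$force_mN, tolerance = 1e-12)
  g <- glance(cv)
  expect_equal(g$gap_nm, 20)
  expect_equal(g$peak_force_mN, max(cv$force_mN))
})
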