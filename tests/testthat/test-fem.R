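pmat <- material()

distorted_hex <- function(seed = 3, scale = 0.2) {
  set.seed(seed)
  fx <- build_fixture_mesh("single_element")$mesh
  fx$nodes[fx$elems[1, ], ] + matrix(runif(24, -scale, scale), 8, 3)
}

test_that("element stiffness is symmetric with a six-dimensional nullspace", {
  coords <- distorted_hex()
  K <- hex_element_stiffness(coords, pmat)
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-12)

  cm <- coords * 1e-6
  trans <- cbind(rep(c(1, 0, 0), 8), rep(c(0, 1, 0), 8), rep(c(0, 0, 1), 8))
  rot <- sapply(list(c(1, 2), c(2, 3), c(3, 1)), function(ax) {
    m <- matrix(0, 8, 3)
    m[, ax[1]] <- -cm[, ax[2]]
    m[, ax[2]] <- cm[, ax[1]]
    as.vector(t(m))
  })
  modes <- cbind(trans, rot)
  expect_lt(max(abs(K %*% modes)) / max(abs(K)), 1e-9)
  # and exactly six: eigenvalue 7 from the bottom is well separated from zero
  ev <- sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(ev[6]) / ev[24], 1e-9)
  expect_gt(ev[7] / ev[24], 1e-6)
})

test_that("element stiffness matches the Hessian of an independent strain energy", {
  coords <- distorted_hex(seed = 8)
  K <- hex_element_stiffness(coords, pmat)
  D <- retorq:::elasticity_matrix(pmat)
  cm <- coords * 1e-6
  a <- 1e-8
  W <- function(u) numeric_strain_energy(cm, u, D)
  w1 <- vapply(1:24, function(i) W(a * (seq_len(24) == i)), numeric(1))
  H <- matrix(0, 24, 24)
  for (i in 1:24) for (j in i:24) {
    wij <- W(a * ((seq_len(24) == i) + (seq_len(24) == j)))
    H[i, j] <- H[j, i] <- (wij - w1[i] - w1[j]) / a^2
  }
  expect_equal(H, K, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("global assembly matches a dense hand-assembled two-element patch", {
  fx <- build_fixture_mesh("block", c(2, 1, 1), c(2, 1, 1))
  sys <- fem_system(fx$mesh, pmat, bc_spec())   # unconstrained
  asm <- retorq:::assemble_reduced(sys, 0)
  Kd <- matrix(0, 36, 36)
  for (e in 1:2) {
    en <- fx$mesh$elems[e, ]
    dofs <- as.vector(t(cbind(3 * (en - 1) + 1, 3 * (en - 1) + 2, 3 * en)))
    Kd[dofs, dofs] <- Kd[dofs, dofs] +
      hex_element_stiffness(fx$mesh$nodes[en, ], pmat)
  }
  # eq map is the identity here up to ordering
  perm <- sys$eq
  expect_equal(as.matrix(asm$K)[perm, perm], Kd, tolerance = 1e-12,
               ignore_attr = TRUE)

  sys2 <- sys
  sys2$mesh <- deactivate_elements(sys2$mesh, 1:2)
  sys2 <- retorq:::rebuild_dofmap(sys2)
  expect_equal(sys2$n_eq, 0L)
})

test_that("constraint handling: fixed, tied and normal-fixed components", {
  fx <- build_fixture_mesh("block", c(2, 2, 2), c(2, 2, 2))
  all_fixed <- fem_system(fx$mesh, pmat,
                          bc_spec(fixed_nodes = seq_len(nrow(fx$mesh$nodes))))
  expect_equal(all_fixed$n_eq, 0L)

  bc <- bc_unit_cell(fx$mesh, fx$sets)
  sys <- fem_system(fx$mesh, pmat, bc)
  # tied pairs share equations in every component
  for (r in seq_len(nrow(bc$ties))) {
    ds <- 3 * (bc$ties[r, 1] - 1) + 1:3
    dm <- 3 * (bc$ties[r, 2] - 1) + 1:3
    expect_identical(sys$eq[ds], sys$eq[dm])
  }
  # y faces have their normal component eliminated
  expect_true(all(sys$eq[3 * (fx$sets$side_y_min - 1) + 2] == 0L))
  # constrained operator is positive definite
  K <- as.matrix(retorq:::assemble_reduced(sys, 0)$K)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("patch tests reproduce affine states exactly", {
  A <- matrix(c(8e-4, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 4e-4, 6e-4), 3, 3)
  for (div in list(c(1, 1, 1), c(2, 2, 2))) {
    fx <- build_fixture_mesh("block", c(2, 2, 2), div)
    n <- fx$mesh$nodes
    bnd <- which(apply(n, 1, function(p) any(p == 0 | p == 2)))
    vals <- n[bnd, , drop = FALSE] %*% t(A)
    presc <- data.frame(node = rep(bnd, 3), comp = rep(1:3, each = length(bnd)),
                        value_um = as.vector(vals))
    sys <- fem_system(fx$mesh, pmat, bc_spec(prescribed = presc))
    st <- solve_displacement(sys)
    uexp <- as.vector(t(n %*% t(A))) * 1e-6
    expect_lt(max(abs(st$u_m - uexp)) / max(abs(uexp)), 1e-9)
    vm <- von_mises_field(st, sys)
    expect_lt(diff(range(vm)) / mean(vm), 1e-9)
  }
})

uniaxial_system <- function(strain, mat = pmat) {
  fx <- build_fixture_mesh("single_element")
  n <- fx$mesh$nodes
  presc <- rbind(
    data.frame(node = which(n[, 1] == 0), comp = 1, value_um = 0),
    data.frame(node = which(n[, 1] == 1), comp = 1, value_um = strain),
    data.frame(node = which(n[, 2] == 0), comp = 2, value_um = 0),
    data.frame(node = which(n[, 3] == 0), comp = 3, value_um = 0))
  fem_system(fx$mesh, mat, bc_spec(prescribed = presc))
}

test_that("uniaxial stress equals E times strain", {
  st <- solve_displacement(uniaxial_system(0.01))    # 1 % strain
  vm <- von_mises_field(st, uniaxial_system(0.01))
  expect_equal(vm, 37.6, tolerance = 1e-9)           # below the 40 MPa yield
  vm2 <- von_mises_field(solve_displacement(uniaxial_system(0.011)),
                         uniaxial_system(0.011))
  expect_equal(vm2, 41.36, tolerance = 1e-9)         # above yield
})

test_that("von Mises invariant algebra", {
  vm_of <- function(s) sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 +
                                     (s[3] - s[1])^2) + 3 * sum(s[4:6]^2))
  expect_equal(vm_of(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(vm_of(c(5, 5, 5, 0, 0, 0)), 0)
  expect_equal(vm_of(c(0, 0, 0, 3, 0, 0)), sqrt(3) * 3)
})

test_that("cantilever tip deflection approaches the beam prediction", {
  fx <- build_fixture_mesh("cantilever", c(10, 1, 1), c(40, 4, 4))
  n <- fx$mesh$nodes
  tip <- which(n[, 1] == 10)
  P <- 1e-6
  f_ext <- numeric(3 * nrow(n))
  f_ext[3 * (tip - 1) + 3] <- P / length(tip)
  sys <- fem_system(fx$mesh, pmat, bc_spec(fixed_nodes = which(n[, 1] == 0)),
                    f_ext = f_ext)
  st <- solve_displacement(sys)
  tipw <- mean(st$u_m[3 * (tip - 1) + 3])
  E <- pmat$elastic_modulus_gpa * 1e9
  I <- 1e-6 * (1e-6)^3 / 12
  delta <- P * (10e-6)^3 / (3 * E * I)
  # shear deformation and the distributed tip load keep this at ~4 %
  expect_lt(abs(tipw - delta) / delta, 0.10)
})

# plane-like contact fixture: a very large cone whose flank cuts past the
# x = 0 edge of a small block, moving towards it as the master advances
contact_fixture <- function(divisions = c(3, 3, 2)) {
  fx <- build_fixture_mesh("block", c(2, 2, 1), divisions)
  cell <- unit_cell(width_um = 1000, length_um = 4, substrate_depth_um = 300)
  cone <- cone_feature(200, 200, apex_um = c(-200.2, 1))
  # the block's top face lies on the base plane; the gap keeps it clear so
  # that only the advancing flank makes contact
  surf <- offset_surface(cone, cell, gap_nm = 100, periodic_x = FALSE)
  n <- fx$mesh$nodes
  sys <- fem_system(fx$mesh, pmat,
                    bc_spec(fixed_nodes = which(n[, 3] == 1)))
  list(sys = sys, surf = surf, mesh = fx$mesh)
}

test_that("contact at zero master displacement is inactive", {
  cf <- contact_fixture()
  st <- solve_contact(cf$sys, cf$surf, 0)
  expect_equal(max(abs(st$u_m)), 0)
  expect_equal(reaction_force(st), 0)
  expect_equal(reaction_force(st, c(0, 1, 0)), 0)
})

test_that("contact solution matches the exhaustive dense active-set oracle", {
  cf <- contact_fixture()
  sys <- cf$sys
  expect_lte(sys$n_eq, 200)
  st <- solve_contact(sys, cf$surf, 0.5)
  expect_gt(length(st$contact_nodes), 0)

  # enumerate all subsets of the near-surface candidates for the gap
  # linearised at the converged configuration; the package fixed point must
  # be the unique complementarity-consistent solution
  u <- matrix(st$u_m, ncol = 3, byrow = TRUE)
  pts <- cf$mesh$nodes + u * 1e6
  free <- matrix(sys$eq, ncol = 3, byrow = TRUE)
  cand <- which(rowSums(free > 0) > 0)
  sd <- cf$surf$sdf(pts[cand, ], shift_um = 0.5)
  near <- which(sd$d_um < 0.05)
  expect_true(all(match(st$contact_nodes, cand[near], nomatch = 0L) > 0L))
  expect_lte(length(near), 14)
  g0 <- vapply(seq_along(near), function(i) {
    j <- near[i]
    d <- 3 * (cand[j] - 1) + 1:3
    r <- sys$eq[d]
    ok <- r > 0
    sd$d_um[j] * 1e-6 - sum(sd$normal[j, ok] * st$u_m[d[ok]])
  }, numeric(1))
  Kd <- as.matrix(retorq:::assemble_reduced(sys, 0)$K)
  orc <- dense_contact_oracle(Kd, sys$eq, cand[near], g0,
                              sd$normal[near, , drop = FALSE],
                              st$kappa_n_per_m)
  expect_false(is.null(orc))
  u_pkg <- numeric(sys$n_eq)
  has <- sys$eq > 0
  u_pkg[sys$eq[has]] <- st$u_m[has]
  # penalty stiffness costs ~2 digits of conditioning between the two paths
  expect_equal(u_pkg, orc$u, tolerance = 1e-6, ignore_attr = TRUE)
  expect_setequal(match(st$contact_nodes, cand[near]), orc$active)
})

test_that("reaction force satisfies global equilibrium", {
  cf <- contact_fixture()
  st <- solve_contact(cf$sys, cf$surf, 0.5)
  resid <- st$fint - st$f_contact
  # free equations carry no residual
  has <- cf$sys$eq > 0
  agg <- rowsum(resid[has], cf$sys$eq[has])
  expect_lt(max(abs(agg)) / max(abs(st$f_contact)), 1e-8)
  # support reactions balance the contact resultant, so the reaction force
  # equals minus the summed residuals of the constrained components
  rx <- sum(resid[seq(1, length(resid), by = 3)])
  expect_equal(reaction_force(st, c(1, 0, 0)), -rx * 1e3, tolerance = 1e-8)
  expect_equal(rx, st$master_force_n[1], tolerance = 1e-12)
})

test_that("reaction force is insensitive to the penalty stiffness", {
  cf <- contact_fixture()
  f1 <- reaction_force(solve_contact(cf$sys, cf$surf, 0.5, penalty_scale = 100))
  f2 <- reaction_force(solve_contact(cf$sys, cf$surf, 0.5, penalty_scale = 1000))
  expect_lt(abs(f2 - f1) / abs(f1), 0.01)
})

test_that("solving with no active elements returns a quiescent state", {
  cf <- contact_fixture()
  sys <- cf$sys
  sys$mesh <- deactivate_elements(sys$mesh, seq_len(nrow(sys$mesh$elems)))
  sys <- retorq:::rebuild_dofmap(sys)
  st <- solve_contact(sys, cf$surf, 0.5)
  expect_equal(reaction_force(st), 0)
})
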