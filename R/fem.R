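#' Linear-elastic material
#'
#' Homogeneous isotropic linear-elastic solid with a von Mises fracture
#' threshold. Defaults are the embedding polymer of the removal-torque bench
#' model; `material_titanium()` returns the grade IV titanium constants kept
#' for the deformable-feature option.
#'
#' @param elastic_modulus_gpa Young's modulus, GPa.
#' @param poisson_ratio Poisson's ratio (0 <= nu < 0.5).
#' @param yield_strength_mpa Yield strength used as the element-deletion
#'   threshold, MPa.
#' @return An object of class `material`.
#' @export
material <- function(elastic_modulus_gpa = 3.76, poisson_ratio = 0.34,
                     yield_strength_mpa = 40) {
  stopifnot(elastic_modulus_gpa > 0, poisson_ratio >= 0, poisson_ratio < 0.5,
            yield_strength_mpa > 0)
  structure(list(elastic_modulus_gpa = elastic_modulus_gpa,
                 poisson_ratio = poisson_ratio,
                 yield_strength_mpa = yield_strength_mpa),
            class = "material")
}

#' @rdname material
#' @export
material_titanium <- function() material(113, 0.32, 800)

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> E = %g GPa, nu = %g, yield = %g MPa\n",
              x$elastic_modulus_gpa, x$poisson_ratio, x$yield_strength_mpa))
  invisible(x)
}

# 6x6 isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx),
# engineering shear strains; Pa
elasticity_matrix <- function(mat) {
  E <- mat$elastic_modulus_gpa * 1e9
  nu <- mat$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) from shape-function gradients G (3 x 8)
b_matrix <- function(G) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- G[1, ]; B[2, ix + 1] <- G[2, ]; B[3, ix + 2] <- G[3, ]
  B[4, ix] <- G[2, ]; B[4, ix + 1] <- G[1, ]
  B[5, ix + 1] <- G[3, ]; B[5, ix + 2] <- G[2, ]
  B[6, ix] <- G[3, ]; B[6, ix + 2] <- G[1, ]
  B
}

# stiffness, volume and volume-averaged B for one element; coords in metres
hex_element_matrices <- function(coords_m, D) {
  Ke <- matrix(0, 24, 24)
  Bsum <- matrix(0, 6, 24)
  vol <- 0
  for (q in seq_len(8)) {
    dN <- hex_dN_gauss[[q]]
    J <- dN %*% coords_m
    detJ <- det(J)
    if (detJ <= 0) stop("inverted element (non-positive Jacobian)")
    B <- b_matrix(solve(J, dN))
    Ke <- Ke + crossprod(B, D %*% B) * detJ
    Bsum <- Bsum + B * detJ
    vol <- vol + detJ
  }
  list(Ke = Ke, Bbar = Bsum / vol, vol = vol)
}

#' Stiffness matrix of one 8-node hexahedron
#'
#' Standard isoparametric first-order hexahedral stiffness with 2 x 2 x 2
#' Gauss quadrature. Degrees of freedom are node-major (x, y, z per node in
#' element node order).
#'
#' @param coords_um 8 x 3 matrix of corner coordinates, micrometres, standard
#'   hexahedron ordering.
#' @param mat A [material()].
#' @return Symmetric 24 x 24 stiffness matrix, N/m.
#' @export
hex_element_stiffness <- function(coords_um, mat) {
  hex_element_matrices(as.matrix(coords_um) * 1e-6, elasticity_matrix(mat))$Ke
}

# ---- boundary conditions ---------------------------------------------------

#' Boundary-condition specification
#'
#' @param fixed_nodes Nodes fixed in all three components.
#' @param normal_fixed List of `list(nodes, comp)` entries fixing a single
#'   component (1 = x, 2 = y, 3 = z) of the given nodes.
#' @param ties Two-column matrix of node pairs `(slave, master)` tied in all
#'   components (exact continuity by master-slave elimination).
#' @param prescribed Data frame with columns `node`, `comp`, `value_um`
#'   prescribing non-zero displacement components (used by the verification
#'   fixtures; the contact solver drives the master surface instead).
#' @return An object of class `bc_spec`.
#' @export
bc_spec <- function(fixed_nodes = integer(), normal_fixed = list(),
                    ties = NULL, prescribed = NULL) {
  if (!is.null(ties)) {
    ties <- matrix(as.integer(ties), ncol = 2)
  }
  if (!is.null(prescribed))
    stopifnot(all(c("node", "comp", "value_um") %in% names(prescribed)))
  structure(list(fixed_nodes = as.integer(fixed_nodes),
                 normal_fixed = normal_fixed, ties = ties,
                 prescribed = prescribed),
            class = "bc_spec")
}

#' Unit-cell boundary conditions
#'
#' The micro-model conditions: bottom surface fixed in all directions, the
#' two faces normal to the enforced (x) direction made continuous by tying
#' constraints (periodic-style), and the faces normal to the transverse (y)
#' direction fixed in their normal component only. Tied pairs are matched
#' geometrically and verified.
#'
#' @param mesh A [hex_mesh()].
#' @param sets Node sets from [build_unit_cell_mesh()].
#' @return A [bc_spec()].
#' @export
bc_unit_cell <- function(mesh, sets) {
  xmin <- sets$side_x_min
  xmax <- sets$side_x_max
  stopifnot(length(xmin) == length(xmax))
  # pair by (y, z) coordinates
  key <- function(idx) order(round(mesh$nodes[idx, 2], 9), round(mesh$nodes[idx, 3], 9))
  xmin <- xmin[key(xmin)]
  xmax <- xmax[key(xmax)]
  mism <- abs(mesh$nodes[xmin, 2:3] - mesh$nodes[xmax, 2:3])
  if (max(mism) > 1e-8)
    stop("tied side faces are not geometrically matched")
  bc_spec(fixed_nodes = sets$bottom,
          normal_fixed = list(list(nodes = sets$side_y_min, comp = 2L),
                              list(nodes = sets$side_y_max, comp = 2L)),
          ties = cbind(xmax, xmin))
}

# ---- assembled system ------------------------------------------------------

#' Assemble the finite-element system
#'
#' Precomputes element stiffness matrices (SI units internally), the global
#' triplet layout and the constrained degree-of-freedom map for the given
#' boundary conditions. Inactive (deleted) elements are excluded at solve
#' time; nodes left without any active element are fully constrained.
#'
#' @param mesh A [hex_mesh()].
#' @param mat A [material()].
#' @param bc A [bc_spec()].
#' @param f_ext Optional full-length external nodal force vector
#'   (3 * n_nodes, newtons, node-major x,y,z).
#' @return An object of class `fem_system`.
#' @export
fem_system <- function(mesh, mat, bc, f_ext = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(mat, "material"),
            inherits(bc, "bc_spec"))
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  ndof <- 3L * nn
  D <- elasticity_matrix(mat)
  nodes_m <- mesh$nodes * 1e-6

  KX <- matrix(0, 576, ne)
  Bbar <- matrix(0, 144, ne)
  vol_m3 <- numeric(ne)
  edof <- matrix(0L, 24, ne)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    m <- hex_element_matrices(nodes_m[en, ], D)
    KX[, e] <- m$Ke
    Bbar[, e] <- m$Bbar
    vol_m3[e] <- m$vol
    edof[, e] <- as.integer(rep(3L * (en - 1L), each = 3L) + 1:3)
  }
  trip_i <- as.integer(edof[rep(1:24, times = 24), ])
  trip_j <- as.integer(edof[rep(1:24, each = 24), ])

  if (is.null(f_ext)) f_ext <- numeric(ndof)
  stopifnot(length(f_ext) == ndof)

  sys <- structure(list(mesh = mesh, material = mat, bc = bc,
                        ndof = ndof, n_nodes = nn, n_elems = ne,
                        KX = KX, Bbar = Bbar, vol_m3 = vol_m3,
                        trip_i = trip_i, trip_j = trip_j, edof = edof,
                        f_ext = f_ext,
                        eq = NULL, n_eq = 0L, u_presc = NULL),
                   class = "fem_system")
  rebuild_dofmap(sys)
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("<fem_system> %d nodes, %d elements (%d active), %d unknowns\n",
              x$n_nodes, x$n_elems, sum(x$mesh$active), x$n_eq))
  invisible(x)
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Nodes of active elements whose connected component (elements joined through
# shared nodes, ties counting as shared) has no path to the fixed support.
# Such debris islands would make the stiffness singular; their dofs are
# frozen, and any stress the moving master then builds in them deletes them
# through the ordinary yield criterion.
unsupported_nodes <- function(mesh, bc) {
  act <- which(mesh$active)
  if (length(act) == 0) return(integer())
  nn <- nrow(mesh$nodes)
  parent <- seq_len(nn)
  link <- function(a, b) {
    ra <- uf_find(parent, a); rb <- uf_find(parent, b)
    if (ra != rb) parent[ra] <<- rb
    invisible(NULL)
  }
  for (e in act) {
    en <- mesh$elems[e, ]
    for (k in 2:8) link(en[1], en[k])
  }
  if (!is.null(bc$ties)) for (r in seq_len(nrow(bc$ties)))
    link(bc$ties[r, 1], bc$ties[r, 2])
  roots <- vapply(seq_len(nn), function(i) uf_find(parent, i), integer(1))
  supported_roots <- unique(roots[bc$fixed_nodes])
  attached_nodes <- unique(as.vector(mesh$elems[act, , drop = FALSE]))
  attached_nodes[!(roots[attached_nodes] %in% supported_roots)]
}

# Rebuild the dof -> equation map: fixed and normal-fixed components (and all
# components of detached or unsupported nodes) are eliminated, tied slave
# dofs share their master's equation. Prescribed dofs are eliminated with
# their value recorded.
rebuild_dofmap <- function(sys) {
  ndof <- sys$ndof
  bc <- sys$bc
  attached <- rep(FALSE, sys$n_nodes)
  attached[unique(as.vector(sys$mesh$elems[sys$mesh$active, , drop = FALSE]))] <- TRUE
  if (length(bc$fixed_nodes))
    attached[unsupported_nodes(sys$mesh, bc)] <- FALSE

  elim <- rep(FALSE, ndof)
  u_presc <- numeric(ndof)
  dof_of <- function(nodes, comp) 3L * (nodes - 1L) + comp
  for (c in 1:3) elim[dof_of(which(!attached), c)] <- TRUE
  for (c in 1:3) elim[dof_of(bc$fixed_nodes, c)] <- TRUE
  for (nf in bc$normal_fixed) elim[dof_of(nf$nodes, nf$comp)] <- TRUE
  if (!is.null(bc$prescribed)) {
    pd <- dof_of(bc$prescribed$node, bc$prescribed$comp)
    elim[pd] <- TRUE
    u_presc[pd] <- bc$prescribed$value_um * 1e-6
  }

  parent <- seq_len(ndof)
  if (!is.null(bc$ties)) {
    for (c in 1:3) {
      ds <- dof_of(bc$ties[, 1], c)
      dm <- dof_of(bc$ties[, 2], c)
      ok <- !elim[ds] & !elim[dm]
      parent[ds[ok]] <- dm[ok]
    }
  }
  root <- parent[parent]  # ties are one level deep; idempotent here
  eq <- integer(ndof)
  is_root <- !elim & root == seq_len(ndof)
  eq[is_root] <- seq_len(sum(is_root))
  slaves <- which(!elim & root != seq_len(ndof))
  eq[slaves] <- eq[root[slaves]]

  sys$eq <- eq
  sys$n_eq <- sum(is_root)
  sys$u_presc <- u_presc
  sys
}

# Reduced stiffness and right-hand side for the current element activity.
# scale: multiplier on the prescribed displacements.
assemble_reduced <- function(sys, scale = 1) {
  act <- rep(sys$mesh$active, each = 576L)
  eqi <- sys$eq[sys$trip_i]
  eqj <- sys$eq[sys$trip_j]
  x <- as.vector(sys$KX)
  keep <- act & eqi > 0L & eqj > 0L
  K <- Matrix::sparseMatrix(i = eqi[keep], j = eqj[keep], x = x[keep],
                            dims = c(sys$n_eq, sys$n_eq))
  K <- Matrix::forceSymmetric(K, uplo = "U")

  rhs <- rowsum_vector(sys$eq, sys$f_ext, sys$n_eq)
  if (scale != 0 && any(sys$u_presc != 0)) {
    up <- sys$u_presc[sys$trip_j] * scale
    k2 <- act & eqi > 0L & up != 0
    if (any(k2)) {
      contrib <- x[k2] * up[k2]
      rhs <- rhs - as.vector(Matrix::sparseMatrix(
        i = eqi[k2], j = rep(1L, sum(k2)), x = contrib, dims = c(sys$n_eq, 1L)))
    }
  }
  list(K = K, rhs = rhs)
}

# scatter-add a full-dof vector into equation space
rowsum_vector <- function(eq, v, n_eq) {
  keep <- eq > 0L & v != 0
  out <- numeric(n_eq)
  if (any(keep)) {
    s <- rowsum(v[keep], eq[keep])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# expand an equation-space solution to the full dof vector (metres)
expand_solution <- function(sys, u_red, scale = 1) {
  u <- sys$u_presc * scale
  has_eq <- sys$eq > 0L
  u[has_eq] <- u_red[sys$eq[has_eq]]
  u
}

# internal force vector K_active %*% u in the full dof space (newtons)
internal_forces <- function(sys, u_full) {
  act <- rep(sys$mesh$active, each = 576L)
  x <- as.vector(sys$KX)[act]
  i <- sys$trip_i[act]
  j <- sys$trip_j[act]
  f <- numeric(sys$ndof)
  s <- rowsum(x * u_full[j], i)
  f[as.integer(rownames(s))] <- s[, 1]
  f
}

#' Solve the constrained linear system under prescribed displacements
#'
#' Direct sparse Cholesky solve of the assembled system with the boundary
#' conditions of the `fem_system` (no contact). Used by the verification
#' fixtures (patch, uniaxial, cantilever tests).
#'
#' @param sys A [fem_system()].
#' @param scale Multiplier applied to the prescribed displacement values.
#' @return An object of class `solve_state`.
#' @export
solve_displacement <- function(sys, scale = 1) {
  asm <- assemble_reduced(sys, scale = scale)
  u_red <- if (sys$n_eq > 0) {
    as.vector(Matrix::solve(Matrix::Cholesky(asm$K, LDL = FALSE, perm = TRUE),
                            asm$rhs))
  } else numeric(0)
  u <- expand_solution(sys, u_red, scale = scale)
  new_solve_state(sys, u,
                  f_contact = numeric(sys$ndof),
                  contact_nodes = integer(),
                  master_force = c(0, 0, 0),
                  converged = TRUE, iterations = 1L, penetration_m = 0)
}

new_solve_state <- function(sys, u_full, f_contact, contact_nodes,
                            master_force, converged, iterations,
                            penetration_m, kappa = NA_real_) {
  structure(list(u_m = u_full, f_contact = f_contact,
                 contact_nodes = contact_nodes, master_force_n = master_force,
                 fint = internal_forces(sys, u_full),
                 converged = converged, iterations = iterations,
                 penetration_m = penetration_m, kappa_n_per_m = kappa,
                 n_active_elems = sum(sys$mesh$active)),
            class = "solve_state")
}

#' @export
print.solve_state <- function(x, ...) {
  cat(sprintf(paste0("<solve_state> max |u| = %.4g um, %d contact nodes, ",
                     "master force (%.4g, %.4g, %.4g) mN, %d iterations\n"),
              max(abs(x$u_m)) * 1e6, length(x$contact_nodes),
              x$master_force_n[1] * 1e3, x$master_force_n[2] * 1e3,
              x$master_force_n[3] * 1e3, x$iterations))
  invisible(x)
}

#' Nodal displacements as a tibble
#'
#' @param state A `solve_state`.
#' @param sys The `fem_system` it came from.
#' @return Tibble with node index, coordinates (um) and displacement
#'   components (um).
#' @export
displacement_field <- function(state, sys) {
  u <- matrix(state$u_m, ncol = 3, byrow = TRUE) * 1e6
  tibble::tibble(node = seq_len(sys$n_nodes),
                 x_um = sys$mesh$nodes[, 1], y_um = sys$mesh$nodes[, 2],
                 z_um = sys$mesh$nodes[, 3],
                 ux_um = u[, 1], uy_um = u[, 2], uz_um = u[, 3])
}

# ---- frictionless contact --------------------------------------------------

#' Solve frictionless unilateral contact against the rigid master surface
#'
#' Penalty formulation with active-set iteration: at each iterate the signed
#' distance of every candidate node (nodes of active elements) to the master
#' surface, translated by `master_displacement_um` along +x, is evaluated at
#' the deformed position; penetrating nodes receive a linearised normal
#' penalty spring and the system is re-solved until the active set is stable
#' and the maximum penetration is below `penetration_tol_rel` times the mean
#' element size. The penalty stiffness defaults to
#' `penalty_scale * E * element size` and is escalated tenfold (at most
#' twice) if the penetration tolerance cannot be met.
#'
#' @param sys A [fem_system()].
#' @param surface A [offset_surface()] contact surface.
#' @param master_displacement_um Rigid tangential translation of the master
#'   along +x, micrometres.
#' @param penalty_scale Dimensionless penalty scale (default 100).
#' @param penetration_tol_rel Penetration tolerance relative to the mean
#'   element size (default 1e-3).
#' @param max_iter Total iteration cap.
#' @param verbose Print per-iteration diagnostics (active-set size, maximum
#'   penetration, displacement change, penalty stiffness).
#' @return An object of class `solve_state`; the element stresses follow from
#'   [von_mises_field()] and the transmitted force from [reaction_force()].
#' @export
solve_contact <- function(sys, surface, master_displacement_um,
                          penalty_scale = 100, penetration_tol_rel = 1e-3,
                          max_iter = 60, verbose = FALSE) {
  stopifnot(inherits(sys, "fem_system"), inherits(surface, "contact_surface"))
  if (!any(sys$mesh$active))
    return(new_solve_state(sys, numeric(sys$ndof),
                           f_contact = numeric(sys$ndof),
                           contact_nodes = integer(),
                           master_force = c(0, 0, 0), converged = TRUE,
                           iterations = 0L, penetration_m = 0))
  elem_size_m <- mean(sys$vol_m3[sys$mesh$active])^(1 / 3)
  pen_tol <- penetration_tol_rel * elem_size_m
  E <- sys$material$elastic_modulus_gpa * 1e9
  kappa <- penalty_scale * E * elem_size_m

  attached <- rep(FALSE, sys$n_nodes)
  attached[unique(as.vector(sys$mesh$elems[sys$mesh$active, , drop = FALSE]))] <- TRUE
  # only nodes with at least one free dof can receive a contact force;
  # fully constrained nodes (supports, frozen debris) are not candidates
  has_free <- matrix(sys$eq, ncol = 3, byrow = TRUE) > 0L
  cand <- which(attached & (has_free[, 1] | has_free[, 2] | has_free[, 3]))
  if (length(cand) == 0)
    return(new_solve_state(sys, numeric(sys$ndof),
                           f_contact = numeric(sys$ndof),
                           contact_nodes = integer(),
                           master_force = c(0, 0, 0), converged = TRUE,
                           iterations = 0L, penetration_m = 0))
  cand_dofs <- t(vapply(cand, function(n) 3L * (n - 1L) + 1:3, integer(3)))

  asm <- assemble_reduced(sys, scale = 0)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(asm$K),
                                  LDL = FALSE, perm = TRUE),
                 error = function(e) e)
  if (inherits(ch, "error")) {
    # near-mechanisms (e.g. element chains hinging at one node) can appear
    # during fracture; a vanishing diagonal shift restores definiteness
    shift <- 1e-9 * max(Matrix::diag(asm$K))
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(
      asm$K + Matrix::Diagonal(sys$n_eq, shift)), LDL = FALSE, perm = TRUE),
      error = function(e) stop("singular constrained system: ",
                               conditionMessage(e)))
  }
  u <- numeric(sys$ndof)
  u_prev <- u
  prev_active <- NULL
  prev2_active <- NULL
  sticky <- FALSE
  active <- integer()
  converged <- FALSE
  it_total <- 0L
  max_pen <- Inf
  n_escalations <- 0L

  while (it_total < max_iter) {
    it_total <- it_total + 1L
    pts <- sys$mesh$nodes[cand, , drop = FALSE] +
      matrix(u[t(cand_dofs)], ncol = 3, byrow = TRUE) * 1e6
    sd <- surface$sdf(pts, shift_um = master_displacement_um)
    g <- sd$d_um * 1e-6
    nrm <- sd$normal
    penetrating <- which(g < 0)
    max_pen <- if (length(penetrating)) max(-g[penetrating]) else 0
    # flip-flopping nodes (period-2 active-set cycles at re-entrant corners of
    # the fractured surface) are kept in the set and pinned at zero gap
    if (!sticky && !is.null(prev2_active) &&
        identical(penetrating, prev2_active) &&
        !identical(penetrating, prev_active)) sticky <- TRUE
    if (it_total > max_iter / 2) sticky <- TRUE
    active <- if (sticky) sort(union(active, penetrating)) else penetrating
    du <- max(abs(u - u_prev))
    stable <- !is.null(prev_active) && identical(active, prev_active)
    if (verbose)
      message(sprintf(
        "  contact it %d: %d active (%d penetrating%s), pen %.3g m, du %.3g m, kappa %.3g",
        it_total, length(active), length(penetrating),
        if (sticky) ", sticky" else "", max_pen, du, kappa))
    stagnant <- it_total > 1 && du < 1e-3 * pen_tol
    if ((stable || stagnant) && max_pen < pen_tol) { converged <- TRUE; break }
    if (stable && stagnant && max_pen >= pen_tol) {
      # penalty too soft for the tolerance at this load: stiffen and continue
      if (n_escalations >= 2L) break
      kappa <- kappa * 10
      n_escalations <- n_escalations + 1L
      prev_active <- NULL
      next
    }
    prev2_active <- prev_active
    prev_active <- active
    u_prev <- u

    if (length(active) == 0) {
      u_red <- if (sys$n_eq > 0) as.vector(Matrix::solve(ch, asm$rhs)) else numeric(0)
      u <- expand_solution(sys, u_red, scale = 0)
      next
    }
    na <- nrm[active, , drop = FALSE]
    # linearised gap about the current iterate: g(u') = g + n . (u' - u)
    ucur <- matrix(u[t(cand_dofs[active, , drop = FALSE])], ncol = 3, byrow = TRUE)
    g0 <- g[active] - rowSums(na * ucur)
    dofs <- cand_dofs[active, , drop = FALSE]
    eqd <- matrix(sys$eq[dofs], ncol = 3)
    last_lin <- list(active = active, na = na, g0 = g0, dofs = dofs)
    m <- length(active)
    Ni <- as.vector(t(eqd))
    Nx <- as.vector(t(na))
    Nj <- rep(seq_len(m), each = 3)
    ok <- Ni > 0L
    N <- Matrix::sparseMatrix(i = Ni[ok], j = Nj[ok], x = Nx[ok],
                              dims = c(sys$n_eq, m))
    rhs <- asm$rhs - as.vector(N %*% (kappa * g0))
    # Woodbury: (K + kappa N N')^{-1} rhs with the cached factor of K
    t1 <- as.vector(Matrix::solve(ch, rhs))
    Z <- as.matrix(Matrix::solve(ch, N))
    S <- as.matrix(Matrix::crossprod(N, Z))
    diag(S) <- diag(S) + 1 / kappa
    u_red <- t1 - Z %*% solve(S, as.vector(Matrix::crossprod(N, t1)))
    u <- expand_solution(sys, as.vector(u_red), scale = 0)
  }
  if (!converged)
    stop(sprintf(paste0("contact solver did not converge: penetration %.3g m ",
                        "(tolerance %.3g m) after %d iterations, ",
                        "%d active nodes, penalty %.3g N/m"),
                 max_pen, pen_tol, it_total, length(active), kappa))

  # contact forces of the converged linearised state: exactly the spring
  # forces the final solve equilibrated (tensile residues of pinned
  # flip-flop nodes are clipped to zero)
  f_contact <- numeric(sys$ndof)
  master_force <- c(0, 0, 0)
  if (exists("last_lin", inherits = FALSE) && length(last_lin$active)) {
    na <- last_lin$na
    dofs <- last_lin$dofs
    ucur <- matrix(u[t(dofs)], ncol = 3, byrow = TRUE)
    g_lin <- last_lin$g0 + rowSums(na * ucur)
    fmag <- pmax(0, -kappa * g_lin)      # normal pressure resultant, >= 0
    fvec <- na * fmag                    # force on the polymer nodes
    # components on eliminated dofs are reacted by the supports
    free <- matrix(sys$eq[dofs] > 0L, ncol = 3)
    fvec_applied <- fvec * free
    f_contact[t(dofs)] <- as.vector(t(fvec_applied))
    master_force <- -colSums(fvec_applied)
    active <- last_lin$active[fmag > 0]
  } else active <- integer()
  new_solve_state(sys, u, f_contact = f_contact,
                  contact_nodes = cand[active], master_force = master_force,
                  converged = TRUE, iterations = it_total,
                  penetration_m = max_pen, kappa = kappa)
}

#' Reaction force transmitted through the contact interface
#'
#' Component along `direction` of the force that must be applied to the rigid
#' master surface to sustain its displacement: minus the resultant of the
#' contact forces the polymer exerts on the master. Positive along the motion
#' direction when the interface resists.
#'
#' @param state A `solve_state`.
#' @param direction Length-3 direction vector (normalised internally).
#' @return Force in millinewtons.
#' @export
reaction_force <- function(state, direction = c(1, 0, 0)) {
  d <- direction / sqrt(sum(direction^2))
  -sum(state$master_force_n * d) * 1e3
}

#' Per-element von Mises stress
#'
#' Scalar stress invariant of the volume-averaged Gauss-point stress tensor
#' of each active element (`sampling = "mean"`, the default and the
#' mesh-robust choice for the deletion criterion) or the maximum over the
#' eight Gauss points (`sampling = "max"`).
#'
#' @param state A `solve_state`.
#' @param sys The [fem_system()] it was solved on.
#' @param sampling `"mean"` or `"max"`.
#' @return Numeric vector, MPa, `NA` for inactive elements.
#' @export
von_mises_field <- function(state, sys, sampling = c("mean", "max")) {
  sampling <- match.arg(sampling)
  D <- elasticity_matrix(sys$material)
  vm_of <- function(s) sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 +
                                     (s[3] - s[1])^2) + 3 * sum(s[4:6]^2))
  out <- rep(NA_real_, sys$n_elems)
  act <- which(sys$mesh$active)
  if (length(act) == 0) return(out)
  if (sampling == "mean") {
    U <- matrix(state$u_m[sys$edof[, act, drop = FALSE]], nrow = 24)
    eps <- matrix(0, 6, length(act))
    for (r in 1:6) {
      Br <- sys$Bbar[seq(r, 144, by = 6), act, drop = FALSE]
      eps[r, ] <- colSums(Br * U)
    }
    sig <- D %*% eps
    out[act] <- apply(sig, 2, vm_of) / 1e6
  } else {
    nodes_m <- sys$mesh$nodes * 1e-6
    for (e in act) {
      xe <- nodes_m[sys$mesh$elems[e, ], ]
      ue <- state$u_m[sys$edof[, e]]
      v <- 0
      for (q in 1:8) {
        J <- hex_dN_gauss[[q]] %*% xe
        B <- b_matrix(solve(J, hex_dN_gauss[[q]]))
        v <- max(v, vm_of(as.vector(D %*% (B %*% ue))))
      }
      out[e] <- v / 1e6
    }
  }
  out
}
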