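#' First-order hexahedral mesh
#'
#' Container for the polymer unit-cell mesh: node coordinates (micrometres),
#' 8-node element connectivity in standard hexahedron ordering (bottom face
#' counter-clockwise, then the top face; here "bottom" is the imprint side,
#' z is depth into the polymer), a per-element activity flag (fracture is
#' modelled as deactivation) and precomputed element volumes.
#'
#' @param nodes n x 3 numeric matrix of coordinates, micrometres.
#' @param elems ne x 8 integer matrix of node indices (1-based).
#' @return An object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elems) {
  nodes <- as.matrix(nodes)
  elems <- matrix(as.integer(elems), nrow = nrow(elems))
  stopifnot(ncol(nodes) == 3, ncol(elems) == 8,
            min(elems) >= 1, max(elems) <= nrow(nodes))
  m <- structure(list(nodes = nodes, elems = elems,
                      active = rep(TRUE, nrow(elems)), elem_vol = NULL),
                 class = "hex_mesh")
  m$elem_vol <- element_volumes(m)
  if (any(m$elem_vol <= 0))
    stop(sprintf("%d elements have non-positive volume", sum(m$elem_vol <= 0)))
  m
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d elements (%d active), volume %.6g um^3\n",
              nrow(x$nodes), nrow(x$elems), sum(x$active),
              mesh_volume(x, active_only = TRUE)))
  invisible(x)
}

# Gauss abscissae for 2-point rule on [-1, 1]
gauss2 <- c(-1, 1) / sqrt(3)

# 8 x 3 matrix of hex corner signs in standard ordering
hex_corner_signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                             -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                           ncol = 3, byrow = TRUE)

# shape-function derivative matrices (3 x 8) at the 8 Gauss points, fixed
hex_dN_gauss <- local({
  gp <- as.matrix(expand.grid(gauss2, gauss2, gauss2))
  lapply(seq_len(8), function(q) {
    xi <- gp[q, ]
    t(sapply(1:3, function(d) {
      s <- hex_corner_signs
      0.125 * s[, d] *
        (1 + s[, (d %% 3) + 1] * xi[(d %% 3) + 1]) *
        (1 + s[, ((d + 1) %% 3) + 1] * xi[((d + 1) %% 3) + 1])
    }))
  })
})

#' Element volumes by Gauss integration of the Jacobian
#'
#' 2 x 2 x 2 Gauss quadrature of `det J` over each element, exact for
#' trilinear hexahedra.
#'
#' @param mesh A [hex_mesh()].
#' @return Numeric vector of element volumes, cubic micrometres.
#' @export
element_volumes <- function(mesh) {
  ne <- nrow(mesh$elems)
  vol <- numeric(ne)
  for (e in seq_len(ne)) {
    xe <- mesh$nodes[mesh$elems[e, ], ]
    v <- 0
    for (q in seq_len(8)) v <- v + det(hex_dN_gauss[[q]] %*% xe)
    vol[e] <- v
  }
  vol
}

#' Total (active) mesh volume
#'
#' @param mesh A [hex_mesh()].
#' @param active_only Sum only non-deleted elements (default).
#' @return Volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh, active_only = TRUE) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (active_only) sum(mesh$elem_vol[mesh$active]) else sum(mesh$elem_vol)
}

#' Deactivate elements (element death)
#'
#' @param mesh A [hex_mesh()].
#' @param ids Element indices to deactivate.
#' @return The mesh with the elements flagged inactive.
#' @export
deactivate_elements <- function(mesh, ids) {
  stopifnot(inherits(mesh, "hex_mesh"))
  mesh$active[ids] <- FALSE
  mesh
}

structured_node_id <- function(i, j, k, nx, ny) {
  1L + i + (nx + 1L) * (j + (ny + 1L) * k)
}

structured_box_connectivity <- function(nx, ny, nz) {
  idx <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  i <- idx$i; j <- idx$j; k <- idx$k
  cbind(structured_node_id(i,     j,     k,     nx, ny),
        structured_node_id(i + 1, j,     k,     nx, ny),
        structured_node_id(i + 1, j + 1, k,     nx, ny),
        structured_node_id(i,     j + 1, k,     nx, ny),
        structured_node_id(i,     j,     k + 1, nx, ny),
        structured_node_id(i + 1, j,     k + 1, nx, ny),
        structured_node_id(i + 1, j + 1, k + 1, nx, ny),
        structured_node_id(i,     j + 1, k + 1, nx, ny))
}

structured_node_sets <- function(nx, ny, nz) {
  grid <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  id <- structured_node_id(grid$i, grid$j, grid$k, nx, ny)
  list(bottom = id[grid$k == nz],
       imprint_surface = id[grid$k == 0],
       side_x_min = id[grid$i == 0],
       side_x_max = id[grid$i == nx],
       side_y_min = id[grid$j == 0],
       side_y_max = id[grid$j == ny],
       dims = c(nx = nx, ny = ny, nz = nz))
}

#' Mesh the polymer unit cell with its conical imprint
#'
#' Structured, body-fitted hexahedral mesh of the polymer block below the
#' implant surface. Node columns follow the terrain of the pit: at footprint
#' position (x, y) the nodes are graded between the imprint surface height
#' `f(x, y) = max(0, h (1 - r / a))` and the substrate depth, so the top node
#' layer lies exactly on the nominal imprint and every element keeps a
#' positive Jacobian. Coordinates: x is the enforced tangential direction,
#' y transverse, z depth into the polymer with z = 0 at the interface plane.
#'
#' @param cone A [cone_feature()]; its height must be smaller than the cell
#'   substrate depth.
#' @param cell A [unit_cell()].
#' @param target_elem_size_um Requested element edge length, micrometres.
#' @return A list with components `mesh` (a [hex_mesh()]) and `sets` (named
#'   boundary node-index sets: `bottom`, `imprint_surface`, `side_x_min`,
#'   `side_x_max`, `side_y_min`, `side_y_max`).
#' @export
build_unit_cell_mesh <- function(cone, cell, target_elem_size_um = 0.35) {
  stopifnot(inherits(cone, "cone_feature"), inherits(cell, "unit_cell"),
            target_elem_size_um > 0)
  if (cone$height_um > 0 && target_elem_size_um >= cone$base_radius_um)
    stop("target element size must be smaller than the cone base radius")
  if (cone$height_um >= cell$substrate_depth_um)
    stop("cone height must be smaller than the substrate depth")
  w <- cell$width_um; l <- cell$length_um; D <- cell$substrate_depth_um
  nx <- max(2L, as.integer(round(w / target_elem_size_um)))
  ny <- max(2L, as.integer(round(l / target_elem_size_um)))
  nz <- max(2L, as.integer(round(D / target_elem_size_um)))
  apex <- cone_apex(cone, cell)
  x <- seq(0, w, length.out = nx + 1)
  y <- seq(0, l, length.out = ny + 1)
  f <- if (cone$height_um > 0) {
    r <- sqrt(outer((x - apex[1])^2, (y - apex[2])^2, `+`))
    ff <- cone$height_um * (1 - r / cone$base_radius_um)
    ff[ff < 0] <- 0
    ff
  } else matrix(0, nx + 1, ny + 1)

  grid <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  fij <- f[cbind(grid$i + 1, grid$j + 1)]
  frac <- grid$k / nz
  nodes <- cbind(x[grid$i + 1], y[grid$j + 1],
                 fij * (1 - frac) + D * frac)
  mesh <- hex_mesh(nodes, structured_box_connectivity(nx, ny, nz))
  list(mesh = mesh, sets = structured_node_sets(nx, ny, nz))
}

#' Canonical fixture meshes
#'
#' Regular box meshes used by the verification suite: a unit single element
#' (`"single_element"`), a block with arbitrary divisions (`"block"`) and a
#' slender cantilever (`"cantilever"`, long axis along x). Node sets follow
#' the unit-cell naming with `imprint_surface` the z = 0 face.
#'
#' @param kind One of `"single_element"`, `"block"`, `"cantilever"`.
#' @param dims_um Length-3 box dimensions, micrometres.
#' @param divisions Length-3 integer divisions per axis.
#' @return A list with `mesh` and `sets` as in [build_unit_cell_mesh()].
#' @export
build_fixture_mesh <- function(kind = c("single_element", "block", "cantilever"),
                               dims_um = c(1, 1, 1), divisions = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (kind == "single_element") divisions <- c(1, 1, 1)
  if (kind == "cantilever" && !(dims_um[1] > dims_um[2]))
    stop("cantilever fixture expects its long axis along x")
  stopifnot(length(dims_um) == 3, all(dims_um > 0),
            length(divisions) == 3, all(divisions >= 1))
  n <- as.integer(divisions)
  xs <- lapply(1:3, function(d) seq(0, dims_um[d], length.out = n[d] + 1))
  grid <- expand.grid(i = 0:n[1], j = 0:n[2], k = 0:n[3])
  nodes <- cbind(xs[[1]][grid$i + 1], xs[[2]][grid$j + 1], xs[[3]][grid$k + 1])
  mesh <- hex_mesh(nodes, structured_box_connectivity(n[1], n[2], n[3]))
  list(mesh = mesh, sets = structured_node_sets(n[1], n[2], n[3]))
}

# ---- mesh export -----------------------------------------------------------

#' Export a mesh in VTK legacy or Gmsh MSH format
#'
#' Plain-ASCII writers for visualisation: VTK legacy unstructured grid
#' (element activity and any extra per-element or per-node fields attached as
#' CELL_DATA / POINT_DATA) and Gmsh MSH 2.2. Coordinates carry a units
#' comment (micrometres).
#'
#' @param mesh A [hex_mesh()].
#' @param path Output file.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "retorq mesh (units: um)", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  cell_data <- c(list(active = as.numeric(mesh$active)), cell_data)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 10), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}

#' @rdname write_vtk
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Comment", "units: um", "$EndComment",
               "$Nodes", as.character(nrow(mesh$nodes))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$nodes)), mesh$nodes), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$elems)), 5L, 2L, 1L,
                           as.integer(!mesh$active) + 1L, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}
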