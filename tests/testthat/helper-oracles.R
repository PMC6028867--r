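# Independent numerical oracles used across the suite. These deliberately do
# not share code with the package implementation beyond the definition of the
# trilinear hexahedron itself.

# 4-point Gauss-Legendre rule on [-1, 1]
gl4 <- list(
  x = c(-0.861136311594053, -0.339981043584856,
        0.339981043584856, 0.861136311594053),
  w = c(0.347854845137454, 0.652145154862546,
        0.652145154862546, 0.347854845137454))

# trilinear shape functions at a parametric point (length-8 vector)
shape_n <- function(xi) {
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
              ncol = 3, byrow = TRUE)
  0.125 * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3])
}

# strain energy of a hex element for nodal displacements u (24-vector, m),
# over the defining 2 x 2 x 2 Gauss rule, with all parametric derivatives
# taken by central finite differences of the trilinear interpolation (the
# differentiation path is independent of the analytic B-matrix assembly)
numeric_strain_energy <- function(coords_m, u, D) {
  U <- matrix(u, ncol = 3, byrow = TRUE)
  h <- 1e-6
  g2 <- c(-1, 1) / sqrt(3)
  total <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    xi <- c(g2[i], g2[j], g2[k])
    Jx <- matrix(0, 3, 3)   # dx/dxi
    Ju <- matrix(0, 3, 3)   # du/dxi
    for (d in 1:3) {
      xp <- xi; xm <- xi
      xp[d] <- xp[d] + h; xm[d] <- xm[d] - h
      np <- shape_n(xp); nm <- shape_n(xm)
      Jx[d, ] <- colSums((np - nm) * coords_m) / (2 * h)
      Ju[d, ] <- colSums((np - nm) * U) / (2 * h)
    }
    G <- solve(Jx, Ju)      # du/dx (rows: d/dx_i, cols: component)
    eps <- c(G[1, 1], G[2, 2], G[3, 3],
             G[1, 2] + G[2, 1], G[2, 3] + G[3, 2], G[3, 1] + G[1, 3])
    total <- total + 0.5 * sum(eps * (D %*% eps)) * det(Jx)
  }
  total
}

# element volume by the divergence theorem: V = (1/3) closed-surface integral
# of x . n over the six bilinear faces, high-order Gauss per face
divergence_volume <- function(coords_m) {
  faces <- list(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  vol <- 0
  for (f in faces) {
    P <- coords_m[f, ]
    for (i in 1:4) for (j in 1:4) {
      a <- gl4$x[i]; b <- gl4$x[j]
      Nq <- 0.25 * c((1 - a) * (1 - b), (1 + a) * (1 - b),
                     (1 + a) * (1 + b), (1 - a) * (1 + b))
      dNa <- 0.25 * c(-(1 - b), (1 - b), (1 + b), -(1 + b))
      dNb <- 0.25 * c(-(1 - a), -(1 + a), (1 + a), (1 - a))
      x <- colSums(Nq * P)
      ta <- colSums(dNa * P)
      tb <- colSums(dNb * P)
      nrm <- c(ta[2] * tb[3] - ta[3] * tb[2],
               ta[3] * tb[1] - ta[1] * tb[3],
               ta[1] * tb[2] - ta[2] * tb[1])
      vol <- vol + gl4$w[i] * gl4$w[j] * sum(x * nrm) / 3
    }
  }
  vol
}

# Exhaustive dense active-set oracle for the frictionless penalty contact
# problem with gaps linearised at the reference configuration: enumerates
# every subset of the candidate nodes, solves the dense system and returns
# the displacement of the complementarity-consistent subset.
dense_contact_oracle <- function(K_dense, eq, cand_nodes, g0, normals, kappa) {
  n_eq <- ncol(K_dense)
  m <- length(cand_nodes)
  stopifnot(m <= 14)
  rows <- lapply(seq_len(m), function(i) {
    d <- 3 * (cand_nodes[i] - 1) + 1:3
    r <- eq[d]
    list(eq = r, n = normals[i, ])
  })
  best <- NULL
  for (mask in 0:(2^m - 1)) {
    A <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    Kp <- K_dense
    rhs <- numeric(n_eq)
    for (i in A) {
      r <- rows[[i]]$eq; nv <- rows[[i]]$n
      ok <- r > 0
      nn_ <- numeric(n_eq)
      nn_[r[ok]] <- nv[ok]
      Kp <- Kp + kappa * outer(nn_, nn_)
      rhs <- rhs - kappa * g0[i] * nn_
    }
    u <- tryCatch(solve(Kp, rhs), error = function(e) NULL)
    if (is.null(u)) next
    glin <- vapply(seq_len(m), function(i) {
      r <- rows[[i]]$eq; nv <- rows[[i]]$n
      ok <- r > 0
      g0[i] + sum(nv[ok] * u[r[ok]])
    }, numeric(1))
    consistent <- all(glin[A] <= 1e-12) &&
      all(glin[setdiff(seq_len(m), A)] >= -1e-12)
    if (consistent) { best <- list(u = u, active = A); break }
  }
  best
}

paper_spec <- function() roughness_spec(849, 50, 40)

paper_fit <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- suppressWarnings(fit_cone(paper_spec(), unit_cell()))
    cached
  }
})
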