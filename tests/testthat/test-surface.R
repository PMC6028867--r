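test_that("flat and analytically known surfaces give exact roughness", {
  cell <- unit_cell()
  flat <- cone_roughness(cone_feature(1, 0), cell)
  expect_equal(unlist(flat), c(sa_nm = 0, sdq_deg = 0, sdr_pct = 0))

  hm_flat <- height_map(matrix(5, 16, 16), dx_nm = 10)
  expect_equal(unlist(roughness_from_height_map(hm_flat)),
               c(sa_nm = 0, sdq_deg = 0, sdr_pct = 0))

  # uniform unit slope: Sdq = 45 degrees, Sdr = sqrt(2) - 1
  n <- 64
  z <- matrix(rep((1:n) * 10, n), n, n)
  r <- roughness_from_height_map(height_map(z, dx_nm = 10))
  expect_equal(r$sdq_deg, 45, tolerance = 1e-12)
  expect_equal(r$sdr_pct, (sqrt(2) - 1) * 100, tolerance = 1e-12)

  # 45-degree flank: rms gradient = sqrt(covered area fraction)
  cone45 <- cone_feature(1, 1)
  f <- pi * 1^2 / cell$area_um2
  expect_equal(cone_roughness(cone45, cell)$sdq_deg,
               atan(sqrt(f)) * 180 / pi, tolerance = 1e-12)
})

test_that("closed-form roughness matches fine-grid numerical integration", {
  # includes cones whose base circle is clipped by the periodic cell edges
  cell <- unit_cell()
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0.3, 3.4)
    h <- runif(1, 0.2, 4.5)
    cone <- cone_feature(a, h)
    cf <- cone_roughness(cone, cell)
    num <- roughness_from_height_map(render_height_map(cone, cell, 2048))
    expect_equal(num$sa_nm, cf$sa_nm, tolerance = 5e-3)
    expect_equal(num$sdq_deg, cf$sdq_deg, tolerance = 5e-3)
    expect_equal(num$sdr_pct, cf$sdr_pct, tolerance = 5e-3)
  }
})

test_that("roughness parameters are monotone in cone height", {
  cell <- unit_cell()
  for (a in c(0.8, 1.5, 2.8)) {
    hs <- seq(0.2, 4, length.out = 12)
    vals <- purrr::map_dfr(hs, ~ cone_roughness(cone_feature(a, .x), cell))
    expect_true(all(diff(vals$sa_nm) > 0))
    expect_true(all(diff(vals$sdq_deg) > 0))
    expect_true(all(diff(vals$sdr_pct) > 0))
  }
})

test_that("two-constraint fits reproduce feasible targets exactly", {
  cell <- unit_cell()
  for (spec in list(roughness_spec(300, 30, 10), roughness_spec(500, 42, 25))) {
    fit <- fit_cone(spec, cell, mode = "sa+sdq")
    expect_true(fit$exact)
    expect_equal(fit$achieved$sa_nm, spec$sa_nm, tolerance = 1e-6)
    expect_equal(fit$achieved$sdq_deg, spec$sdq_deg, tolerance = 1e-6)
  }
  fit2 <- fit_cone(roughness_spec(300, 50, 40), cell, mode = "sdq+sdr")
  expect_true(fit2$exact)
  expect_equal(fit2$achieved$sdq_deg, 50, tolerance = 1e-6)
  expect_equal(fit2$achieved$sdr_pct, 40, tolerance = 1e-6)

  flat <- fit_cone(roughness_spec(0, 0, 0), cell)
  expect_equal(flat$cone$height_um, 0)
})

test_that("sdq+sdr fit agrees with a brute-force grid search", {
  cell <- unit_cell()
  fit <- fit_cone(roughness_spec(300, 50, 40), cell, mode = "sdq+sdr")
  amax <- sqrt((cell$width_um / 2)^2 + (cell$length_um / 2)^2)
  a <- seq(amax / 2000, amax * (1 - 1e-9), length.out = 2000)
  h <- seq(0.01, 8, length.out = 2000)
  best <- c(Inf, NA, NA)
  for (ai in a) {
    v <- retorq:::cone_roughness_core(ai, h, cell$width_um, cell$length_um)
    err <- ((atan(v$rms) * 180 / pi - 50) / 50)^2 + ((v$sdr * 100 - 40) / 40)^2
    j <- which.min(err)
    if (err[j] < best[1]) best <- c(err[j], ai, h[j])
  }
  expect_equal(fit$cone$base_radius_um, best[2], tolerance = 2e-3)
  expect_equal(fit$cone$height_um, best[3], tolerance = 2e-3)
})

test_that("infeasible pairs fall back to least squares or error as requested", {
  cell <- unit_cell()
  expect_error(fit_cone(paper_spec(), cell, on_infeasible = "error"),
               "matches sa_nm")
  expect_warning(fit <- fit_cone(paper_spec(), cell), "least-squares")
  expect_false(fit$exact)
  expect_equal(fit$achieved$sa_nm, 849, tolerance = 0.01)
  expect_equal(fit$achieved$sdq_deg, 50, tolerance = 0.01)
})

test_that("rendered height maps are exact where the surface is smooth", {
  cell <- unit_cell()
  expect_true(all(render_height_map(cone_feature(1, 0), cell, 32)$z == 0))

  cone <- cone_feature(1.2, 2)
  hm <- render_height_map(cone, cell, 129)   # odd: centre pixel at the apex
  expect_equal(max(hm$z), 2000 * (1 - 0 / 1.2), tolerance = 1e-9)

  hm2 <- render_height_map(cone, cell, 1024)
  vol_nm <- sum(hm2$z) * hm2$dx_nm * hm2$dy_nm        # nm^3
  expect_equal(vol_nm / 1e9, pi * 1.2^2 * 2 / 3, tolerance = 5e-3)
})

test_that("height maps round-trip through the commented CSV format", {
  hm <- render_height_map(cone_feature(0.9, 1.7), unit_cell(), 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_height_map(hm, path)
  back <- read_height_map(path)
  expect_equal(back$z, hm$z, tolerance = 1e-12)
  expect_equal(back$dx_nm, hm$dx_nm)
  expect_equal(back$dy_nm, hm$dy_nm)
})

test_that("offset surface realises a uniform normal clearance", {
  cell <- unit_cell()
  cone <- cone_feature(1.5, 2.5)
  # flank points of the nominal cone (away from apex and base edge)
  t <- seq(0.2, 0.8, length.out = 25)
  phi <- seq(0, 2 * pi, length.out = 25)
  pts <- do.call(rbind, lapply(t, function(ti) {
    rho <- 1.5 * (1 - ti)
    cbind(cell$width_um / 2 + rho * cos(phi),
          cell$length_um / 2 + rho * sin(phi), 2.5 * ti)
  }))
  s0 <- offset_surface(cone, cell, gap_nm = 0)
  expect_lt(max(abs(s0$sdf(pts)$d_um)), 1e-12)
  s150 <- offset_surface(cone, cell, gap_nm = 150)
  expect_equal(s150$sdf(pts)$d_um, rep(150e-3, nrow(pts)), tolerance = 1e-12)

  expect_error(offset_surface(cone, cell, gap_nm = 1e6), "degenerates")
})

test_that("signed-distance gradient has unit norm", {
  cell <- unit_cell()
  surf <- offset_surface(cone_feature(2.2, 3.1), cell, gap_nm = 50)
  set.seed(7)
  n <- 1000
  pts <- cbind(runif(n, 0, cell$width_um), runif(n, 0, cell$length_um),
               runif(n, 0, 6))
  pts <- pts[surf$sdf(pts)$d_um > 0.02, , drop = FALSE]  # polymer side
  h <- 1e-5
  gnorm <- vapply(seq_len(nrow(pts)), function(i) {
    g <- vapply(1:3, function(c) {
      pp <- pts[i, ]; pm <- pts[i, ]
      pp[c] <- pp[c] + h; pm[c] <- pm[c] - h
      (surf$sdf(rbind(pp))$d_um - surf$sdf(rbind(pm))$d_um) / (2 * h)
    }, numeric(1))
    sqrt(sum(g^2))
  }, numeric(1))
  # unit almost everywhere; finite differences straddling the medial axis of
  # the surface are excluded by a quantile guard
  expect_lt(stats::quantile(abs(gnorm - 1), 0.995), 1e-6)
  # returned normals agree with the gradient direction
  sd <- surf$sdf(pts)
  expect_lt(max(abs(rowSums(sd$normal^2) - 1)), 1e-12)
})
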