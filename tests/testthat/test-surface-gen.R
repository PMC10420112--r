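make_cyl_params <- function(r = 10, sector = pi / 2, n = 9, len = 160) {
  zs <- seq(0, len, length.out = n)
  roi <- lapply(zs, function(z) circle_triplet(r, z, sector))
  angs <- vapply(roi, function(tr) {
    arc_angle(arc_through_points(tr$left, tr$middle, tr$right))
  }, numeric(1))
  plate_params(roi, angs, rep(0, n), rep(r, n), rep(r, n),
               thickness = 2, frame = z_frame(len))
}

test_that("guiding curves interpolate their points; cylinder guides are parallel", {
  params <- make_cyl_params()
  g <- build_guiding_curves(params)
  u <- g$u_knots
  for (i in seq_along(params$roi)) {
    expect_point_equal(as.numeric(g$left_curve(u[i])), params$roi[[i]]$left,
                       1e-9)
    expect_point_equal(as.numeric(g$right_curve(u[i])), params$roi[[i]]$right,
                       1e-9)
    expect_point_equal(as.numeric(g$spine_curve(u[i])),
                       params$roi[[i]]$middle, 1e-9)
  }
  # collinear middles -> straight spine
  tt <- seq(0, 1, length.out = 33)
  spine <- g$spine_curve(tt)
  lin <- outer(1 - tt, params$roi[[1]]$middle) +
    outer(tt, params$roi[[9]]$middle)
  expect_lt(max(abs(spine - lin)), 1e-9)
  # parallel guides at chord distance 2 r sin(alpha/2)
  d <- plateforge:::row_norms(g$left_curve(tt) - g$right_curve(tt))
  expect_lt(max(abs(d - 2 * 10 * sin(pi / 4))), 1e-9)

  p2 <- make_cyl_params(n = 3)
  p2$roi <- p2$roi[1:2]
  p2$angles <- p2$angles[1:2]
  p2$stations <- p2$stations[1:2]
  p2$n_sections <- 2L
  expect_error(build_guiding_curves(p2), class = "pf_parameter_error")
})

test_that("the loft reproduces its arcs and interpolates radii", {
  params <- make_cyl_params(r = 10)
  surf <- loft_surface(params)
  # knots reproduce the ROI points
  for (i in c(1, 5, 9)) {
    tr <- params$roi[[i]]
    arc <- arc_through_points(tr$left, tr$middle, tr$right)
    vmid <- plateforge:::arc_mid_fraction(arc)
    expect_point_equal(surf$eval(surf$u_knots[i], 0), tr$left, 1e-6)
    expect_point_equal(surf$eval(surf$u_knots[i], 1), tr$right, 1e-6)
    expect_point_equal(surf$eval(surf$u_knots[i], vmid), tr$middle, 1e-6)
  }
  # constant loft: any (u, v) on the cylinder
  uu <- seq(0, 1, length.out = 13)
  for (v in c(0.25, 0.5, 0.8)) {
    p <- surf$eval(uu, rep(v, 13))
    expect_lt(max(abs(sqrt(p[, 1]^2 + p[, 2]^2) - 10)), 1e-6)
  }

  # tapering radii 12 -> 10 over uniform stations: radius at u = 0.5 is 11
  zs <- seq(0, 160, length.out = 9)
  rs <- seq(12, 10, length.out = 9)
  roi <- Map(function(r, z) circle_triplet(r, z), rs, zs)
  angs <- vapply(roi, function(tr) {
    arc_angle(arc_through_points(tr$left, tr$middle, tr$right))
  }, numeric(1))
  taper <- plate_params(roi, angs, rep(0, 9), rs, rs, 2, z_frame(160))
  ts <- loft_surface(taper)
  p <- ts$eval(0.5, 0.5)
  expect_equal(sqrt(p[1]^2 + p[2]^2), 11, tolerance = 1e-6)
})

test_that("surface meshing has exact counts, area and outward orientation", {
  surf <- cylinder_patch_surface(r = 10, alpha = pi / 2, len = 100)
  m2 <- surface_to_mesh(surf, 2, 2)
  expect_equal(nrow(m2$vertices), 4L)
  expect_equal(nrow(m2$faces), 2L)

  m <- surface_to_mesh(surf, 64, 64)
  expect_equal(nrow(m$vertices), 64L * 64L)
  analytic <- 10 * (pi / 2) * 100
  expect_lt(abs(plateforge:::mesh_area(m) - analytic) / analytic, 0.001)
  # outward orientation: normals point away from the axis
  fn <- plateforge:::face_normals(m)
  fc <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
           m$vertices[m$faces[, 3], ]) / 3
  radial <- cbind(fc[, 1], fc[, 2], 0)
  expect_gt(mean(rowSums(fn * radial)), 0)

  expect_error(surface_to_mesh(surf, 1, 8), class = "pf_parameter_error")
})

test_that("loft is invariant under parameter re-serialization", {
  bone <- generate_humerus(bone_phantom_spec(seed = 12))$mesh
  fr <- compute_anatomical_axis(bone)
  st <- place_stations(fr, c(0.4, 0.96) * fr$extent, 9, 0.3)
  params <- assemble_params(bone, fr, st, pi / 2)
  f <- withr::local_tempfile(fileext = ".json")
  save_params(params, f)
  s1 <- loft_surface(params)
  s2 <- loft_surface(load_params(f))
  uu <- seq(0.05, 0.95, length.out = 15)
  expect_lt(max(abs(s1$eval(uu, rev(uu)) - s2$eval(uu, rev(uu)))), 1e-9)
})

test_that("deviation decreases as sections are added on a smooth phantom", {
  out <- generate_humerus(bone_phantom_spec(noise_sd = 0, seed = 1))
  fr <- compute_anatomical_axis(out$mesh)
  meds <- vapply(c(3, 9, 15), function(n) {
    st <- place_stations(fr, c(0.40, 0.96) * fr$extent, n, 0.3)
    p <- assemble_params(out$mesh, fr, st, pi / 2)
    surface_deviation(loft_surface(p), out$mesh, n_samples = 600,
                      seed = 5)$median_abs
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-9))
})
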