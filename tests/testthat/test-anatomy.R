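test_that("axis recovery is exact on a cylinder and equivariant under rotation", {
  cyl <- cylinder_phantom(r = 10, length = 200)
  fr <- compute_anatomical_axis(cyl)
  expect_lt(abs(abs(sum(fr$axis_dir * c(0, 0, 1))) - 1), 1e-6)
  expect_lt(sqrt(sum(fr$origin[1:2]^2)), 1e-6)      # origin on the z-axis

  R <- rotation_oracle(c(1, 2, 3), 0.7)
  rot <- cyl
  rot$vertices <- cyl$vertices %*% t(R)
  fr_rot <- compute_anatomical_axis(rot, posterior_hint = R %*% c(0, 1, 0))
  expect_lt(abs(abs(sum(fr_rot$axis_dir * (R %*% fr$axis_dir))) - 1), 1e-6)
})

test_that("axis recovery meets tolerance on phantoms", {
  # straight, noise-free: sub-0.1 degree
  straight <- generate_humerus(bone_phantom_spec(bow_sagittal = 0,
                                                 noise_sd = 0, seed = 7))
  fr0 <- compute_anatomical_axis(straight$mesh)
  ang0 <- acos(min(abs(sum(fr0$axis_dir * c(0, 0, 1))), 1)) * 180 / pi
  expect_lt(ang0, 0.1)

  # bowed and noisy: within 2 degrees of the shaft tangent fit
  out <- generate_humerus(bone_phantom_spec(noise_sd = 0.1, seed = 7))
  fr <- compute_anatomical_axis(out$mesh)
  cl <- out$ground_truth$centerline
  L <- out$ground_truth$total_length
  shaft <- cl[cl[, 3] > 0.15 * L & cl[, 3] < 0.70 * L, ]
  tangent <- stats::prcomp(shaft)$rotation[, 1]
  ang <- acos(min(abs(sum(fr$axis_dir * tangent)), 1)) * 180 / pi
  expect_lt(ang, 2)
  # orientation: distal (condylar) end is at large z
  expect_gt(sum(fr$axis_dir * c(0, 0, 1)), 0)
})

test_that("cross-sections are exact on a cylinder and range-checked", {
  cyl <- cylinder_phantom(r = 1, length = 2, n_circ = 256)
  fr <- z_frame(extent = 2)
  sec <- slice_cross_section(cyl, fr, 1)
  r <- plateforge:::row_norms(sweep(sec$contour, 2, c(0, 0, 1)))
  expect_lt(max(abs(r - 1)), 1e-4)
  expect_point_equal(sec$centroid, c(0, 0, 1), tol = 1e-6)
  expect_lt(max(abs(sec$contour[, 3] - 1)), 1e-6)   # in-plane

  expect_error(slice_cross_section(cyl, fr, 5), class = "pf_range_error")
  expect_error(slice_cross_section(cyl, fr, -0.5), class = "pf_range_error")
})

test_that("ROI extraction matches circle geometry and a brute-force oracle", {
  # circle of radius r: middle at (0, r), left/right at -/+ 45 degrees
  r <- 7
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  contour <- cbind(r * cos(th), r * sin(th), 0)
  sec <- structure(list(station = 0, plane_point = c(0, 0, 0),
                        plane_normal = c(0, 0, 1), contour = contour,
                        centroid = c(0, 0, 0), area = pi * r^2),
                   class = "cross_section")
  fr <- z_frame(2)
  tri <- extract_roi_triplet(sec, fr, pi / 2)
  expect_point_equal(tri$middle, c(0, r, 0), tol = 1e-4)
  expect_point_equal(tri$left, c(-r / sqrt(2), r / sqrt(2), 0), tol = 1e-4)
  expect_point_equal(tri$right, c(r / sqrt(2), r / sqrt(2), 0), tol = 1e-4)

  # ellipse vs exhaustive search over a dense discretization
  a <- 15; b <- 10
  ell <- cbind(a * cos(th), b * sin(th), 0)
  sec_e <- structure(list(station = 0, plane_point = c(0, 0, 0),
                          plane_normal = c(0, 0, 1), contour = ell,
                          centroid = c(0, 0, 0), area = pi * a * b),
                     class = "cross_section")
  sector <- 120 * pi / 180
  tri_e <- extract_roi_triplet(sec_e, fr, sector)
  # oracle: dense contour, pick posterior max and the ray crossings by
  # minimizing angular mismatch about the centroid
  dense_th <- seq(0, 2 * pi, length.out = 10001)[-1]
  dense <- cbind(a * cos(dense_th), b * sin(dense_th), 0)
  or_middle <- dense[which.max(dense[, 2]), ]
  ang_of <- atan2(-dense[, 1], dense[, 2])   # angle from +Y toward ml (-X)
  or_left <- dense[which.min(abs(ang_of - sector / 2)), ]
  or_right <- dense[which.min(abs(ang_of + sector / 2)), ]
  expect_point_equal(tri_e$middle, or_middle, tol = 0.05)
  expect_point_equal(tri_e$left, or_left, tol = 0.05)
  expect_point_equal(tri_e$right, or_right, tol = 0.05)

  expect_error(extract_roi_triplet(sec, fr, 0), class = "pf_parameter_error")
  expect_error(extract_roi_triplet(sec, fr, pi), class = "pf_parameter_error")
})

test_that("ROI points lie on the contour and transform rigidly", {
  bone <- generate_humerus(bone_phantom_spec(noise_sd = 0, seed = 9))$mesh
  fr <- compute_anatomical_axis(bone)
  sec <- slice_cross_section(bone, fr, 120)
  tri <- extract_roi_triplet(sec, fr, pi / 2)
  on_contour <- function(p) {
    seg_d <- vapply(seq_len(nrow(sec$contour)), function(i) {
      j <- if (i == nrow(sec$contour)) 1L else i + 1L
      a <- sec$contour[i, ]; bb <- sec$contour[j, ]
      tpar <- sum((p - a) * (bb - a)) / sum((bb - a)^2)
      tpar <- min(max(tpar, 0), 1)
      sqrt(sum((a + tpar * (bb - a) - p)^2))
    }, numeric(1))
    min(seg_d)
  }
  expect_lt(on_contour(tri$left), 1e-6)
  expect_lt(on_contour(tri$middle), 1e-6)
  expect_lt(on_contour(tri$right), 1e-6)

  # rigid equivariance: rotate mesh and frame together
  R <- rotation_oracle(c(2, -1, 1), 1.1)
  shift <- c(4, -7, 12)
  bone_t <- bone
  bone_t$vertices <- bone$vertices %*% t(R) +
    matrix(shift, nrow(bone$vertices), 3, byrow = TRUE)
  fr_t <- anatomical_frame(as.numeric(R %*% fr$origin + shift),
                           as.numeric(R %*% fr$axis_dir),
                           as.numeric(R %*% fr$ap_dir), fr$extent)
  tri_t <- extract_roi_triplet(slice_cross_section(bone_t, fr_t, 120),
                               fr_t, pi / 2)
  expect_point_equal(tri_t$left, as.numeric(R %*% tri$left + shift), 1e-6)
  expect_point_equal(tri_t$middle, as.numeric(R %*% tri$middle + shift), 1e-6)
  expect_point_equal(tri_t$right, as.numeric(R %*% tri$right + shift), 1e-6)
})

test_that("station placement pins endpoints and biases distally", {
  fr <- z_frame(200)
  expect_equal(place_stations(fr, c(0, 160), 9, 0), seq(0, 160, by = 20))
  st3 <- place_stations(fr, c(10, 150), 3, 0.8)
  expect_equal(st3[c(1, 3)], c(10, 150))
  st <- place_stations(fr, c(0, 160), 9, 0.5)
  expect_true(all(diff(diff(st)) <= 1e-9))      # spacing non-increasing
  expect_true(all(diff(st) > 0))
  expect_error(place_stations(fr, c(-5, 160), 9, 0), class = "pf_range_error")
  expect_error(place_stations(fr, c(0, 160), 2, 0),
               class = "pf_parameter_error")
})
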