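test_that("arc fitting matches the perpendicular-bisector oracle", {
  # canonical unit circle
  arc <- arc_through_points(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_point_equal(arc$center, c(0, 0, 0), 1e-12)
  expect_equal(arc$radius, 1, tolerance = 1e-12)
  expect_point_equal(abs(arc$plane_normal), c(0, 0, 1), 1e-12)

  expect_error(arc_through_points(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "pf_degeneracy_error")

  set.seed(42)
  for (k in 1:100) {
    pts <- matrix(stats::rnorm(9, sd = 20), 3, 3)
    area <- plateforge:::vnorm(plateforge:::cross3(pts[2, ] - pts[1, ],
                                                   pts[3, ] - pts[1, ])) / 2
    if (area <= 1e-6) next
    arc <- arc_through_points(pts[1, ], pts[2, ], pts[3, ])
    or <- circumcenter_oracle(pts[1, ], pts[2, ], pts[3, ])
    expect_lt(plateforge:::vnorm(arc$center - or$center), 1e-9)
    expect_lt(abs(arc$radius - or$radius), 1e-9)
    # defining points on the circle, coplanar with the center
    for (p in list(pts[1, ], pts[2, ], pts[3, ])) {
      expect_lt(abs(plateforge:::vnorm(p - arc$center) - arc$radius),
                1e-9 * arc$radius)
      expect_lt(abs(sum((p - arc$center) * arc$plane_normal)), 1e-9)
    }
  }
})

test_that("arc angles agree with a dense-sampling oracle", {
  on_circle <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  a1 <- arc_through_points(on_circle(0), on_circle(45), on_circle(90))
  expect_equal(arc_angle(a1), pi / 2, tolerance = 1e-12)
  a2 <- arc_through_points(on_circle(0), on_circle(90), on_circle(180))
  expect_equal(arc_angle(a2), pi, tolerance = 1e-12)
  # middle on the far side forces the long way around
  a3 <- arc_through_points(on_circle(0), on_circle(180), on_circle(90))
  expect_equal(arc_angle(a3), 3 * pi / 2, tolerance = 1e-12)

  set.seed(7)
  for (k in 1:20) {
    pts <- matrix(stats::rnorm(9, sd = 5), 3, 3)
    if (plateforge:::vnorm(plateforge:::cross3(pts[2, ] - pts[1, ],
                                               pts[3, ] - pts[1, ])) < 1e-4) next
    arc <- arc_through_points(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(arc_angle(arc), arc_angle_oracle(arc), tolerance = 1e-6)
  }
})

test_that("center and supporting distances match closed forms", {
  fr <- z_frame(100)
  on_axis <- arc_through_points(c(1, 0, 10), c(0, 1, 10), c(-1, 0, 10))
  expect_equal(center_distance(on_axis, fr), 0, tolerance = 1e-12)
  off <- arc_through_points(c(11, 0, 10), c(10, 1, 10), c(9, 0, 10))
  expect_equal(center_distance(off, fr), 10, tolerance = 1e-9)

  set.seed(11)
  for (k in 1:20) {
    o <- stats::rnorm(3, sd = 10)
    a <- plateforge:::unitize(stats::rnorm(3))
    hint <- stats::rnorm(3)
    if (plateforge:::vnorm(hint - sum(hint * a) * a) < 1e-3) next
    frk <- anatomical_frame(o, a, hint, 100)
    p <- stats::rnorm(3, sd = 30)
    arc <- list(center = p)
    closed <- plateforge:::vnorm((p - o) - sum((p - o) * frk$axis_dir) *
                                   frk$axis_dir)
    expect_equal(center_distance(structure(arc, class = "arc3d"), frk),
                 closed, tolerance = 1e-12)
    # supporting distance against explicit 2D projection coordinates
    tri <- structure(list(left = stats::rnorm(3, sd = 20),
                          middle = p, right = stats::rnorm(3, sd = 20),
                          station = 0), class = "roi_triplet")
    sd_pkg <- supporting_distances(tri, frk)
    proj2d <- function(q) {
      c(sum((q - o) * frk$axis_dir), sum((q - o) * frk$ap_dir))
    }
    expect_equal(unname(sd_pkg[["d_l"]]), abs(proj2d(tri$left)[2]),
                 tolerance = 1e-12)
    expect_equal(unname(sd_pkg[["d_r"]]), abs(proj2d(tri$right)[2]),
                 tolerance = 1e-12)
  }

  # symmetry about the AP plane, and a point on the axis
  frz <- z_frame(10)
  tri_sym <- structure(list(left = c(-3, 4, 1), middle = c(0, 5, 1),
                            right = c(3, 4, 1), station = 1),
                       class = "roi_triplet")
  sd_sym <- supporting_distances(tri_sym, frz)
  expect_equal(sd_sym[["d_l"]], sd_sym[["d_r"]])
  tri_axis <- structure(list(left = c(0, 0, 5), middle = c(0, 5, 1),
                             right = c(3, 4, 1), station = 1),
                        class = "roi_triplet")
  expect_equal(supporting_distances(tri_axis, frz)[["d_l"]], 0)
})

test_that("assembled cylinder parameters recover the analytic cylinder", {
  cyl <- cylinder_phantom(r = 10, length = 200, n_axial = 40, n_circ = 512)
  fr <- z_frame(200)
  stations <- seq(20, 180, length.out = 9)
  params <- assemble_params(cyl, fr, stations, pi / 2, thickness = 2)
  expect_equal(params$n_sections, 9L)
  expect_lt(max(abs(params$angles - pi / 2)), 1e-3)
  expect_lt(diff(range(params$dist)), 1e-3)
  radii <- vapply(params$roi, function(tr) {
    arc_through_points(tr$left, tr$middle, tr$right)$radius
  }, numeric(1))
  expect_lt(max(abs(radii - 10)), 1e-3)
  expect_equal(params$thickness, 2)
})

test_that("parameters survive a JSON round trip and loading validates", {
  bone <- generate_humerus(bone_phantom_spec(seed = 4))$mesh
  fr <- compute_anatomical_axis(bone)
  st <- place_stations(fr, c(0.4, 0.96) * fr$extent, 9, 0.3)
  params <- assemble_params(bone, fr, st, pi / 2)
  f <- withr::local_tempfile(fileext = ".json")
  save_params(params, f)
  back <- load_params(f)
  expect_equal(back$angles, params$angles, tolerance = 1e-12)
  expect_equal(back$dist, params$dist, tolerance = 1e-12)
  expect_equal(back$thickness, params$thickness)
  for (i in seq_along(params$roi)) {
    expect_point_equal(back$roi[[i]]$left, params$roi[[i]]$left, 1e-12)
    expect_point_equal(back$roi[[i]]$middle, params$roi[[i]]$middle, 1e-12)
  }
  # rebuilt surface identical
  s1 <- loft_surface(params)
  s2 <- loft_surface(back)
  uu <- stats::runif(20); vv <- stats::runif(20)
  expect_lt(max(abs(s1$eval(uu, vv) - s2$eval(uu, vv))), 1e-9)

  # hand-edit an angle out of (0, pi): rejected on load
  txt <- jsonlite::read_json(f)
  txt$angles_rad[[3]] <- 3.5
  jsonlite::write_json(txt, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_params(f), class = "pf_format_error")
})

test_that("parameters are rigid-invariant and scale-equivariant", {
  bone <- generate_humerus(bone_phantom_spec(noise_sd = 0, seed = 6))$mesh
  fr <- compute_anatomical_axis(bone)
  st <- place_stations(fr, c(0.4, 0.96) * fr$extent, 9, 0.3)
  params <- assemble_params(bone, fr, st, pi / 2)

  # rigid motion of mesh + frame leaves every scalar unchanged
  R <- rotation_oracle(c(1, 1, -2), 0.9)
  shift <- c(30, -12, 5)
  bone_t <- bone
  bone_t$vertices <- bone$vertices %*% t(R) +
    matrix(shift, nrow(bone$vertices), 3, byrow = TRUE)
  fr_t <- anatomical_frame(as.numeric(R %*% fr$origin + shift),
                           as.numeric(R %*% fr$axis_dir),
                           as.numeric(R %*% fr$ap_dir), fr$extent)
  params_t <- assemble_params(bone_t, fr_t, st, pi / 2)
  expect_equal(params_t$angles, params$angles, tolerance = 1e-9)
  expect_equal(params_t$dist, params$dist, tolerance = 1e-7)
  expect_equal(params_t$sdist_left, params$sdist_left, tolerance = 1e-7)

  # scaling the bone by s scales distances by s, angles unchanged
  s <- 1.25
  bone_s <- bone
  bone_s$vertices <- bone$vertices * s
  fr_s <- anatomical_frame(fr$origin * s, fr$axis_dir, fr$ap_dir,
                           fr$extent * s)
  params_s <- assemble_params(bone_s, fr_s, st * s, pi / 2)
  expect_equal(params_s$angles, params$angles, tolerance = 1e-3)
  expect_equal(params_s$dist, s * params$dist, tolerance = 1e-2)
  expect_equal(params_s$sdist_left, s * params$sdist_left, tolerance = 1e-2)
  expect_equal(params_s$sdist_right, s * params$sdist_right, tolerance = 1e-2)
})
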