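test_that("control grids have the right combinatorics and lie on the loft", {
  bone <- generate_humerus(bone_phantom_spec(seed = 2))$mesh
  fr <- compute_anatomical_axis(bone)
  st <- place_stations(fr, c(0.4, 0.96) * fr$extent, 9, 0.3)
  params <- assemble_params(bone, fr, st, pi / 2)

  cm <- init_control_mesh(params, 3, 3)
  expect_equal(nrow(cm$vertices), 9L)
  expect_equal(nrow(cm$quads), 4L)
  expect_equal(sum(cm$boundary), 2 * (3 + 3) - 4)

  cm2 <- init_control_mesh(params, 9, 5)
  expect_equal(sum(cm2$boundary), 2 * (9 + 5) - 4)
  surf <- loft_surface(params)
  uu <- rep(seq(0, 1, length.out = 9), 5)
  vv <- rep(seq(0, 1, length.out = 5), each = 9)
  expect_lt(max(abs(cm2$vertices - surf$eval(uu, vv))), 1e-9)
})

test_that("one Catmull-Clark step has the standard combinatorics", {
  # single quad -> 4 quads, 9 vertices
  q1 <- quad_grid(2, 2)
  r1 <- catmull_clark_step(q1)
  expect_equal(nrow(r1$vertices), 9L)
  expect_equal(nrow(r1$quads), 4L)

  # closed cube: V' = V + E + F = 26, F' = 4F = 24, still watertight quads
  cube <- control_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
          c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    rbind(c(4, 3, 2, 1), c(5, 6, 7, 8), c(1, 2, 6, 5),
          c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8)))
  rc <- catmull_clark_step(cube)
  expect_equal(nrow(rc$vertices), 26L)
  expect_equal(nrow(rc$quads), 24L)
  expect_false(any(rc$boundary))
  rc2 <- catmull_clark_step(rc)
  expect_equal(nrow(rc2$vertices), 26L + 48L + 24L)  # V + E + F again

  # open grid keeps exactly one boundary loop
  g <- quad_grid(4, 3)
  rg <- catmull_clark_step(g)
  expect_equal(nrow(rg$quads), 4L * nrow(g$quads))
  expect_equal(sum(rg$boundary), 2 * (7 + 5) - 4)
})

test_that("planar grids stay planar under repeated subdivision", {
  g <- quad_grid(6, 5)
  r <- catmull_clark_step(catmull_clark_step(catmull_clark_step(g)))
  expect_lt(max(abs(r$vertices[, 3])), 1e-12)
  # affine weights: a grid on the plane z = 2x + 3y stays on it exactly
  g2 <- quad_grid(6, 5, z_fn = function(x, y) 2 * x + 3 * y)
  r2 <- catmull_clark_step(catmull_clark_step(g2))
  expect_lt(max(abs(r2$vertices[, 3] -
                      (2 * r2$vertices[, 1] + 3 * r2$vertices[, 2]))),
            1e-12)
})

test_that("the subdivision limit of a regular grid is the bicubic B-spline", {
  set.seed(31)
  nu <- 9; nv <- 8
  zf <- matrix(stats::rnorm(nu * nv, sd = 2), nu, nv)
  g <- quad_grid(nu, nv, z_fn = function(x, y) zf[cbind(x + 1, y + 1)])
  lev <- 2L
  r <- plateforge:::cc_operator_levels(g, lev)$mesh
  h <- 1 / 2^lev
  # lattice lookup by the (exact) x/y coordinates
  key <- paste(round(r$vertices[, 1] / h), round(r$vertices[, 2] / h))
  pos <- function(i, j) match(paste(i, j), key)
  # deep-interior lattice nodes, away from boundary-rule influence
  ii <- seq(2 / h, (nu - 3) / h)
  jj <- seq(2 / h, (nv - 3) / h)
  sten <- c(1, 4, 1) / 6
  for (i in sample(ii, 5)) {
    for (j in sample(jj, 5)) {
      nbh <- outer(i + c(-1, 0, 1), j + c(-1, 0, 1), Vectorize(pos))
      zlim <- as.numeric(t(sten) %*%
                           matrix(r$vertices[nbh, 3], 3, 3) %*% sten)
      zspl <- bicubic_bspline_eval(zf, i * h, j * h)
      expect_lt(abs(zlim - zspl), 1e-6)
    }
  }
})

test_that("fitting conforms the subdivision surface to the target", {
  plane <- tri_mesh(rbind(c(-10, -10, 0), c(20, -10, 0), c(20, 20, 0),
                          c(-10, 20, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)), "plane",
                    validate = FALSE)
  # already on the target: fixed point, no movement
  flat <- quad_grid(6, 5)
  fit0 <- fit_control_mesh(flat, plane, n_iter = 5)
  expect_lt(max(abs(fit0$vertices - flat$vertices)), 1e-12)

  # 1 mm off the plane: solvable projection, converges well under 0.05 mm
  off <- quad_grid(6, 5, z_fn = function(x, y) 1)
  fit1 <- fit_control_mesh(off, plane, n_iter = 50, step = 0.5)
  W <- plateforge:::cc_operator_levels(off, 2)$W
  samples <- W %*% fit1$vertices
  expect_lt(mean(abs(samples[, 3])), 0.05)

  # objective trace is monotone non-increasing
  hist <- attr(fit1, "history")
  expect_true(all(diff(hist) <= 1e-15))

  # fixed boundary leaves rim control points in place
  fitb <- fit_control_mesh(off, plane, n_iter = 10, boundary = "fixed")
  expect_lt(max(abs(fitb$vertices[off$boundary, ] -
                      off$vertices[off$boundary, ])), 1e-12)
})

test_that("fitting a plate control grid to the bone reduces the deviation", {
  out <- generate_humerus(bone_phantom_spec(noise_sd = 0, seed = 3,
                                            n_axial = 50,
                                            n_circumferential = 40))
  fr <- compute_anatomical_axis(out$mesh)
  st <- place_stations(fr, c(0.45, 0.9) * fr$extent, 9, 0.3)
  params <- assemble_params(out$mesh, fr, st, pi / 2)
  cm <- init_control_mesh(params, 9, 5)
  pre <- surface_deviation(control_mesh_to_tri(cm, 2), out$mesh,
                           n_samples = 500, seed = 8)
  fit <- fit_control_mesh(cm, out$mesh, n_iter = 25, step = 0.6)
  post <- surface_deviation(control_mesh_to_tri(fit, 2), out$mesh,
                            n_samples = 500, seed = 8)
  expect_lte(post$median_abs, pre$median_abs)
  expect_lte(post$median_abs, 0.2)
})
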