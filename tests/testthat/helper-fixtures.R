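# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# Pure-cylinder phantom: equal radii, circular sections, no bow, condyle
# flare blended to the same radius.
cylinder_phantom <- function(r = 10, length = 200, n_axial = 40,
                             n_circ = 48, seed = 7) {
  spec <- bone_phantom_spec(
    shaft_length = length * 0.8, shaft_radius_proximal = r,
    shaft_radius_distal = r, ellipse_ratio = 1, condyle_width = 2 * r,
    condyle_height = length * 0.2, bow_sagittal = 0, n_axial = n_axial,
    n_circumferential = n_circ, noise_sd = 0, seed = seed)
  generate_humerus(spec)$mesh
}

z_frame <- function(extent = 200) {
  anatomical_frame(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), extent = extent)
}

unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),    # bottom (z = 0, outward -z)
             c(5, 6, 7), c(5, 7, 8),    # top
             c(1, 2, 6), c(1, 6, 5),    # y = 0
             c(2, 3, 7), c(2, 7, 6),    # x = 1
             c(3, 4, 8), c(3, 8, 7),    # y = 1
             c(4, 1, 5), c(4, 5, 8))    # x = 0
  tri_mesh(v, f, provenance = "unit cube", validate = FALSE)
}

# UV sphere mesh of radius r, consistently outward-oriented.
uv_sphere_mesh <- function(r, n_th = 48, n_ph = 96) {
  th <- seq(0, pi, length.out = n_th + 1)[2:n_th]
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[-1]
  v <- do.call(rbind, lapply(th, function(t) {
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))
  }))
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  top <- nrow(v) - 1L
  bot <- nrow(v)
  nr <- length(th)
  jn <- c(2:n_ph, 1)
  f <- list()
  for (k in seq_len(nr - 1)) {
    a <- (k - 1) * n_ph + seq_len(n_ph)
    f[[k]] <- rbind(cbind(a, a + n_ph, jn + (k - 1) * n_ph),
                    cbind(jn + (k - 1) * n_ph, a + n_ph, jn + k * n_ph))
  }
  f$top <- cbind(seq_len(n_ph), jn, top)
  f$bot <- cbind((nr - 1) * n_ph + jn, (nr - 1) * n_ph + seq_len(n_ph), bot)
  m <- tri_mesh(v, do.call(rbind, f), "uv sphere", validate = FALSE)
  if (plateforge:::mesh_volume(m) < 0) m$faces <- m$faces[, c(3, 2, 1)]
  m
}

# Regular quad control grid with integer (x, y) lattice and z = z_fn(x, y).
quad_grid <- function(nu, nv, z_fn = function(x, y) 0) {
  g <- expand.grid(x = seq_len(nu) - 1, y = seq_len(nv) - 1)
  idx <- function(i, j) i + (j - 1) * nu
  i <- rep(seq_len(nu - 1), nv - 1)
  j <- rep(seq_len(nv - 1), each = nu - 1)
  control_mesh(cbind(g$x, g$y, z_fn(g$x, g$y)),
               cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1),
                     idx(i, j + 1)))
}

# Synthetic ROI triplet on a circle of radius r at height z; left/right
# at +/- sector/2 from posterior (+Y) toward ml (-X).
circle_triplet <- function(r, z, sector = pi / 2) {
  pt <- function(a) c(-r * sin(a), r * cos(a), z)
  structure(list(left = pt(sector / 2), middle = pt(0),
                 right = pt(-sector / 2), station = z),
            class = "roi_triplet")
}

# Parametric cylinder-patch surface (radius r, arc alpha about +Y,
# length len along +Z), hand-built to bypass the loft.
cylinder_patch_surface <- function(r = 10, alpha = pi / 2, len = 100) {
  frame <- z_frame(len)
  ev <- function(u, v) {
    phi <- -alpha / 2 + v * alpha
    cbind(-r * sin(phi), r * cos(phi), len * u)
  }
  structure(list(
    eval = ev,
    sample_grid = function(nu, nv) {
      uu <- seq(0, 1, length.out = nu)
      vv <- seq(0, 1, length.out = nv)
      g <- array(NA_real_, c(nu, nv, 3))
      for (j in seq_len(nv)) g[, j, ] <- ev(uu, rep(vv[j], nu))
      g
    },
    source_params = list(frame = frame, thickness = 2, n_sections = 9,
                         stations = seq(0, len, length.out = 9)),
    u_knots = seq(0, 1, length.out = 9)
  ), class = "plate_surface")
}

# Planar patch surface (a x b mm in the z = 0 plane).
planar_patch_surface <- function(a = 10, b = 10) {
  ev <- function(u, v) cbind(a * u, b * v, 0)
  structure(list(
    eval = ev,
    sample_grid = function(nu, nv) {
      uu <- seq(0, 1, length.out = nu)
      vv <- seq(0, 1, length.out = nv)
      g <- array(NA_real_, c(nu, nv, 3))
      for (j in seq_len(nv)) g[, j, ] <- ev(uu, rep(vv[j], nu))
      g
    },
    source_params = list(frame = NULL, thickness = 2, n_sections = 3,
                         stations = c(0, 5, 10)),
    u_knots = c(0, 0.5, 1)
  ), class = "plate_surface")
}

# --- independent oracles -------------------------------------------------

# Circumcenter of three 3D points by the perpendicular-bisector linear
# system (independent of the in-plane construction in the package).
circumcenter_oracle <- function(a, b, c) {
  n <- plateforge:::cross3(b - a, c - a)
  A <- rbind(b - a, c - a, n)
  rhs <- c((sum(b^2) - sum(a^2)) / 2, (sum(c^2) - sum(a^2)) / 2, sum(n * a))
  x <- solve(A, rhs)
  list(center = as.numeric(x), radius = sqrt(sum((a - x)^2)))
}

# Central angle by dense sampling: walk the circle from start to end
# through mid and accumulate chord angles.
arc_angle_oracle <- function(arc, n = 2e5) {
  f1 <- plateforge:::unitize(arc$point_start - arc$center)
  f2 <- plateforge:::cross3(arc$plane_normal, f1)
  ang_of <- function(p) {
    rel <- p - arc$center
    a <- atan2(sum(rel * f2), sum(rel * f1))
    if (a < 0) a + 2 * pi else a
  }
  am <- ang_of(arc$point_mid)
  ae <- ang_of(arc$point_end)
  # try both candidate sweeps; pick the one passing through mid
  cand <- c(ae, ae - 2 * pi)
  for (sw in cand) {
    tt <- seq(0, 1, length.out = n) * sw
    hit <- min(abs(((am - tt) + pi) %% (2 * pi) - pi))
    if (hit < 2 * pi / n * 2) return(abs(sw))
  }
  NA_real_
}

# Uniform bicubic B-spline surface over an integer control lattice,
# evaluated by the per-patch basis-matrix form.
bspline_basis_seg <- function(s) {
  c((1 - s)^3, 3 * s^3 - 6 * s^2 + 4, -3 * s^3 + 3 * s^2 + 3 * s + 1, s^3) / 6
}

bicubic_bspline_eval <- function(P, u, v) {
  # P: nu x nv matrix of z-values at integer lattice (x = 0..nu-1)
  k <- floor(u); l <- floor(v)
  k <- min(max(k, 1), nrow(P) - 3)
  l <- min(max(l, 1), ncol(P) - 3)
  bu <- bspline_basis_seg(u - k)
  bv <- bspline_basis_seg(v - l)
  as.numeric(t(bu) %*% P[k:(k + 3), l:(l + 3)] %*% bv)
}

rotation_oracle <- function(axis, angle) plateforge:::rotation_about(axis, angle)

expect_point_equal <- function(p, q, tol = 1e-9) {
  expect_lt(max(abs(p - q)), tol)
}
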