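#' Thicken the plate contact surface into a watertight solid
#'
#' Offsets the sampled contact surface by `thickness` along its outward
#' normals (away from the anatomical axis, so the inner face stays the
#' bone-fitting face), stitches the rims with ruled side walls, and
#' returns a closed, outward-oriented solid with positive volume.
#'
#' @param surface a [loft_surface()] result.
#' @param thickness wall thickness in mm (> 0); default 2, the usual
#'   clinical specification.
#' @param nu,nv sampling resolution of the shells.
#' @return watertight `tri_mesh` of the plate solid.
#' @export
thicken <- function(surface, thickness = 2, nu = 80L, nv = 24L) {
  if (!is.numeric(thickness) || !is.finite(thickness) || thickness <= 0) {
    stop_pf("pf_parameter_error", "thickness must be > 0")
  }
  if (nu < 2L || nv < 2L) stop_pf("pf_parameter_error", "need nu, nv >= 2")
  uu <- seq(0, 1, length.out = nu)
  vv <- seq(0, 1, length.out = nv)
  ug <- rep(uu, nv)
  vg <- rep(vv, each = nu)
  inner <- surface$eval(ug, vg)
  nrm <- surface_normals(surface, ug, vg)
  outer_v <- inner + thickness * nrm

  idx <- function(i, j) i + (j - 1L) * nu
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  F_grid <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                  cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))

  # make F_grid's orientation agree with the outward normals
  fc_n <- (nrm[F_grid[, 1], ] + nrm[F_grid[, 2], ] + nrm[F_grid[, 3], ]) / 3
  e1 <- inner[F_grid[, 2], ] - inner[F_grid[, 1], ]
  e2 <- inner[F_grid[, 3], ] - inner[F_grid[, 1], ]
  if (mean(rowSums(cross3_rows(e1, e2) * fc_n)) < 0) {
    F_grid <- F_grid[, c(1, 3, 2)]
  }

  # offset self-intersection check: offset cell normals must not flip
  eo1 <- outer_v[F_grid[, 2], ] - outer_v[F_grid[, 1], ]
  eo2 <- outer_v[F_grid[, 3], ] - outer_v[F_grid[, 1], ]
  if (any(rowSums(cross3_rows(eo1, eo2) * fc_n) <= 0)) {
    stop_pf("pf_geometry_error",
            "offset by %.2f mm self-intersects (normal flip)", thickness)
  }

  n_pts <- nu * nv
  # boundary directed edges of the grid shell (reverse edge absent)
  e_all <- face_edge_table(F_grid)
  keys <- paste(e_all[, 1], e_all[, 2])
  rev_keys <- paste(e_all[, 2], e_all[, 1])
  boundary <- e_all[!(keys %in% rev_keys), , drop = FALSE]

  walls <- rbind(
    cbind(boundary[, 1], boundary[, 2], boundary[, 2] + n_pts),
    cbind(boundary[, 1], boundary[, 2] + n_pts, boundary[, 1] + n_pts)
  )
  faces <- rbind(F_grid[, c(1, 3, 2)],          # inner shell, toward bone
                 F_grid + n_pts,                # outer shell
                 walls)
  solid <- tri_mesh(rbind(inner, outer_v), faces,
                    provenance = "plate solid", validate = FALSE)
  if (mesh_volume(solid) < 0) solid$faces <- solid$faces[, c(1, 3, 2)]
  if (!is_watertight(solid)) {
    stop_pf("pf_geometry_error", "thickened solid is not watertight")
  }
  solid
}

#' Measure the wall thickness of a plate solid
#'
#' Casts rays from interior sample points of the contact surface along
#' the local outward normal and records where each ray exits the solid;
#' verifies the thickness contract of the build.
#'
#' @param solid the [thicken()] result.
#' @param surface the [loft_surface()] the solid was built from.
#' @param n_samples number of interior sample points.
#' @param seed RNG seed for the sample positions.
#' @param margin parametric margin kept away from the rim.
#' @return list with `median`, `min`, `max` (mm) and `n`.
#' @export
measure_thickness <- function(solid, surface, n_samples = 200L, seed = 1L,
                              margin = 0.08) {
  uv <- with_seed(seed, cbind(stats::runif(n_samples, margin, 1 - margin),
                              stats::runif(n_samples, margin, 1 - margin)))
  p <- surface$eval(uv[, 1], uv[, 2])
  nrm <- surface_normals(surface, uv[, 1], uv[, 2])
  d <- rep(NA_real_, n_samples)
  for (k in seq_len(n_samples)) {
    # start just behind the inner face so its own crossing is captured
    t_hit <- ray_mesh_intersections(p[k, ] - 0.05 * nrm[k, ], nrm[k, ], solid)
    t_hit <- t_hit - 0.05
    t_hit <- t_hit[t_hit > 0]
    if (length(t_hit)) d[k] <- max(t_hit)
  }
  miss <- sum(is.na(d))
  if (miss > 0) {
    stop_pf("pf_geometry_error",
            "%d of %d thickness rays missed the solid", miss, n_samples)
  }
  list(median = stats::median(d), min = min(d), max = max(d),
       n = n_samples)
}
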