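.spline_curve <- function(u_knots, pts) {
  fx <- stats::splinefun(u_knots, pts[, 1], method = "natural")
  fy <- stats::splinefun(u_knots, pts[, 2], method = "natural")
  fz <- stats::splinefun(u_knots, pts[, 3], method = "natural")
  structure(function(t) cbind(fx(t), fy(t), fz(t)), class = "space_curve",
            knots = u_knots, points = pts)
}

#' Guiding curves of the plate surface
#'
#' Interpolating natural cubic splines through the left maxima, right
#' maxima and middle (spine) ROI points, parameterized by normalized
#' station: the left/right boundary guiding curves and the surface spine.
#'
#' @param params a [plate_params()] with at least 3 sections.
#' @return list with `left_curve`, `right_curve`, `spine_curve`
#'   (functions `t -> n x 3` points) and `u_knots`.
#' @export
build_guiding_curves <- function(params) {
  if (params$n_sections < 3L) {
    stop_pf("pf_parameter_error", "need at least 3 sections for curves")
  }
  s <- params$stations
  u_knots <- (s - s[1]) / (s[length(s)] - s[1])
  pts_of <- function(field) do.call(rbind, lapply(params$roi, `[[`, field))
  list(left_curve = .spline_curve(u_knots, pts_of("left")),
       right_curve = .spline_curve(u_knots, pts_of("right")),
       spine_curve = .spline_curve(u_knots, pts_of("middle")),
       u_knots = u_knots)
}

#' Loft the plate contact surface through the section arcs
#'
#' Builds the C1 surface `eval(u, v)`: at each section knot `u_i` the
#' surface traces the section's circular arc exactly, parameterized
#' across the arc by normalized arc length `v` (left at `v = 0`, right at
#' `v = 1`), so section-to-section correspondence is geometric rather
#' than index-based; between sections, points of equal `v` are joined by
#' natural cubic splines in `u`. When a stored arc angle disagrees with
#' the arc through the stored ROI points, the angle wins: the arc is
#' re-trimmed symmetrically about its middle point and a warning is
#' raised (the guiding curves are implicitly recomputed from the new
#' endpoints).
#'
#' @param params a [plate_params()].
#' @return object of class `plate_surface` with `eval(u, v)` (vectors of
#'   equal length, returns `n x 3`), `sample_grid(nu, nv)`,
#'   `source_params`, `u_knots`, `arcs`.
#' @export
loft_surface <- function(params) {
  n <- params$n_sections
  if (n < 3L) stop_pf("pf_parameter_error", "need at least 3 sections")
  s <- params$stations
  u_knots <- (s - s[1]) / (s[n] - s[1])

  arcs <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- params$roi[[i]]
    arc <- arc_through_points(tr$left, tr$middle, tr$right)
    a_pts <- arc_angle(arc)
    if (abs(a_pts - params$angles[i]) > 1e-6) {
      warning(sprintf(paste0("section %d: stored angle %.4f rad differs from ",
                             "ROI arc angle %.4f rad; using the stored angle ",
                             "and re-trimming the arc"),
                      i, params$angles[i], a_pts), call. = FALSE)
      arc <- retrim_arc(arc, params$angles[i])
    }
    arcs[[i]] <- arc
  }

  eval_uv <- function(u, v) {
    u <- as.numeric(u); v <- as.numeric(v)
    stopifnot(length(u) == length(v))
    out <- matrix(NA_real_, length(u), 3)
    for (vv in unique(v)) {
      sel <- v == vv
      sec_pts <- do.call(rbind, lapply(arcs, arc_point, v = vv))
      crv <- .spline_curve(u_knots, sec_pts)
      out[sel, ] <- crv(u[sel])
    }
    out
  }

  sample_grid <- function(nu, nv) {
    uu <- seq(0, 1, length.out = nu)
    vv <- seq(0, 1, length.out = nv)
    grid <- array(NA_real_, c(nu, nv, 3))
    for (j in seq_len(nv)) {
      sec_pts <- do.call(rbind, lapply(arcs, arc_point, v = vv[j]))
      crv <- .spline_curve(u_knots, sec_pts)
      grid[, j, ] <- crv(uu)
    }
    grid
  }

  surf <- structure(list(eval = eval_uv, sample_grid = sample_grid,
                         source_params = params, u_knots = u_knots,
                         arcs = arcs,
                         guides = build_guiding_curves(params)),
                    class = "plate_surface")
  check_loft_self_intersection(surf)
  surf
}

# Re-trim an arc to a prescribed central angle, symmetric about the ray
# through its middle point.
retrim_arc <- function(arc, angle) {
  ph <- arc_phases(arc)
  f_mid <- unitize(arc$point_mid - arc$center)
  g2 <- cross3(arc$plane_normal, f_mid)
  ccw <- ph$mid <= ph$end
  half <- angle / 2
  pt_at <- function(a) arc$center + arc$radius * (cos(a) * f_mid + sin(a) * g2)
  if (ccw) {
    structure(list(center = arc$center, radius = arc$radius,
                   plane_normal = arc$plane_normal,
                   point_start = pt_at(-half), point_mid = arc$point_mid,
                   point_end = pt_at(half)), class = "arc3d")
  } else {
    structure(list(center = arc$center, radius = arc$radius,
                   plane_normal = arc$plane_normal,
                   point_start = pt_at(half), point_mid = arc$point_mid,
                   point_end = pt_at(-half)), class = "arc3d")
  }
}

# Detect loft self-intersection via normal flips between u-adjacent grid
# cells; errors naming the section interval involved.
check_loft_self_intersection <- function(surface, nu_per_span = 4L,
                                         nv = 9L) {
  n <- surface$source_params$n_sections
  nu <- nu_per_span * (n - 1L) + 1L
  g <- surface$sample_grid(nu, nv)
  # cell normals from the grid
  du <- g[-1, -1, , drop = FALSE] - g[-nu, -1, , drop = FALSE]
  dv <- g[-1, -1, , drop = FALSE] - g[-1, -nv, , drop = FALSE]
  nrm <- array(NA_real_, dim = dim(du))
  nrm[, , 1] <- du[, , 2] * dv[, , 3] - du[, , 3] * dv[, , 2]
  nrm[, , 2] <- du[, , 3] * dv[, , 1] - du[, , 1] * dv[, , 3]
  nrm[, , 3] <- du[, , 1] * dv[, , 2] - du[, , 2] * dv[, , 1]
  dots <- rowSums(nrm[-1, , , drop = FALSE] * nrm[-(nu - 1), , , drop = FALSE],
                  dims = 2)
  if (any(dots < 0)) {
    bad <- which(dots < 0, arr.ind = TRUE)[1, 1]
    sec <- ceiling(bad / nu_per_span)
    stop_pf("pf_geometry_error",
            "loft self-intersects between sections %d and %d", sec, sec + 1L)
  }
  invisible(TRUE)
}

# Outward (away from the anatomical axis) unit normals of the surface at
# (u, v), by central differences of eval.
surface_normals <- function(surface, u, v, h = 1e-4) {
  up <- pmin(u + h, 1); um <- pmax(u - h, 0)
  vp <- pmin(v + h, 1); vm <- pmax(v - h, 0)
  du <- (surface$eval(up, v) - surface$eval(um, v)) / (up - um)
  dv <- (surface$eval(u, vp) - surface$eval(u, vm)) / (vp - vm)
  nrm <- cross3_rows(du, dv)
  nrm <- nrm / pmax(row_norms(nrm), .Machine$double.xmin)
  fr <- surface$source_params$frame
  p <- surface$eval(u, v)
  if (!is.null(fr)) {
    rel <- sweep(p, 2, fr$origin)
    t_ax <- as.vector(rel %*% fr$axis_dir)
    radial <- rel - outer(t_ax, fr$axis_dir)
    flip <- rowSums(nrm * radial) < 0
    nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  }
  nrm
}

#' Triangulate a plate surface
#'
#' Samples the surface on an `nu x nv` grid and triangulates it into an
#' open shell with `nu * nv` vertices, oriented outward (away from the
#' anatomical axis).
#'
#' @param surface a [loft_surface()] result.
#' @param nu,nv grid resolution along / across the plate (>= 2).
#' @return open-shell `tri_mesh`.
#' @export
surface_to_mesh <- function(surface, nu = 64L, nv = 24L) {
  if (nu < 2L || nv < 2L) stop_pf("pf_parameter_error", "need nu, nv >= 2")
  g <- surface$sample_grid(nu, nv)
  verts <- matrix(aperm(g, c(1, 2, 3)), nu * nv, 3)  # index = i + (j-1)*nu
  idx <- function(i, j) i + (j - 1L) * nu
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  mesh <- tri_mesh(verts, rbind(f1, f2), provenance = "plate surface",
                   validate = FALSE)
  # orient outward: majority vote against radial-out
  fr <- surface$source_params$frame
  if (!is.null(fr)) {
    fc <- (verts[mesh$faces[, 1], ] + verts[mesh$faces[, 2], ] +
             verts[mesh$faces[, 3], ]) / 3
    rel <- sweep(fc, 2, fr$origin)
    t_ax <- as.vector(rel %*% fr$axis_dir)
    radial <- rel - outer(t_ax, fr$axis_dir)
    if (mean(rowSums(face_normals(mesh) * radial)) < 0) {
      mesh$faces <- mesh$faces[, c(1, 3, 2)]
    }
  }
  mesh
}
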