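#' Anatomical reference frame of a long bone
#'
#' The frame every plate parameter is measured in: an origin on the
#' anatomical axis at the proximal end, the axis direction
#' (proximal to distal), the posterior (AP) direction and the
#' medio-lateral direction completing a right-handed orthonormal triple
#' `{axis_dir, ap_dir, ml_dir}`. `extent` is the bone's length along the
#' axis, so stations live in `[0, extent]`.
#'
#' @param origin 3D point on the axis (mm).
#' @param axis_dir unit vector, proximal to distal.
#' @param ap_dir posterior direction; orthogonalized against `axis_dir`.
#' @param extent axial extent in mm (scalar).
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axis_dir, ap_dir, extent = NA_real_) {
  origin <- as_point3(origin, "origin")
  axis_dir <- unitize(as_point3(axis_dir, "axis_dir"))
  ap_raw <- as_point3(ap_dir, "ap_dir")
  ap <- ap_raw - sum(ap_raw * axis_dir) * axis_dir
  if (vnorm(ap) < 1e-8) {
    stop_pf("pf_geometry_error", "ap_dir is (near-)parallel to axis_dir")
  }
  ap <- unitize(ap)
  ml <- cross3(axis_dir, ap)
  structure(list(origin = origin, axis_dir = axis_dir, ap_dir = ap,
                 ml_dir = ml, extent = as.numeric(extent)),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> origin (%.2f, %.2f, %.2f), extent %.1f mm\n",
              x$origin[1], x$origin[2], x$origin[3], x$extent))
  invisible(x)
}

# Perpendicular distance from points (n x 3) to the frame's axis line.
dist_to_axis <- function(points, frame) {
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, frame$origin)
  t_ax <- as.vector(rel %*% frame$axis_dir)
  row_norms(rel - outer(t_ax, frame$axis_dir))
}

# ---- plane slicing ------------------------------------------------------

# Intersect a mesh with a plane; returns a list of closed loops, each an
# ordered k x 3 matrix of points (first point not repeated). Errors if an
# intersected contour is open (non-watertight mesh).
slice_mesh_plane <- function(mesh, point, normal) {
  v <- mesh$vertices
  f <- mesh$faces
  sd <- as.vector(sweep(v, 2, point) %*% unitize(normal))
  # nudge vertices lying exactly in the plane to keep crossings transverse
  on_plane <- abs(sd) < 1e-12
  if (any(on_plane)) sd[on_plane] <- 1e-12
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- which(pmin(s1, s2, s3) < 0 & pmax(s1, s2, s3) > 0)
  if (!length(crossing)) return(list())

  # for each crossing face, its two crossed edges (canonical ids)
  edge_of <- function(i, j) {
    paste(pmin(f[crossing, i], f[crossing, j]),
          pmax(f[crossing, i], f[crossing, j]))
  }
  crosses <- cbind(s1[crossing] * s2[crossing] < 0,
                   s2[crossing] * s3[crossing] < 0,
                   s3[crossing] * s1[crossing] < 0)
  eids <- cbind(edge_of(1, 2), edge_of(2, 3), edge_of(3, 1))
  face_edges <- t(vapply(seq_along(crossing),
                         function(r) eids[r, crosses[r, ]], character(2)))

  # unique crossed edges and their intersection points
  ue <- unique(as.vector(face_edges))
  epts <- matrix(NA_real_, length(ue), 3)
  ij <- do.call(rbind, strsplit(ue, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  tt <- sd[i] / (sd[i] - sd[j])
  epts <- v[i, , drop = FALSE] + tt * (v[j, , drop = FALSE] -
                                         v[i, , drop = FALSE])

  # adjacency: each edge id -> the (1 or 2) crossing faces using it
  eidx <- matrix(match(face_edges, ue), ncol = 2)
  edge_faces <- vector("list", length(ue))
  for (r in seq_len(nrow(eidx))) {
    edge_faces[[eidx[r, 1]]] <- c(edge_faces[[eidx[r, 1]]], r)
    edge_faces[[eidx[r, 2]]] <- c(edge_faces[[eidx[r, 2]]], r)
  }
  if (any(lengths(edge_faces) != 2L)) {
    stop_pf("pf_geometry_error",
            "open intersection contour: mesh is not closed at this plane")
  }

  # walk loops: alternate face -> other edge -> other face
  visited_face <- logical(nrow(eidx))
  loops <- list()
  while (any(!visited_face)) {
    r0 <- which(!visited_face)[1]
    e_cur <- eidx[r0, 1]
    r_cur <- r0
    loop_edges <- integer(0)
    repeat {
      visited_face[r_cur] <- TRUE
      loop_edges <- c(loop_edges, e_cur)
      e_next <- setdiff(eidx[r_cur, ], e_cur)[1]
      pair <- edge_faces[[e_next]]
      r_next <- setdiff(pair, r_cur)
      e_cur <- e_next
      if (!length(r_next) || visited_face[r_next]) {
        loop_edges <- c(loop_edges, e_cur)
        break
      }
      r_cur <- r_next
    }
    # drop the closing duplicate if the walk returned to the start edge
    if (loop_edges[length(loop_edges)] == loop_edges[1]) {
      loop_edges <- loop_edges[-length(loop_edges)]
    }
    loops[[length(loops) + 1L]] <- epts[loop_edges, , drop = FALSE]
  }
  loops
}

# Signed area and area centroid of a closed planar loop given in-plane
# axes (u_axis, w_axis) about `point`.
loop_area_centroid <- function(loop, point, u_axis, w_axis) {
  rel <- sweep(loop, 2, point)
  u <- as.vector(rel %*% u_axis)
  w <- as.vector(rel %*% w_axis)
  u2 <- c(u[-1], u[1]); w2 <- c(w[-1], w[1])
  cr <- u * w2 - u2 * w
  area <- sum(cr) / 2
  cu <- sum((u + u2) * cr) / (6 * area)
  cw <- sum((w + w2) * cr) / (6 * area)
  list(area = abs(area), centroid = point + cu * u_axis + cw * w_axis,
       ccw = area > 0)
}

#' Slice one cross-section
#'
#' Intersects the mesh with the plane normal to the anatomical axis at the
#' given station. When the plane cuts several loops the largest-area loop
#' is kept and the event is recorded in the section's `log` attribute.
#'
#' @param mesh a `tri_mesh` (closed).
#' @param frame an [anatomical_frame()].
#' @param station arc-length position along the axis, mm, in
#'   `[0, frame$extent]`.
#' @return object of class `cross_section`: `station`, `plane_point`,
#'   `plane_normal`, `contour` (ordered closed polyline, `k x 3`),
#'   `centroid`, `area`.
#' @export
slice_cross_section <- function(mesh, frame, station) {
  if (!is.finite(station) || station < 0 || station > frame$extent) {
    stop_pf("pf_range_error",
            "station %.3f outside bone extent [0, %.3f]",
            station, frame$extent)
  }
  point <- frame$origin + station * frame$axis_dir
  loops <- slice_mesh_plane(mesh, point, frame$axis_dir)
  if (!length(loops)) {
    stop_pf("pf_range_error", "no intersection at station %.3f", station)
  }
  info <- lapply(loops, loop_area_centroid, point = point,
                 u_axis = frame$ml_dir, w_axis = frame$ap_dir)
  areas <- vapply(info, `[[`, numeric(1), "area")
  k <- which.max(areas)
  contour <- loops[[k]]
  # orient the contour counter-clockwise in the (ml, ap) plane
  if (!info[[k]]$ccw) contour <- contour[rev(seq_len(nrow(contour))), ,
                                         drop = FALSE]
  out <- structure(list(station = station, plane_point = point,
                        plane_normal = frame$axis_dir, contour = contour,
                        centroid = info[[k]]$centroid, area = areas[k]),
                   class = "cross_section")
  if (length(loops) > 1L) {
    attr(out, "log") <- sprintf(
      "station %.3f: %d loops intersected, kept largest (area %.3f mm^2)",
      station, length(loops), areas[k])
  }
  out
}

#' Read the Left/Middle/Right ROI points off a cross-section
#'
#' The middle point is the contour point with maximal posterior (AP)
#' coordinate (refined parabolically along the polyline). The left and
#' right points are where rays from the section centroid at angles
#' +/- `sector_angle / 2` from the posterior ray meet the contour, so the
#' sector angle directly controls plate width.
#'
#' @param section a [slice_cross_section()] result.
#' @param frame the [anatomical_frame()] the section was cut in.
#' @param sector_angle full angular width of the plate sector, radians,
#'   in `(0, pi)`.
#' @return object of class `roi_triplet`: `left`, `middle`, `right`
#'   (3D points on the contour), `station`.
#' @export
extract_roi_triplet <- function(section, frame, sector_angle) {
  if (!is.finite(sector_angle) || sector_angle <= 0 || sector_angle >= pi) {
    stop_pf("pf_parameter_error", "sector_angle must be in (0, pi)")
  }
  ctr <- section$centroid
  rel <- sweep(section$contour, 2, ctr)
  u <- as.vector(rel %*% frame$ml_dir)
  w <- as.vector(rel %*% frame$ap_dir)
  n <- length(u)
  nxt <- c(2:n, 1)

  # middle: maximal posterior coordinate, parabolic refinement over the
  # polyline arc-length near the argmax vertex
  k <- which.max(w)
  km <- if (k == 1) n else k - 1
  kp <- if (k == n) 1 else k + 1
  sm <- -vnorm(section$contour[k, ] - section$contour[km, ])
  sp <- vnorm(section$contour[kp, ] - section$contour[k, ])
  # quadratic through (sm, w[km]), (0, w[k]), (sp, w[kp])
  denom <- sm * sp * (sm - sp)
  a_q <- (sp * (w[km] - w[k]) - sm * (w[kp] - w[k])) / denom
  b_q <- (sm^2 * (w[kp] - w[k]) - sp^2 * (w[km] - w[k])) / denom
  s_star <- if (abs(a_q) > 1e-14) -b_q / (2 * a_q) else 0
  s_star <- min(max(s_star, sm), sp)
  middle <- if (s_star >= 0 && sp > 0) {
    section$contour[k, ] + (s_star / sp) *
      (section$contour[kp, ] - section$contour[k, ])
  } else if (s_star < 0 && sm < 0) {
    section$contour[k, ] + (s_star / sm) *
      (section$contour[km, ] - section$contour[k, ])
  } else section$contour[k, ]

  ray_hit <- function(phi) {
    d <- c(sin(phi), cos(phi))              # (u, w) components
    s <- -d[2] * u + d[1] * w               # signed side of the ray line
    # vertices exactly on the ray would hide the crossing from the strict
    # sign test; nudge them to one side
    tiny <- 1e-12 * max(abs(s), 1)
    s[abs(s) < tiny] <- tiny
    cross_seg <- which(s * s[nxt] < 0)
    best <- NULL
    for (i in cross_seg) {
      lam <- s[i] / (s[i] - s[nxt][i])
      pu <- u[i] + lam * (u[nxt[i]] - u[i])
      pw <- w[i] + lam * (w[nxt[i]] - w[i])
      t_ray <- d[1] * pu + d[2] * pw
      if (t_ray > 0 && (is.null(best) || t_ray > best$t)) {
        best <- list(t = t_ray, i = i, lam = lam)
      }
    }
    if (is.null(best)) {
      stop_pf("pf_geometry_error",
              "ray at angle %.3f rad does not meet the contour", phi)
    }
    section$contour[best$i, ] + best$lam *
      (section$contour[nxt[best$i], ] - section$contour[best$i, ])
  }

  left <- ray_hit(sector_angle / 2)
  right <- ray_hit(-sector_angle / 2)
  tri_area <- vnorm(cross3(middle - left, right - left)) / 2
  if (tri_area <= 1e-9) {
    stop_pf("pf_geometry_error", "ROI triplet is (near-)collinear")
  }
  structure(list(left = left, middle = middle, right = right,
                 station = section$station),
            class = "roi_triplet")
}

#' Place cross-section stations along the plate span
#'
#' Distributes `n_sections` stations over `plate_span`, endpoints pinned.
#' `distal_bias > 0` shifts density toward the distal end through the
#' warp `g(t) = 1 - (1 - t)^(1 + 2 bias)`, giving non-increasing spacing
#' toward distal; `distal_bias = 0` is uniform.
#'
#' @param frame an [anatomical_frame()] (supplies the valid extent).
#' @param plate_span length-2 vector, proximal and distal end of the
#'   plate footprint along the axis (mm).
#' @param n_sections number of sections (>= 3), default 9.
#' @param distal_bias in `[0, 1]`.
#' @return increasing numeric vector of stations (mm).
#' @export
place_stations <- function(frame, plate_span, n_sections = 9L,
                           distal_bias = 0) {
  if (n_sections < 3L) stop_pf("pf_parameter_error", "need n_sections >= 3")
  if (distal_bias < 0 || distal_bias > 1) {
    stop_pf("pf_parameter_error", "distal_bias must be in [0, 1]")
  }
  if (length(plate_span) != 2L || plate_span[1] >= plate_span[2]) {
    stop_pf("pf_parameter_error", "plate_span must be increasing length-2")
  }
  if (is.finite(frame$extent) &&
      (plate_span[1] < 0 || plate_span[2] > frame$extent)) {
    stop_pf("pf_range_error", "plate_span [%.2f, %.2f] outside bone [0, %.2f]",
            plate_span[1], plate_span[2], frame$extent)
  }
  t <- seq(0, 1, length.out = n_sections)
  g <- 1 - (1 - t)^(1 + 2 * distal_bias)
  g <- g / g[n_sections]
  plate_span[1] + (plate_span[2] - plate_span[1]) * g
}

#' Compute the anatomical axis and frame from a bone mesh
#'
#' Fits the axis as the total-least-squares line through cross-section
#' centroids over the shaft portion of the bone (the long-bone
#' convention), with one refinement pass re-slicing normal to the fitted
#' line. The axis points proximal to distal, identified by the end with
#' the larger cross-section area (the condylar flare); for symmetric
#' shapes either sign may be returned. The posterior direction cannot be
#' inferred from a bare mesh, so `posterior_hint` must supply it (for
#' phantoms, the generator's `+Y`).
#'
#' @param mesh closed `tri_mesh` of the bone.
#' @param shaft_fraction length-2 fractions of the principal extent used
#'   for axis fitting (excludes the condylar flare).
#' @param posterior_hint approximate posterior direction.
#' @param n_slices number of centroid stations used in the fit.
#' @return an [anatomical_frame()] with `extent` filled in.
#' @export
compute_anatomical_axis <- function(mesh, shaft_fraction = c(0.15, 0.70),
                                    posterior_hint = c(0, 1, 0),
                                    n_slices = 40L) {
  if (length(shaft_fraction) != 2L || shaft_fraction[1] < 0 ||
      shaft_fraction[2] > 1 || diff(shaft_fraction) <= 0.05) {
    stop_pf("pf_parameter_error", "invalid shaft_fraction")
  }
  v <- mesh$vertices
  ctr <- colMeans(v)
  dir <- stats::prcomp(v, center = TRUE, scale. = FALSE)$rotation[, 1]

  fit_pass <- function(dir, point) {
    t_all <- as.vector(sweep(v, 2, point) %*% dir)
    lo <- min(t_all); hi <- max(t_all)
    if (hi - lo < 1e-6) {
      stop_pf("pf_geometry_error", "mesh has no extent along the axis")
    }
    tt <- lo + (hi - lo) * seq(shaft_fraction[1], shaft_fraction[2],
                               length.out = n_slices)
    cents <- matrix(NA_real_, length(tt), 3)
    for (i in seq_along(tt)) {
      loops <- slice_mesh_plane(mesh, point + tt[i] * dir, dir)
      if (!length(loops)) next
      basis <- orthobasis(dir)
      info <- lapply(loops, loop_area_centroid, point = point + tt[i] * dir,
                     u_axis = basis[, 1], w_axis = basis[, 2])
      areas <- vapply(info, `[[`, numeric(1), "area")
      cents[i, ] <- info[[which.max(areas)]]$centroid
    }
    cents <- cents[stats::complete.cases(cents), , drop = FALSE]
    if (nrow(cents) < 3L) {
      stop_pf("pf_geometry_error", "too few valid shaft sections for axis fit")
    }
    p <- stats::prcomp(cents, center = TRUE, scale. = FALSE)
    if (p$sdev[1] < 1e-9) {
      stop_pf("pf_geometry_error", "degenerate centroid scatter")
    }
    list(dir = unitize(p$rotation[, 1]), point = colMeans(cents))
  }

  pass1 <- fit_pass(dir, ctr)
  pass2 <- fit_pass(pass1$dir, pass1$point)
  dir <- pass2$dir
  point <- pass2$point
  if (sum(dir * pass1$dir) < 0) dir <- -dir

  # orient proximal -> distal: the distal end carries the condylar flare,
  # i.e. the widest cross-sections sit near that end
  t_all <- as.vector(sweep(v, 2, point) %*% dir)
  lo <- min(t_all); hi <- max(t_all)
  basis <- orthobasis(dir)
  end_width <- function(fracs) {
    mean(vapply(fracs, function(fr) {
      loops <- slice_mesh_plane(mesh, point + (lo + (hi - lo) * fr) * dir, dir)
      if (!length(loops)) return(NA_real_)
      max(vapply(loops, function(l) {
        u <- as.vector(sweep(l, 2, point) %*% basis[, 1])
        w <- as.vector(sweep(l, 2, point) %*% basis[, 2])
        max(diff(range(u)), diff(range(w)))
      }, numeric(1)))
    }, numeric(1)), na.rm = TRUE)
  }
  a_lo <- end_width(c(0.02, 0.06))
  a_hi <- end_width(c(0.94, 0.98))
  if (is.finite(a_lo) && is.finite(a_hi) &&
      abs(a_hi - a_lo) > 1e-6 * max(a_hi, a_lo) && a_lo > a_hi) {
    dir <- -dir
    t_all <- -t_all
    tmp <- lo; lo <- -hi; hi <- -tmp
  }
  origin <- point + lo * dir
  anatomical_frame(origin, dir, posterior_hint, extent = hi - lo)
}

# Any orthonormal basis of the plane normal to `dir` (columns u, w).
orthobasis <- function(dir) {
  dir <- unitize(dir)
  seed <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(seed - sum(seed * dir) * dir)
  cbind(u, cross3(dir, u))
}
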