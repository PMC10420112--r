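#' Circular arc through three points
#'
#' The unique circle through `left`, `middle`, `right`, restricted to the
#' arc running from `left` to `right` through `middle`. The arc is the
#' elementary curve of the parametric plate model: one arc per
#' cross-section.
#'
#' @param left,middle,right 3D points (mm), non-collinear.
#' @return object of class `arc3d`: `center`, `radius`, `plane_normal`,
#'   `point_start` (= left), `point_mid`, `point_end` (= right).
#' @export
arc_through_points <- function(left, middle, right) {
  l <- as_point3(left, "left")
  m <- as_point3(middle, "middle")
  r <- as_point3(right, "right")
  n_raw <- cross3(m - l, r - l)
  if (vnorm(n_raw) / 2 <= 1e-9) {
    stop_pf("pf_degeneracy_error", "arc points are (near-)collinear")
  }
  n <- unitize(n_raw)
  e1 <- unitize(m - l)
  e2 <- cross3(n, e1)
  xm <- sum((m - l) * e1)
  xr <- sum((r - l) * e1)
  yr <- sum((r - l) * e2)
  cx <- xm / 2
  cy <- (xr^2 + yr^2 - 2 * cx * xr) / (2 * yr)
  center <- l + cx * e1 + cy * e2
  structure(list(center = center, radius = sqrt(cx^2 + cy^2),
                 plane_normal = n, point_start = l, point_mid = m,
                 point_end = r),
            class = "arc3d")
}

# In-plane polar angles (radians, in [0, 2pi)) of the arc's three points
# about its center, with start at 0.
arc_phases <- function(arc) {
  f1 <- unitize(arc$point_start - arc$center)
  f2 <- cross3(arc$plane_normal, f1)
  ang <- function(p) {
    rel <- p - arc$center
    a <- atan2(sum(rel * f2), sum(rel * f1))
    if (a < 0) a + 2 * pi else a
  }
  list(f1 = f1, f2 = f2, mid = ang(arc$point_mid), end = ang(arc$point_end))
}

#' Central angle of an arc
#'
#' Angle subtended at the center going from the start point to the end
#' point through the middle point; in `(0, 2*pi)`.
#'
#' @param arc an [arc_through_points()] result.
#' @return angle in radians.
#' @export
arc_angle <- function(arc) {
  ph <- arc_phases(arc)
  if (ph$mid <= ph$end) ph$end else 2 * pi - ph$end
}

# Point on the arc at normalized arc length v in [0, 1] (start -> end
# through mid). Vectorized over v.
arc_point <- function(arc, v) {
  ph <- arc_phases(arc)
  ccw <- ph$mid <= ph$end
  sweep_ang <- if (ccw) ph$end else 2 * pi - ph$end
  phi <- if (ccw) v * sweep_ang else -v * sweep_ang
  outer(cos(phi), ph$f1) * arc$radius + outer(sin(phi), ph$f2) * arc$radius +
    matrix(arc$center, length(v), 3, byrow = TRUE)
}

# Normalized arc-length position of the middle point.
arc_mid_fraction <- function(arc) {
  ph <- arc_phases(arc)
  if (ph$mid <= ph$end) ph$mid / ph$end else (2 * pi - ph$mid) / (2 * pi - ph$end)
}

#' Distance from the arc center to the anatomical axis
#'
#' Perpendicular (point-to-line) distance of the arc center to the
#' frame's axis; one of the personalization parameters.
#'
#' @param arc an `arc3d`.
#' @param frame an [anatomical_frame()].
#' @return distance in mm.
#' @export
center_distance <- function(arc, frame) {
  as.numeric(dist_to_axis(arc$center, frame))
}

#' Supporting distances of a ROI triplet
#'
#' The left and right ROI points and the anatomical axis are projected
#' into the AP plane (spanned by the axis and posterior directions); the
#' supporting distances are the in-plane perpendicular distances of the
#' projected points to the projected axis. They let a usable plate be
#' rebuilt from a single AP radiograph.
#'
#' @param triplet a [extract_roi_triplet()] result.
#' @param frame an [anatomical_frame()].
#' @return named numeric vector `c(d_l, d_r)` in mm.
#' @export
supporting_distances <- function(triplet, frame) {
  d_of <- function(p) abs(sum((p - frame$origin) * frame$ap_dir))
  c(d_l = d_of(triplet$left), d_r = d_of(triplet$right))
}

#' Parametric plate description
#'
#' Bundles the full parameter set of the plate contact surface: the ROI
#' point matrix (one Left/Middle/Right triplet per section), the arc
#' angles, the arc-center distances to the anatomical axis, the left and
#' right supporting distances in the AP plane, and the solid thickness.
#'
#' @param roi list of `roi_triplet` (stations strictly increasing).
#' @param angles arc central angles, radians, each in `(0, pi)`.
#' @param dist arc-center-to-axis distances, mm (>= 0).
#' @param sdist_left,sdist_right supporting distances, mm (>= 0).
#' @param thickness plate solid thickness, mm (> 0); default 2.
#' @param frame the [anatomical_frame()] the parameters are measured in.
#' @return object of class `plate_params`.
#' @export
plate_params <- function(roi, angles, dist, sdist_left, sdist_right,
                         thickness = 2, frame = NULL) {
  n <- length(roi)
  if (!all(lengths(list(angles, dist, sdist_left, sdist_right)) == n)) {
    stop_pf("pf_format_error", "parameter vectors must all have length %d", n)
  }
  stations <- vapply(roi, `[[`, numeric(1), "station")
  if (n >= 2 && any(diff(stations) <= 0)) {
    stop_pf("pf_format_error", "ROI stations must be strictly increasing")
  }
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= pi)) {
    stop_pf("pf_format_error", "arc angles must lie in (0, pi)")
  }
  if (any(dist < 0) || any(sdist_left < 0) || any(sdist_right < 0)) {
    stop_pf("pf_format_error", "distances must be >= 0")
  }
  if (!is.finite(thickness) || thickness <= 0) {
    stop_pf("pf_parameter_error", "thickness must be > 0")
  }
  structure(list(roi = roi, angles = as.numeric(angles),
                 dist = as.numeric(dist),
                 sdist_left = as.numeric(sdist_left),
                 sdist_right = as.numeric(sdist_right),
                 thickness = thickness, frame = frame,
                 stations = stations, n_sections = n),
            class = "plate_params")
}

#' @export
print.plate_params <- function(x, ...) {
  cat(sprintf(paste0("<plate_params> %d sections, stations %.1f-%.1f mm, ",
                     "thickness %.2f mm\n"),
              x$n_sections, min(x$stations), max(x$stations), x$thickness))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.plate_params <- function(x, ...) {
  data.frame(
    section = seq_len(x$n_sections),
    station_mm = x$stations,
    angle_deg = x$angles * 180 / pi,
    dist_mm = x$dist,
    sdist_left_mm = x$sdist_left,
    sdist_right_mm = x$sdist_right
  )
}

#' Extract the full plate parameter set from a bone mesh
#'
#' Runs the per-section chain - slice, read the ROI triplet, fit the
#' circular arc, measure angle, center distance and supporting
#' distances - and assembles a [plate_params()].
#'
#' @param mesh closed bone `tri_mesh`.
#' @param frame an [anatomical_frame()].
#' @param stations section stations (mm), strictly increasing.
#' @param sector_angles plate sector angle per section (radians); a
#'   scalar is recycled.
#' @param thickness plate thickness, mm; default 2 (the usual clinical
#'   choice, adjustable to the physician's specification).
#' @return a [plate_params()].
#' @export
assemble_params <- function(mesh, frame, stations, sector_angles,
                            thickness = 2) {
  n <- length(stations)
  if (length(sector_angles) == 1L) sector_angles <- rep(sector_angles, n)
  if (length(sector_angles) != n) {
    stop_pf("pf_parameter_error",
            "sector_angles must have length 1 or %d", n)
  }
  roi <- vector("list", n)
  angles <- dist <- sdl <- sdr <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sec <- slice_cross_section(mesh, frame, stations[i])
      tri <- extract_roi_triplet(sec, frame, sector_angles[i])
      arc <- arc_through_points(tri$left, tri$middle, tri$right)
      list(tri = tri, arc = arc)
    }, plateforge_error = function(e) {
      stop_pf(class(e)[1], "section %d (station %.2f mm): %s",
              i, stations[i], conditionMessage(e))
    })
    roi[[i]] <- res$tri
    angles[i] <- arc_angle(res$arc)
    dist[i] <- center_distance(res$arc, frame)
    sd_i <- supporting_distances(res$tri, frame)
    sdl[i] <- sd_i[["d_l"]]
    sdr[i] <- sd_i[["d_r"]]
  }
  plate_params(roi, angles, dist, sdl, sdr, thickness = thickness,
               frame = frame)
}

#' Save / load plate parameters as JSON
#'
#' Lossless (full double precision) round trip of a [plate_params()];
#' loading re-validates every invariant, so a hand-edited file with, for
#' example, an arc angle outside `(0, pi)` is rejected.
#'
#' @param params a [plate_params()].
#' @param path JSON file path.
#' @return `save_params`: `path` invisibly; `load_params`: the restored
#'   [plate_params()].
#' @export
save_params <- function(params, path) {
  roi_arr <- lapply(params$roi, function(tr) {
    list(left = tr$left, middle = tr$middle, right = tr$right,
         station = tr$station)
  })
  fr <- params$frame
  obj <- list(
    schema_version = "1.0",
    n_sections = params$n_sections,
    roi = roi_arr,
    angles_rad = params$angles,
    dist_mm = params$dist,
    sdist_left_mm = params$sdist_left,
    sdist_right_mm = params$sdist_right,
    stations_mm = params$stations,
    thickness_mm = params$thickness,
    frame = if (is.null(fr)) NULL else
      list(origin = fr$origin, axis_dir = fr$axis_dir,
           ap_dir = fr$ap_dir, extent = fr$extent)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop_pf("pf_format_error", "file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_pf("pf_format_error",
                                              "unparsable JSON: %s", path))
  need <- c("schema_version", "roi", "angles_rad", "dist_mm",
            "sdist_left_mm", "sdist_right_mm", "thickness_mm")
  if (!all(need %in% names(obj))) {
    stop_pf("pf_format_error", "parameter file missing keys: %s",
            paste(setdiff(need, names(obj)), collapse = ", "))
  }
  num <- function(x) as.numeric(unlist(x))
  roi <- lapply(obj$roi, function(tr) {
    structure(list(left = num(tr$left), middle = num(tr$middle),
                   right = num(tr$right), station = num(tr$station)),
              class = "roi_triplet")
  })
  frame <- if (!is.null(obj$frame)) {
    anatomical_frame(num(obj$frame$origin), num(obj$frame$axis_dir),
                     num(obj$frame$ap_dir), num(obj$frame$extent))
  }
  obj$angles_rad <- num(obj$angles_rad)
  obj$dist_mm <- num(obj$dist_mm)
  obj$sdist_left_mm <- num(obj$sdist_left_mm)
  obj$sdist_right_mm <- num(obj$sdist_right_mm)
  obj$thickness_mm <- num(obj$thickness_mm)
  tryCatch(
    plate_params(roi, obj$angles_rad, obj$dist_mm, obj$sdist_left_mm,
                 obj$sdist_right_mm, thickness = obj$thickness_mm,
                 frame = frame),
    plateforge_error = function(e) {
      stop_pf("pf_format_error", "invalid parameter file %s: %s",
              path, conditionMessage(e))
    }
  )
}

#' Re-extract plate parameters from a built plate surface
#'
#' Reads each section curve off the surface itself (left and right rim
#' points, posterior-most point as the middle) and re-fits the arcs.
#' Used to verify that surface construction preserves the parameter set.
#'
#' @param surface a [loft_surface()] result.
#' @param frame the measuring [anatomical_frame()].
#' @param n_dense samples per section curve for the middle-point search.
#' @return a [plate_params()].
#' @export
params_from_surface <- function(surface, frame, n_dense = 720L) {
  src <- surface$source_params
  n <- src$n_sections
  u_knots <- surface$u_knots
  roi <- vector("list", n)
  angles <- dist <- sdl <- sdr <- numeric(n)
  vv <- seq(0, 1, length.out = n_dense)
  for (i in seq_len(n)) {
    pts <- surface$eval(rep(u_knots[i], n_dense), vv)
    w <- as.vector(sweep(pts, 2, frame$origin) %*% frame$ap_dir)
    k <- which.max(w)
    middle <- pts[k, ]
    tri <- structure(list(left = pts[1, ], middle = middle,
                          right = pts[n_dense, ],
                          station = src$stations[i]),
                     class = "roi_triplet")
    arc <- arc_through_points(tri$left, tri$middle, tri$right)
    roi[[i]] <- tri
    angles[i] <- arc_angle(arc)
    dist[i] <- center_distance(arc, frame)
    sd_i <- supporting_distances(tri, frame)
    sdl[i] <- sd_i[["d_l"]]
    sdr[i] <- sd_i[["d_r"]]
  }
  plate_params(roi, angles, dist, sdl, sdr,
               thickness = src$thickness, frame = frame)
}
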