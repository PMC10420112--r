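#' Free-form deformation lattice
#'
#' A trivariate Bernstein FFD box: origin plus three spanning vectors
#' define the parallelepiped, and an `l x m x n` grid of control points
#' (initially the regular grid positions) defines the deformation.
#'
#' @param origin corner of the lattice box (mm).
#' @param axes `3 x 3` matrix whose columns span the box.
#' @param degree integer triple `c(l, m, n)` of control points per axis
#'   (each >= 2).
#' @return object of class `ffd_lattice` with `control` array
#'   `(l, m, n, 3)`; edit entries of `control` to deform.
#' @export
ffd_lattice <- function(origin, axes, degree = c(2L, 2L, 2L)) {
  origin <- as_point3(origin, "origin")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3L, 3L)) || abs(det(axes)) < 1e-12) {
    stop_pf("pf_parameter_error", "axes must be a non-singular 3 x 3 matrix")
  }
  degree <- as.integer(degree)
  if (length(degree) != 3L || any(degree < 2L)) {
    stop_pf("pf_parameter_error", "degree must be three integers >= 2")
  }
  l <- degree[1]; m <- degree[2]; n <- degree[3]
  control <- array(NA_real_, c(l, m, n, 3))
  for (i in seq_len(l)) for (j in seq_len(m)) for (k in seq_len(n)) {
    control[i, j, k, ] <- origin +
      axes %*% c((i - 1) / (l - 1), (j - 1) / (m - 1), (k - 1) / (n - 1))
  }
  structure(list(origin = origin, axes = axes, degree = degree,
                 control = control),
            class = "ffd_lattice")
}

# Fit the smallest axis-aligned lattice box around a mesh (small padding
# so every vertex is strictly inside).
ffd_lattice_around <- function(mesh, degree = c(3L, 3L, 3L), pad = 1e-6) {
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  ffd_lattice(lo, diag(hi - lo), degree)
}

bernstein_basis <- function(t, n_ctrl) {
  d <- n_ctrl - 1L
  vapply(0:d, function(i) choose(d, i) * t^i * (1 - t)^(d - i),
         numeric(length(t)))
}

#' Deform a mesh through an FFD lattice
#'
#' Classic trivariate Bernstein free-form deformation: each vertex is
#' mapped through the tensor-product Bernstein polynomial of the control
#' points at its local box coordinates. Topology is unchanged. With an
#' undeformed lattice this is the identity map, and any affine transform
#' encoded in the control points is reproduced exactly.
#'
#' @param mesh a `tri_mesh` lying inside the lattice box.
#' @param lattice an [ffd_lattice()].
#' @return deformed `tri_mesh`.
#' @export
ffd_deform <- function(mesh, lattice) {
  rel <- sweep(mesh$vertices, 2, lattice$origin)
  stu <- t(solve(lattice$axes, t(rel)))
  out_box <- which(rowSums(stu < -1e-9 | stu > 1 + 1e-9) > 0)
  if (length(out_box)) {
    stop_pf("pf_range_error",
            "%d vertices outside the lattice box (first: %s)",
            length(out_box),
            paste(utils::head(out_box, 5L), collapse = ", "))
  }
  stu <- pmin(pmax(stu, 0), 1)
  l <- lattice$degree[1]; m <- lattice$degree[2]; n <- lattice$degree[3]
  Bs <- bernstein_basis(stu[, 1], l)
  Bt <- bernstein_basis(stu[, 2], m)
  Bu <- bernstein_basis(stu[, 3], n)
  new_v <- matrix(0, nrow(mesh$vertices), 3)
  for (i in seq_len(l)) for (j in seq_len(m)) for (k in seq_len(n)) {
    coef <- Bs[, i] * Bt[, j] * Bu[, k]
    new_v <- new_v + outer(coef, lattice$control[i, j, k, ])
  }
  mesh$vertices <- new_v
  mesh
}

#' Scale plate parameters from radiograph projection factors
#'
#' Personalizes a template parameter set when only an X-ray projection is
#' available: all in-plane quantities (center distances, supporting
#' distances, in-plane ROI coordinates) scale by `scale_ap`, stations by
#' `scale_axial`; the arc angles and the thickness are unchanged. With a
#' single AP view pass `scale_axial = scale_ap`; the resulting plate is a
#' less accurate but usable template (a warning notes the single-view
#' approximation when the two factors are equal by default).
#'
#' @param params a [plate_params()] with a frame.
#' @param scale_ap in-plane scale factor (> 0).
#' @param scale_axial axial scale factor (> 0); defaults to `scale_ap`.
#' @return scaled [plate_params()].
#' @export
scale_params_from_projection <- function(params, scale_ap,
                                         scale_axial = scale_ap) {
  if (!is.finite(scale_ap) || scale_ap <= 0 ||
      !is.finite(scale_axial) || scale_axial <= 0) {
    stop_pf("pf_parameter_error", "scale factors must be > 0")
  }
  fr <- params$frame
  if (is.null(fr)) stop_pf("pf_parameter_error", "params carry no frame")
  scale_point <- function(p) {
    rel <- p - fr$origin
    z <- sum(rel * fr$axis_dir)
    inplane <- rel - z * fr$axis_dir
    fr$origin + scale_axial * z * fr$axis_dir + scale_ap * inplane
  }
  roi <- lapply(params$roi, function(tr) {
    structure(list(left = scale_point(tr$left),
                   middle = scale_point(tr$middle),
                   right = scale_point(tr$right),
                   station = scale_axial * tr$station),
              class = "roi_triplet")
  })
  frame2 <- anatomical_frame(fr$origin, fr$axis_dir, fr$ap_dir,
                             extent = fr$extent * scale_axial)
  plate_params(roi,
               angles = params$angles,
               dist = scale_ap * params$dist,
               sdist_left = scale_ap * params$sdist_left,
               sdist_right = scale_ap * params$sdist_right,
               thickness = params$thickness,
               frame = frame2)
}

#' Estimate the projection scale factor from matched landmarks
#'
#' Maps template millimetres to patient millimetres by the ratio of a
#' landmark's pixel measure on the patient radiograph to the same
#' landmark's pixel measure on the template rendered at known scale.
#'
#' @param template_landmark_mm the landmark's physical size on the
#'   template (mm, > 0; recorded for traceability).
#' @param image_landmark_px landmark measure on the patient image (px).
#' @param template_px landmark measure on the template rendering (px).
#' @return dimensionless scale factor.
#' @export
estimate_scale <- function(template_landmark_mm, image_landmark_px,
                           template_px) {
  vals <- c(template_landmark_mm, image_landmark_px, template_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_pf("pf_parameter_error", "all landmark measures must be > 0")
  }
  image_landmark_px / template_px
}

# Orthographic AP-silhouette width of a mesh (max ML extent), used to
# recover the projection scale of a phantom in tests and the CLI.
ap_silhouette_width <- function(mesh, frame) {
  u <- as.vector(sweep(mesh$vertices, 2, frame$origin) %*% frame$ml_dir)
  max(u) - min(u)
}
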