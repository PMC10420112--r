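#' Synthetic humerus phantom specification
#'
#' Parameter set for a humerus-like bone phantom: a tapering elliptical
#' shaft with an optional sagittal bow, flaring medio-laterally over the
#' distal (condylar) segment, plus optional surface noise along vertex
#' normals. The phantom stands in for a CT-derived surface model so the
#' whole plate pipeline can be exercised with analytic ground truth.
#'
#' Conventions of the generator frame: the long axis is +Z
#' (proximal at z = 0, distal at z = shaft_length + condyle_height),
#' posterior is +Y, and the medio-lateral direction is X. The
#' cross-section at height z is the ellipse with AP semi-axis `r(z)` and
#' ML semi-axis `ellipse_ratio * r(z)`, where `r(z)` tapers linearly from
#' `shaft_radius_proximal` to `shaft_radius_distal` along the shaft.
#' Defaults approximate an adult humerus at plate scale.
#'
#' @param shaft_length shaft length, mm.
#' @param shaft_radius_proximal,shaft_radius_distal AP semi-axis at the
#'   proximal / distal end of the shaft, mm.
#' @param ellipse_ratio ML/AP semi-axis ratio, in `[0.5, 2]`.
#' @param condyle_width full medio-lateral width at the distal end, mm.
#' @param condyle_height length of the condylar flare segment, mm.
#' @param bow_sagittal maximum posterior deflection of the centerline, mm.
#' @param n_axial number of axial stations (>= 20).
#' @param n_circumferential points per ring (>= 16).
#' @param noise_sd SD of surface noise along vertex normals, mm.
#' @param seed RNG seed for the noise.
#' @return object of class `bone_phantom_spec`.
#' @export
bone_phantom_spec <- function(shaft_length = 210,
                              shaft_radius_proximal = 12,
                              shaft_radius_distal = 10,
                              ellipse_ratio = 1.2,
                              condyle_width = 42,
                              condyle_height = 40,
                              bow_sagittal = 4,
                              n_axial = 80,
                              n_circumferential = 48,
                              noise_sd = 0.05,
                              seed = 1L) {
  spec <- list(shaft_length = shaft_length,
               shaft_radius_proximal = shaft_radius_proximal,
               shaft_radius_distal = shaft_radius_distal,
               ellipse_ratio = ellipse_ratio,
               condyle_width = condyle_width,
               condyle_height = condyle_height,
               bow_sagittal = bow_sagittal,
               n_axial = as.integer(n_axial),
               n_circumferential = as.integer(n_circumferential),
               noise_sd = noise_sd,
               seed = as.integer(seed))
  lengths <- c(shaft_length, shaft_radius_proximal, shaft_radius_distal,
               condyle_width, condyle_height)
  if (any(!is.finite(unlist(spec[1:10])))) {
    stop_pf("pf_parameter_error", "non-finite phantom parameter")
  }
  if (any(lengths <= 0)) {
    stop_pf("pf_parameter_error", "all phantom lengths must be > 0")
  }
  if (ellipse_ratio < 0.5 || ellipse_ratio > 2) {
    stop_pf("pf_parameter_error", "ellipse_ratio must be in [0.5, 2]")
  }
  if (bow_sagittal < 0 || noise_sd < 0) {
    stop_pf("pf_parameter_error", "bow_sagittal and noise_sd must be >= 0")
  }
  if (spec$n_axial < 20L || spec$n_circumferential < 16L) {
    stop_pf("pf_parameter_error",
            "need n_axial >= 20 and n_circumferential >= 16")
  }
  structure(spec, class = "bone_phantom_spec")
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Analytic cross-section of the phantom at height z: ellipse center,
# semi-axes and in-plane axes of the generator frame.
phantom_section <- function(spec, z) {
  total <- spec$shaft_length + spec$condyle_height
  r <- spec$shaft_radius_proximal +
    (spec$shaft_radius_distal - spec$shaft_radius_proximal) *
      pmin(z / spec$shaft_length, 1)
  a_ml <- spec$ellipse_ratio * r
  in_condyle <- z > spec$shaft_length
  if (any(in_condyle)) {
    s <- smoothstep((z - spec$shaft_length) / spec$condyle_height)
    a_tip <- spec$condyle_width / 2
    a_ml <- ifelse(in_condyle, a_ml + s * (a_tip - a_ml), a_ml)
  }
  y_bow <- spec$bow_sagittal * sin(pi * z / total)
  list(center = cbind(0, y_bow, z), a_ml = a_ml, b_ap = r,
       ml_axis = c(1, 0, 0), ap_axis = c(0, 1, 0))
}

#' Generate a synthetic humerus mesh with ground truth
#'
#' Builds a watertight phantom mesh from a [bone_phantom_spec()] together
#' with its analytic ground truth (centerline polyline and the
#' cross-section function). With `noise_sd = 0` the mesh vertices lie
#' exactly on the analytic surface; output is identical for identical
#' spec and seed.
#'
#' @param spec a [bone_phantom_spec()].
#' @return list with `mesh` (a `tri_mesh`) and `ground_truth` (class
#'   `bone_ground_truth`: `centerline` polyline, `section_fn(z)`,
#'   `posterior` direction, `axis` direction, `total_length`).
#' @export
generate_humerus <- function(spec) {
  if (!inherits(spec, "bone_phantom_spec")) {
    stop_pf("pf_parameter_error", "spec must be a bone_phantom_spec")
  }
  total <- spec$shaft_length + spec$condyle_height
  z <- seq(0, total, length.out = spec$n_axial)
  theta <- seq(0, 2 * pi, length.out = spec$n_circumferential + 1L)[-1L]
  nc <- spec$n_circumferential

  sec <- phantom_section(spec, z)
  verts <- matrix(NA_real_, spec$n_axial * nc + 2L, 3L)
  for (k in seq_along(z)) {
    idx <- (k - 1L) * nc + seq_len(nc)
    verts[idx, 1] <- sec$a_ml[k] * cos(theta)
    verts[idx, 2] <- sec$center[k, 2] + sec$b_ap[k] * sin(theta)
    verts[idx, 3] <- z[k]
  }
  apex_prox <- spec$n_axial * nc + 1L
  apex_dist <- apex_prox + 1L
  verts[apex_prox, ] <- sec$center[1, ]
  verts[apex_dist, ] <- sec$center[spec$n_axial, ]

  faces <- vector("list", spec$n_axial + 1L)
  jn <- c(seq_len(nc - 1L) + 1L, 1L)  # next index around the ring
  for (k in seq_len(spec$n_axial - 1L)) {
    a <- (k - 1L) * nc + seq_len(nc)
    b <- a + nc
    faces[[k]] <- rbind(cbind(a, jn + (k - 1L) * nc, b),
                        cbind(jn + (k - 1L) * nc, jn + k * nc, b))
  }
  faces[[spec$n_axial]] <- cbind(seq_len(nc), apex_prox,
                                 jn)                       # proximal cap
  faces[[spec$n_axial + 1L]] <- cbind((spec$n_axial - 1L) * nc + seq_len(nc),
                                      (spec$n_axial - 1L) * nc + jn,
                                      apex_dist)           # distal cap
  mesh <- tri_mesh(verts, do.call(rbind, faces),
                   provenance = sprintf("synthetic humerus (seed %d)",
                                        spec$seed),
                   validate = FALSE)
  mesh <- orient_outward(mesh)

  if (spec$noise_sd > 0) {
    mesh <- perturb(mesh, spec$noise_sd, spec$seed)
  }

  gt <- structure(list(
    centerline = sec$center,
    section_fn = function(zq) phantom_section(spec, zq),
    posterior = c(0, 1, 0),
    axis = c(0, 0, 1),
    total_length = total,
    spec = spec
  ), class = "bone_ground_truth")
  list(mesh = mesh, ground_truth = gt)
}

#' Displace mesh vertices along their normals
#'
#' Adds i.i.d. Gaussian displacement `N(0, noise_sd^2)` along area-weighted
#' vertex normals, emulating segmentation roughness. Topology is
#' unchanged; `noise_sd = 0` returns the mesh untouched.
#'
#' @param mesh a `tri_mesh`.
#' @param noise_sd displacement SD in mm (>= 0).
#' @param seed RNG seed.
#' @return perturbed `tri_mesh`.
#' @export
perturb <- function(mesh, noise_sd, seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_pf("pf_parameter_error", "noise_sd must be >= 0")
  }
  if (noise_sd == 0) return(mesh)
  vn <- vertex_normals(mesh)
  d <- with_seed(seed, stats::rnorm(nrow(mesh$vertices), 0, noise_sd))
  mesh$vertices <- mesh$vertices + d * vn
  mesh
}

# JSON-serializable view of the ground truth (CLI sidecar).
ground_truth_sidecar <- function(gt) {
  z <- gt$centerline[, 3]
  sec <- gt$section_fn(z)
  list(
    posterior = gt$posterior,
    axis = gt$axis,
    total_length = gt$total_length,
    centerline = gt$centerline,
    sections = data.frame(z = z, center_y = sec$center[, 2],
                          a_ml = sec$a_ml, b_ap = sec$b_ap),
    spec = unclass(gt$spec)
  )
}
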