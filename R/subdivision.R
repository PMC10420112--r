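#' Quad control mesh for subdivision surfaces
#'
#' @param vertices `n x 3` control point matrix (mm).
#' @param quads `m x 4` integer matrix of vertex indices (consistent
#'   orientation).
#' @param provenance free-text tag.
#' @return object of class `control_mesh` with per-vertex boundary flags.
#' @export
control_mesh <- function(vertices, quads, provenance = "control mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  quads <- as.matrix(quads)
  storage.mode(quads) <- "integer"
  if (ncol(vertices) != 3L || ncol(quads) != 4L) {
    stop_pf("pf_geometry_error", "need n x 3 vertices and m x 4 quads")
  }
  if (min(quads) < 1L || max(quads) > nrow(vertices)) {
    stop_pf("pf_geometry_error", "quad indices out of range")
  }
  if (any(apply(quads, 1, anyDuplicated) > 0)) {
    stop_pf("pf_geometry_error", "degenerate quad (repeated vertex)")
  }
  ed <- quad_edges(quads)
  cnt <- table(ed$key)
  if (any(cnt > 2L)) {
    stop_pf("pf_geometry_error", "non-manifold edge (more than 2 quads)")
  }
  boundary_keys <- names(cnt)[cnt == 1L]
  bverts <- unique(as.integer(unlist(strsplit(boundary_keys, " "))))
  boundary <- rep(FALSE, nrow(vertices))
  boundary[bverts] <- TRUE
  structure(list(vertices = vertices, quads = quads, boundary = boundary,
                 provenance = provenance),
            class = "control_mesh")
}

#' @export
print.control_mesh <- function(x, ...) {
  cat(sprintf("<control_mesh> %d vertices (%d boundary), %d quads [%s]\n",
              nrow(x$vertices), sum(x$boundary), nrow(x$quads),
              x$provenance))
  invisible(x)
}

quad_edges <- function(quads) {
  from <- as.vector(quads)
  to <- as.vector(quads[, c(2, 3, 4, 1)])
  list(from = from, to = to,
       key = paste(pmin(from, to), pmax(from, to)),
       face = rep(seq_len(nrow(quads)), 4L))
}

#' Initialize a control grid over the plate footprint
#'
#' Samples an `nu x nv` grid of control points from the lofted plate
#' surface; the subdivision surface of this grid is then fitted to the
#' bone with [fit_control_mesh()].
#'
#' @param params a [plate_params()].
#' @param nu,nv grid size (>= 2); vertex `(i, j)` sits at
#'   `eval((i-1)/(nu-1), (j-1)/(nv-1))`.
#' @return a [control_mesh()] with `2(nu + nv) - 4` boundary vertices.
#' @export
init_control_mesh <- function(params, nu = 9L, nv = 5L) {
  if (nu < 2L || nv < 2L) stop_pf("pf_parameter_error", "need nu, nv >= 2")
  surf <- loft_surface(params)
  g <- surf$sample_grid(nu, nv)
  verts <- matrix(g, nu * nv, 3)
  idx <- function(i, j) i + (j - 1L) * nu
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  quads <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L),
                 idx(i, j + 1L))
  control_mesh(verts, quads, provenance = "plate control grid")
}

# One Catmull-Clark refinement as a linear operator: returns the weight
# matrix W (n_new x n_old), the new quads and new-vertex count layout
# [old vertices | face points | edge points].
cc_step_operator <- function(mesh) {
  v_n <- nrow(mesh$vertices)
  quads <- mesh$quads
  m <- nrow(quads)
  ed <- quad_edges(quads)
  ukey <- unique(ed$key)
  e_n <- length(ukey)
  e_id <- match(ed$key, ukey)             # 4m entries -> edge index
  e_ends <- do.call(rbind, strsplit(ukey, " "))
  e_v1 <- as.integer(e_ends[, 1])
  e_v2 <- as.integer(e_ends[, 2])
  # faces adjacent to each edge
  e_faces <- split(ed$face, e_id)
  e_nf <- lengths(e_faces)
  if (any(e_nf > 2L)) stop_pf("pf_geometry_error", "non-manifold input")
  e_boundary <- e_nf == 1L

  n_new <- v_n + m + e_n
  W <- matrix(0, n_new, v_n)
  fp_row <- v_n + seq_len(m)
  ep_row <- v_n + m + seq_len(e_n)

  # face points: centroid
  for (k in 1:4) {
    W[cbind(fp_row, quads[, k])] <- W[cbind(fp_row, quads[, k])] + 0.25
  }

  # edge points
  for (e in seq_len(e_n)) {
    r <- ep_row[e]
    if (e_boundary[e]) {
      W[r, e_v1[e]] <- W[r, e_v1[e]] + 0.5
      W[r, e_v2[e]] <- W[r, e_v2[e]] + 0.5
    } else {
      W[r, e_v1[e]] <- W[r, e_v1[e]] + 0.25
      W[r, e_v2[e]] <- W[r, e_v2[e]] + 0.25
      for (f in e_faces[[e]]) {
        W[r, ] <- W[r, ] + 0.25 * W[fp_row[f], ]
      }
    }
  }

  # vertex points: incident unique edges and faces per vertex
  inc_edges <- lapply(seq_len(v_n), function(i) integer(0))
  for (e in seq_len(e_n)) {
    inc_edges[[e_v1[e]]] <- c(inc_edges[[e_v1[e]]], e)
    inc_edges[[e_v2[e]]] <- c(inc_edges[[e_v2[e]]], e)
  }
  inc_faces <- lapply(seq_len(v_n), function(i) integer(0))
  for (k in 1:4) {
    for (f in seq_len(m)) {
      i <- quads[f, k]
      inc_faces[[i]] <- c(inc_faces[[i]], f)
    }
  }
  for (i in seq_len(v_n)) {
    edges_i <- inc_edges[[i]]
    if (mesh$boundary[i]) {
      bed <- edges_i[e_boundary[edges_i]]
      if (length(bed) != 2L) {
        stop_pf("pf_geometry_error",
                "boundary vertex %d with %d boundary edges (non-manifold)",
                i, length(bed))
      }
      nb <- ifelse(e_v1[bed] == i, e_v2[bed], e_v1[bed])
      W[i, i] <- 0.75
      W[i, nb[1]] <- W[i, nb[1]] + 0.125
      W[i, nb[2]] <- W[i, nb[2]] + 0.125
    } else {
      val <- length(edges_i)                      # valence
      faces_i <- inc_faces[[i]]
      fbar <- colMeans(W[fp_row[faces_i], , drop = FALSE])
      rbar <- numeric(v_n)
      for (e in edges_i) {
        rbar[e_v1[e]] <- rbar[e_v1[e]] + 0.5 / val
        rbar[e_v2[e]] <- rbar[e_v2[e]] + 0.5 / val
      }
      W[i, ] <- (fbar + 2 * rbar) / val
      W[i, i] <- W[i, i] + (val - 3) / val
    }
  }

  # new quads: one per corner of each old quad
  edge_at <- matrix(e_id, m, 4L)        # edge (k, k+1) of each face
  new_quads <- vector("list", m)
  for (f in seq_len(m)) {
    q <- quads[f, ]
    ep <- ep_row[edge_at[f, ]]
    fp <- fp_row[f]
    new_quads[[f]] <- rbind(
      c(q[1], ep[1], fp, ep[4]),
      c(q[2], ep[2], fp, ep[1]),
      c(q[3], ep[3], fp, ep[2]),
      c(q[4], ep[4], fp, ep[3])
    )
  }
  list(W = W, quads = do.call(rbind, new_quads))
}

#' One Catmull-Clark subdivision step
#'
#' Standard rules: face points at face centroids; interior edge points
#' average the edge endpoints and the two adjacent face points; boundary
#' edge points are edge midpoints; interior vertices use the valence
#' rule `(F + 2R + (n-3)P)/n`; boundary vertices use the cubic B-spline
#' boundary rule `(P_prev + 6P + P_next)/8`. All output faces are quads.
#'
#' @param mesh a [control_mesh()].
#' @return refined [control_mesh()].
#' @export
catmull_clark_step <- function(mesh) {
  op <- cc_step_operator(mesh)
  control_mesh(op$W %*% mesh$vertices, op$quads,
               provenance = mesh$provenance)
}

# `levels` subdivisions with the composed linear operator.
cc_operator_levels <- function(mesh, levels) {
  W <- diag(nrow(mesh$vertices))
  cur <- mesh
  for (l in seq_len(levels)) {
    op <- cc_step_operator(cur)
    W <- op$W %*% W
    cur <- control_mesh(op$W %*% cur$vertices, op$quads,
                        provenance = mesh$provenance)
  }
  list(W = W, mesh = cur)
}

#' Fit a subdivision control mesh to a bone surface
#'
#' Adjusts the control vertices so the subdivision surface conforms to
#' the bone: the control mesh is subdivided `levels` times, the
#' subdivided samples are projected to their nearest points on the bone,
#' and each control vertex moves by `step` times the weighted mean
#' residual of the samples it influences. The objective (mean squared
#' sample-to-bone distance) is non-increasing over accepted iterations;
#' a rejected trial halves the step, and five consecutive rejections
#' raise a convergence error.
#'
#' @param mesh a [control_mesh()].
#' @param bone closed `tri_mesh` to conform to.
#' @param n_iter maximum iterations.
#' @param step update fraction in `(0, 1]`.
#' @param levels subdivision depth used for the fitting samples.
#' @param boundary `"free"` (boundary control vertices move too) or
#'   `"fixed"` (pinned, preserving the plate footprint rim).
#' @param rel_tol stop when the relative objective improvement drops
#'   below this.
#' @return fitted [control_mesh()]; attribute `history` holds the
#'   objective trace (mm^2).
#' @export
fit_control_mesh <- function(mesh, bone, n_iter = 50L, step = 0.5,
                             levels = 2L, boundary = c("free", "fixed"),
                             rel_tol = 1e-6) {
  boundary <- match.arg(boundary)
  if (step <= 0 || step > 1) stop_pf("pf_parameter_error",
                                     "step must be in (0, 1]")
  op <- cc_operator_levels(mesh, levels)
  W <- op$W
  wsum <- colSums(W)
  V <- mesh$vertices
  objective <- function(V) {
    S <- W %*% V
    cp <- closest_point_on_mesh(S, bone)
    list(obj = mean(cp$dist^2), resid = cp$points - S)
  }
  cur <- objective(V)
  history <- cur$obj
  fails <- 0L
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    delta <- step * (t(W) %*% cur$resid) / wsum
    if (boundary == "fixed") delta[mesh$boundary, ] <- 0
    cand <- V + delta
    nxt <- objective(cand)
    if (nxt$obj <= cur$obj * (1 + 1e-12)) {
      improve <- (cur$obj - nxt$obj) / max(cur$obj, .Machine$double.xmin)
      V <- cand
      cur <- nxt
      history <- c(history, cur$obj)
      fails <- 0L
      if (improve < rel_tol) break
    } else {
      fails <- fails + 1L
      step <- step / 2
      if (fails >= 5L) {
        stop_pf("pf_convergence_error",
                "objective increased for 5 consecutive trials")
      }
    }
  }
  out <- control_mesh(V, mesh$quads, provenance = mesh$provenance)
  attr(out, "history") <- history
  out
}

#' Triangulate a (subdivided) control mesh
#'
#' Splits each quad into two triangles; used to export or measure the
#' subdivision surface.
#'
#' @param mesh a [control_mesh()].
#' @param levels extra Catmull-Clark refinements to apply first.
#' @return open-shell `tri_mesh`.
#' @export
control_mesh_to_tri <- function(mesh, levels = 2L) {
  if (levels > 0L) mesh <- cc_operator_levels(mesh, levels)$mesh
  q <- mesh$quads
  tri_mesh(mesh$vertices,
           rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)]),
           provenance = mesh$provenance, validate = FALSE)
}
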