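#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated surface in millimetres: an
#' `n x 3` vertex matrix, an `m x 3` integer face matrix (1-based vertex
#' indices, counter-clockwise seen from outside), and a free-text
#' provenance tag. All pipeline stages (bone, plate shell, plate solid)
#' use this one type.
#'
#' @param vertices numeric matrix `n x 3`, coordinates in mm.
#' @param faces integer matrix `m x 3` of vertex indices (1-based).
#' @param provenance free-text source tag carried through the pipeline.
#' @param validate merge duplicate vertices and drop degenerate faces
#'   (see [validate_mesh()]).
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, provenance = "unknown", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_pf("pf_content_error", "vertices must be n x 3")
  if (ncol(faces) != 3L) stop_pf("pf_content_error", "faces must be m x 3")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    stop_pf("pf_content_error", "mesh is empty")
  }
  if (!all(is.finite(vertices))) {
    stop_pf("pf_content_error", "non-finite vertex coordinates")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop_pf("pf_content_error", "face indices out of range")
  }
  m <- structure(
    list(vertices = vertices, faces = faces, provenance = provenance),
    class = "tri_mesh"
  )
  if (validate) m <- validate_mesh(m) else m
}

#' Validate and clean a mesh
#'
#' Merges vertices closer than `merge_tol`, drops degenerate faces
#' (repeated indices or area below `area_tol`) and records the counts in
#' the `validation` attribute. Idempotent: validating twice changes
#' nothing.
#'
#' @param mesh a `tri_mesh`.
#' @param merge_tol vertex merge tolerance in mm.
#' @param area_tol faces with area (mm^2) at or below this are dropped.
#' @return cleaned `tri_mesh` with a `validation` attribute
#'   (`merged_vertices`, `dropped_faces`).
#' @export
validate_mesh <- function(mesh, merge_tol = 1e-6, area_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- !duplicated(key)
  idx_map <- match(key, key[first])
  n_merged <- nrow(v) - sum(first)
  v <- v[first, , drop = FALSE]
  f <- matrix(idx_map[f], ncol = 3L)

  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  area2 <- row_norms(cross3_rows(ab, ac)) / 2
  degen <- degen | area2 <= area_tol
  n_dropped <- sum(degen)
  f <- f[!degen, , drop = FALSE]

  # drop vertices no longer referenced
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
  }
  if (nrow(f) == 0L) stop_pf("pf_content_error", "mesh empty after cleaning")
  out <- structure(
    list(vertices = v, faces = f, provenance = mesh$provenance),
    class = "tri_mesh"
  )
  attr(out, "validation") <- list(merged_vertices = n_merged,
                                  dropped_faces = n_dropped)
  out
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces [%s]%s\n",
              nrow(x$vertices), nrow(x$faces), x$provenance,
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

face_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  colnames(e) <- c("from", "to")
  e
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite orientation (closed, orientable 2-manifold). STL
#' carries no topology, so this is always computed, never trusted.
#'
#' @param mesh a `tri_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- face_edge_table(mesh$faces)
  directed <- paste(e[, 1], e[, 2])
  if (anyDuplicated(directed)) return(FALSE)  # not consistently orientable
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(undirected) == 2L)
}

# TRUE when every undirected edge bounds one or two faces (manifold with
# boundary); used by the subdivision module.
is_edge_manifold <- function(faces) {
  e <- face_edge_table(faces)
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(undirected) <= 2L)
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- cross3_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                   v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  if (normalize) n / pmax(row_norms(n), .Machine$double.xmin) else n
}

face_areas <- function(mesh) {
  row_norms(face_normals(mesh, normalize = FALSE)) / 2
}

# Area-weighted vertex normals.
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE)  # length = 2 * area
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    vn[, 1] <- vn[, 1] + tapply_add(fn[, 1], idx, nrow(vn))
    vn[, 2] <- vn[, 2] + tapply_add(fn[, 2], idx, nrow(vn))
    vn[, 3] <- vn[, 3] + tapply_add(fn[, 3], idx, nrow(vn))
  }
  vn / pmax(row_norms(vn), .Machine$double.xmin)
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s
  out
}

# Signed enclosed volume (divergence theorem); positive for outward-oriented
# closed meshes.
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3_rows(b, c_))) / 6
}

mesh_area <- function(mesh) sum(face_areas(mesh))

# Flip face orientation so enclosed volume is positive.
orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

#' Sample points uniformly by area on a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param n number of samples.
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @return list with `points` (`n x 3`), `face` (face index per sample).
#' @export
sample_points_on_mesh <- function(mesh, n, seed = 1L) {
  areas <- face_areas(mesh)
  with_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    c_ <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    p <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    list(points = p, face = fi)
  })
}

# Exact closest point on a set of triangles (Ericson's region test),
# vectorized over triangles for one query point.
closest_on_triangles <- function(p, A, B, C) {
  ab <- B - A
  ac <- C - A
  ap <- -sweep(A, 2, p)
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- -sweep(B, 2, p)
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- -sweep(C, 2, p)
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  n <- nrow(A)
  out <- matrix(NA_real_, n, 3)
  done <- logical(n)

  take <- function(cond, pts) {
    sel <- cond & !done
    if (any(sel)) out[sel, ] <<- pts[sel, , drop = FALSE]
    done <<- done | cond
  }
  take(d1 <= 0 & d2 <= 0, A)
  take(d3 >= 0 & d4 <= d3, B)
  vab <- d1 / pmax(d1 - d3, .Machine$double.xmin)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, A + vab * ab)
  take(d6 >= 0 & d5 <= d6, C)
  wac <- d2 / pmax(d2 - d6, .Machine$double.xmin)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, A + wac * ac)
  wbc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.xmin)
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + wbc * (C - B))
  denom <- 1 / (va + vb + vc)
  v <- vb * denom
  w <- vc * denom
  take(rep(TRUE, n), A + v * ab + w * ac)
  out
}

#' Closest points on a mesh
#'
#' Exact nearest-facet closest point for each query point, with a
#' nearest-vertex prune so cost stays modest on dense meshes.
#'
#' @param points `n x 3` query points.
#' @param mesh a `tri_mesh`.
#' @return list with `points` (`n x 3` closest points), `dist`, `face`.
#' @export
closest_point_on_mesh <- function(points, mesh) {
  points <- matrix(points, ncol = 3)
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  max_edge <- pmax(row_norms(B - A), row_norms(C - B), row_norms(A - C))
  n <- nrow(points)
  cp <- matrix(NA_real_, n, 3)
  dist <- numeric(n)
  face <- integer(n)
  for (i in seq_len(n)) {
    p <- points[i, ]
    dvert <- sqrt(rowSums(sweep(v, 2, p)^2))
    dv <- min(dvert)
    fmin <- pmin(dvert[f[, 1]], dvert[f[, 2]], dvert[f[, 3]])
    cand <- which(fmin - max_edge <= dv + 1e-12)
    q <- closest_on_triangles(p, A[cand, , drop = FALSE],
                              B[cand, , drop = FALSE],
                              C[cand, , drop = FALSE])
    d2 <- rowSums(sweep(q, 2, p)^2)
    j <- which.min(d2)
    cp[i, ] <- q[j, ]
    dist[i] <- sqrt(d2[j])
    face[i] <- cand[j]
  }
  list(points = cp, dist = dist, face = face)
}

# All intersections of the ray origin + t * dir (t > t_min) with the mesh
# (Moller-Trumbore, vectorized over faces). Returns sorted t values.
ray_mesh_intersections <- function(origin, dir, mesh, t_min = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - A
  e2 <- v[f[, 3], , drop = FALSE] - A
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- -sweep(A, 2, origin)
  u <- rowSums(s * h) / a
  q <- cross3_rows(s, e1)
  vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
  t <- rowSums(e2 * q) / a
  eps <- 1e-9
  hit <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps & t > t_min
  sort(t[hit])
}
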