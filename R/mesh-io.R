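#' Read a triangulated surface mesh
#'
#' Supports STL (binary and ASCII), ASCII PLY, and OBJ (geometry only).
#' STL triangle soup is welded: duplicate vertices are merged within
#' 1e-6 mm and degenerate faces dropped, with counts recorded in the
#' `validation` attribute. Coordinates are taken to be millimetres (the
#' CT-derived convention); no unit conversion is attempted.
#'
#' @param path file path (`.stl`, `.ply`, `.obj`).
#' @param expected_units must be `"mm"`.
#' @return a validated [tri_mesh()].
#' @export
read_mesh <- function(path, expected_units = "mm") {
  expected_units <- match.arg(expected_units, "mm")
  if (!file.exists(path)) stop_pf("pf_format_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop_pf("pf_format_error", "unsupported mesh format: .%s", ext)
  )
  tri_mesh(raw$vertices, raw$faces, provenance = basename(path))
}

#' Write a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @param format one of `stl_binary`, `stl_ascii`, `ply`, `obj`; default is
#'   inferred from the file extension (`.stl` means binary STL).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl_binary", "stl_ascii",
                                  "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl_binary", ply = "ply", obj = "obj",
                     stop_pf("pf_format_error",
                             "cannot infer format for %s", path))
  }
  switch(format,
    stl_binary = write_stl_binary(mesh, path),
    stl_ascii  = write_stl_ascii(mesh, path),
    ply        = write_ply(mesh, path),
    obj        = write_obj(mesh, path)
  )
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(size, 84 + 50 * as.numeric(n))
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(n) || n < 1) stop_pf("pf_format_error", "empty binary STL")
  rec <- readBin(con, "raw", 50 * n)
  if (length(rec) < 50 * n) stop_pf("pf_format_error", "truncated binary STL")
  m <- matrix(rec, nrow = 50)
  tri <- matrix(readBin(as.vector(m[1:48, ]), "numeric", size = 4,
                        n = 12L * n, endian = "little"),
                ncol = 12, byrow = TRUE)
  verts <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
                 tri[, 10:12, drop = FALSE])
  # interleave back to per-face order
  ord <- as.vector(t(matrix(seq_len(3L * n), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_pf("pf_format_error",
                                                "unreadable STL: %s", path))
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vx) || length(vx) %% 3 != 0) {
    stop_pf("pf_format_error", "malformed ASCII STL: %s", path)
  }
  num <- lapply(strsplit(trimws(vx), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, num)
  if (anyNA(verts)) stop_pf("pf_format_error", "non-numeric STL vertex")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_pf("pf_io_error",
                                              "cannot write %s", path))
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  n <- nrow(mesh$faces)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  tri <- cbind(fn, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  payload <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  blocks <- matrix(as.raw(0), nrow = 50, ncol = n)
  blocks[1:48, ] <- matrix(payload, nrow = 48)
  writeBin(as.vector(blocks), con)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  fmt3 <- function(m) sprintf("%.10e %.10e %.10e", m[, 1], m[, 2], m[, 3])
  body <- paste0(
    "  facet normal ", fmt3(fn), "\n    outer loop\n",
    "      vertex ", fmt3(v[f[, 1], , drop = FALSE]), "\n",
    "      vertex ", fmt3(v[f[, 2], , drop = FALSE]), "\n",
    "      vertex ", fmt3(v[f[, 3], , drop = FALSE]), "\n",
    "    endloop\n  endfacet"
  )
  writeLines(c("solid plateforge", body, "endsolid plateforge"), path)
}

# ---- PLY (ASCII) --------------------------------------------------------

read_ply <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_pf("pf_format_error",
                                                "unreadable PLY: %s", path))
  if (!length(lines) || lines[1] != "ply") {
    stop_pf("pf_format_error", "not a PLY file: %s", path)
  }
  end_hdr <- match("end_header", lines)
  if (is.na(end_hdr)) stop_pf("pf_format_error", "PLY header not terminated")
  hdr <- lines[seq_len(end_hdr)]
  if (any(grepl("^format\\s+binary", hdr))) {
    stop_pf("pf_format_error", "only ASCII PLY is supported")
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop_pf("pf_format_error", "bad PLY header")
  body <- lines[(end_hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop_pf("pf_format_error", "truncated PLY body")
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts,
                                 function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    k <- as.integer(p[1])
    idx <- as.integer(p[1 + seq_len(k)]) + 1L  # 0-based on disk
    if (k == 3L) idx else t(vapply(2:(k - 1),
                                   function(j) c(idx[1], idx[j], idx[j + 1]),
                                   integer(3)))
  }))
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(c(hdr,
               sprintf("%.10e %.10e %.10e", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_pf("pf_format_error",
                                                "unreadable OBJ: %s", path))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) {
    stop_pf("pf_format_error", "OBJ without v/f records: %s", path)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*$", "", p[-1]))
    if (length(idx) == 3L) idx else
      t(vapply(2:(length(idx) - 1),
               function(j) c(idx[1], idx[j], idx[j + 1]), integer(3)))
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# plateforge OBJ",
               sprintf("v %.10e %.10e %.10e", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}
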