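#' Triangle surface meshes
#'
#' A `trimesh` holds vertices in world mm and 1-based triangle vertex
#' indices. Meshes produced by [extract_surface()] are watertight (every
#' edge shared by exactly two triangles) and oriented with outward normals.
#'
#' @param vertices `n x 3` numeric matrix (mm).
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @return A `trimesh` object.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L)
    stop_vamorph("vertices must be an n x 3 matrix with n >= 3",
                 class = "vamorph_geometry_error")
  if (ncol(faces) != 3L || nrow(faces) < 1L)
    stop_vamorph("faces must be an m x 3 index matrix", class = "vamorph_geometry_error")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop_vamorph("face indices out of range", class = "vamorph_geometry_error")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Is every mesh edge shared by exactly two triangles?
#'
#' @param mesh a [trimesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a watertight oriented mesh
#'
#' Sum of signed tetrahedron volumes of each triangle against the origin
#' (divergence theorem); the absolute value is returned so either global
#' orientation yields the same magnitude.
#'
#' @param mesh a watertight [trimesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (!is_watertight(mesh))
    stop_vamorph("mesh is not watertight; volume undefined",
                 class = "vamorph_geometry_error")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

#' Euler characteristic V - E + F of a mesh
#'
#' @param mesh a [trimesh()].
#' @return Integer; 2 for a single closed genus-0 shell.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  ne <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Write and read surface meshes (ascii PLY / STL)
#'
#' Format chosen by extension. PLY preserves vertex identity and count;
#' STL stores per-triangle vertices (identity not preserved on re-read).
#'
#' @param mesh a [trimesh()].
#' @param path file path ending in `.ply` or `.stl`.
#' @return `path` (write) or a `trimesh` (read).
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  ext <- mesh_ext(path)
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
    nn <- pmax(sqrt(rowSums(n^2)), 1e-30)
    n <- n / nn
    body <- vapply(seq_len(nrow(f)), function(i) paste(
      sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
      sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
      sprintf("    vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
      "  endloop", "endfacet", sep = "\n"), character(1))
    writeLines(c("solid vamorph", body, "endsolid vamorph"), path)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- mesh_ext(path)
  lines <- readLines(path)
  if (ext == "ply") {
    if (length(lines) < 3L || lines[1] != "ply")
      stop_vamorph("not an ascii PLY file: %s", path, class = "vamorph_format_error")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    start <- which(lines == "end_header")[1]
    vv <- do.call(rbind, lapply(strsplit(lines[start + seq_len(nv)], "\\s+"),
                                function(s) as.double(s[1:3])))
    ff <- do.call(rbind, lapply(strsplit(lines[start + nv + seq_len(nf)], "\\s+"),
                                function(s) as.integer(s[2:4]) + 1L))
    trimesh(vv, ff)
  } else {
    vs <- grep("^\\s*vertex", lines, value = TRUE)
    vv <- do.call(rbind, lapply(strsplit(trimws(vs), "\\s+"),
                                function(s) as.double(s[2:4])))
    if (is.null(vv) || nrow(vv) %% 3L != 0L)
      stop_vamorph("malformed STL file: %s", path, class = "vamorph_format_error")
    trimesh(vv, matrix(seq_len(nrow(vv)), ncol = 3L, byrow = TRUE))
  }
}

mesh_ext <- function(path) {
  low <- tolower(path)
  if (grepl("\\.ply$", low)) return("ply")
  if (grepl("\\.stl$", low)) return("stl")
  stop_vamorph("unknown mesh extension in '%s' (use .ply or .stl)", path,
               class = "vamorph_format_error")
}
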