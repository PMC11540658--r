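#' Construct a triangle mesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices; every
#'   index must be in range and no face may reference a vertex twice.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(vertices) == 0) vertices <- matrix(numeric(0), ncol = 3)
  if (ncol(vertices) != 3) stop("`vertices` must have 3 columns")
  faces <- as.matrix(faces)
  if (length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  }
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stop("`faces` must have 3 columns")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face index out of range")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen)) stop("face references a vertex twice (face ",
                         which(degen)[1], ")")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("# triangle_mesh: %d vertices, %d faces, area %.6g\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' Sum over faces of half the cross-product magnitude of two edge
#' vectors. Degenerate (collinear) triangles contribute zero. Faces
#' sharing the same vertex set (coincident opposite-winding duplicates
#' that ball pivoting can emit on open surfaces) are counted once.
#'
#' @param mesh a [triangle_mesh()].
#' @param dedupe count duplicate faces (same vertex set) once
#'   (default `TRUE`).
#' @return Area in squared input units; >= 0.
#' @export
mesh_area <- function(mesh, dedupe = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  if (dedupe) {
    key <- t(apply(f, 1, sort))
    f <- f[!duplicated(key), , drop = FALSE]
  }
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

#' Write a triangle mesh as ASCII PLY or OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"` or `"obj"`; default from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "obj") "obj" else "ply"
  }
  format <- match.arg(format, c("ply", "obj"))
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  if (format == "ply") {
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header",
      if (nrow(v) > 0)
        apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
      if (nrow(f) > 0)
        sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    ), con, sep = "\n")
  } else {
    writeLines(c(
      if (nrow(v) > 0)
        apply(v, 1, function(r) paste("v", paste(sprintf("%.17g", r),
                                                 collapse = " "))),
      if (nrow(f) > 0) sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    ), con, sep = "\n")
  }
  invisible(path)
}
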