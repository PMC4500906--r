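#' Triangle mesh in world coordinates
#'
#' Vertices are world-mm coordinates (same frame as volume affines).
#' Triangles are stored 1-based as is natural in R; file formats that index
#' from 0 (GIFTI, OBJ-internal) are converted at IO time.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `TriangleMesh`.
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as_points(vertices)
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(triangles) != 3L) stop("'triangles' must be m x 3")
  if (nrow(triangles)) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices out of range")
    degen <- triangles[, 1] == triangles[, 2] |
             triangles[, 1] == triangles[, 3] |
             triangles[, 2] == triangles[, 3]
    if (any(degen)) stop("degenerate triangle (repeated vertex index)")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "TriangleMesh")
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-vertex scalar map
#'
#' Carries one scalar per surface vertex plus a validity flag and the method
#' that produced it (`"nn"`, `"linear"`, `"sgdm"`, `"sgdm-fallback"`, ...).
#' Invalid entries carry no value (`NA`).
#'
#' @param value numeric vector, one entry per vertex.
#' @param valid logical vector; defaults to `is.finite(value)`.
#' @param method character scalar or per-vertex character vector.
#' @return An object of class `VertexMap` with elements `value`, `valid`,
#'   `method`.
#' @export
vertex_map <- function(value, valid = NULL, method = "unknown") {
  value <- as.numeric(value)
  if (is.null(valid)) valid <- is.finite(value)
  valid <- as.logical(valid)
  if (length(valid) != length(value)) stop("'valid' length mismatch")
  value[!valid] <- NA_real_
  if (length(method) == 1L) method <- rep(method, length(value))
  if (length(method) != length(value)) stop("'method' length mismatch")
  structure(list(value = value, valid = valid, method = as.character(method)),
            class = "VertexMap")
}

#' @export
print.VertexMap <- function(x, ...) {
  cat(sprintf("VertexMap: %d vertices (%d valid; methods: %s)\n",
              length(x$value), sum(x$valid),
              paste(unique(x$method), collapse = ", ")))
  if (any(x$valid))
    cat(sprintf("  value range [%g, %g]\n",
                min(x$value[x$valid]), max(x$value[x$valid])))
  invisible(x)
}

#' @export
length.VertexMap <- function(x) length(x$value)

#' @export
as.numeric.VertexMap <- function(x, ...) x$value
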