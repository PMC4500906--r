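#' Linked cortical surface set
#'
#' White (GM/WM) and pial (GM/CSF) meshes with index-wise vertex
#' correspondence, the arithmetic midsurface and the t-link thickness. The
#' correspondence is by vertex index and is a precondition of this
#' constructor — it is not recomputed.
#'
#' @param white,pial [triangle_mesh()] objects with identical vertex count
#'   and triangle topology.
#' @param mid optional midsurface; computed with [compute_midsurface()]
#'   when omitted. If given it must equal the per-vertex white/pial
#'   midpoint to within 1e-9 mm.
#' @return a `LinkedSurfaceSet`: list with `white`, `pial`, `mid`,
#'   `thickness` (per-vertex mm).
#' @export
linked_surface_set <- function(white, pial, mid = NULL) {
  check_matched(white, pial)
  if (is.null(mid)) mid <- compute_midsurface(white, pial)
  else {
    check_matched(white, mid)
    dev <- max(abs(mid$vertices - (white$vertices + pial$vertices) / 2))
    if (dev > 1e-9)
      stop(sprintf("supplied midsurface deviates from the white/pial midpoint by %g mm", dev))
  }
  structure(list(white = white, pial = pial, mid = mid,
                 thickness = compute_thickness_tlink(white, pial)),
            class = "LinkedSurfaceSet")
}

#' @export
print.LinkedSurfaceSet <- function(x, ...) {
  cat(sprintf("LinkedSurfaceSet: %d vertices, thickness %.2f-%.2f mm\n",
              n_vertices(x$white), min(x$thickness), max(x$thickness)))
  invisible(x)
}

check_matched <- function(a, b) {
  if (n_vertices(a) != n_vertices(b))
    stop(sprintf("linked meshes must share a vertex count (%d vs %d)",
                 n_vertices(a), n_vertices(b)))
  if (nrow(a$triangles) != nrow(b$triangles))
    stop("linked meshes must share triangle topology")
  invisible(TRUE)
}

#' t-link cortical thickness
#'
#' Euclidean distance between correspondingly indexed white and pial
#' vertices, in mm.
#'
#' @inheritParams linked_surface_set
#' @return numeric per-vertex thickness vector.
#' @export
compute_thickness_tlink <- function(white, pial) {
  check_matched(white, pial)
  unname(sqrt(rowSums((pial$vertices - white$vertices)^2)))
}

#' Arithmetic midsurface of linked white/pial meshes
#'
#' Vertex-wise midpoint `(white + pial) / 2`; triangles are copied from the
#' white mesh.
#'
#' @inheritParams linked_surface_set
#' @return a [triangle_mesh()].
#' @export
compute_midsurface <- function(white, pial) {
  check_matched(white, pial)
  triangle_mesh((white$vertices + pial$vertices) / 2, white$triangles)
}

#' Per-vertex cortical-column frames
#'
#' For each vertex the profile direction follows the cortical column: the
#' anchor is the pial vertex and `inward` is the unit vector towards the
#' linked white vertex. Vertices whose white and pial positions coincide
#' (thickness below `eps`) have no direction and are flagged undefined;
#' the mapping stage assigns those by its fallback rule.
#'
#' @param surfaces a [linked_surface_set()].
#' @param eps degenerate-column threshold (mm).
#' @return list with `anchor` (n x 3), `inward` (n x 3 unit rows),
#'   `thickness`, `defined` (logical).
#' @export
column_frames <- function(surfaces, eps = 1e-6) {
  stopifnot(inherits(surfaces, "LinkedSurfaceSet"))
  th <- surfaces$thickness
  defined <- th > eps
  inward <- surfaces$white$vertices - surfaces$pial$vertices
  inward[defined, ] <- inward[defined, , drop = FALSE] / th[defined]
  inward[!defined, ] <- NA_real_
  list(anchor = surfaces$pial$vertices, inward = inward,
       thickness = th, defined = defined)
}
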