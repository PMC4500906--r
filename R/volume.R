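#' Scalar volume with world affine
#'
#' A `ScalarVolume` is a 3-D scalar grid together with a 4x4 voxel-to-world
#' affine (mm). Voxel indices are 0-based and the world position of voxel
#' `(i, j, k)` is `affine %*% c(i, j, k, 1)` (voxel-centre convention, the
#' dominant NIfTI interpretation). Surface meshes are assumed to live in the
#' same world frame; no transform is applied anywhere downstream.
#'
#' @param data numeric 3-D array.
#' @param affine numeric 4x4 invertible voxel-to-world matrix (mm).
#' @param units free-text unit tag, e.g. `"mm^2/s"` or `"fraction"`.
#' @return An object of class `ScalarVolume` with elements `data`, `affine`,
#'   `units`.
#' @export
scalar_volume <- function(data, affine = diag(4), units = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1 on each axis")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("'affine' must be invertible")
  if (identical(units, "fraction")) {
    v <- data[is.finite(data)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("fraction-tagged volume has values outside [0, 1]")
  }
  structure(list(data = data, affine = affine, units = units),
            class = "ScalarVolume")
}

#' @export
print.ScalarVolume <- function(x, ...) {
  cat(sprintf("ScalarVolume %s [%s]\n", paste(dim(x$data), collapse = " x "),
              if (nzchar(x$units)) x$units else "unitless"))
  cat("voxel-to-world affine:\n")
  print(x$affine)
  invisible(x)
}

#' @export
dim.ScalarVolume <- function(x) dim(x$data)

is_scalar_volume <- function(x) inherits(x, "ScalarVolume")

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel coordinates are 0-based and continuous; integer values fall on
#' voxel centres.
#'
#' @param vol a [scalar_volume()].
#' @param points numeric n x 3 matrix (rows are points).
#' @return n x 3 matrix of transformed coordinates.
#' @export
world_to_voxel <- function(vol, points) {
  points <- as_points(points)
  inv <- solve(vol$affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, points) {
  points <- as_points(points)
  h <- cbind(points, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be n x 3")
  points
}

#' Sample a volume at world-space points
#'
#' Trilinear interpolation over the 8 surrounding voxel centres
#' (`method = "linear"`), or the value of the voxel whose centre is nearest
#' (`method = "nn"`). Points whose interpolation support leaves the grid
#' (linear) or whose nearest voxel centre is outside it (nn) return `NA`.
#'
#' @inheritParams world_to_voxel
#' @param method `"linear"` or `"nn"`.
#' @return numeric vector of sampled values, `NA` where undefined.
#' @export
sample_volume_at <- function(vol, points, method = c("linear", "nn")) {
  method <- match.arg(method)
  v <- world_to_voxel(vol, points)
  d <- dim(vol$data)
  n <- nrow(v)
  out <- rep(NA_real_, n)
  if (n == 0L) return(out)
  if (method == "nn") {
    r <- round(v)
    ok <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
          r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
          r[, 3] >= 0 & r[, 3] <= d[3] - 1
    ok[!is.finite(rowSums(r))] <- FALSE
    if (any(ok))
      out[ok] <- vol$data[cbind(r[ok, 1] + 1, r[ok, 2] + 1, r[ok, 3] + 1)]
    return(out)
  }
  f <- floor(v)
  w <- v - f
  # points exactly on the far face still have full support
  for (ax in 1:3) {
    fix <- is.finite(v[, ax]) & v[, ax] == d[ax] - 1
    f[fix, ax] <- d[ax] - 2
    w[fix, ax] <- 1
  }
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
        f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
        f[, 3] >= 0 & f[, 3] <= d[3] - 2
  ok[!is.finite(rowSums(v))] <- FALSE
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE] + 1   # to 1-based array index
  w <- w[ok, , drop = FALSE]
  dat <- vol$data
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * dat[cbind(f[, 1] + dx, f[, 2] + dy, f[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

# clamped sampling: coordinates outside the grid are pulled to the edge.
# Used by apply_distortion so that shift/unshift pairs round-trip away from
# genuinely new content.
sample_volume_clamped <- function(vol, points) {
  v <- world_to_voxel(vol, points)
  d <- dim(vol$data)
  for (ax in 1:3) v[, ax] <- pmin(pmax(v[, ax], 0), d[ax] - 1)
  pts <- voxel_to_world(vol, v)
  sample_volume_at(vol, pts, method = "linear")
}
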