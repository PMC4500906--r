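#' Log-linear least-squares diffusion tensor fit
#'
#' Fits the single-tensor model `ln S = ln S0 - b g' D g` per voxel by
#' ordinary least squares on log-signals — the plain unweighted fit, with
#' `ln S0` estimated jointly as the intercept of the same linear system.
#' No positivity constraint or eigenvalue clamping is applied; voxels with
#' nonpositive signal (inside the mask) are flagged invalid rather than
#' aborting the fit.
#'
#' @param dwi a [dwi_series()]: at least 7 entries, at least one `b = 0`,
#'   and at least 6 distinct nonzero gradient directions.
#' @param mask optional [scalar_volume()]; voxels where `mask > 0` are fit.
#' @return a `TensorVolume`: list with `components` (4-D array, last axis
#'   ordered Dxx, Dxy, Dxz, Dyy, Dyz, Dzz, mm^2/s), `log_s0`, `valid`
#'   (logical 3-D array) and `affine`.
#' @export
fit_tensor_lls <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "DWISeries"))
  g <- dwi$gradients
  b <- g$bvals
  v <- g$bvecs
  n <- length(b)
  # design: columns (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
  X <- cbind(1,
             -b * v[, 1]^2,
             -2 * b * v[, 1] * v[, 2],
             -2 * b * v[, 1] * v[, 3],
             -b * v[, 2]^2,
             -2 * b * v[, 2] * v[, 3],
             -b * v[, 3]^2)
  qrX <- qr(X)
  if (n < 7L || qrX$rank < 7L) {
    ndir <- nrow(unique(round(v[b > 0, , drop = FALSE], 6)))
    stop(sprintf(paste("tensor fit needs >= 6 distinct nonzero directions",
                       "plus b0 (got %d entries, %d distinct directions,",
                       "design rank %d)"), n, ndir, qrX$rank))
  }
  d <- dim(dwi$stacks)[1:3]
  nvox <- prod(d)
  S <- matrix(dwi$stacks, nrow = nvox, ncol = n)
  in_mask <- if (is.null(mask)) rep(TRUE, nvox) else {
    if (!all(dim(mask$data) == d)) stop("mask grid does not match DWI grid")
    as.vector(mask$data > 0)
  }
  pos <- in_mask & rowSums(S <= 0 | !is.finite(S)) == 0L
  coefs <- matrix(NA_real_, nrow = nvox, ncol = 7L)
  if (any(pos))
    coefs[pos, ] <- t(qr.coef(qrX, t(log(S[pos, , drop = FALSE]))))
  structure(list(
    components = array(coefs[, 2:7], dim = c(d, 6L)),
    log_s0 = array(coefs[, 1], dim = d),
    valid = array(pos, dim = d),
    affine = dwi$affine), class = "TensorVolume")
}

#' Mean diffusivity from a fitted tensor volume
#'
#' `MD = (Dxx + Dyy + Dzz) / 3`. Invalid tensor voxels propagate as `NA`;
#' mildly negative MD (possible under noise, since the fit is
#' unconstrained) is passed through.
#'
#' @param tensor a `TensorVolume` from [fit_tensor_lls()].
#' @return a [scalar_volume()] with units `"mm^2/s"`.
#' @export
compute_md <- function(tensor) {
  stopifnot(inherits(tensor, "TensorVolume"))
  comp <- tensor$components
  md <- (comp[, , , 1] + comp[, , , 4] + comp[, , , 6]) / 3
  md[!tensor$valid] <- NA_real_
  d <- dim(tensor$valid)
  scalar_volume(array(md, dim = d), tensor$affine, units = "mm^2/s")
}
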