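#' Nearest-neighbour and trilinear volume-to-vertex mapping
#'
#' The two baseline samplers: `map_nn()` assigns each vertex the value of
#' the voxel whose centre is closest to it; `map_linear()` interpolates
#' trilinearly over the 8 surrounding voxel centres. Vertices outside the
#' grid (or whose interpolation support leaves it) are invalid.
#'
#' @param volume a [scalar_volume()].
#' @param mesh a [triangle_mesh()] in the volume's world frame.
#' @return a [vertex_map()] tagged `"nn"` / `"linear"`.
#' @export
map_nn <- function(volume, mesh) {
  vals <- sample_volume_at(volume, mesh$vertices, method = "nn")
  vertex_map(vals, method = "nn")
}

#' @rdname map_nn
#' @export
map_linear <- function(volume, mesh) {
  vals <- sample_volume_at(volume, mesh$vertices, method = "linear")
  vertex_map(vals, method = "linear")
}

# ---------------------------------------------------------------------------
# Cortical-column intensity profiles

#' Sample an intensity profile along a cortical column
#'
#' Samples the volume along the column line of one vertex. The profile is
#' centred on the pial vertex (`t = 0`); positive `t` runs outward (away
#' from the white surface), negative `t` inward, in steps of `spacing`
#' covering `[-range_in, +range_out]`. Each sample is trilinearly
#' interpolated; samples whose support leaves the grid are `NA` (missing).
#'
#' @param volume a [scalar_volume()] (typically the MD map).
#' @param frame a single-vertex column frame: list with `anchor` (pial
#'   position, mm), `inward` (unit vector towards the white vertex) and
#'   `defined`; see [column_frames()].
#' @param range_in,range_out profile extent inward / outward of the pial
#'   vertex (mm).
#' @param spacing sample step (mm), `> 0`.
#' @return a `Profile`: list with `t` (signed positions, mm), `samples`,
#'   `center_index`, `spacing`, `valid`, and the generating `frame`.
#' @export
sample_profile <- function(volume, frame, range_in, range_out,
                           spacing = 0.5) {
  stopifnot(spacing > 0)
  tgrid <- profile_t_grid(range_in, range_out, spacing)
  if (!isTRUE(frame$defined)) {
    return(structure(list(t = tgrid$t, samples = rep(NA_real_,
                                                     length(tgrid$t)),
                          center_index = tgrid$center, spacing = spacing,
                          frame = frame, valid = FALSE),
                     class = "Profile"))
  }
  anchor <- as.numeric(frame$anchor)
  inward <- as.numeric(frame$inward)
  pts <- matrix(rep(anchor, each = length(tgrid$t)), ncol = 3) -
    outer(tgrid$t, inward)
  vals <- sample_volume_at(volume, pts, method = "linear")
  structure(list(t = tgrid$t, samples = vals, center_index = tgrid$center,
                 spacing = spacing, frame = frame,
                 valid = any(is.finite(vals))),
            class = "Profile")
}

profile_t_grid <- function(range_in, range_out, spacing) {
  n_in <- floor(range_in / spacing + 1e-9)
  n_out <- floor(range_out / spacing + 1e-9)
  list(t = c(-rev(seq_len(n_in)), 0, seq_len(n_out)) * spacing,
       center = n_in + 1L)
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("Profile: %d samples, spacing %g mm, centre at index %d, %d missing\n",
              length(x$samples), x$spacing, x$center_index,
              sum(!is.finite(x$samples))))
  invisible(x)
}

#' Moving-average smoothing of a profile
#'
#' Centred moving average of odd width. Because the raw MD profile has a
#' stepwise character (it is pieced together from voxel values), it is
#' smoothed before extrema and gradients are taken. The window is truncated
#' and renormalised at the profile ends and around missing samples; the
#' centre index is unchanged.
#'
#' @param profile a [sample_profile()] result.
#' @param kernel_width odd number of samples (`1` = identity).
#' @return a `Profile` with smoothed samples.
#' @export
smooth_profile <- function(profile, kernel_width = 3L) {
  stopifnot(inherits(profile, "Profile"))
  kernel_width <- as.integer(kernel_width)
  if (kernel_width < 1L || kernel_width %% 2L == 0L)
    stop("'kernel_width' must be an odd positive sample count")
  s <- profile$samples
  n <- length(s)
  h <- (kernel_width - 1L) %/% 2L
  if (h > 0L) {
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      win <- s[max(1L, i - h):min(n, i + h)]
      win <- win[is.finite(win)]
      if (length(win)) out[i] <- mean(win)
    }
    out[!is.finite(s)] <- NA_real_  # missing samples stay missing
    profile$samples <- out
  }
  profile
}

#' First differential of a profile
#'
#' Central differences on interior samples, one-sided at the ends, scaled
#' by `1/spacing`. Sign convention: positive gradient means MD increasing
#' outward (towards CSF). Entries adjacent to missing samples are `NA`.
#'
#' @param profile a `Profile` (normally smoothed first).
#' @return numeric gradient vector (volume units per mm), or all-`NA` when
#'   fewer than 3 contiguous valid samples exist.
#' @export
differentiate_profile <- function(profile) {
  stopifnot(inherits(profile, "Profile"))
  s <- profile$samples
  n <- length(s)
  g <- rep(NA_real_, n)
  if (max_contiguous_finite(s) < 3L) return(g)
  h <- profile$spacing
  if (n >= 2L) {
    g[1] <- (s[2] - s[1]) / h
    g[n] <- (s[n] - s[n - 1]) / h
  }
  if (n >= 3L) {
    i <- 2:(n - 1)
    g[i] <- (s[i + 1] - s[i - 1]) / (2 * h)
  }
  g
}

max_contiguous_finite <- function(x) {
  r <- rle(is.finite(x))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Search window for the GM/CSF boundary
#'
#' On the smoothed profile, the local maximum nearest the profile centre
#' (the pial vertex) marks the CSF side of the window and the local
#' minimum nearest to it on its inward (WM) side marks the WM bound, so the
#' window stretches from the WM area into the CSF area. A local extremum is
#' a sample strictly greater (smaller) than both neighbours; plateaus are
#' skipped. The window is invalid when either extremum is absent or when
#' missing samples fall inside it.
#'
#' @param profile a smoothed `Profile` with at least 5 valid samples.
#' @return a `SearchWindow`: list with `inner_index`, `outer_index`,
#'   `valid` (and `inner_index < outer_index` when valid).
#' @export
find_search_window <- function(profile) {
  stopifnot(inherits(profile, "Profile"))
  s <- profile$samples
  n <- length(s)
  invalid <- list(inner_index = NA_integer_, outer_index = NA_integer_,
                  valid = FALSE)
  if (sum(is.finite(s)) < 5L) return(structure(invalid,
                                               class = "SearchWindow"))
  i <- 2:(n - 1)
  fin <- is.finite(s[i]) & is.finite(s[i - 1]) & is.finite(s[i + 1])
  maxima <- i[fin & s[i] > s[i - 1] & s[i] > s[i + 1]]
  minima <- i[fin & s[i] < s[i - 1] & s[i] < s[i + 1]]
  if (!length(maxima)) return(structure(invalid, class = "SearchWindow"))
  dc <- abs(maxima - profile$center_index)
  cand <- maxima[dc == min(dc)]
  outer <- max(cand)          # tie: prefer the outward (CSF-side) maximum
  minima <- minima[minima < outer]
  if (!length(minima)) {      # CSF bound found, WM bound absent
    invalid$outer_index <- as.integer(outer)
    return(structure(invalid, class = "SearchWindow"))
  }
  inner <- max(minima)        # nearest minimum inward of the CSF bound
  if (any(!is.finite(s[inner:outer]))) {
    invalid$inner_index <- as.integer(inner)
    invalid$outer_index <- as.integer(outer)
    return(structure(invalid, class = "SearchWindow"))
  }
  structure(list(inner_index = as.integer(inner),
                 outer_index = as.integer(outer), valid = TRUE),
            class = "SearchWindow")
}

#' Relocated GM/CSF boundary within the search window
#'
#' The new boundary is the sample with the largest first differential of
#' the (smoothed) profile inside the window — the steepest MD rise from
#' cortex into CSF. Ties are broken towards the profile centre, i.e. the
#' smallest implied misalignment (and inward on an exact distance tie).
#'
#' @param profile the smoothed `Profile` used for the window.
#' @param window a valid [find_search_window()] result.
#' @return integer boundary sample index, or `NA` when the window is
#'   invalid or no finite gradient exists inside it (fallback trigger).
#' @export
detect_gm_csf_boundary <- function(profile, window) {
  stopifnot(inherits(profile, "Profile"))
  if (!isTRUE(window$valid)) return(NA_integer_)
  g <- differentiate_profile(profile)
  idx <- window$inner_index:window$outer_index
  gv <- g[idx]
  if (!any(is.finite(gv))) return(NA_integer_)
  gmax <- max(gv, na.rm = TRUE)
  # ties at the numerical level: values within a relative epsilon of the
  # maximum count as tied, so exactly-flat gradient stretches (constant
  # ramps) collapse to the tie rule instead of being decided by
  # floating-point dust
  tol <- max(abs(gmax), .Machine$double.eps) * 1e-9
  best <- idx[which(is.finite(gv) & gv >= gmax - tol)]
  if (length(best) > 1L) {
    dc <- abs(best - profile$center_index)
    best <- best[dc == min(dc)]
    best <- min(best)
  }
  as.integer(best)
}

# ---------------------------------------------------------------------------
# SGDM

#' Parameters of the surface-guided mapping
#'
#' @param spacing profile sample step (mm); sub-voxel relative to typical
#'   1.7-2 mm DWI voxels.
#' @param range_in,range_out fixed profile extents (mm); when `NULL` the
#'   per-vertex default `max(min_range, 2 * thickness)` is used so the
#'   window can contain both the WM minimum and the CSF maximum under
#'   plausible distortions.
#' @param min_range floor of the per-vertex default extent (mm).
#' @param smooth_width moving-average width in samples (odd).
#' @param sample_method how the final value is drawn at the relocated
#'   point: `"linear"` (trilinear, default) or `"nn"` (literal single-voxel
#'   lookup).
#' @param eps degenerate-column threshold passed to [column_frames()].
#' @return list of class `SgdmParams`.
#' @export
sgdm_params <- function(spacing = 0.5, range_in = NULL, range_out = NULL,
                        min_range = 8, smooth_width = 3L,
                        sample_method = c("linear", "nn"), eps = 1e-6) {
  sample_method <- match.arg(sample_method)
  stopifnot(spacing > 0, min_range > 0)
  structure(list(spacing = spacing, range_in = range_in,
                 range_out = range_out, min_range = min_range,
                 smooth_width = as.integer(smooth_width),
                 sample_method = sample_method, eps = eps),
            class = "SgdmParams")
}

#' Surface-guided diffusion mapping (SGDM)
#'
#' For every vertex: build the cortical-column frame, sample the MD profile
#' centred on the pial vertex, smooth it, locate the search window between
#' the WM-side local minimum and the CSF-side local maximum, take the
#' gradient argmax inside the window as the relocated GM/CSF boundary, and
#' sample the volume half the cortical thickness inward of that boundary
#' along the column — the point that corresponds to the mid-surface vertex
#' once the local misalignment is undone. Any per-vertex stage failure
#' falls back to trilinear sampling at the mid-surface vertex (tag
#' `"sgdm-fallback"`); nothing is fatal.
#'
#' @param md MD [scalar_volume()] used to detect boundaries.
#' @param surfaces a [linked_surface_set()] in the volume's world frame.
#' @param params an [sgdm_params()] list.
#' @param values volume actually sampled at the relocated point; defaults
#'   to `md` itself, but can be another volume in the same (distorted)
#'   space, e.g. a CSF class-probability map.
#' @return a [vertex_map()] tagged `"sgdm"` / `"sgdm-fallback"`, with extra
#'   elements `shift` (detected boundary offset from the pial vertex, mm,
#'   positive outward; `NA` for fallbacks) and `reason` (per-vertex
#'   fallback reason, `"ok"` where SGDM succeeded).
#' @export
map_sgdm <- function(md, surfaces, params = sgdm_params(), values = md) {
  stopifnot(is_scalar_volume(md), inherits(surfaces, "LinkedSurfaceSet"),
            inherits(params, "SgdmParams"))
  frames <- column_frames(surfaces, eps = params$eps)
  nv <- n_vertices(surfaces$pial)
  value <- rep(NA_real_, nv)
  method <- rep("sgdm-fallback", nv)
  shift <- rep(NA_real_, nv)
  reason <- rep("ok", nv)
  mid <- surfaces$mid$vertices
  for (k in seq_len(nv)) {
    th <- frames$thickness[k]
    res <- sgdm_vertex(md, values,
                       frame = list(anchor = frames$anchor[k, ],
                                    inward = frames$inward[k, ],
                                    defined = frames$defined[k]),
                       thickness = th, params = params)
    if (is.na(res$reason) || res$reason == "ok") {
      value[k] <- res$value
      method[k] <- "sgdm"
      shift[k] <- res$shift
    } else {
      reason[k] <- res$reason
      value[k] <- sample_volume_at(values, mid[k, , drop = FALSE],
                                   method = "linear")
    }
  }
  out <- vertex_map(value, method = method)
  out$method[!out$valid] <- method[!out$valid]
  out$shift <- shift
  out$reason <- reason
  out
}

sgdm_vertex <- function(md, values, frame, thickness, params) {
  fail <- function(why) list(value = NA_real_, shift = NA_real_,
                             reason = why)
  if (!isTRUE(frame$defined)) return(fail("undefined_frame"))
  r_in <- params$range_in %||% max(params$min_range, 2 * thickness)
  r_out <- params$range_out %||% max(params$min_range, 2 * thickness)
  p <- sample_profile(md, frame, r_in, r_out, params$spacing)
  if (sum(is.finite(p$samples)) < 5L) return(fail("profile_invalid"))
  ps <- smooth_profile(p, params$smooth_width)
  w <- find_search_window(ps)
  if (!w$valid) return(fail("window_invalid"))
  bi <- detect_gm_csf_boundary(ps, w)
  if (is.na(bi)) return(fail("no_boundary"))
  # boundary lies at anchor - t_b * inward; step half the thickness inward
  t_b <- p$t[bi]
  point <- frame$anchor - (t_b - thickness / 2) * frame$inward
  val <- sample_volume_at(values, matrix(point, ncol = 3),
                          method = params$sample_method)
  if (!is.finite(val)) return(fail("sample_missing"))
  list(value = val, shift = t_b, reason = "ok")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
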