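#' Specification of a synthetic layered-brain phantom
#'
#' Describes a WM/GM/CSF layered geometry (concentric spheres or a flat
#' slab) with known per-tissue MD, matched analytic surfaces and a
#' controllable misalignment field standing in for EPI distortion. The
#' default MD levels are 0.7e-3 (WM), 0.8e-3 (GM) and 3.0e-3 mm^2/s (CSF,
#' matching the fixed CSF diffusivity of the partial-volume correction);
#' the default noise is Gaussian with sd 0.05e-3 mm^2/s on the MD map.
#' All randomness is fixed by `seed`.
#'
#' The layering mirrors a cortical column embedded in a head, inward to
#' outward: ventricular CSF core, WM sheet of width `wm_width`, GM shell
#' of width `thickness`, subarachnoid CSF shell of width `csf_width`, and
#' a low-signal background (skull/dura) beyond. The finite CSF shell and
#' the ventricular core give MD profiles the genuine CSF local maximum
#' and WM-side local minimum that real cortical profiles show — the
#' landmarks the search window is built from.
#'
#' @param geometry `"sphere"` (concentric shells around the origin) or
#'   `"slab"` (flat sheets normal to z).
#' @param white_level white-surface radius (sphere) or plane height
#'   (slab), mm.
#' @param thickness cortical (GM shell) thickness, mm, `> 0`.
#' @param wm_width WM sheet width between ventricle and white surface, mm.
#' @param csf_width subarachnoid CSF shell width outside the pial
#'   surface, mm.
#' @param voxel isotropic voxel size, mm.
#' @param md_wm,md_gm,md_csf per-tissue MD levels (mm^2/s);
#'   `md_csf > md_gm` is required for boundary contrast.
#' @param md_background apparent MD of the extracranial background
#'   (mm^2/s); low, as in real MD maps where skull and air carry little
#'   signal.
#' @param noise_sd Gaussian noise sd added to the MD volume (mm^2/s).
#'   Noise is Gaussian, not Rician: MD is a derived map, not raw signal.
#' @param distortion displacement description: list with `type` in
#'   `"none"`, `"shift"` (constant `vector`, mm), `"radial"` (uniform
#'   `amplitude` mm outward from `center`), `"smooth"` (low-order cosine
#'   field with seeded coefficients, peak `amplitude` mm).
#' @param subdivision icosphere subdivision level (sphere; level 3 gives
#'   642 vertices) or per-side grid refinement (slab).
#' @param margin world-space padding between the pial surface and the grid
#'   edge (mm); must exceed the outward profile range.
#' @param slab_extent lateral extent of the slab sheets (mm).
#' @param seed integer fixing all randomness.
#' @return list of class `PhantomSpec`.
#' @export
phantom_spec <- function(geometry = c("sphere", "slab"), white_level = 30,
                         thickness = 3, wm_width = 3, csf_width = 4,
                         voxel = 2, md_wm = 0.7e-3,
                         md_gm = 0.8e-3, md_csf = 3.0e-3,
                         md_background = 0.3e-3,
                         noise_sd = 0.05e-3,
                         distortion = list(type = "none"),
                         subdivision = 3L, margin = 11, slab_extent = 40,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(thickness > 0, voxel > 0, margin > 0, wm_width > 0,
            csf_width > 0)
  if (geometry == "sphere" && wm_width >= white_level)
    stop("wm_width must be smaller than the white-surface radius")
  if (md_csf <= md_gm)
    stop("phantom requires md_csf > md_gm (GM/CSF boundary contrast)")
  distortion$type <- distortion$type %||% "none"
  if (!distortion$type %in% c("none", "shift", "radial", "smooth"))
    stop("unknown distortion type: ", distortion$type)
  structure(list(geometry = geometry, white_level = white_level,
                 thickness = thickness, wm_width = wm_width,
                 csf_width = csf_width, voxel = voxel, md_wm = md_wm,
                 md_gm = md_gm, md_csf = md_csf,
                 md_background = md_background, noise_sd = noise_sd,
                 distortion = distortion,
                 subdivision = as.integer(subdivision), margin = margin,
                 slab_extent = slab_extent, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a ground-truth phantom
#'
#' Builds the full synthetic input set: an MD volume with per-tissue
#' levels assigned by sub-voxel volume sampling (8 subsamples per axis,
#' i.e. 512 per boundary voxel), tissue-fraction volumes, a CSF
#' class-probability volume (equal to the CSF fraction), exact analytic
#' linked surfaces, and the per-vertex true GM MD. The spec's distortion
#' affects the MD and CSF-probability volumes only — they stand for maps
#' acquired in the distorted EPI space and are voxelised directly from the
#' displaced anatomy (a single voxelisation, like a real acquisition) —
#' while the fraction volumes remain aligned, like fractions derived from
#' an undistorted structural scan. Noise is added last (acquisition noise
#' lives in the distorted space), seeded by `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `md`, `md_clean` (undistorted, noise-free),
#'   `fractions` (list of `wm`, `gm`, `csf`, `bg` [scalar_volume()]s,
#'   summing to 1 at every voxel; `bg` is zero throughout the head),
#'   `csf_class_prob` (the CSF class fraction: ventricular plus
#'   subarachnoid), `surfaces` (a [linked_surface_set()]), `truth`
#'   (per-vertex true GM MD) and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$thickness < 2 * spec$voxel)
    warning("cortical thickness below 2 voxels: severe partial volume")
  grid <- phantom_grid(spec)
  fr <- phantom_fractions(spec, grid)
  mk <- function(a, units) scalar_volume(array(a, grid$dim), grid$affine,
                                         units)
  md_clean <- fr$wm * spec$md_wm + fr$gm * spec$md_gm +
    fr$csf * spec$md_csf + fr$bg * spec$md_background
  if (spec$distortion$type != "none") {
    disp <- displacement_field(grid$world, spec$distortion,
                               seed = spec$seed)
    frd <- phantom_fractions(spec, grid, disp = disp)
    md_vol <- mk(frd$wm * spec$md_wm + frd$gm * spec$md_gm +
                   frd$csf * spec$md_csf + frd$bg * spec$md_background,
                 "mm^2/s")
    prob_vol <- mk(frd$csf, "fraction")
  } else {
    md_vol <- mk(md_clean, "mm^2/s")
    prob_vol <- mk(fr$csf, "fraction")
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    md_vol$data <- md_vol$data +
      array(stats::rnorm(prod(grid$dim), 0, spec$noise_sd), grid$dim)
  }
  surfaces <- phantom_surfaces(spec)
  list(md = md_vol,
       md_clean = mk(md_clean, "mm^2/s"),
       fractions = list(wm = mk(fr$wm, "fraction"),
                        gm = mk(fr$gm, "fraction"),
                        csf = mk(fr$csf, "fraction"),
                        bg = mk(fr$bg, "fraction")),
       csf_class_prob = prob_vol,
       surfaces = surfaces,
       truth = rep(spec$md_gm, n_vertices(surfaces$pial)),
       spec = spec)
}

phantom_grid <- function(spec) {
  v <- spec$voxel
  if (spec$geometry == "sphere") {
    ext <- spec$white_level + spec$thickness + spec$margin
    nh <- ceiling(ext / v)
    n <- rep(2L * nh + 1L, 3)
    orig <- rep(-nh * v, 3)
  } else {
    half_xy <- spec$slab_extent / 2 + spec$margin
    nh_xy <- ceiling(half_xy / v)
    zlo <- spec$white_level - spec$margin
    zhi <- spec$white_level + spec$thickness + spec$margin
    nz <- ceiling((zhi - zlo) / v) + 1L
    n <- c(2L * nh_xy + 1L, 2L * nh_xy + 1L, nz)
    orig <- c(-nh_xy * v, -nh_xy * v, zlo)
  }
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- orig
  centers <- as.matrix(expand.grid(i = seq_len(n[1]) - 1,
                                   j = seq_len(n[2]) - 1,
                                   k = seq_len(n[3]) - 1))
  world <- centers * v
  world[, 1] <- world[, 1] + orig[1]
  world[, 2] <- world[, 2] + orig[2]
  world[, 3] <- world[, 3] + orig[3]
  list(dim = n, affine = aff, world = world)
}

# signed "depth coordinate": radius (sphere) or z (slab); the white surface
# sits at spec$white_level and the pial at white_level + thickness
phantom_depth <- function(spec, pts) {
  if (spec$geometry == "sphere") sqrt(rowSums(pts^2)) else pts[, 3]
}

# class of a depth coordinate in the 5-layer model:
# ventricle CSF | WM | GM | subarachnoid CSF | background
phantom_class <- function(spec, r) {
  t0 <- spec$white_level - spec$wm_width
  t1 <- spec$white_level
  t2 <- spec$white_level + spec$thickness
  t3 <- t2 + spec$csf_width
  cls <- integer(length(r))              # 1 wm, 2 gm, 3 csf, 4 background
  cls[r < t0] <- 3L
  cls[r >= t0 & r < t1] <- 1L
  cls[r >= t1 & r < t2] <- 2L
  cls[r >= t2 & r < t3] <- 3L
  cls[r >= t3] <- 4L
  cls
}

# Voxelised class fractions by sub-voxel volume sampling. When `disp` is
# given (one displacement per voxel centre, pull convention) the displaced
# anatomy is voxelised directly — the distorted image is an image of
# displaced tissue, not a resampled image, so it carries a single
# voxelisation like a real acquisition. The displacement is treated as
# constant within a voxel (it varies on the cm scale).
phantom_fractions <- function(spec, grid, subsamples = 8L, disp = NULL) {
  world <- grid$world
  if (!is.null(disp)) world <- world + disp
  r <- phantom_depth(spec, world)
  bounds <- spec$white_level + c(-spec$wm_width, 0, spec$thickness,
                                 spec$thickness + spec$csf_width)
  half_diag <- spec$voxel * sqrt(3) / 2
  cls <- phantom_class(spec, r)
  f <- lapply(1:4, function(ci) as.numeric(cls == ci))
  near <- which(Reduce(`|`, lapply(bounds,
                                   function(b) abs(r - b) <= half_diag)))
  if (length(near)) {
    s <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * spec$voxel
    offs <- as.matrix(expand.grid(x = s, y = s, z = s))
    ns <- nrow(offs)
    block <- 2000L
    for (start in seq(1L, length(near), by = block)) {
      rng <- start:min(start + block - 1L, length(near))
      base <- world[near[rng], , drop = FALSE]
      m <- length(rng)
      pts <- base[rep(seq_len(m), each = ns), , drop = FALSE] +
        offs[rep(seq_len(ns), times = m), , drop = FALSE]
      sub_cls <- phantom_class(spec, phantom_depth(spec, pts))
      for (ci in 1:4)   # sub-points are ordered in blocks of ns per voxel
        f[[ci]][near[rng]] <- colMeans(matrix(sub_cls == ci, nrow = ns))
    }
  }
  list(wm = f[[1]], gm = f[[2]], csf = f[[3]], bg = f[[4]])
}

phantom_surfaces <- function(spec) {
  if (spec$geometry == "sphere") {
    unit <- icosphere(spec$subdivision)
    white <- triangle_mesh(unit$vertices * spec$white_level,
                           unit$triangles)
    pial <- triangle_mesh(unit$vertices *
                            (spec$white_level + spec$thickness),
                          unit$triangles)
  } else {
    sheet <- slab_sheet(spec$slab_extent, 2L^spec$subdivision + 1L)
    wv <- cbind(sheet$xy, spec$white_level)
    pv <- cbind(sheet$xy, spec$white_level + spec$thickness)
    white <- triangle_mesh(wv, sheet$triangles)
    pial <- triangle_mesh(pv, sheet$triangles)
  }
  linked_surface_set(white, pial)
}

#' Icosphere mesh
#'
#' Unit-radius geodesic sphere: a regular icosahedron subdivided `level`
#' times (each subdivision splits every triangle in four and re-projects
#' onto the sphere). Level 0 has 12 vertices; level 3 has 642; each level
#' multiplies the triangle count by 4.
#'
#' @param level non-negative integer subdivision level.
#' @return a [triangle_mesh()] with unit-norm vertices.
#' @export
icosphere <- function(level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      idx <- mids[[key]]
      if (is.null(idx)) {
        m <- (verts[a, ] + verts[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        mids[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c3, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  triangle_mesh(v, f)
}

slab_sheet <- function(extent, n_side) {
  xs <- seq(-extent / 2, extent / 2, length.out = n_side)
  xy <- as.matrix(expand.grid(x = xs, y = xs))
  idx <- function(i, j) (j - 1L) * n_side + i
  tris <- matrix(0L, nrow = 2L * (n_side - 1L)^2, ncol = 3)
  t <- 0L
  for (j in seq_len(n_side - 1L)) for (i in seq_len(n_side - 1L)) {
    tris[t <- t + 1L, ] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
    tris[t <- t + 1L, ] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L),
                             idx(i, j + 1L))
  }
  list(xy = xy, triangles = tris)
}

#' Apply a synthetic misalignment field to a volume
#'
#' Resamples the volume at `x + d(x)` with trilinear interpolation (pull
#' convention): a displacement field `d` pointing outward moves apparent
#' tissue content inward, the way EPI distortion misplaces tissue relative
#' to structural space. Sample coordinates falling outside the grid are
#' clamped to the grid edge, so shift/unshift pairs round-trip wherever no
#' genuinely new content enters. Deterministic given `seed` (used only by
#' the `"smooth"` field's coefficients).
#'
#' @param vol a [scalar_volume()].
#' @param distortion displacement description; see [phantom_spec()].
#' @param seed integer seed for the smooth field's coefficients.
#' @return a distorted [scalar_volume()] on the same grid.
#' @export
apply_distortion <- function(vol, distortion, seed = 1L) {
  stopifnot(is_scalar_volume(vol))
  type <- distortion$type %||% "none"
  if (type == "none") return(vol)
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                               j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  pts <- voxel_to_world(vol, idx)
  disp <- displacement_field(pts, distortion, seed)
  vals <- sample_volume_clamped(vol, pts + disp)
  scalar_volume(array(vals, d), vol$affine, vol$units)
}

displacement_field <- function(pts, distortion, seed = 1L) {
  n <- nrow(pts)
  switch(distortion$type,
    shift = matrix(rep(as.numeric(distortion$vector), each = n), ncol = 3),
    radial = {
      ctr <- distortion$center %||% c(0, 0, 0)
      rel <- sweep(pts, 2, as.numeric(ctr))
      r <- sqrt(rowSums(rel^2))
      u <- rel / pmax(r, 1e-12)
      u * distortion$amplitude
    },
    smooth = {
      ord <- distortion$order %||% 2L
      lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
      u <- sweep(sweep(pts, 2, lo), 2, pmax(hi - lo, 1e-12), "/")
      set.seed(seed)
      ks <- as.matrix(expand.grid(k1 = 0:ord, k2 = 0:ord, k3 = 0:ord))
      disp <- matrix(0, n, 3)
      for (ax in 1:3) {
        coef <- stats::rnorm(nrow(ks))
        f <- numeric(n)
        for (m in seq_len(nrow(ks)))
          f <- f + coef[m] * cos(pi * ks[m, 1] * u[, 1]) *
            cos(pi * ks[m, 2] * u[, 2]) * cos(pi * ks[m, 3] * u[, 3])
        disp[, ax] <- f / max(abs(f)) * distortion$amplitude
      }
      disp
    },
    stop("unknown distortion type: ", distortion$type))
}

#' Analytic profile fixtures
#'
#' Builds stand-alone `Profile` objects with known structure for testing
#' the boundary-detection chain without a volume. The column mirrors the
#' phantom's five layers, inward to outward: ventricular CSF, WM of width
#' `wm_width`, GM of width `gm_width`, a CSF band of width `csf_width`,
#' background beyond. The GM/CSF transition sits at `t = shift` mm
#' (positive outward) and its sample index is attached as attribute
#' `"truth_index"`. Shapes: `"step"` is piecewise constant (note its
#' plateaus carry no strict local extrema until noise is added);
#' `"smoothed_step"` uses logistic transitions (width 0.8 mm) and carries
#' genuine WM-minimum / CSF-maximum landmarks even noise-free — the
#' canonical fixture for shift-recovery sweeps; `"peak"` is a single
#' Gaussian CSF peak at `t = shift`. Optional seeded Gaussian noise is
#' correlated over `noise_scale` mm (iid node noise, linearly
#' interpolated), emulating voxel-scale noise read through trilinear
#' interpolation.
#'
#' @param shape `"step"`, `"smoothed_step"` or `"peak"`.
#' @param shift displacement of the GM/CSF transition from the profile
#'   centre (mm); `|shift|` must stay inside `range`.
#' @param spacing sample step (mm).
#' @param range profile half-extent (mm).
#' @param gm_width,wm_width,csf_width layer widths (mm).
#' @param levels tissue values, list with `wm`, `gm`, `csf`, `bg`.
#' @param noise_sd sd of additive Gaussian noise (0 = none).
#' @param noise_scale correlation length of the noise (mm).
#' @param seed integer seed for the noise.
#' @return a `Profile` with attribute `truth_index`.
#' @export
make_profile_fixture <- function(shape = c("step", "smoothed_step", "peak"),
                                 shift = 0, spacing = 0.5, range = 8,
                                 gm_width = 3, wm_width = 3, csf_width = 4,
                                 levels = list(wm = 0.7e-3, gm = 0.8e-3,
                                               csf = 3.0e-3, bg = 0.3e-3),
                                 noise_sd = 0, noise_scale = 2,
                                 seed = 1L) {
  shape <- match.arg(shape)
  if (abs(shift) >= range) stop("|shift| must be smaller than 'range'")
  tg <- profile_t_grid(range, range, spacing)
  t <- tg$t
  t1 <- shift - gm_width          # WM/GM
  t0 <- t1 - wm_width             # ventricle/WM
  t3 <- shift + csf_width         # CSF/background
  vals <- switch(shape,
    step = ifelse(t < t0, levels$csf,
             ifelse(t < t1, levels$wm,
               ifelse(t < shift, levels$gm,
                 ifelse(t < t3, levels$csf, levels$bg)))),
    smoothed_step = {
      w <- 0.8
      sig <- function(x) 1 / (1 + exp(-x))
      levels$csf + (levels$wm - levels$csf) * sig((t - t0) / w) +
        (levels$gm - levels$wm) * sig((t - t1) / w) +
        (levels$csf - levels$gm) * sig((t - shift) / w) +
        (levels$bg - levels$csf) * sig((t - t3) / w)
    },
    peak = levels$gm + (levels$csf - levels$gm) *
      exp(-(t - shift)^2 / (2 * 1.5^2)))
  if (noise_sd > 0) {
    set.seed(seed)
    nodes <- seq(min(t) - noise_scale, max(t) + noise_scale,
                 by = noise_scale)
    eta <- stats::rnorm(length(nodes), 0, noise_sd)
    vals <- vals + stats::approx(nodes, eta, xout = t)$y
  }
  p <- structure(list(t = t, samples = vals, center_index = tg$center,
                      spacing = spacing,
                      frame = list(anchor = c(0, 0, 0),
                                   inward = c(0, 0, -1), defined = TRUE),
                      valid = TRUE),
                 class = "Profile")
  attr(p, "truth_index") <- tg$center + as.integer(round(shift / spacing))
  p
}
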