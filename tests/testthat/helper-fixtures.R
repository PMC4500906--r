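# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# undistorted spherical phantom at the default study conditions
phantom_aligned <- function() cached("aligned", function()
  suppressWarnings(make_phantom(phantom_spec(seed = 11))))

# the same sphere with a uniform 2 mm outward displacement field
phantom_shifted <- function() cached("shifted", function()
  suppressWarnings(make_phantom(phantom_spec(
    seed = 11, distortion = list(type = "radial", amplitude = 2)))))

# small linked icosphere pair (white r = 30, pial r = 33)
linked_spheres <- function(level = 2L, r_white = 30, r_pial = 33) {
  unit <- icosphere(level)
  linked_surface_set(
    triangle_mesh(unit$vertices * r_white, unit$triangles),
    triangle_mesh(unit$vertices * r_pial, unit$triangles))
}

# simple volume with a linear ramp along x
ramp_volume <- function(n = 8, voxel = 1) {
  a <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) a[i, , ] <- i - 1
  scalar_volume(a, diag(c(voxel, voxel, voxel, 1)))
}

# isotropic DWI series: S = s0 * exp(-b * d), 6 axes + b0
isotropic_dwi <- function(d = 0.8e-3, b = 600, s0 = 1000,
                          dims = c(3, 3, 3)) {
  dirs <- rbind(c(0, 0, 0),
                diag(3),
                c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2),
                c(1, 0, 1) / sqrt(2))
  bvals <- c(0, rep(b, 6))
  sig <- s0 * exp(-bvals * d)
  stacks <- array(rep(sig, each = prod(dims)), dim = c(dims, 7))
  dwi_series(stacks, diag(4), gradient_table(bvals, dirs))
}
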