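test_that("phantom generation is fully deterministic given the seed", {
  spec <- phantom_spec(subdivision = 2L, seed = 9)
  a <- suppressWarnings(make_phantom(spec))
  b <- suppressWarnings(make_phantom(spec))
  expect_identical(a$md$data, b$md$data)
  expect_identical(a$fractions$csf$data, b$fractions$csf$data)
  expect_identical(a$surfaces$pial$vertices, b$surfaces$pial$vertices)
  c3 <- suppressWarnings(make_phantom(phantom_spec(subdivision = 2L,
                                                   seed = 10)))
  expect_false(identical(a$md$data, c3$md$data))
})

test_that("noise-free voxels deep in each layer take the exact MD level", {
  spec <- phantom_spec(subdivision = 2L, noise_sd = 0, seed = 1)
  ph <- suppressWarnings(make_phantom(spec))
  # voxels fully inside a layer (class fraction 1) carry the level exactly
  pure_gm <- ph$fractions$gm$data == 1
  expect_gt(sum(pure_gm), 100)
  expect_true(all(abs(ph$md$data[pure_gm] - spec$md_gm) < 1e-15))
  pure_wm <- ph$fractions$wm$data == 1
  expect_gt(sum(pure_wm), 100)
  expect_true(all(abs(ph$md$data[pure_wm] - spec$md_wm) < 1e-15))
  grid <- as.matrix(expand.grid(i = seq_len(dim(ph$md)[1]) - 1,
                                j = seq_len(dim(ph$md)[2]) - 1,
                                k = seq_len(dim(ph$md)[3]) - 1))
  r <- sqrt(rowSums(voxel_to_world(ph$md, grid)^2))
  vent <- r < 25                     # deep in the ventricular core
  expect_true(all(abs(ph$md$data[vent] - spec$md_csf) < 1e-15))
  expect_identical(ph$truth, rep(spec$md_gm,
                                 n_vertices(ph$surfaces$pial)))
})

test_that("class fractions partition every voxel and match finer
           supersampling", {
  ph <- phantom_aligned()
  tot <- ph$fractions$wm$data + ph$fractions$gm$data +
    ph$fractions$csf$data + ph$fractions$bg$data
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-12)
  expect_identical(ph$csf_class_prob$data, ph$fractions$csf$data)

  # oracle: 20x20x20 sub-voxel sampling of the analytic shell geometry on
  # a sample of boundary voxels
  spec <- ph$spec
  d <- dim(ph$md)
  set.seed(12)
  grid <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                                j = seq_len(d[2]) - 1,
                                k = seq_len(d[3]) - 1))
  world <- voxel_to_world(ph$md, grid)
  r <- sqrt(rowSums(world^2))
  near_pial <- which(abs(r - 33) < 1.7)
  pick <- sample(near_pial, 40)
  s <- ((seq_len(20) - 0.5) / 20 - 0.5) * spec$voxel
  offs <- as.matrix(expand.grid(s, s, s))
  for (v in pick) {
    rr <- sqrt(rowSums((offs + matrix(world[v, ], nrow(offs), 3,
                                      byrow = TRUE))^2))
    f_csf_oracle <- mean(rr >= 33 & rr < 37)
    expect_lt(abs(ph$fractions$csf$data[v] - f_csf_oracle), 0.02)
  }
})

test_that("thin cortex warns about severe partial volume", {
  expect_warning(make_phantom(phantom_spec(subdivision = 1L,
                                           thickness = 3, voxel = 2)),
                 "partial volume")
  expect_silent(ph <- make_phantom(phantom_spec(subdivision = 1L,
                                                thickness = 5,
                                                voxel = 2)))
})

test_that("distortion fields resample with the pull convention", {
  # smooth blob so interpolation error is tiny
  n <- 21
  ax <- seq(-10, 10)
  blob <- array(0, dim = c(n, n, n))
  for (i in 1:n) for (j in 1:n)
    blob[i, j, ] <- exp(-(ax[i]^2 + ax[j]^2 + ax^2) / 40)
  aff <- diag(4); aff[1:3, 4] <- -10
  vol <- scalar_volume(blob, aff)

  same <- apply_distortion(vol, list(type = "none"))
  expect_identical(same$data, vol$data)

  # +2 then -2 mm shifts recover the original away from the faces
  fwd <- apply_distortion(vol, list(type = "shift", vector = c(2, 0, 0)))
  back <- apply_distortion(fwd, list(type = "shift", vector = c(-2, 0, 0)))
  core <- 4:(n - 3)
  expect_lt(max(abs(back$data[core, core, core] -
                      vol$data[core, core, core])), 1e-6)

  # full-voxel shift is an exact index shift
  one <- apply_distortion(vol, list(type = "shift", vector = c(1, 0, 0)))
  expect_equal(one$data[1:(n - 1), , ], vol$data[2:n, , ],
               tolerance = 1e-12)

  # radial displacement moves content inward by its amplitude
  ph <- phantom_shifted()
  clean <- phantom_aligned()
  pial_dir <- c(1, 0, 0)
  probe_r <- seq(26, 36, by = 0.5)
  pts <- outer(probe_r, pial_dir)
  shifted_vals <- sample_volume_at(ph$md, pts)
  clean_vals <- sample_volume_at(clean$md_clean, pts + 2 * pts /
                                   sqrt(rowSums(pts^2)))
  expect_lt(median(abs(shifted_vals - clean_vals), na.rm = TRUE),
            3 * ph$spec$noise_sd)

  # deterministic smooth field
  s1 <- apply_distortion(vol, list(type = "smooth", amplitude = 1.5),
                         seed = 4)
  s2 <- apply_distortion(vol, list(type = "smooth", amplitude = 1.5),
                         seed = 4)
  expect_identical(s1$data, s2$data)
})

test_that("profile fixtures encode the displaced transition", {
  fix0 <- make_profile_fixture("smoothed_step", shift = 0)
  expect_identical(attr(fix0, "truth_index"), fix0$center_index)
  g <- differentiate_profile(smooth_profile(fix0, 3))
  expect_equal(which.max(g), fix0$center_index)

  fix2 <- make_profile_fixture("smoothed_step", shift = 2, spacing = 0.5)
  expect_identical(attr(fix2, "truth_index"), fix2$center_index + 4L)

  pk <- smooth_profile(make_profile_fixture("peak", shift = 0), 3)
  expect_equal(find_search_window(pk)$outer_index, pk$center_index)

  # step shape carries the exact levels; noise is seeded and correlated
  st <- make_profile_fixture("step", shift = 0)
  expect_setequal(unique(st$samples),
                  c(0.7e-3, 0.8e-3, 3.0e-3, 0.3e-3))
  n1 <- make_profile_fixture("step", shift = 0, noise_sd = 0.02e-3,
                             seed = 5)
  n2 <- make_profile_fixture("step", shift = 0, noise_sd = 0.02e-3,
                             seed = 5)
  expect_identical(n1$samples, n2$samples)
  expect_error(make_profile_fixture("step", shift = 9, range = 8),
               "shift")
})

test_that("slab phantoms expose the same layered structure", {
  spec <- phantom_spec(geometry = "slab", subdivision = 2L, noise_sd = 0,
                       seed = 2)
  ph <- suppressWarnings(make_phantom(spec))
  th <- ph$surfaces$thickness
  expect_equal(th, rep(spec$thickness, length(th)), tolerance = 1e-12)
  # white sheet at z = 30, pial at 33
  expect_true(all(ph$surfaces$white$vertices[, 3] == 30))
  expect_true(all(ph$surfaces$pial$vertices[, 3] == 33))
  # a voxel layer fully inside GM carries the exact level (z = 31 spans
  # 30-32, inside the 30-33 band)
  mid_val <- sample_volume_at(ph$md, rbind(c(1, 1, 31)))
  expect_equal(mid_val, spec$md_gm, tolerance = 1e-12)
})
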