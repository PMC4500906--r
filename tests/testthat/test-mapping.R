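make_profile <- function(samples, spacing = 0.5,
                         center = (length(samples) + 1L) %/% 2L) {
  structure(list(t = (seq_along(samples) - center) * spacing,
                 samples = samples, center_index = center,
                 spacing = spacing,
                 frame = list(anchor = c(0, 0, 0), inward = c(0, 0, -1),
                              defined = TRUE),
                 valid = TRUE), class = "Profile")
}

test_that("nearest-neighbour mapping equals exhaustive nearest-voxel search", {
  set.seed(5)
  vol <- scalar_volume(array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)),
                       affine = rbind(c(2, 0, 0, -4), c(0, 1.5, 0, 0),
                                      c(0, 0, 2, -6), c(0, 0, 0, 1)))
  centers <- voxel_to_world(vol, as.matrix(expand.grid(0:4, 0:5, 0:6)))
  # vertex exactly at a voxel centre returns that voxel
  mesh_at <- triangle_mesh(centers[c(1, 37, 100), ], rbind(c(1, 2, 3)))
  expect_equal(map_nn(vol, mesh_at)$value,
               as.vector(vol$data)[c(1, 37, 100)])
  # random vertices against a brute-force scan over all voxels
  pts <- cbind(runif(100, -4, 4), runif(100, 0, 7.5),
               runif(100, -6, 6))  # inside the voxel-centre bounding box
  got <- sample_volume_at(vol, pts, method = "nn")
  brute <- apply(pts, 1, function(p) {
    d2 <- rowSums((centers - matrix(p, nrow(centers), 3,
                                    byrow = TRUE))^2)
    as.vector(vol$data)[which.min(d2)]
  })
  expect_equal(got, brute)
  # outside the grid bounding box -> invalid
  out <- map_nn(vol, triangle_mesh(rbind(c(100, 0, 0), c(-50, 0, 0),
                                         c(0, 0, 50)), rbind(c(1, 2, 3))))
  expect_false(any(out$valid))
})

test_that("trilinear mapping reproduces closed-form ramp values", {
  vol <- ramp_volume(8)
  # voxel centre -> exact value; constant direction -> partition of unity
  expect_equal(sample_volume_at(vol, rbind(c(3, 2, 2))), 3)
  const <- scalar_volume(array(7, dim = c(4, 4, 4)))
  set.seed(6)
  pts <- matrix(runif(60, 0.2, 2.8), ncol = 3)
  expect_equal(sample_volume_at(const, pts), rep(7, 20))
  # midpoint along the ramp axis -> arithmetic mean of neighbours
  expect_equal(sample_volume_at(vol, rbind(c(2.5, 3, 3))), 2.5)
  expect_equal(sample_volume_at(vol, rbind(c(2.25, 3.7, 1.1))), 2.25)
  # support leaving the grid -> invalid
  expect_true(is.na(sample_volume_at(vol, rbind(c(-0.5, 3, 3)))))
  expect_equal(sample_volume_at(vol, rbind(c(7, 7, 7))), 7)  # far corner
})

test_that("profiles sample along the column with the stated orientation", {
  vol <- ramp_volume(20)  # value equals x coordinate
  frame <- list(anchor = c(10, 10, 10), inward = c(-1, 0, 0),
                defined = TRUE)  # outward = -inward = +x
  p <- sample_profile(vol, frame, range_in = 3, range_out = 3,
                      spacing = 0.5)
  expect_equal(p$t, seq(-3, 3, by = 0.5))
  expect_equal(p$center_index, 7L)
  expect_equal(p$samples, 10 + p$t)  # outward samples see larger x
  # constant volume -> constant profile
  const <- scalar_volume(array(3, dim = c(10, 10, 10)))
  pc <- sample_profile(const, list(anchor = c(5, 5, 5),
                                   inward = c(0, 0, -1), defined = TRUE),
                       2, 2, 0.5)
  expect_equal(pc$samples, rep(3, 9))
  # anchor far outside -> all samples missing, profile invalid
  po <- sample_profile(const, list(anchor = c(500, 0, 0),
                                   inward = c(0, 0, -1), defined = TRUE),
                       2, 2, 0.5)
  expect_false(po$valid)
  expect_true(all(is.na(po$samples)))
  pu <- sample_profile(const, list(defined = FALSE), 2, 2, 0.5)
  expect_false(pu$valid)
})

test_that("moving-average smoothing truncates and renormalises", {
  p <- make_profile(c(0, 0, 3, 0, 0))
  expect_equal(smooth_profile(p, 3)$samples, c(0, 1, 1, 1, 0))
  expect_equal(smooth_profile(p, 1)$samples, p$samples)
  pc <- make_profile(rep(2.5, 9))
  for (w in c(3, 5, 7)) expect_equal(smooth_profile(pc, w)$samples,
                                     pc$samples)
  expect_error(smooth_profile(p, 2), "odd")
  # missing samples stay missing and are excluded from neighbours' windows
  pm <- make_profile(c(1, NA, 4, 4, 4))
  sm <- smooth_profile(pm, 3)
  expect_true(is.na(sm$samples[2]))
  expect_equal(sm$samples[3], 4)
})

test_that("profile differentiation is exact on lines and flags short input", {
  slope <- 0.3
  p <- make_profile(slope * seq(-2, 2, by = 0.5), spacing = 0.5)
  expect_equal(differentiate_profile(p), rep(slope, 9))
  expect_equal(differentiate_profile(make_profile(rep(1, 7))), rep(0, 7))
  short <- make_profile(c(1, NA, 2, NA, 3))
  expect_true(all(is.na(differentiate_profile(short))))
  # smoothed displaced step: gradient maximal at the transition
  fix <- make_profile_fixture("smoothed_step", shift = 1.5)
  g <- differentiate_profile(smooth_profile(fix, 3))
  expect_equal(which.max(g), attr(fix, "truth_index"))
})

test_that("search window spans from the WM minimum to the CSF maximum", {
  fix <- smooth_profile(make_profile_fixture("smoothed_step", shift = 0), 3)
  w <- find_search_window(fix)
  expect_true(w$valid)
  expect_lt(w$inner_index, w$outer_index)
  # independent exhaustive extrema scan
  s <- fix$samples
  i <- 2:(length(s) - 1)
  maxima <- i[s[i] > s[i - 1] & s[i] > s[i + 1]]
  minima <- i[s[i] < s[i - 1] & s[i] < s[i + 1]]
  expect_equal(w$outer_index,
               maxima[which.min(abs(maxima - fix$center_index))])
  expect_equal(w$inner_index, max(minima[minima < w$outer_index]))
  # the window brackets the true boundary
  expect_true(w$inner_index < fix$center_index &&
                fix$center_index <= w$outer_index)

  mono <- make_profile(seq(0, 2, length.out = 11))
  expect_false(find_search_window(mono)$valid)

  peak <- smooth_profile(make_profile_fixture("peak", shift = 0), 3)
  wp <- find_search_window(peak)
  expect_equal(wp$outer_index, peak$center_index)

  # missing samples inside the window invalidate it
  holed <- fix
  holed$samples[w$inner_index + 1L] <- NA
  expect_false(find_search_window(holed)$valid)
})

test_that("boundary detection takes the windowed gradient argmax with
           ties broken toward the centre", {
  fix <- smooth_profile(make_profile_fixture("smoothed_step", shift = 0), 3)
  w <- find_search_window(fix)
  expect_equal(detect_gm_csf_boundary(fix, w), fix$center_index)

  disp <- smooth_profile(make_profile_fixture("smoothed_step", shift = 2), 3)
  wd <- find_search_window(disp)
  expect_equal(detect_gm_csf_boundary(disp, wd), disp$center_index + 4L)

  # two equal gradient maxima straddling the centre -> the one nearer it
  s <- c(5, 4, 2, 1, 1, 1, 1, 2, 4, 5, 5.5)
  p <- make_profile(s, center = 5L)
  w2 <- list(inner_index = 5L, outer_index = 10L, valid = TRUE)
  g <- differentiate_profile(p)
  expect_equal(max(g[8], g[9]), g[8])  # construction check: tie present
  expect_equal(detect_gm_csf_boundary(p, w2), 8L)

  expect_true(is.na(detect_gm_csf_boundary(fix,
    list(inner_index = NA, outer_index = NA, valid = FALSE))))
})

test_that("detector equals an exhaustive windowed argmax on random
           profiles", {
  set.seed(77)
  n_ok <- 0L
  n_valid <- 0L
  for (rep in seq_len(1000)) {
    samples <- cumsum(rnorm(25)) + rnorm(25, sd = 0.3)
    p <- make_profile(samples, center = 13L)
    ps <- smooth_profile(p, 3)
    w <- find_search_window(ps)
    if (!w$valid) next
    n_valid <- n_valid + 1L
    got <- detect_gm_csf_boundary(ps, w)
    # independent oracle: plain loop over the window on a freshly
    # computed central-difference gradient, nearest-to-centre tie rule
    s <- ps$samples
    n <- length(s)
    g <- numeric(n)
    g[1] <- (s[2] - s[1]) / ps$spacing
    g[n] <- (s[n] - s[n - 1]) / ps$spacing
    for (i in 2:(n - 1)) g[i] <- (s[i + 1] - s[i - 1]) / (2 * ps$spacing)
    best <- NA_integer_
    for (i in w$inner_index:w$outer_index) {
      if (is.na(best) || g[i] > g[best] + 1e-15 ||
          (abs(g[i] - g[best]) <= 1e-15 &&
             abs(i - ps$center_index) < abs(best - ps$center_index)))
        best <- i
    }
    if (identical(got, as.integer(best))) n_ok <- n_ok + 1L
  }
  expect_gt(n_valid, 300)          # the random family must exercise it
  expect_identical(n_ok, n_valid)  # 100% agreement
})

test_that("displaced steps are recovered within one sample across the
           sweep", {
  hits <- 0L; total <- 0L
  for (shift in seq(-3, 3, by = 0.5)) {
    fix <- make_profile_fixture("smoothed_step", shift = shift,
                                range = 10)
    ps <- smooth_profile(fix, 3)
    w <- find_search_window(ps)
    b <- detect_gm_csf_boundary(ps, w)
    total <- total + 1L
    if (!is.na(b) && abs(b - attr(fix, "truth_index")) <= 1L)
      hits <- hits + 1L
  }
  expect_gte(hits / total, 0.99)
})

test_that("SGDM reduces to the linear map on an aligned phantom and
           falls back gracefully", {
  ph <- phantom_aligned()
  lin <- map_linear(ph$md, ph$surfaces$mid)
  sg <- map_sgdm(ph$md, ph$surfaces)
  expect_s3_class(sg, "VertexMap")
  expect_true(all(sg$method %in% c("sgdm", "sgdm-fallback")))
  ok <- sg$method == "sgdm" & lin$valid
  expect_lt(median(abs(sg$value[ok] - lin$value[ok])),
            ph$spec$noise_sd)
  # boundary shifts stay within one sample of the centre when aligned
  expect_true(all(abs(sg$shift[ok]) <= sgdm_params()$spacing + 1e-9))

  # vertices whose columns leave the volume fall back (or go invalid)
  far <- ph$surfaces
  far$pial$vertices[1, ] <- c(500, 0, 0)
  far$white$vertices[1, ] <- c(497, 0, 0)
  far$mid$vertices[1, ] <- c(498.5, 0, 0)
  far$thickness[1] <- 3
  sg2 <- map_sgdm(ph$md, far)
  expect_identical(sg2$method[1], "sgdm-fallback")
  expect_false(sg2$valid[1])
})

test_that("SGDM recovers GM under a uniform outward distortion while the
           baselines read CSF", {
  ph <- phantom_shifted()
  sg <- map_sgdm(ph$md, ph$surfaces)
  nn <- map_nn(ph$md, ph$surfaces$mid)
  lin <- map_linear(ph$md, ph$surfaces$mid)
  # detected shifts track the 2 mm displacement
  expect_lt(abs(median(sg$shift, na.rm = TRUE) + 2), 0.5)
  expect_lt(mean(sg$method == "sgdm-fallback"), 0.05)
  expect_lt(mean(abs(sg$value - ph$truth), na.rm = TRUE), 0.3e-3)
  expect_gt(mean(abs(nn$value - ph$truth), na.rm = TRUE), 0.5e-3)
  expect_gt(mean(abs(lin$value - ph$truth), na.rm = TRUE), 0.5e-3)
  expect_lt(mean(sg$value, na.rm = TRUE), mean(lin$value, na.rm = TRUE))
  expect_lt(mean(sg$value, na.rm = TRUE), mean(nn$value, na.rm = TRUE))
})
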