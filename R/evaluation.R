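#' Project a CSF class-probability volume to the mid surface
#'
#' Applies one of the three mapping methods to a class-probability volume.
#' `"nn"` and `"linear"` sample the probability volume at the mid-surface
#' vertices directly. `"sgdm"` detects the GM/CSF boundary on the MD
#' volume (which shares the probability volume's distorted space) and
#' samples the probability volume at the relocated mid-cortical point —
#' probability leaking onto the surface therefore measures residual
#' mapping error.
#'
#' @param csf_prob [scalar_volume()] with values in `[0, 1]`.
#' @param surfaces a [linked_surface_set()].
#' @param method `"nn"`, `"linear"` or `"sgdm"`.
#' @param md MD [scalar_volume()]; required for `"sgdm"`.
#' @param params an [sgdm_params()] (sgdm only).
#' @return a [vertex_map()].
#' @export
project_csf_probability <- function(csf_prob, surfaces,
                                    method = c("nn", "linear", "sgdm"),
                                    md = NULL, params = sgdm_params()) {
  if (length(method) != 1L || !method %in% c("nn", "linear", "sgdm"))
    stop("unknown mapping method: ", paste(method, collapse = "/"))
  rngv <- csf_prob$data[is.finite(csf_prob$data)]
  if (length(rngv) && (min(rngv) < -1e-6 || max(rngv) > 1 + 1e-6))
    stop("'csf_prob' must hold probabilities in [0, 1]")
  switch(method,
    nn = map_nn(csf_prob, surfaces$mid),
    linear = map_linear(csf_prob, surfaces$mid),
    sgdm = {
      if (is.null(md))
        stop("SGDM projection needs the MD volume to detect boundaries")
      map_sgdm(md, surfaces, params = params, values = csf_prob)
    })
}

#' Smooth per-vertex data on the mesh
#'
#' Heat-kernel-style smoothing by iterated graph-Laplacian diffusion with
#' uniform symmetric edge weights: `v <- v + tau * sum_j (v_j - v_i)` over
#' mesh edges. Symmetric weights make every step exactly mean-conserving
#' on a valid-everywhere map. The iteration count is calibrated from the
#' per-step variance increment (`tau * sum_j d_ij^2`, averaged over
#' vertices) so the accumulated kernel variance matches a Gaussian of the
#' requested FWHM; the fractional residual is applied as one final scaled
#' step. Invalid vertices are excluded from all averages and keep their
#' value; disconnected vertices are returned unchanged and flagged.
#'
#' @param map a [vertex_map()].
#' @param mesh the [triangle_mesh()] carrying the map.
#' @param fwhm target kernel full-width at half-maximum (mm); `0` is the
#'   identity.
#' @return a smoothed [vertex_map()]; extra element `flagged_disconnected`
#'   marks vertices with no valid neighbour.
#' @export
smooth_surface_data <- function(map, mesh, fwhm) {
  stopifnot(inherits(map, "VertexMap"), inherits(mesh, "TriangleMesh"),
            fwhm >= 0)
  if (length(map) != n_vertices(mesh))
    stop("map length does not match mesh vertex count")
  out <- map
  out$flagged_disconnected <- rep(FALSE, length(map))
  if (fwhm == 0) return(out)
  ed <- mesh_edges(mesh)
  a <- ed$a; b <- ed$b
  keep <- map$valid[a] & map$valid[b]   # diffuse among valid vertices only
  a <- a[keep]; b <- b[keep]
  deg <- tabulate(c(a, b), nbins = n_vertices(mesh))
  disconnected <- map$valid & deg == 0L
  out$flagged_disconnected <- disconnected
  if (!length(a)) return(out)
  d2 <- rowSums((mesh$vertices[a, , drop = FALSE] -
                   mesh$vertices[b, , drop = FALSE])^2)
  tau <- 0.4 / max(deg)                  # explicit-Euler stability
  # first-guess step count from the flat-space variance budget: each step
  # adds ~ tau * sum_j d_ij^2 of squared displacement, and an isotropic
  # 2-D Gaussian of variance sigma^2 has E[r^2] = 2 sigma^2
  inc_per_tau <- sum(2 * d2) / sum(deg > 0L)
  sigma2 <- (fwhm / (2 * sqrt(2 * log(2))))^2
  n_steps <- 2 * sigma2 / (tau * inc_per_tau)
  if (n_steps < 24) {                    # keep the iterated kernel
    tau <- tau * n_steps / 24            # close to Gaussian
    n_steps <- 24
  }
  step <- function(v, tau_k) {
    flux <- tau_k * (v[b] - v[a])
    v + tapply_sum(flux, a, length(v)) + tapply_sum(-flux, b, length(v))
  }
  run <- function(v, n) {
    n_full <- floor(n)
    for (i in seq_len(n_full)) v <- step(v, tau)
    if (n > n_full) v <- step(v, tau * (n - n_full))
    v
  }
  # curvature and mesh irregularity make the realised kernel narrower
  # than the flat-space budget predicts (tangential drift); calibrate the
  # step count on a probe impulse, whose squared-displacement moment is
  # measured with chord distances (~ geodesic at kernel scale)
  probe_at <- which(map$valid & deg == max(deg))[1]
  if (is.finite(probe_at)) {
    probe <- numeric(length(map$value))
    probe[probe_at] <- 1
    r2 <- rowSums((mesh$vertices -
                     matrix(mesh$vertices[probe_at, ],
                            length(probe), 3, byrow = TRUE))^2)
    for (it in 1:2) {
      m2 <- sum(run(probe, n_steps) * r2)
      if (m2 <= 0) break
      ratio <- 2 * sigma2 / m2
      if (abs(ratio - 1) < 0.02) break
      n_steps <- n_steps * ratio
    }
  }
  v <- map$value
  v[!map$valid] <- 0
  v <- run(v, n_steps)
  out$value[map$valid] <- v[map$valid]
  out
}

tapply_sum <- function(x, idx, n) {
  acc <- numeric(n)
  s <- rowsum(x, idx)
  acc[as.integer(rownames(s))] <- s[, 1]
  acc
}

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  list(a = e[, 1], b = e[, 2])
}

#' Vertex-wise paired t statistics
#'
#' Paired Student's t at each vertex across subjects: a one-sample t on
#' the within-subject differences with `n - 1` degrees of freedom and
#' two-sided p. Vertices with fewer than 3 complete pairs (both members
#' valid) are invalid. A nonzero constant difference with zero variance
#' yields an infinite statistic: `t = +-Inf`, `p = 0`, flagged
#' `degenerate`; an all-zero difference yields `t = 0`, `p = 1`.
#'
#' @param group_a,group_b lists of [vertex_map()]s (one per subject, same
#'   subjects and order in both groups), or numeric vertex-by-subject
#'   matrices.
#' @return data.frame with `t`, `p`, `q` (Benjamini-Hochberg FDR-adjusted
#'   p — a substitution for the random-field-theory correction used in
#'   surface-statistics practice), `n_pairs`, `valid`, `degenerate`.
#' @export
paired_vertexwise_t <- function(group_a, group_b) {
  ma <- as_vertex_matrix(group_a)
  mb <- as_vertex_matrix(group_b)
  if (!all(dim(ma) == dim(mb)))
    stop(sprintf("groups differ in shape: %d x %d vs %d x %d",
                 nrow(ma), ncol(ma), nrow(mb), ncol(mb)))
  if (ncol(ma) < 3L) stop("paired t needs at least 3 subjects")
  d <- ma - mb
  complete <- is.finite(ma) & is.finite(mb)
  d[!complete] <- NA_real_
  n <- rowSums(complete)
  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
  valid <- n >= 3L
  tstat <- rep(NA_real_, nrow(d))
  p <- rep(NA_real_, nrow(d))
  degenerate <- rep(FALSE, nrow(d))
  zero_var <- valid & sd_d == 0
  reg <- valid & !zero_var
  tstat[reg] <- mean_d[reg] / (sd_d[reg] / sqrt(n[reg]))
  p[reg] <- 2 * stats::pt(-abs(tstat[reg]), df = n[reg] - 1)
  tstat[zero_var & mean_d == 0] <- 0
  p[zero_var & mean_d == 0] <- 1
  deg_nz <- zero_var & mean_d != 0
  tstat[deg_nz] <- sign(mean_d[deg_nz]) * Inf
  p[deg_nz] <- 0
  degenerate[deg_nz] <- TRUE
  q <- rep(NA_real_, length(p))
  q[valid] <- stats::p.adjust(p[valid], method = "BH")
  data.frame(t = tstat, p = p, q = q, n_pairs = n, valid = valid,
             degenerate = degenerate)
}

as_vertex_matrix <- function(g) {
  if (is.matrix(g)) return(g)
  if (!is.list(g) || !length(g)) stop("expected a list of VertexMaps")
  cols <- lapply(g, function(m) {
    if (inherits(m, "VertexMap")) m$value else as.numeric(m)
  })
  if (length(unique(lengths(cols))) != 1L)
    stop("all maps must share one vertex count")
  do.call(cbind, cols)
}

#' Per-subject mapping results
#'
#' @param id subject identifier.
#' @param md named list of [vertex_map()]s of MD per method.
#' @param csf_prob named list of [vertex_map()]s of projected CSF
#'   probability per method (same method names).
#' @return list of class `SubjectResult`.
#' @export
subject_result <- function(id, md, csf_prob) {
  stopifnot(is.list(md), is.list(csf_prob),
            identical(sort(names(md)), sort(names(csf_prob))))
  nv <- unique(c(vapply(md, length, integer(1)),
                 vapply(csf_prob, length, integer(1))))
  if (length(nv) != 1L)
    stop("all maps of a subject must share one vertex count")
  structure(list(id = id, md = md, csf_prob = csf_prob),
            class = "SubjectResult")
}

#' Summarise mapping methods over subjects
#'
#' Pools valid vertices over all subjects per method and reports mean and
#' median projected CSF probability, mean MD and the SGDM fallback rate.
#'
#' @param results list of [subject_result()]s (at least one).
#' @return data.frame with one row per method: `method`, `mean_csf_prob`,
#'   `median_csf_prob`, `mean_md`, `fallback_rate`, `n_valid`.
#' @export
summarize_methods <- function(results) {
  if (!length(results)) stop("need at least one subject")
  if (inherits(results, "SubjectResult")) results <- list(results)
  methods <- names(results[[1]]$md)
  rows <- lapply(methods, function(m) {
    probs <- unlist(lapply(results, function(s) {
      x <- s$csf_prob[[m]]; x$value[x$valid]
    }))
    mds <- unlist(lapply(results, function(s) {
      x <- s$md[[m]]; x$value[x$valid]
    }))
    fb <- unlist(lapply(results, function(s) {
      x <- s$md[[m]]
      x$method == "sgdm-fallback"
    }))
    data.frame(method = m,
               mean_csf_prob = if (length(probs)) mean(probs) else NA_real_,
               median_csf_prob = if (length(probs)) stats::median(probs)
                                 else NA_real_,
               mean_md = if (length(mds)) mean(mds) else NA_real_,
               fallback_rate = mean(fb),
               n_valid = length(mds))
  })
  do.call(rbind, rows)
}
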