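#' Two-compartment model parameters
#'
#' Houses the acquisition constants (b, TE, TR), the per-tissue relaxation
#' constants (proton density rho, T1, T2 for GM and CSF) and the fixed CSF
#' diffusivity used by the partial-volume correction. The relaxation
#' defaults are common 3 T literature values; the correction depends on
#' them only through the ratio of the relaxation-weighted signals S_i(0),
#' and every one is overridable.
#'
#' @param b diffusion weighting (s/mm^2), `> 0`.
#' @param te echo time (ms), `>= 0`.
#' @param tr repetition time (ms), `> te`.
#' @param d_csf CSF diffusivity (mm^2/s).
#' @param gm,csf per-tissue relaxation: list with `rho` (arbitrary units),
#'   `t1` (ms), `t2` (ms), all strictly positive.
#' @return list of class `TwoCompartmentParams`.
#' @export
two_compartment_params <- function(b = 600, te = 60, tr = 7696,
                                   d_csf = 3.0e-3,
                                   gm = list(rho = 0.8, t1 = 1300, t2 = 80),
                                   csf = list(rho = 1.0, t1 = 4000,
                                              t2 = 2000)) {
  stopifnot(b > 0, te >= 0, tr > te, d_csf > 0)
  for (tis in list(gm, csf))
    if (any(unlist(tis[c("rho", "t1", "t2")]) <= 0))
      stop("tissue relaxation constants must be strictly positive")
  structure(list(b = b, te = te, tr = tr, d_csf = d_csf, gm = gm,
                 csf = csf), class = "TwoCompartmentParams")
}

#' Relaxation-weighted equilibrium signal S_i(0)
#'
#' Spin-echo signal of a compartment at b = 0, weighted solely by
#' relaxation: `S_i(0) = rho_i * exp(-TE/T2_i) * (1 - exp(-TR/T1_i))`.
#'
#' @param rho equilibrium proton spin density (arbitrary units), `> 0`.
#' @param t1,t2 longitudinal / transverse relaxation times (ms), `> 0`.
#' @param tr,te repetition / echo time (ms).
#' @return strictly positive signal (same arbitrary units as `rho`).
#' @export
s0_relaxation <- function(rho, t1, t2, tr, te) {
  if (any(rho <= 0) || any(t1 <= 0) || any(t2 <= 0) || any(tr <= 0) ||
      any(te < 0))
    stop("s0_relaxation: inputs must satisfy rho, T1, T2, TR > 0 and TE >= 0")
  rho * exp(-te / t2) * (1 - exp(-tr / t1))
}

#' Apparent (signal-weighted) tissue fractions
#'
#' Converts partial volume fractions into apparent signal fractions by
#' weighting each with its relaxation signal:
#' `lambda_app_i = lambda_i S_i(0) / sum_j lambda_j S_j(0)`.
#' The apparent fractions sum to 1 exactly; vertices where both input
#' fractions are zero are invalid.
#'
#' @param lambda_gm,lambda_csf per-vertex volume fractions in `[0, 1]`
#'   with `lambda_gm + lambda_csf <= 1` (a supplied WM fraction should be
#'   folded into `lambda_gm`; the model has two compartments).
#' @param params a [two_compartment_params()].
#' @return list with `lambda_app_gm`, `lambda_app_csf`, `valid`.
#' @export
apparent_fractions <- function(lambda_gm, lambda_csf, params) {
  stopifnot(inherits(params, "TwoCompartmentParams"))
  check_fraction(lambda_gm, "lambda_gm")
  check_fraction(lambda_csf, "lambda_csf")
  if (any((lambda_gm + lambda_csf) > 1 + 1e-6, na.rm = TRUE))
    stop("lambda_gm + lambda_csf exceeds 1")
  s_gm <- s0_relaxation(params$gm$rho, params$gm$t1, params$gm$t2,
                        params$tr, params$te)
  s_csf <- s0_relaxation(params$csf$rho, params$csf$t1, params$csf$t2,
                         params$tr, params$te)
  denom <- lambda_gm * s_gm + lambda_csf * s_csf
  valid <- is.finite(denom) & denom > 0
  app_gm <- ifelse(valid, lambda_gm * s_gm / denom, NA_real_)
  list(lambda_app_gm = app_gm,
       lambda_app_csf = ifelse(valid, 1 - app_gm, NA_real_),
       valid = valid)
}

check_fraction <- function(x, name) {
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    stop(sprintf("'%s' must lie in [0, 1]", name))
  invisible(TRUE)
}

#' Forward two-compartment contamination model
#'
#' Observed diffusivity when a vertex mixes GM and CSF signal:
#' `exp(-b D) = lambda_app_gm exp(-b D_gm) + lambda_app_csf exp(-b D_csf)`,
#' solved for `D`. Strictly increasing in `lambda_app_csf` whenever
#' `D_csf > D_gm`.
#'
#' @param d_gm true GM diffusivity (mm^2/s), vectorised.
#' @param lambda_app_gm,lambda_app_csf apparent signal fractions summing
#'   to 1 (see [apparent_fractions()]).
#' @param params a [two_compartment_params()].
#' @return observed diffusivity `D` (mm^2/s).
#' @export
forward_model <- function(d_gm, lambda_app_gm, lambda_app_csf, params) {
  stopifnot(inherits(params, "TwoCompartmentParams"))
  b <- params$b
  -log(lambda_app_gm * exp(-b * d_gm) +
         lambda_app_csf * exp(-b * params$d_csf)) / b
}

#' Remove CSF contamination from per-vertex MD
#'
#' Closed-form inversion of the two-compartment model:
#' `D_gm = -(1/b) ln[(exp(-b D) - lambda_app_csf exp(-b D_csf)) /
#' lambda_app_gm]`. Vertices where the log argument is nonpositive or the
#' apparent GM fraction falls below `lambda_min` are CSF-dominated (the
#' inversion is ill-conditioned as `lambda_app_gm -> 0`) and are flagged
#' invalid with a reason code rather than failing.
#'
#' @param d_obs observed MD: a [vertex_map()] or numeric vector (mm^2/s).
#' @param lambda_app_gm,lambda_app_csf apparent signal fractions.
#' @param params a [two_compartment_params()].
#' @param lambda_min smallest apparent GM fraction still inverted.
#' @return a [vertex_map()] of corrected GM diffusivity, with an extra
#'   element `reason` in
#'   `{"ok", "log_nonpositive", "gm_fraction_too_small", "input_invalid"}`.
#' @export
correct_csf <- function(d_obs, lambda_app_gm, lambda_app_csf, params,
                        lambda_min = 0.05) {
  stopifnot(inherits(params, "TwoCompartmentParams"))
  if (inherits(d_obs, "VertexMap")) {
    input_valid <- d_obs$valid
    d <- d_obs$value
  } else {
    d <- as.numeric(d_obs)
    input_valid <- is.finite(d)
  }
  b <- params$b
  reason <- rep("ok", length(d))
  reason[!input_valid] <- "input_invalid"
  small <- input_valid & (!is.finite(lambda_app_gm) |
                            lambda_app_gm < lambda_min)
  reason[small] <- "gm_fraction_too_small"
  ok <- reason == "ok"
  arg <- rep(NA_real_, length(d))
  arg[ok] <- (exp(-b * d[ok]) -
                lambda_app_csf[ok] * exp(-b * params$d_csf)) /
             lambda_app_gm[ok]
  nonpos <- ok & (!is.finite(arg) | arg <= 0)
  reason[nonpos] <- "log_nonpositive"
  ok <- reason == "ok"
  out <- rep(NA_real_, length(d))
  out[ok] <- -log(arg[ok]) / b
  res <- vertex_map(out, valid = ok, method = "csf-corrected")
  res$reason <- reason
  res
}
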