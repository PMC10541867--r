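#' Tracer moments inside the patch
#'
#' Spatial statistics of the two tracer fields inside the patch, obtained
#' from the Reynolds decomposition `p_i = <p_i> + p_i'`: the means of
#' resource and biomass, their spatial variances, and their covariance.
#' Biomass is carried in iron currency (see [bio_params()]).
#'
#' @param mean_r Resource spatial mean, umol m^-3.
#' @param mean_b Biomass spatial mean, umol m^-3 (iron currency).
#' @param var_r Resource spatial variance, (umol m^-3)^2.
#' @param var_b Biomass spatial variance, (umol m^-3)^2.
#' @param cov_rb Resource-biomass spatial covariance, (umol m^-3)^2.
#' @return An object of class `tracer_moments` (a named list).
#' @examples
#' tracer_moments(mean_r = 1, mean_b = 0.0249)
#' @export
tracer_moments <- function(mean_r, mean_b, var_r = 0, var_b = 0, cov_rb = 0) {
  x <- list(
    mean_r = mean_r, mean_b = mean_b,
    var_r = var_r, var_b = var_b, cov_rb = cov_rb
  )
  validate_moments(x)
  structure(x, class = "tracer_moments")
}

#' Mean-field state of the surrounding water
#'
#' The water outside the patch is treated as a mean-field reservoir: its
#' means and second moments are fixed in time. The defaults used in the
#' fertilization experiments set the surrounding second moments to zero
#' (well-mixed far field) and the means at the ecosystem steady state.
#'
#' @inheritParams tracer_moments
#' @return An object of class `surrounding_state` (a named list).
#' @examples
#' surrounding_state(mean_r = 0.1, mean_b = 0.0249)
#' @export
surrounding_state <- function(mean_r, mean_b, var_r = 0, var_b = 0,
                              cov_rb = 0) {
  x <- list(
    mean_r = mean_r, mean_b = mean_b,
    var_r = var_r, var_b = var_b, cov_rb = cov_rb
  )
  validate_moments(x)
  structure(x, class = "surrounding_state")
}

validate_moments <- function(x) {
  vals <- unlist(x)
  if (!all(is.finite(vals))) stop("moments must be finite", call. = FALSE)
  if (x$mean_r < 0 || x$mean_b < 0) {
    stop("tracer means must be non-negative", call. = FALSE)
  }
  if (x$var_r < 0 || x$var_b < 0) {
    stop("tracer variances must be non-negative", call. = FALSE)
  }
  # Cauchy-Schwarz, with a tiny numerical slack
  if (x$cov_rb^2 > x$var_r * x$var_b * (1 + 1e-9) + 1e-300) {
    stop("covariance violates Cauchy-Schwarz: cov^2 > var_r * var_b",
      call. = FALSE
    )
  }
  invisible(x)
}

#' Entrainment tendency of a tracer mean
#'
#' Dilution entrains surrounding water at the area growth rate `dA/dt`.
#' The patch mean relaxes toward the surrounding mean:
#' \deqn{d<p>/dt = (dA/dt / A)(<s> - <p>).}
#' Combined with the area equation this conserves tracer mass exactly:
#' `d(A <p>)/dt = (dA/dt) <s>` (the mass flux is surrounding water).
#'
#' @param p_mean Patch tracer mean, umol m^-3.
#' @param s_mean Surrounding tracer mean, umol m^-3.
#' @param A Patch area, km^2. Must be positive.
#' @param dAdt Area growth rate, km^2 day^-1. Non-negative.
#' @return Tendency of the patch mean, umol m^-3 day^-1.
#' @examples
#' entrainment_mean_tendency(1.0, 0.1, A = 100, dAdt = 10)  # -0.09
#' @export
entrainment_mean_tendency <- function(p_mean, s_mean, A, dAdt) {
  if (any(A <= 0)) stop("patch area A must be positive", call. = FALSE)
  (dAdt / A) * (s_mean - p_mean)
}

#' Entrainment tendency of a second moment
#'
#' Entrained water differs from the patch both in its fluctuation
#' statistics and in its mean. Pooling the two water bodies gives
#' \deqn{d<p_i' p_j'>/dt = (dA/dt / A)\,[(<s_i' s_j'> - <p_i' p_j'>) +
#'       (<s_i> - <p_i>)(<s_j> - <p_j>)].}
#' The production term is the product of mean contrasts: entraining water
#' with a different mean always generates variance (for `i = j` it is a
#' square), which is how dilution creates patchiness from a homogeneous
#' initial state.
#'
#' @param p_com Patch second moment `<p_i' p_j'>`, (umol m^-3)^2.
#' @param s_com Surrounding second moment, (umol m^-3)^2.
#' @param p_mean_i,p_mean_j Patch means of tracers i and j, umol m^-3.
#' @param s_mean_i,s_mean_j Surrounding means of tracers i and j, umol m^-3.
#' @param A Patch area, km^2. Must be positive.
#' @param dAdt Area growth rate, km^2 day^-1. Non-negative.
#' @return Tendency of the second moment, (umol m^-3)^2 day^-1.
#' @examples
#' # a fresh dilution front generates variance from nothing:
#' entrainment_comoment_tendency(0, 0, 1, 1, 0.1, 0.1, A = 100, dAdt = 10)
#' @export
entrainment_comoment_tendency <- function(p_com, s_com,
                                          p_mean_i, p_mean_j,
                                          s_mean_i, s_mean_j,
                                          A, dAdt) {
  if (any(A <= 0)) stop("patch area A must be positive", call. = FALSE)
  (dAdt / A) *
    ((s_com - p_com) + (s_mean_i - p_mean_i) * (s_mean_j - p_mean_j))
}

#' Internal-mixing tendency of a second moment
#'
#' Diffusion inside the patch homogenizes tracer fields: variances and
#' covariances decay exponentially at the effective rate `kappa / S^2`,
#' the diffusive rate at the scale of the patch size. Means are untouched.
#'
#' @param p_com Patch second moment, (umol m^-3)^2.
#' @param kappa Diffusivity, km^2 day^-1. Non-negative.
#' @param S Patch size, km. Must be positive.
#' @return Tendency of the second moment, (umol m^-3)^2 day^-1.
#' @examples
#' mixing_tendency(0.5, kappa = 0.1, S = 10)  # -5e-4
#' @export
mixing_tendency <- function(p_com, kappa, S) {
  if (any(S <= 0)) stop("patch size S must be positive", call. = FALSE)
  if (any(kappa < 0)) stop("kappa must be non-negative", call. = FALSE)
  -(kappa / S^2) * p_com
}
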