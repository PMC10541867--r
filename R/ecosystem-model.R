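#' Biological parameters of the resource-consumer pair
#'
#' Parameters of the idealized iron-phytoplankton dynamics: Monod uptake
#' of an inorganic resource by a planktonic consumer with linear (or,
#' optionally, quadratic) mortality, and a remineralized fraction `alpha`
#' of dead biomass returned to the resource pool. Biomass is expressed in
#' iron currency; `fe_to_c` converts mol Fe to mol C when reporting
#' carbon-based diagnostics.
#'
#' Defaults are the values used for the fertilization experiments:
#' `nu = 1.05` day^-1, `k = 2` umol m^-3, `m = 0.05` day^-1, `alpha = 0`,
#' `fe_to_c = 1e-5`.
#'
#' @param nu Maximum growth rate, day^-1. Positive.
#' @param k Half-saturation constant for uptake, umol m^-3. Positive.
#' @param m Linear mortality rate, day^-1. Non-negative.
#' @param alpha Remineralized fraction of dead biomass, in \[0, 1\].
#' @param mortality_form `"linear"` (default) or `"quadratic"`.
#' @param m_quad Quadratic mortality coefficient m', (umol m^-3)^-1 day^-1.
#'   Required when `mortality_form = "quadratic"`.
#' @param fe_to_c Fe:C molar ratio, dimensionless.
#' @return An object of class `bio_params`.
#' @examples
#' bio_params()
#' bio_params(mortality_form = "quadratic", m_quad = 0.05)
#' @export
bio_params <- function(nu = 1.05, k = 2, m = 0.05, alpha = 0,
                       mortality_form = c("linear", "quadratic"),
                       m_quad = NULL, fe_to_c = 1e-5) {
  mortality_form <- match.arg(mortality_form)
  stopifnot(is.numeric(nu), is.numeric(k), is.numeric(m), is.numeric(alpha))
  if (nu <= 0) stop("nu must be positive", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (fe_to_c <= 0) stop("fe_to_c must be positive", call. = FALSE)
  if (mortality_form == "quadratic") {
    if (is.null(m_quad) || !is.numeric(m_quad) || m_quad < 0) {
      stop("quadratic mortality requires a non-negative m_quad", call. = FALSE)
    }
  }
  structure(
    list(
      nu = nu, k = k, m = m, alpha = alpha,
      mortality_form = mortality_form, m_quad = m_quad, fe_to_c = fe_to_c
    ),
    class = "bio_params"
  )
}

#' @export
format.bio_params <- function(x, ...) {
  mort <- if (x$mortality_form == "linear") {
    sprintf("m = %.4g/day", x$m)
  } else {
    sprintf("m' = %.4g/(umol/m^3)/day (quadratic)", x$m_quad)
  }
  sprintf(
    "<bio_params> nu = %.4g/day, k = %.4g umol/m^3, %s, alpha = %.4g, Fe:C = %.3g",
    x$nu, x$k, mort, x$alpha, x$fe_to_c
  )
}

#' @export
print.bio_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Resource level at which growth balances linear mortality
#'
#' Setting Monod growth equal to linear mortality,
#' `nu r / (r + k) = m`, gives the steady-state resource
#' \deqn{r^* = m k / (\nu - m),}
#' which exists only when `nu > m`. With the default parameters
#' (`nu = 1.05`, `m = 0.05`, `k = 2`) this is 0.1 umol m^-3 - the
#' surrounding iron concentration used in the fertilization runs, so the
#' far field is at ecological equilibrium.
#'
#' @param params A [bio_params()] object with linear mortality.
#' @return Steady-state resource concentration, umol m^-3.
#' @examples
#' steady_state_resource(bio_params())  # 0.1
#' @export
steady_state_resource <- function(params) {
  stopifnot(inherits(params, "bio_params"))
  if (params$mortality_form != "linear") {
    stop("steady_state_resource() is defined for linear mortality",
      call. = FALSE
    )
  }
  if (params$nu <= params$m) {
    stop("no steady state: growth rate nu must exceed mortality m",
      call. = FALSE
    )
  }
  params$m * params$k / (params$nu - params$m)
}

#' Moment-closed reaction tendencies
#'
#' Right-hand sides of the closed moment equations for the
#' resource-consumer pair. Writing `r = <p_r>`, `b = <p_b>` and the Monod
#' factor `G = nu r / (r + k)`, the mean equations are the mean-field
#' kinetics plus second-moment corrections arising from the curvature of
#' the Monod function:
#' \deqn{d r/dt = -G b + \nu k\, b\, var_r/(r+k)^3 - \nu k\, cov/(r+k)^2
#'   + \alpha m b,}
#' \deqn{d b/dt = +G b - \nu k\, b\, var_r/(r+k)^3 + \nu k\, cov/(r+k)^2
#'   - m b,}
#' and the second-moment equations follow from the Reynolds decomposition
#' truncated at second order (third central moments dropped). A positive
#' resource-biomass covariance raises the realized growth above its
#' mean-field value; resource variance lowers it.
#'
#' With `alpha = 1` the mean tendencies cancel, so reactions conserve
#' `<p_r> + <p_b>`; in general they remove biomass at the export rate
#' `m (1 - alpha) b`.
#'
#' @param mom A [tracer_moments()] object.
#' @param params A [bio_params()] object. Dispatches on `mortality_form`.
#' @return Named numeric vector of tendencies
#'   `c(mean_r, mean_b, var_r, var_b, cov_rb)` in (umol m^-3) day^-1 and
#'   (umol m^-3)^2 day^-1.
#' @examples
#' mom <- tracer_moments(mean_r = 1, mean_b = 0.0249, cov_rb = 0)
#' reaction_tendencies(mom, bio_params())
#' @export
reaction_tendencies <- function(mom, params) {
  stopifnot(inherits(mom, "tracer_moments"), inherits(params, "bio_params"))
  if (params$mortality_form == "quadratic") {
    return(quadratic_mortality_tendencies(mom, params))
  }
  reaction_rhs_linear(
    mom$mean_r, mom$mean_b, mom$var_r, mom$var_b, mom$cov_rb,
    params$nu, params$k, params$m, params$alpha
  )
}

# Closed tendencies with linear mortality; scalar hot path shared with the
# integrator.
reaction_rhs_linear <- function(r, b, vr, vb, cv, nu, k, m, alpha) {
  rk <- r + k
  G <- nu * r / rk # Monod growth factor
  Q <- nu * k / rk^2 # covariance sensitivity of uptake
  C3 <- nu * k / rk^3 # variance (curvature) sensitivity
  uptake <- G * b - C3 * b * vr + Q * cv
  c(
    mean_r = -uptake + alpha * m * b,
    mean_b = uptake - m * b,
    var_r  = -2 * Q * b * vr - 2 * G * cv + 2 * alpha * m * cv,
    var_b  = 2 * G * vb + 2 * Q * b * cv - 2 * m * vb,
    cov_rb = G * (cv - vb) + Q * b * (vr - cv) + m * (alpha * vb - cv)
  )
}

#' Moment-closed tendencies with quadratic mortality
#'
#' Variant of [reaction_tendencies()] in which the linear loss `m p_b` is
#' replaced by `m' p_b^2`, an implicit stand-in for grazing pressure that
#' grows with prey density. The mean loss uses the exact identity
#' `<p_b^2> = <p_b>^2 + var_b`; the second-moment loss terms use the same
#' second-order truncation as the growth terms (third central moments
#' dropped): `4 m' b var_b` for the biomass variance, `2 m' b cov` for the
#' covariance, with the remineralized fractions `alpha m' (b^2 + var_b)`
#' and `2 alpha m' b cov` returned to the resource mean and to the
#' resource variance's covariance coupling.
#'
#' @inheritParams reaction_tendencies
#' @return Same shape as [reaction_tendencies()].
#' @examples
#' qp <- bio_params(mortality_form = "quadratic", m_quad = 0.05)
#' quadratic_mortality_tendencies(
#'   tracer_moments(1, 1, var_b = 0.5), qp
#' )
#' @export
quadratic_mortality_tendencies <- function(mom, params) {
  stopifnot(inherits(mom, "tracer_moments"), inherits(params, "bio_params"))
  if (params$mortality_form != "quadratic") {
    stop("params must have mortality_form = \"quadratic\"", call. = FALSE)
  }
  r <- mom$mean_r
  b <- mom$mean_b
  vr <- mom$var_r
  vb <- mom$var_b
  cv <- mom$cov_rb
  nu <- params$nu
  k <- params$k
  mq <- params$m_quad
  alpha <- params$alpha

  rk <- r + k
  G <- nu * r / rk
  Q <- nu * k / rk^2
  C3 <- nu * k / rk^3
  uptake <- G * b - C3 * b * vr + Q * cv
  loss_mean <- mq * (b^2 + vb) # exact: <b^2> = b^2 + var_b
  c(
    mean_r = -uptake + alpha * loss_mean,
    mean_b = uptake - loss_mean,
    var_r  = -2 * Q * b * vr - 2 * G * cv + 2 * alpha * mq * b * cv,
    var_b  = 2 * G * vb + 2 * Q * b * cv - 4 * mq * b * vb,
    cov_rb = G * (cv - vb) + Q * b * (vr - cv) +
      mq * b * (2 * alpha * vb - 2 * cv)
  )
}
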