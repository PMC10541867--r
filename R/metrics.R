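#' Unit conversion for carbon-based diagnostics
#'
#' Converts the raw biomass-anomaly integral (umol Fe m^-3 x km^2, i.e. a
#' concentration times an area) into megagrams of carbon. The chain is:
#' multiply by the patch thickness `h` (m) and by 1e6 m^2/km^2 to get
#' umol Fe; times 1e-6 mol/umol gives mol Fe; dividing by the Fe:C molar
#' ratio gives mol C; times 12 g/mol and 1e-6 Mg/g gives Mg C.
#'
#' @param thickness Patch thickness, m.
#' @param fe_to_c Fe:C molar ratio, dimensionless.
#' @param carbon_molar_mass Molar mass of carbon, g/mol. Default 12.
#' @return An object of class `unit_conversion`.
#' @examples
#' conv <- unit_conversion(thickness = 10, fe_to_c = 1e-5)
#' # 1 umol Fe m^-3 over 1 km^2: 10 mol Fe -> 1e6 mol C -> 12 Mg C
#' fe_km2_to_MgC(1, conv)
#' @export
unit_conversion <- function(thickness = 10, fe_to_c = 1e-5,
                            carbon_molar_mass = 12) {
  stopifnot(thickness > 0, fe_to_c > 0, carbon_molar_mass > 0)
  structure(
    list(
      thickness = thickness, fe_to_c = fe_to_c,
      carbon_molar_mass = carbon_molar_mass
    ),
    class = "unit_conversion"
  )
}

#' Convert umol Fe m^-3 km^2 to Mg C
#'
#' @param x Quantity in umol Fe m^-3 x km^2.
#' @param conv A [unit_conversion()].
#' @return The same quantity in Mg C.
#' @rdname unit_conversion
#' @export
fe_km2_to_MgC <- function(x, conv) {
  stopifnot(inherits(conv, "unit_conversion"))
  # umol/m^3 * km^2 -> umol: x h [m] x 1e6 [m^2/km^2]; -> mol: x 1e-6;
  # mol Fe -> mol C: / (Fe:C); -> g: x 12; -> Mg: x 1e-6
  x * conv$thickness * 1e6 * 1e-6 / conv$fe_to_c *
    conv$carbon_molar_mass * 1e-6
}

trajectory_config <- function(traj) {
  cfg <- attr(traj, "config")
  if (is.null(cfg)) {
    stop("trajectory carries no config; pass the relevant arguments explicitly",
      call. = FALSE
    )
  }
  cfg
}

check_trajectory <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) < 2) {
    stop("need a trajectory with at least two time points", call. = FALSE)
  }
  invisible(traj)
}

# Trapezoidal quadrature on an (ordered) time grid.
trapz <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

#' Lagrangian biomass anomaly (LBA)
#'
#' Time-averaged, area-weighted biomass excess of the patch over its
#' surroundings:
#' \deqn{LBA = \frac{1}{\tau}\int_0^\tau A(t)\,(\langle p_b\rangle -
#'   \langle s_b\rangle)\, dt,}
#' converted to Mg C through the patch thickness and the Fe:C ratio. At
#' each instant `A (p_b - s_b)` is the biomass the patch holds beyond an
#' equal area of surrounding water, so a positive LBA means the fertilized
#' patch out-produced its surroundings on average; it is also a proxy for
#' export, the mean export-rate anomaly being `m (1 - alpha) LBA`.
#'
#' @param traj A `patch_trajectory` from [run_simulation()].
#' @param s_b Surrounding biomass, umol m^-3. Defaults to the value in the
#'   trajectory's config.
#' @param conv A [unit_conversion()]. Defaults to the trajectory's
#'   thickness and Fe:C.
#' @return LBA in Mg C (a single number).
#' @examples
#' traj <- run_simulation(sim_config(tau = 10))
#' lagrangian_biomass_anomaly(traj)
#' @export
lagrangian_biomass_anomaly <- function(traj, s_b = NULL, conv = NULL) {
  check_trajectory(traj)
  if (is.null(s_b) || is.null(conv)) {
    cfg <- trajectory_config(traj)
    if (is.null(s_b)) s_b <- cfg$surrounding$mean_b
    if (is.null(conv)) {
      conv <- unit_conversion(
        thickness = cfg$thickness, fe_to_c = cfg$bio$fe_to_c
      )
    }
  }
  tau <- traj$time_day[nrow(traj)]
  raw <- trapz(traj$time_day, traj$A_km2 * (traj$mean_b - s_b)) / tau
  fe_km2_to_MgC(raw, conv)
}

#' Mean export-rate anomaly implied by an LBA
#'
#' Under linear mortality a fraction `1 - alpha` of dead biomass leaves
#' the system, so the time-mean export-rate anomaly is `m (1 - alpha)`
#' times the Lagrangian biomass anomaly.
#'
#' @param lba LBA in Mg C.
#' @param params A [bio_params()] with linear mortality.
#' @return Export-rate anomaly, Mg C day^-1.
#' @examples
#' export_rate_anomaly(12, bio_params())  # 0.6
#' @export
export_rate_anomaly <- function(lba, params) {
  stopifnot(inherits(params, "bio_params"))
  if (params$mortality_form != "linear") {
    stop("export_rate_anomaly() assumes linear mortality", call. = FALSE)
  }
  params$m * (1 - params$alpha) * lba
}

#' Average dilution factor of a trajectory
#'
#' Ratio of the time-mean patch area to its initial value,
#' `(1/tau int A dt) / A(0)`. Equals 1 exactly for a non-diffusing patch
#' and exceeds 1 whenever surrounding water is entrained.
#'
#' @param traj A `patch_trajectory`.
#' @return Dimensionless dilution factor.
#' @examples
#' dilution_factor(run_simulation(sim_config(tau = 10)))
#' @export
dilution_factor <- function(traj) {
  check_trajectory(traj)
  tau <- traj$time_day[nrow(traj)]
  (trapz(traj$time_day, traj$A_km2) / tau) / traj$A_km2[1]
}

#' Time-integrated heterogeneity contribution to biomass growth
#'
#' Integrates the second-moment terms of the closed mean-biomass equation
#' over the run:
#' \deqn{\int_0^\tau \left[-\nu k \frac{\langle p_b\rangle\,var_r}
#'   {(\langle p_r\rangle + k)^3} + \nu k \frac{cov_{rb}}
#'   {(\langle p_r\rangle + k)^2}\right] dt.}
#' This is the cumulative biomass change (umol m^-3) attributable to
#' within-patch heterogeneity: positive when covariance-enhanced growth
#' outweighs the variance penalty, zero identically for a well-mixed run.
#'
#' @param traj A `patch_trajectory`.
#' @param params A [bio_params()]. Defaults to the trajectory's config.
#' @return Time-integrated contribution, umol m^-3.
#' @examples
#' heterogeneity_contribution(run_simulation(soiree_config(tau = 10)))
#' @export
heterogeneity_contribution <- function(traj, params = NULL) {
  check_trajectory(traj)
  if (is.null(params)) params <- trajectory_config(traj)$bio
  stopifnot(inherits(params, "bio_params"))
  rk <- traj$mean_r + params$k
  rate <- -params$nu * params$k * traj$mean_b * traj$var_r / rk^3 +
    params$nu * params$k * traj$cov_rb / rk^2
  trapz(traj$time_day, rate)
}
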