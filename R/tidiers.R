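#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a patch trajectory into long format
#'
#' @param x A `patch_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_day`, `variable`, `value`.
#' @export
tidy.patch_trajectory <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = -"time_day",
    names_to = "variable", values_to = "value"
  )
}

#' One-row summary of a patch trajectory
#'
#' Reports the bloom peak (day, biomass, ratio to the surrounding), the
#' Lagrangian biomass anomaly and implied mean export-rate anomaly, the
#' average dilution factor, the time-integrated heterogeneity contribution
#' to growth, and how often the positivity guard fired.
#'
#' @param x A `patch_trajectory` produced by [run_simulation()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @examples
#' glance(run_simulation(soiree_config(tau = 20)))
#' @export
glance.patch_trajectory <- function(x, ...) {
  cfg <- trajectory_config(x)
  peak <- which.max(x$mean_b)
  lba <- lagrangian_biomass_anomaly(x)
  export <- if (cfg$bio$mortality_form == "linear") {
    export_rate_anomaly(lba, cfg$bio)
  } else {
    NA_real_
  }
  tibble::tibble(
    mode = cfg$mode,
    peak_day = x$time_day[peak],
    peak_mean_b = x$mean_b[peak],
    peak_ratio = x$mean_b[peak] / cfg$surrounding$mean_b,
    lba_MgC = lba,
    export_MgC_per_day = export,
    dilution_factor = dilution_factor(x),
    heterogeneity_contribution = heterogeneity_contribution(x),
    n_clamped = attr(x, "n_clamped") %||% NA_integer_
  )
}

#' Summarize a strain-by-diffusion ensemble
#'
#' When both modes are present, pairs the members at matched
#' `(gamma0, kappa0)` and reports the grid maxima per mode and the largest
#' percent excess of heterogeneous over well-mixed LBA.
#'
#' @param x A `patch_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.patch_ensemble <- function(x, ...) {
  wm <- dplyr::filter(x, .data$mode == "well_mixed")
  het <- dplyr::filter(x, .data$mode == "heterogeneous")
  out <- tibble::tibble(
    n_members = nrow(x),
    n_failed = sum(!is.na(x$error)),
    max_lba_well_mixed = if (nrow(wm)) max(wm$lba_MgC, na.rm = TRUE) else NA_real_,
    max_lba_heterogeneous = if (nrow(het)) max(het$lba_MgC, na.rm = TRUE) else NA_real_
  )
  out$max_excess_pct <- if (nrow(wm) && nrow(het)) {
    paired <- dplyr::inner_join(
      dplyr::select(wm, "gamma0", "kappa0", wm_lba = "lba_MgC"),
      dplyr::select(het, "gamma0", "kappa0", het_lba = "lba_MgC"),
      by = c("gamma0", "kappa0")
    )
    max(100 * (paired$het_lba - paired$wm_lba) / paired$wm_lba, na.rm = TRUE)
  } else {
    NA_real_
  }
  out
}

#' Plot a patch trajectory
#'
#' Four-panel diagnostic of a run: ellipse half-axes, tracer means,
#' variances, and the resource-biomass covariance against time.
#'
#' @param object A `patch_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patch_trajectory <- function(object, ...) {
  panels <- dplyr::bind_rows(
    tibble::tibble(
      time_day = rep(object$time_day, 2),
      panel = "patch axes [km]",
      series = rep(c("W", "L"), each = nrow(object)),
      value = c(object$W_km, object$L_km)
    ),
    tibble::tibble(
      time_day = rep(object$time_day, 2),
      panel = "means [umol/m^3]",
      series = rep(c("resource", "biomass"), each = nrow(object)),
      value = c(object$mean_r, object$mean_b)
    ),
    tibble::tibble(
      time_day = rep(object$time_day, 2),
      panel = "variances [(umol/m^3)^2]",
      series = rep(c("resource", "biomass"), each = nrow(object)),
      value = c(object$var_r, object$var_b)
    ),
    tibble::tibble(
      time_day = object$time_day,
      panel = "covariance [(umol/m^3)^2]",
      series = "resource-biomass",
      value = object$cov_rb
    )
  )
  ggplot2::ggplot(
    panels,
    ggplot2::aes(x = .data$time_day, y = .data$value, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time [day]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble result
#'
#' `type = "surface"` draws the LBA over the strain-diffusion plane, one
#' facet per mode; `type = "dilution"` plots LBA against the average
#' dilution factor, coloured by mode.
#'
#' @param object A `patch_ensemble`.
#' @param type `"surface"` or `"dilution"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patch_ensemble <- function(object, type = c("surface", "dilution"),
                                    ...) {
  type <- match.arg(type)
  if (type == "surface") {
    ggplot2::ggplot(
      object,
      ggplot2::aes(x = .data$gamma0, y = .data$kappa0, fill = .data$lba_MgC)
    ) +
      ggplot2::geom_tile() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::facet_wrap(~mode) +
      ggplot2::labs(
        x = "initial strain [1/day]", y = "initial diffusion [km^2/day]",
        fill = "LBA [Mg C]"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      object,
      ggplot2::aes(
        x = .data$dilution_factor, y = .data$lba_MgC, colour = .data$mode
      )
    ) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(
        x = "average dilution factor", y = "LBA [Mg C]", colour = NULL
      ) +
      ggplot2::theme_minimal()
  }
}
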