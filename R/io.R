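#' Read a simulation configuration from a flat key/value file
#'
#' The file is YAML-compatible flat `key: value` text. Recognized keys
#' (all optional; defaults are the fertilization-experiment values):
#' `W0`, `L0` (km), `thickness` (m), `gamma0`, `kappa0`, `S0`,
#' `strain_exponent`, `kappa_exponent`, `nu`, `k`, `m`, `alpha`,
#' `mortality_form`, `m_quad`, `fe_to_c`, `patch_r`, `patch_b`,
#' `surround_r`, `surround_b`, `tau`, `dt`, `mode`. Unknown keys are an
#' error (typos should not silently fall back to defaults).
#'
#' @param path Path to the config file.
#' @return A [sim_config()].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("gamma0: 0.2", "kappa0: 0.3", "tau: 10"), f)
#' read_sim_config(f)
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(
    "W0", "L0", "thickness", "gamma0", "kappa0", "S0",
    "strain_exponent", "kappa_exponent",
    "nu", "k", "m", "alpha", "mortality_form", "m_quad", "fe_to_c",
    "patch_r", "patch_b", "surround_r", "surround_b",
    "tau", "dt", "mode"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(
      "unknown config keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  get <- function(key, default) raw[[key]] %||% default

  shape <- patch_shape(get("W0", 5), get("L0", 5))
  bio <- bio_params(
    nu = get("nu", 1.05), k = get("k", 2), m = get("m", 0.05),
    alpha = get("alpha", 0),
    mortality_form = get("mortality_form", "linear"),
    m_quad = raw[["m_quad"]],
    fe_to_c = get("fe_to_c", 1e-5)
  )
  s_r_default <- if (bio$mortality_form == "linear") {
    steady_state_resource(bio)
  } else {
    0.1
  }
  surrounding <- surrounding_state(
    mean_r = get("surround_r", s_r_default),
    mean_b = get("surround_b", 0.0249)
  )
  initial <- tracer_moments(
    mean_r = get("patch_r", 1.0),
    mean_b = get("patch_b", surrounding$mean_b)
  )
  sim_config(
    shape = shape,
    forcing = forcing_laws(
      gamma0 = get("gamma0", 0.12), kappa0 = get("kappa0", 0.1),
      S0 = get("S0", shape$S),
      strain_exponent = get("strain_exponent", -2 / 3),
      kappa_exponent = get("kappa_exponent", 1)
    ),
    bio = bio, surrounding = surrounding, initial = initial,
    tau = get("tau", 30), dt = get("dt", 0.01),
    thickness = get("thickness", 10),
    mode = get("mode", "heterogeneous")
  )
}

#' Write a trajectory and its run summary
#'
#' Writes `<prefix>_trajectory.csv` (full double precision, columns as in
#' [run_simulation()]) and `<prefix>_summary.json` with the run parameters
#' and the [glance()] diagnostics.
#'
#' @param traj A `patch_trajectory`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(traj, prefix) {
  check_trajectory(traj)
  cfg <- trajectory_config(traj)
  csv <- paste0(prefix, "_trajectory.csv")
  utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  summary <- c(
    list(
      mode = cfg$mode,
      gamma0 = cfg$forcing$gamma0, kappa0 = cfg$forcing$kappa0,
      S0 = cfg$forcing$S0,
      nu = cfg$bio$nu, k = cfg$bio$k, m = cfg$bio$m, alpha = cfg$bio$alpha,
      fe_to_c = cfg$bio$fe_to_c,
      tau = cfg$tau, dt = cfg$dt, thickness = cfg$thickness
    ),
    as.list(glance(traj))
  )
  json <- paste0(prefix, "_summary.json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Write an ensemble grid as long-format CSV
#'
#' Columns: `gamma0`, `kappa0`, `mode`, `LBA_MgC`, `dilution_factor`.
#'
#' @param ens A `patch_ensemble`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "patch_ensemble"))
  out <- data.frame(
    gamma0 = ens$gamma0, kappa0 = ens$kappa0, mode = ens$mode,
    LBA_MgC = ens$lba_MgC, dilution_factor = ens$dilution_factor
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
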