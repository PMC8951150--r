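# Configuration-driven scenario runner and synthetic-trace generator.
#
# A scenario config is a plain named list (or a YAML/JSON file with the same
# structure):
#
#   model: "neutral" | "weak_acid"
#   geometry: {ro_nm, h_nm, aL_dm2, cL_M, VT_dm3}
#   solute:   neutral   -> {KP, kloi}
#             weak_acid -> {KPSH, KPSD, pKaSw, kloiSH}
#   environment: {pHo0, pHi0, KaP, PT_M, KaB, BT_M}   (weak acids only)
#   ST_M: total solute concentration w.r.t. VT
#   sweep: {axis: "ro"|"KP"|"KPSH"|"pKaSw"|"PT", values: [...]}
#   radius: barrier-radius convention for the estimators
#
# Units are spelled out in the key names where ambiguity is possible.

.sweep_axes <- c("ro", "KP", "KPSH", "pKaSw", "PT")

#' Read a scenario configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.json` -> JSON,
#'   anything else -> YAML, of which JSON is a subset anyway).
#' @return The configuration as a named list.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    .stop_permkin(paste0("config file not found: ", path),
                  "permkin_config_error")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

.config_geometry <- function(config) {
  g <- config$geometry
  if (is.null(g) || is.null(g$ro_nm))
    .stop_permkin("config$geometry$ro_nm is required", "permkin_config_error")
  vesicle_geometry(ro_nm = g$ro_nm,
                   h_nm = g$h_nm %||% 3.95,
                   aL_dm2 = g$aL_dm2 %||% 6.4e-17,
                   cL_M = g$cL_M %||% 1e-3,
                   VT_dm3 = g$VT_dm3 %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_one <- function(model, geom, solute, environment, nST, radius) {
  if (model == "neutral") {
    params <- neutral_params(KP = solute$KP %||% 1,
                             kloi = solute$kloi %||% 1, geom = geom)
    sim <- simulate_neutral(geom, params, nST)
  } else {
    KPSH <- solute$KPSH %||% 1
    # KPSD may be tied to KPSH (e.g. 0.1*KPSH along a lipophilicity sweep)
    if (!is.null(solute$KPSD_ratio)) solute$KPSD <- solute$KPSD_ratio * KPSH
    params <- weak_acid_params(KPSH = KPSH,
                               KPSD = solute$KPSD %||% KPSH,
                               pKaSw = solute$pKaSw %||% 7,
                               kloiSH = solute$kloiSH %||% 1, geom = geom)
    env <- proton_environment(pHo0 = environment$pHo0 %||% 7,
                              pHi0 = environment$pHi0 %||% 7,
                              KaP = environment$KaP %||% 1e-7,
                              PT = environment$PT_M %||% 0,
                              KaB = environment$KaB %||% 1e-7,
                              BT = environment$BT_M %||% 0.01)
    sim <- simulate_weak_acid(geom, params, env, nST)
  }
  est <- estimate_permeability(sim, radius = radius)
  data.frame(beta = est$beta, Papp = est$Papp, Pappr = est$Pappr,
             PapprV = est$PapprV, Pappw = est$Pappw,
             Pappw_star = est$Pappw_star, Pobs = est$Pobs,
             P_intrinsic = est$P_intrinsic,
             nSA_inf_frac = est$nSA_inf / est$nSD_0, dpHi = est$dpHi)
}

#' Run a sweep scenario
#'
#' Simulates the configured system at every value of the sweep axis and
#' returns one row per value with the fitted rate constant, every
#' permeability estimator, the equilibrium transfer fraction and (for weak
#' acids) the equilibrium pH gradient.  Deterministic: no randomness is
#' involved in the model, so identical configs give identical tables.
#'
#' @param config Named list or path to a YAML/JSON file (see
#'   [read_scenario_config()]).
#' @return A data.frame with one row per sweep value (zero rows for an
#'   empty sweep), with the sweep axis as its first column.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- read_scenario_config(config)
  model <- match.arg(config$model %||% "neutral", c("neutral", "weak_acid"))
  sweep <- config$sweep
  axis <- sweep$axis %||% "ro"
  if (!axis %in% .sweep_axes)
    .stop_permkin(paste0("unknown sweep axis '", axis, "'; valid: ",
                         paste(.sweep_axes, collapse = ", ")),
                  "permkin_config_error")
  values <- sweep$values
  nST_of <- function(geom) (config$ST_M %||% 1e-6) * geom$VT
  radius <- config$radius %||% "interleaflet"
  rows <- lapply(values, function(v) {
    cfg <- config
    if (axis == "ro") cfg$geometry$ro_nm <- v
    else if (axis %in% c("KP", "KPSH", "pKaSw")) cfg$solute[[axis]] <- v
    else if (axis == "PT") cfg$environment$PT_M <- v
    geom <- .config_geometry(cfg)
    row <- .run_one(model, geom, cfg$solute %||% list(),
                    cfg$environment %||% list(), nST_of(geom), radius)
    cbind(stats::setNames(data.frame(v), axis), row)
  })
  if (length(rows) == 0) {
    empty <- stats::setNames(
      data.frame(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
                 numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
                 numeric(0)),
      c(axis, "beta", "Papp", "Pappr", "PapprV", "Pappw", "Pappw_star",
        "Pobs", "P_intrinsic", "nSA_inf_frac", "dpHi"))
    return(empty)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic mono-exponential trace with Gaussian noise
#'
#' Stand-in for an experimental influx (or probe-signal) trace:
#' `y(t) = amplitude * (1 - exp(-beta t))` plus i.i.d. Gaussian noise.
#' Reproducible from the seed.
#'
#' @param beta Ground-truth rate constant (s^-1).
#' @param amplitude Plateau value.
#' @param n_points Number of points (uniform grid over `[0, t_max]`).
#' @param noise_sd Standard deviation of the additive noise (same units as
#'   `amplitude`).
#' @param seed Integer RNG seed.
#' @param t_max End of the time grid; default `10/beta`.
#' @return data.frame with columns `t`, `y_true`, `y`; attributes `beta`,
#'   `amplitude`, `noise_sd`, `seed`.
#' @export
generate_fixture <- function(beta, amplitude, n_points = 200, noise_sd = 0,
                             seed = 1, t_max = 10 / beta) {
  .check_pos(beta, amplitude, n_points)
  if (noise_sd < 0)
    .stop_permkin("noise_sd must be non-negative", "permkin_config_error")
  t <- seq(0, t_max, length.out = n_points)
  y_true <- amplitude * (1 - exp(-beta * t))
  noise <- if (noise_sd > 0) {
    rng <- .with_isolated_seed(seed)
    on.exit(rng(), add = TRUE)
    stats::rnorm(n_points, sd = noise_sd)
  } else rep(0, n_points)
  structure(data.frame(t = t, y_true = y_true, y = y_true + noise),
            beta = beta, amplitude = amplitude, noise_sd = noise_sd,
            seed = seed)
}

# save/restore .Random.seed around a seeded draw so fixtures do not disturb
# the caller's RNG stream; returns the restore function
.with_isolated_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reference sweep scenarios
#'
#' Named, ready-to-run configurations for the characteristic behaviours of
#' the model: size invariance of the general estimator for non-lipophilic
#' solutes, saturation with lipophilicity, pH-gradient effects for weak
#' acids, and the probe buffer-capacity series.
#'
#' @return Named list of scenario configurations for [run_scenario()].
#' @export
reference_scenarios <- function() {
  base_geom <- list(ro_nm = 100, h_nm = 3.95, aL_dm2 = 6.4e-17,
                    cL_M = 1e-3, VT_dm3 = 1)
  list(
    size_sweep_nonlipophilic = list(
      model = "neutral", geometry = base_geom,
      solute = list(KP = 1, kloi = 1),
      sweep = list(axis = "ro", values = c(25, 50, 100, 500, 2500, 5000))),
    size_sweep_lipophilic = list(
      model = "neutral", geometry = base_geom,
      solute = list(KP = 1e4, kloi = 1),
      sweep = list(axis = "ro", values = c(25, 50, 100, 500, 2500, 5000))),
    lipophilicity_sweep = list(
      model = "neutral", geometry = base_geom,
      solute = list(KP = 1, kloi = 1),
      sweep = list(axis = "KP", values = c(1, 1e2, 1e3, 5e3, 1e4))),
    weak_acid_pka_sweep = list(
      model = "weak_acid", geometry = base_geom,
      solute = list(KPSH = 1, KPSD = 1, kloiSH = 1),
      environment = list(pHo0 = 7, pHi0 = 7, KaP = 1e-7, PT_M = 1e-5),
      sweep = list(axis = "pKaSw", values = c(4, 5, 6, 7, 8, 9, 10))),
    weak_acid_probe_sweep = list(
      model = "weak_acid", geometry = base_geom,
      solute = list(KPSH = 1, KPSD = 1, pKaSw = 7, kloiSH = 1),
      environment = list(pHo0 = 7, pHi0 = 7, KaP = 1e-7, PT_M = 0),
      sweep = list(axis = "PT", values = c(0, 1e-6, 1e-5, 1e-4))),
    weak_acid_lipophilicity_sweep = list(
      model = "weak_acid", geometry = base_geom,
      solute = list(KPSH = 100, KPSD_ratio = 0.1, pKaSw = 7, kloiSH = 1),
      environment = list(pHo0 = 7, pHi0 = 7, KaP = 1e-7, PT_M = 1e-5),
      sweep = list(axis = "KPSH", values = c(1e2, 1e3, 1e4)))
  )
}
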