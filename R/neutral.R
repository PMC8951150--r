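# Model for non-ionisable solutes: aqueous/leaflet partition at
# quasi-equilibrium on both sides of the barrier, flip-flop across the
# bilayer midplane as the single slow step.  The dynamics reduce to one
# linear ODE in the aggregated amount of solute in the inner compartments.

#' Kinetic parameters of a non-ionisable solute
#'
#' @param KP Water-to-leaflet partition coefficient (concentration ratio,
#'   dimensionless).
#' @param kloi Outer-to-inner flip-flop rate constant (s^-1).
#' @param klio Inner-to-outer flip-flop rate constant (s^-1).  If `NULL`
#'   (default) it is set to `kloi * Vlo / Vli` from `geom`, the detailed-
#'   balance choice that equalises leaflet concentrations at equilibrium.
#' @param geom [vesicle_geometry()], required only when `klio` is `NULL`.
#' @return Object of class `neutral_params` with fields `KP`, `kloi`, `klio`.
#' @export
neutral_params <- function(KP, kloi = 1, klio = NULL, geom = NULL) {
  if (!is.finite(KP) || KP < 0)
    .stop_permkin("KP must be a non-negative number", "permkin_params_error")
  if (kloi <= 0)
    .stop_permkin("kloi must be positive", "permkin_params_error")
  if (is.null(klio)) {
    if (is.null(geom))
      .stop_permkin("provide either klio or geom (klio defaults to kloi*Vlo/Vli)",
                    "permkin_params_error")
    klio <- kloi * geom$Vlo / geom$Vli
  }
  if (klio <= 0)
    .stop_permkin("klio must be positive", "permkin_params_error")
  structure(list(KP = KP, kloi = kloi, klio = klio), class = "neutral_params")
}

#' @export
print.neutral_params <- function(x, ...) {
  cat(sprintf("Non-ionisable solute: KP = %.4g, kloi = %.4g s^-1, klio = %.4g s^-1\n",
              x$KP, x$kloi, x$klio))
  invisible(x)
}

# fraction of the solute of a compartment group that sits in its leaflet,
# for leaflet volume Vl and aqueous volume Vw at partition coefficient KP
.leaflet_fraction <- function(KP, Vl, Vw) KP * Vl / (Vw + KP * Vl)

#' Per-compartment amounts of a non-ionisable solute
#'
#' Splits the total solute between the four compartments given the amount in
#' the inner compartment group, using the quasi-equilibrium partition within
#' each group: leaflet concentration = KP x adjacent aqueous concentration.
#'
#' @param nSi Amount of solute in the inner compartments (mol); may be a
#'   vector.
#' @param nST Total amount of solute (mol).
#' @param geom [vesicle_geometry()].
#' @param params [neutral_params()].
#' @return A data.frame with columns `nSwo`, `nSlo`, `nSli`, `nSwi` (mol).
#' @export
speciate_neutral <- function(nSi, nST, geom, params) {
  if (any(nSi < 0) || nST < 0 || any(nSi > nST * (1 + 1e-12)))
    .stop_permkin("need 0 <= nSi <= nST", "permkin_speciation_error")
  fo <- .leaflet_fraction(params$KP, geom$Vlo, geom$Vwo)
  fi <- .leaflet_fraction(params$KP, geom$Vli, geom$Vwi)
  nSo <- nST - nSi
  data.frame(nSwo = nSo * (1 - fo), nSlo = nSo * fo,
             nSli = nSi * fi, nSwi = nSi * (1 - fi))
}

#' Analytic equilibration rate constant of a non-ionisable solute
#'
#' The reduced influx dynamics are linear, so the relaxation rate has the
#' closed form `kloi * KP*Vlo/(Vwo + KP*Vlo) + klio * KP*Vli/(Vwi + KP*Vli)`.
#' Used both directly and as an oracle for the numerical trace.
#'
#' @inheritParams speciate_neutral
#' @return Rate constant (s^-1).
#' @export
beta_analytic_neutral <- function(geom, params) {
  params$kloi * .leaflet_fraction(params$KP, geom$Vlo, geom$Vwo) +
    params$klio * .leaflet_fraction(params$KP, geom$Vli, geom$Vwi)
}

#' Equilibrium distribution of a non-ionisable solute
#'
#' @inheritParams speciate_neutral
#' @return A data.frame as in [speciate_neutral()], plus the attribute
#'   `nSi_inf` (total equilibrium amount inside, mol).
#' @export
equilibrium_neutral <- function(geom, params, nST) {
  # steady state of the linear ODE: kloi*nSlo = klio*nSli
  fo <- .leaflet_fraction(params$KP, geom$Vlo, geom$Vwo)
  fi <- .leaflet_fraction(params$KP, geom$Vli, geom$Vwi)
  # kloi*fo*(nST - nSi) = klio*fi*nSi
  nSi_inf <- nST * params$kloi * fo / (params$kloi * fo + params$klio * fi)
  out <- speciate_neutral(nSi_inf, nST, geom, params)
  attr(out, "nSi_inf") <- nSi_inf
  out
}

# default log-spaced grid resolving both the initial rate and the plateau
.default_t_grid <- function(beta, n_points, span = 20) {
  t_end <- span / beta
  c(0, exp(seq(log(t_end * 1e-4), log(t_end), length.out = n_points - 1)))
}

#' Simulate the influx of a non-ionisable solute
#'
#' Integrates the reduced one-state ODE for the amount of solute in the
#' inner compartments, starting from all solute outside (pre-equilibrated
#' between outer aqueous medium and outer leaflet), and returns the full
#' speciated trace.
#'
#' @inheritParams speciate_neutral
#' @param nST Total amount of solute (mol).  The default corresponds to a
#'   1 uM total concentration in 1 dm^3.
#' @param t_grid Output time grid (s).  Default: log-spaced over
#'   `[0, 20/beta]` with `n_points` points, where beta is the analytic rate.
#' @param n_points Number of points of the default grid.
#' @param rtol,atol_frac Integrator tolerances; absolute tolerance is
#'   `atol_frac * nST`.
#' @return A data.frame of class `permeation_sim` with columns `t_s`,
#'   `nSi`, `nSwo`, `nSlo`, `nSli`, `nSwi` (mol) and `Si_M` (total inner
#'   concentration, M); attributes `geom`, `params`, `nST`,
#'   `model = "neutral"`, `beta_analytic`, `nSi_inf`.
#' @export
simulate_neutral <- function(geom, params, nST = 1e-6, t_grid = NULL,
                             n_points = 200, rtol = 1e-9, atol_frac = 1e-15) {
  stopifnot(inherits(geom, "vesicle_geometry"),
            inherits(params, "neutral_params"), nST > 0)
  beta <- beta_analytic_neutral(geom, params)
  if (is.null(t_grid)) t_grid <- .default_t_grid(beta, n_points)
  fo <- .leaflet_fraction(params$KP, geom$Vlo, geom$Vwo)
  fi <- .leaflet_fraction(params$KP, geom$Vli, geom$Vwi)
  rhs <- function(t, y, p) {
    nSi <- y[[1]]
    list(params$kloi * fo * (nST - nSi) - params$klio * fi * nSi)
  }
  sol <- tryCatch(
    deSolve::ode(c(nSi = 0), t_grid, rhs, NULL, method = "lsoda",
                 rtol = rtol, atol = atol_frac * nST),
    warning = function(w) .stop_permkin(
      paste0("ODE integration failed: ", conditionMessage(w)),
      "permkin_integration_error"))
  nSi <- pmin(pmax(sol[, "nSi"], 0), nST)
  sp <- speciate_neutral(nSi, nST, geom, params)
  out <- cbind(data.frame(t_s = sol[, "time"], nSi = nSi), sp,
               Si_M = nSi / (geom$Vli + geom$Vwi))
  eq <- equilibrium_neutral(geom, params, nST)
  nSi_inf <- attr(eq, "nSi_inf")
  if (max(t_grid) * beta >= 15 &&
      abs(nSi[length(nSi)] - nSi_inf) > 1e-3 * nSi_inf)
    .stop_permkin("simulated plateau deviates from the analytic equilibrium by > 0.1%",
                  "permkin_integration_error")
  structure(out,
            class = c("permeation_sim", "data.frame"),
            geom = geom, params = params, nST = nST, model = "neutral",
            beta_analytic = beta, nSi_inf = nSi_inf)
}

#' @export
print.permeation_sim <- function(x, ...) {
  cat(sprintf("Permeation trace (%s model): %d points over %.4g s\n",
              attr(x, "model"), nrow(x), max(x$t_s)))
  cat(sprintf("  nSi(end)/nST = %.4g\n", x$nSi[nrow(x)] / attr(x, "nST")))
  if (!is.null(attr(x, "beta_analytic")))
    cat(sprintf("  analytic beta = %.4g s^-1\n", attr(x, "beta_analytic")))
  NextMethod()
}

#' Write a simulated trace as tidy CSV plus JSON metadata
#'
#' @param sim A `permeation_sim` object.
#' @param path CSV output path; metadata are written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(sim, path) {
  stopifnot(inherits(sim, "permeation_sim"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  meta <- list(model = attr(sim, "model"), nST = attr(sim, "nST"),
               beta_analytic = attr(sim, "beta_analytic"),
               geometry = unclass(attr(sim, "geom")),
               params = unclass(attr(sim, "params")))
  env <- attr(sim, "env")
  if (!is.null(env)) meta$environment <- unclass(env)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
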