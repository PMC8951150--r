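# Model for weak acids: only the neutral (protonated) species flips across
# the bilayer midplane.  Protonation/deprotonation in both aqueous media and
# both leaflets, as well as aqueous/leaflet partition of both species, are at
# quasi-equilibrium.  The outer pH is clamped by an external buffer; the
# inner pH follows from conservation of labile protons (free H+ plus protons
# bound to solute and to the encapsulated pH probe) because each permeating
# neutral acid molecule carries exactly one labile proton inward.

#' Kinetic and equilibrium parameters of a weak acid
#'
#' The membrane acidity constant is not free: the thermodynamic cycle formed
#' by partition of both species and ionisation in both phases forces
#' `KaSl = KaSw * KPSD / KPSH` (microreversibility), so it is always computed
#' from the other three constants.
#'
#' @param KPSH Partition coefficient of the protonated (neutral) species.
#' @param KPSD Partition coefficient of the deprotonated (anionic) species.
#' @param pKaSw Aqueous pKa of the solute.
#' @param kloiSH Outer-to-inner flip-flop rate constant of the neutral
#'   species (s^-1).
#' @param klioSH Inner-to-outer flip-flop rate constant; default
#'   `kloiSH * Vlo / Vli` from `geom` (detailed balance).
#' @param geom [vesicle_geometry()], required only when `klioSH` is `NULL`.
#' @return Object of class `weak_acid_params` with fields `KPSH`, `KPSD`,
#'   `KaSw`, `KaSl`, `kloiSH`, `klioSH`.
#' @export
weak_acid_params <- function(KPSH, KPSD = KPSH, pKaSw = 7, kloiSH = 1,
                             klioSH = NULL, geom = NULL) {
  if (KPSH < 0 || KPSD < 0 || kloiSH <= 0)
    .stop_permkin("KPSH, KPSD must be non-negative and kloiSH positive",
                  "permkin_params_error")
  if (is.null(klioSH)) {
    if (is.null(geom))
      .stop_permkin("provide either klioSH or geom (klioSH defaults to kloiSH*Vlo/Vli)",
                    "permkin_params_error")
    klioSH <- kloiSH * geom$Vlo / geom$Vli
  }
  KaSw <- 10^(-pKaSw)
  structure(list(KPSH = KPSH, KPSD = KPSD, KaSw = KaSw,
                 KaSl = if (KPSH > 0) KaSw * KPSD / KPSH else NA_real_,
                 kloiSH = kloiSH, klioSH = klioSH),
            class = "weak_acid_params")
}

#' @export
print.weak_acid_params <- function(x, ...) {
  cat(sprintf("Weak acid: KPSH = %.4g, KPSD = %.4g, pKa(aq) = %.4g, pKa(membrane) = %.4g\n",
              x$KPSH, x$KPSD, -log10(x$KaSw), -log10(x$KaSl)))
  cat(sprintf("  kloiSH = %.4g s^-1, klioSH = %.4g s^-1\n", x$kloiSH, x$klioSH))
  invisible(x)
}

#' Proton environment: external buffer and encapsulated pH probe
#'
#' The external buffer clamps the outer pH at `pHo0`; its constants are kept
#' for completeness of the run configuration.  The probe is confined to the
#' inner aqueous volume and provides the internal buffer capacity; `PT` is
#' its total concentration with respect to `Vwi`.
#'
#' @param pHo0,pHi0 Initial pH outside / inside the vesicles.
#' @param KaP,PT Probe acidity constant (M) and total concentration (M,
#'   w.r.t. the inner aqueous volume).
#' @param KaB,BT Buffer acidity constant (M) and total concentration (M,
#'   w.r.t. the outer aqueous volume).
#' @return Object of class `proton_environment`.
#' @export
proton_environment <- function(pHo0 = 7, pHi0 = 7, KaP = 1e-7, PT = 0,
                               KaB = 1e-7, BT = 0.01) {
  if (KaP <= 0 || KaB <= 0 || PT < 0 || BT < 0)
    .stop_permkin("acidity constants must be positive, concentrations non-negative",
                  "permkin_params_error")
  structure(list(pHo0 = pHo0, pHi0 = pHi0, KaP = KaP, PT = PT,
                 KaB = KaB, BT = BT),
            class = "proton_environment")
}

#' @export
print.proton_environment <- function(x, ...) {
  cat(sprintf("Proton environment: pHo = %.4g (buffered), pHi(0) = %.4g, probe PT = %.4g M (pKaP = %.4g)\n",
              x$pHo0, x$pHi0, x$PT, -log10(x$KaP)))
  invisible(x)
}

#' Speciation of the solute in the outer compartments
#'
#' The external buffer keeps the outer pH at its initial value, so the outer
#' speciation is a linear split of the total outer amount: aqueous acid/base
#' by the aqueous Ka at the clamped pH, leaflet species by the two partition
#' coefficients.
#'
#' @param nSo Total amount of solute in the outer compartments (mol);
#'   may be a vector.
#' @param geom [vesicle_geometry()].
#' @param params [weak_acid_params()].
#' @param env [proton_environment()].
#' @return data.frame with local concentrations (M) `SHwo`, `SDwo`, `SHlo`,
#'   `SDlo` and the clamped `pHo`.
#' @export
speciate_outer <- function(nSo, geom, params, env) {
  if (any(nSo < 0))
    .stop_permkin("nSo must be non-negative", "permkin_speciation_error")
  Ho <- 10^(-env$pHo0)
  ratio <- params$KaSw / Ho # SDwo / SHwo
  SHwo <- nSo / (geom$Vwo * (1 + ratio) +
                   geom$Vlo * (params$KPSH + params$KPSD * ratio))
  data.frame(SHwo = SHwo, SDwo = SHwo * ratio,
             SHlo = params$KPSH * SHwo, SDlo = params$KPSD * SHwo * ratio,
             pHo = env$pHo0)
}

# labile protons initially present in the inner compartments (mol)
.nHi0 <- function(geom, env) {
  Hi0 <- 10^(-env$pHi0)
  geom$Vwi * (Hi0 + env$PT * Hi0 / (Hi0 + env$KaP))
}

#' Inner speciation from the two conserved inner totals
#'
#' Given the total solute (`nSi`) and total labile protons (`nHi`) in the
#' inner compartments, solves for the free proton concentration `Hwi` such
#' that all quasi-equilibrium relations (solute aqueous and leaflet
#' ionisation, partition of both species, probe protonation) and the
#' labile-proton balance hold simultaneously.  The residual is monotone in
#' `Hwi`, so a bracketed scalar root search on log10(Hwi) over [-14, 0]
#' suffices.  Water autoionisation is not included in the proton balance
#' (see the package vignette for the rationale).
#'
#' @param nSi Total amount of solute in the inner compartments (mol).
#' @param nHi Total amount of labile protons in the inner compartments (mol).
#' @inheritParams speciate_outer
#' @return data.frame with local concentrations (M) `SHwi`, `SDwi`, `SHli`,
#'   `SDli`, `Hwi`, `PHwi`, `PDwi` and `pHi`.
#' @export
solve_inner_speciation <- function(nSi, nHi, geom, params, env) {
  if (length(nSi) != 1 || length(nHi) != 1 || nSi < 0 || nHi <= 0)
    .stop_permkin("nSi must be >= 0 and nHi > 0 (scalars)",
                  "permkin_speciation_error")
  SHwi_of <- function(H) {
    ratio <- params$KaSw / H
    nSi / (geom$Vwi * (1 + ratio) +
             geom$Vli * (params$KPSH + params$KPSD * ratio))
  }
  residual <- function(logH) {
    H <- 10^logH
    SHwi <- SHwi_of(H)
    geom$Vwi * (H + env$PT * H / (H + env$KaP) + SHwi) +
      geom$Vli * params$KPSH * SHwi - nHi
  }
  root <- tryCatch(
    stats::uniroot(residual, c(-14, 0), tol = 1e-12)$root,
    error = function(e) .stop_permkin(
      paste0("inner speciation root-finding failed: ", conditionMessage(e)),
      "permkin_root_error"))
  H <- 10^root
  SHwi <- SHwi_of(H)
  ratio <- params$KaSw / H
  data.frame(SHwi = SHwi, SDwi = SHwi * ratio,
             SHli = params$KPSH * SHwi, SDli = params$KPSD * SHwi * ratio,
             Hwi = H,
             PHwi = env$PT * H / (H + env$KaP),
             PDwi = env$PT * env$KaP / (H + env$KaP),
             pHi = -log10(H))
}

#' Equilibrium state of a weak acid across the vesicle membrane
#'
#' At equilibrium the flip-flop fluxes of the neutral species balance:
#' `kloiSH * SHlo * Vlo = klioSH * SHli * Vli`.  Because the inward proton
#' flux is tied to the solute flux, net flow stops before the total solute
#' concentrations equalise whenever a pH gradient develops.  Solved by a
#' scalar root search on the total amount inside.
#'
#' @inheritParams speciate_outer
#' @param nST Total amount of solute (mol).
#' @return A one-row data.frame with `nSi_inf`, `nHi_inf`, the inner and
#'   outer speciation (M) and `pHi`, `dpHi` (= pHi - pHo).
#' @export
equilibrium_weak_acid <- function(geom, params, env, nST) {
  nHi0 <- .nHi0(geom, env)
  flux_imbalance <- function(nSi) {
    o <- speciate_outer(nST - nSi, geom, params, env)
    i <- solve_inner_speciation(nSi, nHi0 + nSi, geom, params, env)
    params$kloiSH * o$SHlo * geom$Vlo - params$klioSH * i$SHli * geom$Vli
  }
  nSi_inf <- tryCatch(
    stats::uniroot(flux_imbalance, c(nST * 1e-30, nST * (1 - 1e-12)),
                   tol = nST * 1e-14)$root,
    error = function(e) .stop_permkin(
      paste0("equilibrium root-finding failed: ", conditionMessage(e)),
      "permkin_root_error"))
  o <- speciate_outer(nST - nSi_inf, geom, params, env)
  i <- solve_inner_speciation(nSi_inf, nHi0 + nSi_inf, geom, params, env)
  cbind(data.frame(nSi_inf = nSi_inf, nHi_inf = nHi0 + nSi_inf), o, i,
        data.frame(dpHi = i$pHi - env$pHo0))
}

#' Simulate the influx of a weak acid
#'
#' Integrates the one-state ODE for the total amount of solute in the inner
#' compartments; the amount of labile protons inside is slaved to it exactly
#' (`nHi(t) = nHi(0) + nSi(t)`), which avoids integration drift in the proton
#' balance.  The full inner/outer speciation, the inner pH and the
#' protonated-probe fraction are reported along the trace.
#'
#' @inheritParams equilibrium_weak_acid
#' @param t_grid Output time grid (s).  Default: log-spaced over
#'   `[0, 20/beta0]`, with `beta0 = (initial flux)/(equilibrium amount)`,
#'   the exact rate a mono-exponential trace would have.
#' @param n_points Number of points of the default grid.
#' @param rtol,atol_frac Integrator tolerances (absolute = `atol_frac*nST`).
#' @return A data.frame of class `permeation_sim` with columns `t_s`, `nSi`,
#'   `nHi`, per-species concentrations, `pHi`, `fPH` and `Si_M`; attributes
#'   `geom`, `params`, `env`, `nST`, `model = "weak_acid"`, `beta0`,
#'   `nSi_inf`.
#' @export
simulate_weak_acid <- function(geom, params, env, nST = 1e-6, t_grid = NULL,
                               n_points = 200, rtol = 1e-9,
                               atol_frac = 1e-15) {
  stopifnot(inherits(geom, "vesicle_geometry"),
            inherits(params, "weak_acid_params"),
            inherits(env, "proton_environment"), nST > 0)
  nHi0 <- .nHi0(geom, env)
  eq <- equilibrium_weak_acid(geom, params, env, nST)
  flux0 <- params$kloiSH * speciate_outer(nST, geom, params, env)$SHlo * geom$Vlo
  beta0 <- flux0 / eq$nSi_inf
  if (is.null(t_grid)) t_grid <- .default_t_grid(beta0, n_points)
  rhs <- function(t, y, p) {
    nSi <- min(max(y[[1]], 0), nST)
    o <- speciate_outer(nST - nSi, geom, params, env)
    i <- solve_inner_speciation(nSi, nHi0 + nSi, geom, params, env)
    list(params$kloiSH * o$SHlo * geom$Vlo -
           params$klioSH * i$SHli * geom$Vli)
  }
  sol <- tryCatch(
    deSolve::ode(c(nSi = 0), t_grid, rhs, NULL, method = "lsoda",
                 rtol = rtol, atol = atol_frac * nST),
    warning = function(w) .stop_permkin(
      paste0("ODE integration failed: ", conditionMessage(w)),
      "permkin_integration_error"))
  nSi <- pmin(pmax(sol[, "nSi"], 0), nST)
  outer <- speciate_outer(nST - nSi, geom, params, env)
  inner <- do.call(rbind, lapply(nSi, function(x)
    solve_inner_speciation(x, nHi0 + x, geom, params, env)))
  out <- cbind(data.frame(t_s = sol[, "time"], nSi = nSi, nHi = nHi0 + nSi),
               outer, inner,
               data.frame(fPH = inner$Hwi / (inner$Hwi + env$KaP),
                          Si_M = nSi / (geom$Vli + geom$Vwi)))
  if (max(t_grid) * beta0 >= 15 &&
      abs(nSi[length(nSi)] - eq$nSi_inf) > 1e-3 * eq$nSi_inf)
    .stop_permkin("simulated plateau deviates from the equilibrium state by > 0.1%",
                  "permkin_integration_error")
  structure(out,
            class = c("permeation_sim", "data.frame"),
            geom = geom, params = params, env = env, nST = nST,
            model = "weak_acid", beta0 = beta0, nSi_inf = eq$nSi_inf,
            equilibrium = eq)
}

#' Protonated fraction of the encapsulated pH probe
#'
#' Henderson-Hasselbalch applied pointwise to an inner-pH trace: the
#' fluorescence read-out of the pH variation assay.
#'
#' @param pHi Vector of inner pH values.
#' @param env [proton_environment()].
#' @return Vector of protonated-probe fractions in `[0, 1]`.
#' @export
probe_signal <- function(pHi, env) {
  H <- 10^(-pHi)
  H / (H + env$KaP)
}
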