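# Extraction of the equilibration rate constant from influx traces and the
# family of permeability-coefficient estimators.  All estimators return
# dm/s.  Bookkeeping for influx into vesicles: donor = outer aqueous medium
# + outer leaflet, acceptor = inner leaflet + inner aqueous lumen; the
# "aqueous-only" variants restrict the amounts (and the donor volume) to the
# aqueous sub-compartments.

#' Fit a mono-exponential approach to equilibrium
#'
#' Least-squares fit of `y(t) = y_inf + (y0 - y_inf) * exp(-beta t)`.
#' By default the fit is performed in two passes: a crude fit over the whole
#' series fixes the time scale, then the fit is repeated over the window
#' `[0, window/beta]` so that early-time curvature is not swamped by a long
#' plateau.
#'
#' @param t Time points (s), strictly increasing, length >= 5.
#' @param y Amounts (or any signal proportional to them).
#' @param window Refit window in units of `1/beta`; `Inf` disables the
#'   second pass.
#' @return Object of class `exp_fit`: list with `beta` (s^-1), `amplitude`
#'   (the plateau `y_inf`), `offset` (`y0`), `rss`, `stderr_beta`, `n_used`.
#' @export
fit_monoexponential <- function(t, y, window = 10) {
  if (length(t) < 5 || length(t) != length(y))
    .stop_permkin("need at least 5 (t, y) pairs", "permkin_fit_error")
  if (any(diff(t) <= 0))
    .stop_permkin("t must be strictly increasing", "permkin_fit_error")
  if (diff(range(y)) <= 0 ||
      diff(range(y)) < 1e-12 * max(abs(y)))
    .stop_permkin("flat series: no relaxation to fit", "permkin_fit_error")

  # fit on a unit scale so the problem is well conditioned whatever the
  # physical magnitude of y (amounts in mol can be ~1e-9); Levenberg-
  # Marquardt through nls.lm with an analytic Jacobian, which is robust to
  # the zero-residual (noiseless) case
  y_scale <- max(abs(y))
  ys <- y / y_scale
  model_fn <- function(par, t) par[1] + (par[2] - par[1]) * exp(-par[3] * t)
  one_pass <- function(t, ys, start = NULL) {
    if (is.null(start)) {
      y0 <- ys[1]
      yinf <- mean(ys[t >= stats::quantile(t, 0.9)])
      z <- (yinf - ys) / (yinf - y0)
      ok <- is.finite(z) & z > 1e-12 & z < 1
      b0 <- if (sum(ok) >= 3)
        max(-stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[[2]], 1e-12)
      else 1 / max(t)
      start <- c(yinf = yinf, y0 = y0, beta = b0)
    }
    res <- minpack.lm::nls.lm(
      par = start,
      fn = function(par) model_fn(par, t) - ys,
      jac = function(par) {
        e <- exp(-par[3] * t)
        cbind(yinf = 1 - e, y0 = e, beta = -(par[2] - par[1]) * t * e)
      },
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    if (res$info %in% c(0, 9))
      stop("nls.lm did not converge: ", res$message)
    res
  }
  fit <- tryCatch(one_pass(t, ys), error = function(e) .stop_permkin(
    paste0("mono-exponential fit failed: ", conditionMessage(e)),
    "permkin_fit_error"))
  n_used <- length(t)
  if (is.finite(window)) {
    b <- fit$par[["beta"]]
    keep <- t <= window / b
    if (sum(keep) >= 5 && sum(keep) < length(t)) {
      fit <- tryCatch(one_pass(t[keep], ys[keep], start = fit$par),
                      error = function(e) fit)
      n_used <- sum(keep)
    }
  }
  cf <- fit$par
  if (cf[["beta"]] <= 0)
    .stop_permkin("fit converged to a non-positive rate constant",
                  "permkin_fit_error")
  rss <- fit$deviance
  se <- tryCatch({
    dof <- max(n_used - 3, 1)
    sqrt(diag(solve(fit$hessian))[["beta"]] * rss / dof)
  }, error = function(e) NA_real_)
  structure(list(beta = cf[["beta"]], amplitude = cf[["yinf"]] * y_scale,
                 offset = cf[["y0"]] * y_scale, rss = rss * y_scale^2,
                 stderr_beta = se, n_used = n_used),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential fit: beta = %.6g s^-1 (se %.2g), plateau = %.6g, offset = %.6g, rss = %.3g (n = %d)\n",
              x$beta, x$stderr_beta, x$amplitude, x$offset, x$rss, x$n_used))
  invisible(x)
}

.check_pos <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .stop_permkin("all estimator inputs must be positive and finite",
                  "permkin_estimator_error")
}

#' General apparent permeability coefficient
#'
#' `Papp = beta * nSA_inf / nSD_0 * VD / A`: the definition-based estimator,
#' valid whenever the equilibration is mono-exponential, regardless of how
#' much solute actually crosses before net flow stops.
#'
#' @param beta Equilibration rate constant (s^-1).
#' @param nSA_inf Amount of solute in the acceptor compartments at
#'   equilibrium (mol).
#' @param nSD_0 Initial amount of solute in the donor compartments (mol).
#' @param VD Donor volume (dm^3).
#' @param A Barrier area (dm^2).
#' @return Permeability coefficient (dm/s).
#' @export
papp_general <- function(beta, nSA_inf, nSD_0, VD, A) {
  .check_pos(beta, nSA_inf, nSD_0, VD, A)
  beta * nSA_inf / nSD_0 * VD / A
}

#' Simplified radius-based permeability estimator
#'
#' `Pappr = beta * r / 3`, the expression in common use for spherical
#' vesicles.  It presumes a negligible acceptor volume fraction and full
#' equalisation of solute concentrations at equilibrium.
#'
#' @inheritParams papp_general
#' @param r Vesicle radius (dm); the midplane radius is the physically
#'   relevant choice.
#' @return Permeability coefficient (dm/s).
#' @export
papp_r <- function(beta, r) {
  .check_pos(beta, r)
  beta * r / 3
}

#' Volume-corrected radius-based estimator
#'
#' `PapprV = beta * r/3 * (1 - VA/VT)`: corrects [papp_r()] for a
#' non-negligible acceptor volume fraction (it still presumes concentration
#' equalisation).
#'
#' @inheritParams papp_r
#' @param VA Acceptor volume (dm^3).
#' @param VT Total volume (dm^3).
#' @return Permeability coefficient (dm/s).
#' @export
papp_rV <- function(beta, r, VA, VT) {
  .check_pos(beta, r, VA, VT)
  beta * r / 3 * (1 - VA / VT)
}

#' Aqueous-only apparent permeability
#'
#' `Pappw = beta * nSwA_inf / nSwD_0 * VwD / A`: the estimator obtained when
#' only the solute dissolved in the aqueous media is followed, with the donor
#' volume likewise restricted to its aqueous part.
#'
#' @inheritParams papp_general
#' @param nSwA_inf Equilibrium amount in the acceptor aqueous compartment
#'   (mol).
#' @param nSwD_0 Initial amount in the donor aqueous compartment (mol).
#' @param VwD Donor aqueous volume (dm^3).
#' @return Permeability coefficient (dm/s).
#' @export
papp_w <- function(beta, nSwA_inf, nSwD_0, VwD, A) {
  .check_pos(beta, nSwA_inf, nSwD_0, VwD, A)
  beta * nSwA_inf / nSwD_0 * VwD / A
}

#' Aqueous-only permeability from the general one (closed form)
#'
#' Re-expresses [papp_w()] in terms of [papp_general()] using the
#' quasi-equilibrium aqueous fractions of a non-ionisable solute:
#' `Pappw = Papp * (fVwD + KP fVlD)/(fVwD + fVlD) * fVwA/(fVwA + KP fVlA)`,
#' with all volume fractions relative to the same reference volume.
#'
#' @param Papp General apparent permeability (dm/s).
#' @param KP Partition coefficient.
#' @param fVwD,fVlD Donor aqueous and leaflet volume fractions.
#' @param fVwA,fVlA Acceptor aqueous and leaflet volume fractions.
#' @return Permeability coefficient (dm/s).
#' @export
papp_w_from_papp <- function(Papp, KP, fVwD, fVlD, fVwA, fVlA) {
  .check_pos(Papp, fVwD, fVwA)
  if (KP < 0 || fVlD < 0 || fVlA < 0)
    .stop_permkin("KP and volume fractions must be non-negative",
                  "permkin_estimator_error")
  Papp * (fVwD + KP * fVlD) / (fVwD + fVlD) * fVwA / (fVwA + KP * fVlA)
}

#' Hybrid aqueous-donor permeability estimator
#'
#' `Pappw* = beta * nSA_inf / nSwD_0 * VwD / A`: driving force from the
#' donor aqueous concentration, but all permeated solute (aqueous + leaflet)
#' counted in the acceptor.  On the present model this estimator equals the
#' intrinsic permeability, and grows linearly with lipophilicity.
#'
#' @inheritParams papp_general
#' @inheritParams papp_w
#' @return Permeability coefficient (dm/s).
#' @export
papp_w_star <- function(beta, nSA_inf, nSwD_0, VwD, A) {
  .check_pos(beta, nSA_inf, nSwD_0, VwD, A)
  beta * nSA_inf / nSwD_0 * VwD / A
}

#' Intrinsic permeability of a non-ionisable solute
#'
#' `P = kloi * KP * h`, with `h` the thickness of the membrane volume used
#' to define `KP`.  `KP` here is defined per leaflet volume, so `h` is the
#' leaflet (half-bilayer) thickness.  Geometry-independent.
#'
#' @param kloi Flip-flop rate constant (s^-1).
#' @param KP Partition coefficient (per leaflet volume).
#' @param h_leaflet Leaflet thickness (dm).
#' @return Permeability coefficient (dm/s).
#' @export
p_intrinsic_neutral <- function(kloi, KP, h_leaflet) {
  .check_pos(kloi, h_leaflet)
  if (KP < 0) .stop_permkin("KP must be non-negative", "permkin_estimator_error")
  kloi * KP * h_leaflet
}

#' Observed permeability of a non-ionisable solute in a given system
#'
#' `Pobs = kloi * KP * h / (fVwD + KP * fVlD)`: the intrinsic permeability
#' corrected for sequestration of the solute in the donor-side membrane
#' leaflet; reduces to [p_intrinsic_neutral()] when `KP * fVlD << fVwD`.
#'
#' @inheritParams p_intrinsic_neutral
#' @param fVwD,fVlD Donor aqueous and leaflet volume fractions (sum <= 1).
#' @return Permeability coefficient (dm/s).
#' @export
p_obs_neutral <- function(kloi, KP, h_leaflet, fVwD, fVlD) {
  .check_pos(kloi, h_leaflet, fVwD)
  if (KP < 0 || fVlD < 0 || fVwD + fVlD > 1 + 1e-9)
    .stop_permkin("need KP, fVlD >= 0 and fVwD + fVlD <= 1",
                  "permkin_estimator_error")
  kloi * KP * h_leaflet / (fVwD + KP * fVlD)
}

#' Observed permeability of a weak acid in a given system
#'
#' Only the neutral species permeates, so the amount of permeant near the
#' barrier carries Henderson-Hasselbalch and double-partition corrections:
#' `Pobs = kloiSH * KPSH * h / ((1 + KaSw/H) fVwD + (KPSH + KaSw/H * KPSD) fVlD)`.
#'
#' @param kloiSH Flip-flop rate constant of the neutral species (s^-1).
#' @param KPSH,KPSD Partition coefficients of the neutral/anionic species.
#' @param KaSw Aqueous acidity constant (M).
#' @param H Proton concentration of the donor aqueous phase (M).
#' @param h_leaflet Leaflet thickness (dm).
#' @param fVwD,fVlD Donor aqueous and leaflet volume fractions.
#' @return Permeability coefficient (dm/s).
#' @export
p_obs_weak_acid <- function(kloiSH, KPSH, KPSD, KaSw, H, h_leaflet,
                            fVwD, fVlD) {
  .check_pos(kloiSH, h_leaflet, fVwD, H, KaSw)
  if (KPSH < 0 || KPSD < 0 || fVlD < 0)
    .stop_permkin("partition coefficients and volume fractions must be non-negative",
                  "permkin_estimator_error")
  kloiSH * KPSH * h_leaflet /
    ((1 + KaSw / H) * fVwD + (KPSH + KaSw / H * KPSD) * fVlD)
}

#' Intrinsic permeability of a weak acid
#'
#' Negligible-sequestration limit of [p_obs_weak_acid()]:
#' `P = fSH * kloiSH * KPSH * h` with `fSH = 1/(1 + KaSw/H)` the neutral
#' fraction in the donor aqueous phase.
#'
#' @inheritParams p_obs_weak_acid
#' @return Permeability coefficient (dm/s).
#' @export
p_intrinsic_weak_acid <- function(kloiSH, KPSH, KaSw, H, h_leaflet) {
  .check_pos(kloiSH, h_leaflet, H, KaSw)
  if (KPSH < 0)
    .stop_permkin("KPSH must be non-negative", "permkin_estimator_error")
  kloiSH * KPSH * h_leaflet / (1 + KaSw / H)
}

#' Meyer-Overton permeability
#'
#' `P = KP * D / h`, the classical solubility-diffusion expression; with the
#' identification `D = kflip * h^2` it coincides with the intrinsic
#' permeability of this model.  Provided for comparison.
#'
#' @param KP Partition coefficient.
#' @param D Diffusion coefficient across the barrier (dm^2/s).
#' @param h Barrier thickness (dm).
#' @return Permeability coefficient (dm/s).
#' @export
meyer_overton <- function(KP, D, h) {
  .check_pos(D, h)
  if (KP < 0) .stop_permkin("KP must be non-negative", "permkin_estimator_error")
  KP * D / h
}

#' All permeability estimates from a simulated influx trace
#'
#' Fits the equilibration rate constant to the simulated amount-inside trace
#' and evaluates every estimator variant with the influx bookkeeping
#' (donor = outer compartments, acceptor = inner compartments).  Equilibrium
#' amounts are taken from the model's own equilibrium state; for weak acids
#' the trace is only approximately mono-exponential and the fit residual is
#' reported rather than asserted.
#'
#' @param sim A `permeation_sim` from [simulate_neutral()] or
#'   [simulate_weak_acid()].
#' @param radius Barrier-radius convention, see [barrier_area()].
#' @param window Fit window passed to [fit_monoexponential()].
#' @return Object of class `permeability_estimates`: list with `beta`, the
#'   estimators `Papp`, `Pappr`, `PapprV`, `Pappw`, `Pappw_star`, `Pobs`,
#'   `P_intrinsic`, the fit object, and the bookkeeping quantities
#'   (`nSA_inf`, `nSD_0`, `nSwA_inf`, `nSwD_0`, `VD`, `VwD`, `VA`, `A`, `r`,
#'   `dpHi` for weak acids).
#' @export
estimate_permeability <- function(sim, radius = "interleaflet", window = 10) {
  stopifnot(inherits(sim, "permeation_sim"))
  geom <- attr(sim, "geom")
  params <- attr(sim, "params")
  nST <- attr(sim, "nST")
  model <- attr(sim, "model")
  A <- barrier_area(geom, radius)
  r <- barrier_radius(geom, radius)
  VD <- geom$Vwo + geom$Vlo
  VA <- geom$Vli + geom$Vwi
  h_leaflet <- geom$h / 2
  fVwD <- geom$Vwo / geom$VT
  fVlD <- geom$Vlo / geom$VT

  fit <- fit_monoexponential(sim$t_s, sim$nSi, window = window)
  beta <- fit$beta

  if (model == "neutral") {
    eq <- equilibrium_neutral(geom, params, nST)
    nSA_inf <- attr(eq, "nSi_inf")
    nSwA_inf <- eq$nSwi
    sp0 <- speciate_neutral(0, nST, geom, params)
    nSwD_0 <- sp0$nSwo
    KP <- params$KP
    Pobs <- p_obs_neutral(params$kloi, KP, h_leaflet, fVwD, fVlD)
    P <- p_intrinsic_neutral(params$kloi, KP, h_leaflet)
    dpHi <- NA_real_
  } else {
    env <- attr(sim, "env")
    eq <- attr(sim, "equilibrium")
    nSA_inf <- eq$nSi_inf
    nSwA_inf <- (eq$SHwi + eq$SDwi) * geom$Vwi
    o0 <- speciate_outer(nST, geom, params, env)
    nSwD_0 <- (o0$SHwo + o0$SDwo) * geom$Vwo
    KP <- params$KPSH # lipophilicity of the permeating species
    H <- 10^(-env$pHo0)
    Pobs <- p_obs_weak_acid(params$kloiSH, params$KPSH, params$KPSD,
                            params$KaSw, H, h_leaflet, fVwD, fVlD)
    P <- p_intrinsic_weak_acid(params$kloiSH, params$KPSH, params$KaSw, H,
                               h_leaflet)
    dpHi <- eq$dpHi
  }

  structure(list(
    beta = beta,
    Papp = papp_general(beta, nSA_inf, nST, VD, A),
    Pappr = papp_r(beta, r),
    PapprV = papp_rV(beta, r, VA, geom$VT),
    Pappw = papp_w(beta, nSwA_inf, nSwD_0, geom$Vwo, A),
    Pappw_star = papp_w_star(beta, nSA_inf, nSwD_0, geom$Vwo, A),
    Pobs = Pobs, P_intrinsic = P,
    fit = fit, model = model, radius = radius,
    nSA_inf = nSA_inf, nSD_0 = nST, nSwA_inf = nSwA_inf, nSwD_0 = nSwD_0,
    VD = VD, VwD = geom$Vwo, VA = VA, A = A, r = r, dpHi = dpHi),
    class = "permeability_estimates")
}

#' @export
print.permeability_estimates <- function(x, ...) {
  cat(sprintf("Permeability estimates (%s model, %s radius)\n",
              x$model, x$radius))
  cat(sprintf("  beta        = %.6g s^-1\n", x$beta))
  for (nm in c("Papp", "Pappr", "PapprV", "Pappw", "Pappw_star", "Pobs",
               "P_intrinsic"))
    cat(sprintf("  %-11s = %.6g dm/s\n", nm, x[[nm]]))
  if (is.finite(x$dpHi)) cat(sprintf("  dpHi (eq)   = %.4g\n", x$dpHi))
  invisible(x)
}
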