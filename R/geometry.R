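# Vesicle suspension geometry.
#
# Internal canonical units throughout the package: length dm, area dm^2,
# volume dm^3, concentration mol/dm^3 (M), time s.  Permeability coefficients
# then come out in dm/s with no further conversion.  User-facing constructors
# take lengths in nm (the natural unit for vesicle radii and bilayer
# thickness) and convert once at the boundary.

#' Avogadro's number (mol^-1)
#' @keywords internal
.NA_AVOGADRO <- 6.02214076e23

# 1 nm expressed in dm
.NM <- 1e-8

.stop_permkin <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "permkin_error")))
}

#' Four-compartment geometry of a vesicle suspension
#'
#' Computes all volumes, areas and counts describing a suspension of
#' monodisperse unilamellar spherical vesicles: the outer aqueous medium, the
#' outer and inner membrane leaflets (split at the bilayer midplane), and the
#' encapsulated aqueous lumen.  The number of vesicles follows from the lipid
#' concentration and the area per lipid molecule, counting lipids on both
#' monolayer surfaces.
#'
#' @param ro_nm Outer vesicle radius (nm).
#' @param h_nm Bilayer thickness (nm).  Default 3.95 nm, typical of a fluid
#'   POPC bilayer.
#' @param aL_dm2 Area per lipid molecule (dm^2).  Default 6.4e-17 dm^2
#'   (0.64 nm^2).
#' @param cL_M Total lipid concentration (mol/dm^3).
#' @param VT_dm3 Total suspension volume (dm^3).
#'
#' @return An object of class `vesicle_geometry`: a list with elements
#'   `ro`, `h`, `ri` (= ro - h), `rio` (= ro - h/2, the midplane radius), all
#'   in dm; `N_vesicles`, `NL_per_vesicle`; the compartment volumes `Vwo`,
#'   `Vlo`, `Vli`, `Vwi` (dm^3) which sum to `VT`; the total barrier areas
#'   `Aio` (at the midplane), `Ao` (outer) and `Ai` (inner) in dm^2; and the
#'   inputs `VT`, `cL`, `aL`.
#'
#' @details The leaflet boundary is placed exactly at the bilayer midplane
#'   `ro - h/2`; the non-polar midplane is the permeation barrier, so `Aio`
#'   is the default barrier area used by the estimators.
#'
#' @examples
#' g <- vesicle_geometry(ro_nm = 100)
#' g$Vwo + g$Vlo + g$Vli + g$Vwi  # == 1 dm^3
#' @export
vesicle_geometry <- function(ro_nm, h_nm = 3.95, aL_dm2 = 6.4e-17,
                             cL_M = 1e-3, VT_dm3 = 1) {
  if (!is.finite(ro_nm) || !is.finite(h_nm) || ro_nm <= 0 || h_nm <= 0)
    .stop_permkin("ro_nm and h_nm must be positive finite numbers",
                  "permkin_geometry_error")
  if (ro_nm <= h_nm)
    .stop_permkin("outer radius must exceed bilayer thickness (no aqueous lumen otherwise)",
                  "permkin_geometry_error")
  if (aL_dm2 <= 0 || VT_dm3 <= 0 || cL_M < 0)
    .stop_permkin("aL_dm2 and VT_dm3 must be positive; cL_M must be non-negative",
                  "permkin_geometry_error")

  ro <- ro_nm * .NM
  h <- h_nm * .NM
  ri <- ro - h
  rio <- ro - h / 2

  NL_per_vesicle <- 4 * pi * (ro^2 + ri^2) / aL_dm2
  N <- cL_M * VT_dm3 * .NA_AVOGADRO / NL_per_vesicle

  vol <- function(r) 4 / 3 * pi * r^3
  Vwo <- VT_dm3 - vol(ro) * N
  if (Vwo < 0)
    .stop_permkin("lipid volume exceeds the total suspension volume; reduce cL or ro",
                  "permkin_geometry_error")
  Vlo <- (vol(ro) - vol(rio)) * N
  Vli <- (vol(rio) - vol(ri)) * N
  Vwi <- vol(ri) * N

  structure(
    list(ro = ro, h = h, ri = ri, rio = rio,
         N_vesicles = N, NL_per_vesicle = NL_per_vesicle,
         Vwo = Vwo, Vlo = Vlo, Vli = Vli, Vwi = Vwi,
         Aio = 4 * pi * rio^2 * N,
         Ao = 4 * pi * ro^2 * N,
         Ai = 4 * pi * ri^2 * N,
         VT = VT_dm3, cL = cL_M, aL = aL_dm2),
    class = "vesicle_geometry")
}

#' Total barrier area for a given radius convention
#'
#' The permeation barrier is the non-polar bilayer midplane, so the midplane
#' (interleaflet) radius is the physically relevant choice; the outer and
#' inner radii are provided for comparison, as the three conventions differ
#' appreciably for highly curved (small) vesicles.
#'
#' @param geom A [vesicle_geometry()] object.
#' @param radius One of `"interleaflet"` (default), `"outer"`, `"inner"`.
#' @return Total barrier area (dm^2) summed over all vesicles.
#' @export
barrier_area <- function(geom, radius = c("interleaflet", "outer", "inner")) {
  stopifnot(inherits(geom, "vesicle_geometry"))
  switch(match.arg(radius),
         interleaflet = geom$Aio,
         outer = geom$Ao,
         inner = geom$Ai)
}

#' Radius corresponding to a barrier-area convention
#' @inheritParams barrier_area
#' @return Radius in dm.
#' @export
barrier_radius <- function(geom, radius = c("interleaflet", "outer", "inner")) {
  stopifnot(inherits(geom, "vesicle_geometry"))
  switch(match.arg(radius),
         interleaflet = geom$rio,
         outer = geom$ro,
         inner = geom$ri)
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat("Vesicle suspension geometry\n")
  cat(sprintf("  ro = %.4g nm, h = %.4g nm, cL = %.4g M, VT = %.4g dm^3\n",
              x$ro / .NM, x$h / .NM, x$cL, x$VT))
  cat(sprintf("  %.4g vesicles, %.4g lipids each\n", x$N_vesicles,
              x$NL_per_vesicle))
  cat(sprintf("  Vwo = %.4g, Vlo = %.4g, Vli = %.4g, Vwi = %.4g dm^3\n",
              x$Vwo, x$Vlo, x$Vli, x$Vwi))
  cat(sprintf("  barrier area (midplane) = %.4g dm^2\n", x$Aio))
  invisible(x)
}

#' @export
as.list.vesicle_geometry <- function(x, ...) unclass(x)

#' Geometry summary as JSON
#'
#' @param geom A [vesicle_geometry()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
geometry_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "vesicle_geometry"))
  js <- jsonlite::toJSON(unclass(geom), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
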