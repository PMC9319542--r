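#' Stability class climatology
#'
#' Frequencies of occurrence of the six Pasquill classes used to form yearly
#' average deposition fluxes. The default is a Northern Hemisphere climatology
#' combining day and night in equal parts: a/b/c 4% each, d 37%, e/f 25.5%
#' each.
#'
#' @param p named numeric vector of frequencies for classes a-f; must be
#'   nonnegative and sum to 1 (tolerance 1e-6).
#' @return Named numeric vector of class `"stability_climatology"`.
#' @export
stability_climatology <- function(p = c(a = 0.04, b = 0.04, c = 0.04,
                                        d = 0.37, e = 0.255, f = 0.255)) {
  p <- unlist(p)
  if (is.null(names(p)) || !setequal(names(p), stability_classes())) {
    stop("climatology needs one frequency per class a-f", call. = FALSE)
  }
  p <- p[stability_classes()]
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > 1e-6) stop("climatology frequencies must sum to 1")
  structure(p, class = "stability_climatology")
}

#' Climatology-weighted average of per-class profiles
#'
#' Pointwise convex combination `F_avg = P(a) F_a + ... + P(f) F_f` of
#' per-stability-class profiles sharing one x grid, used to form yearly
#' average fluxes and concentrations.
#'
#' @param models named list of [plume_model()] fits, one per class `"a"`-`"f"`,
#'   all on the same grid.
#' @param clim a [stability_climatology()].
#' @return A data frame with the grid `x` and weighted `conc_ground` (g/m3),
#'   `flux` (g/m2/s), `crosswind_flux` (g/m/s) and `fdep` profiles.
#' @export
stability_average <- function(models, clim = stability_climatology()) {
  if (!setequal(names(models), stability_classes())) {
    stop("need one fitted model per stability class a-f", call. = FALSE)
  }
  x <- models[["a"]]$x
  for (cl in stability_classes()) {
    if (!isTRUE(all.equal(models[[cl]]$x, x))) {
      stop("all per-class models must share the same x grid", call. = FALSE)
    }
  }
  acc <- list(conc_ground = 0, flux = 0, crosswind_flux = 0, fdep = 0)
  for (cl in stability_classes()) {
    m <- models[[cl]]
    w <- unclass(clim)[[cl]]
    acc$conc_ground <- acc$conc_ground + w * m$conc_ground
    acc$flux <- acc$flux + w * m$flux
    acc$crosswind_flux <- acc$crosswind_flux + w * m$crosswind_flux
    acc$fdep <- acc$fdep + w * m$fdep
  }
  data.frame(x = x, conc_ground = acc$conc_ground, flux = acc$flux,
             crosswind_flux = acc$crosswind_flux, fdep = acc$fdep)
}

#' Near-field and far-field compartment concentrations
#'
#' Steady-state concentrations of the two fully mixed compartments separated
#' at the half-deposited distance: `CN = E / (2 pi x50^2 vdep)` for the local
#' (near-field) disc and `CF = E / (2 pi (xtot^2 - x50^2) vdep)` for the
#' regional (far-field) annulus.
#'
#' @param E emission rate g/s.
#' @param vdep deposition velocity m/s (> 0; the steady state is undefined
#'   without removal).
#' @param x50 near-field/far-field boundary m (0 < x50 < xtot).
#' @param xtot regional domain radius m.
#' @return List with `CN` and `CF` in g/m3.
#' @examples
#' nf_ff_concentrations(E = 29e-6, vdep = 0.01, x50 = 1700, xtot = 5e5)
#' @export
nf_ff_concentrations <- function(E, vdep, x50, xtot = 5e5) {
  stopifnot(E > 0)
  if (vdep <= 0) stop("vdep must be > 0 for a steady state", call. = FALSE)
  if (!is.finite(x50) || x50 <= 0) stop("x50 must be finite and > 0")
  if (x50 >= xtot) stop("x50 must be smaller than xtot (far field vanishes)")
  list(CN = E / (2 * pi * x50^2 * vdep),
       CF = E / (2 * pi * (xtot^2 - x50^2) * vdep))
}

#' Soil scenario
#'
#' Uniform topsoil mixing-layer parameters for long-term accumulation.
#'
#' @param Hsoil soil mixing depth m.
#' @param rho_soil soil density kg/m3.
#' @param pnec predicted no-effect concentration in soil, g/kg (the default is
#'   the nano-TiO2 value, 1000 ug/kg).
#' @return List of class `"soil_scenario"`.
#' @export
soil_scenario <- function(Hsoil = 0.05, rho_soil = 1500, pnec = 1e-3) {
  stopifnot(Hsoil > 0, rho_soil > 0, pnec > 0)
  structure(list(Hsoil = Hsoil, rho_soil = rho_soil, pnec = pnec),
            class = "soil_scenario")
}

#' Predicted environmental concentration in soil
#'
#' Accumulated soil concentration after `years` of continuous deposition into
#' a uniform mixing layer:
#' `PECsoil = F * years * 365*24*3600 / (Hsoil * rho_soil)` (g/kg). Linear in
#' both the flux and the accumulation time; the year is 365 days exactly.
#'
#' @param flux deposition flux g/m2/s (vectorised).
#' @param years accumulation time in years.
#' @param soil a [soil_scenario()].
#' @return Concentration in g/kg.
#' @export
pec_soil <- function(flux, years, soil = soil_scenario()) {
  stopifnot(all(flux >= 0), all(years > 0))
  flux * years * 365 * 24 * 3600 / (soil$Hsoil * soil$rho_soil)
}

#' @rdname pec_soil
#' @param pec concentration g/kg.
#' @param pnec predicted no-effect concentration g/kg.
#' @return `pec_pnec_ratio()`: the dimensionless risk ratio PEC/PNEC.
#' @export
pec_pnec_ratio <- function(pec, pnec = 1e-3) {
  stopifnot(all(pnec > 0))
  pec / pnec
}

#' Registry of soil PNEC values
#'
#' Reads the packaged (user-editable) registry of predicted no-effect
#' concentrations in soil.
#'
#' @param substance optional substance name; when given, the PNEC is returned
#'   in g/kg, otherwise the full registry table.
#' @return A data frame, or a single PNEC in g/kg.
#' @export
pnec_registry <- function(substance = NULL) {
  path <- system.file("extdata", "pnec_soil.csv", package = "nanoplume",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(substance)) return(tab)
  i <- match(substance, tab$substance)
  if (is.na(i)) stop("unknown substance: ", substance, call. = FALSE)
  tab$pnec_ug_per_kg[i] * 1e-6
}
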