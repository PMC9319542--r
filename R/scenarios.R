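#' Scenario configuration
#'
#' A validated, internally consistent (SI units) description of one exposure
#' screening run: source, particle or fixed velocities (exactly one of the
#' two), atmosphere, optional stability climatology, domain extent and soil
#' accumulation settings. Scenario files on disk (YAML, see [read_scenario()])
#' carry explicit unit suffixes; this constructor takes SI values.
#'
#' @param name scenario label.
#' @param E emission rate g/s.
#' @param H source height m.
#' @param dp,rho particle diameter (nm) and density (kg/m3); give these or
#'   `vset`/`vdep`.
#' @param vset,vdep fixed settling/deposition velocities m/s (generic
#'   pollutant mode).
#' @param U wind speed m/s.
#' @param T_K air temperature K.
#' @param Hpbl boundary layer height m.
#' @param stability one class, or a vector of classes (e.g. all six for a
#'   climatology-weighted yearly average).
#' @param scheme dispersion scheme name or object.
#' @param climatology a [stability_climatology()] or `NULL`; defaults to the
#'   packaged climatology when all six classes are requested.
#' @param xmax domain radius m.
#' @param z_ref ground-level evaluation height m.
#' @param years accumulation times for PECsoil, in years.
#' @param soil a [soil_scenario()].
#' @param pnec_substance name in [pnec_registry()] used for risk ratios.
#' @return Object of class `"scenario"`.
#' @export
scenario <- function(name, E, H, dp = NULL, rho = NULL, vset = NULL,
                     vdep = NULL, U, T_K = 288.15, Hpbl = 1000,
                     stability = "d", scheme = "davidson",
                     climatology = NULL, xmax = 5e5, z_ref = 2,
                     years = c(10, 20, 30, 100), soil = soil_scenario(),
                     pnec_substance = "nano-TiO2") {
  has_particle <- !is.null(dp) || !is.null(rho)
  has_fixed <- !is.null(vset) || !is.null(vdep)
  if (has_particle == has_fixed) {
    stop("give exactly one of {particle (dp, rho)} or {fixed velocities (vset, vdep)}",
         call. = FALSE)
  }
  if (has_particle && (is.null(dp) || is.null(rho))) {
    stop("particle mode needs both dp and rho", call. = FALSE)
  }
  if (has_fixed && (is.null(vset) || is.null(vdep))) {
    stop("fixed-velocity mode needs both vset and vdep", call. = FALSE)
  }
  stability <- .check_class(stability)
  if (length(stability) == 6L && is.null(climatology)) {
    climatology <- stability_climatology()
  }
  out <- list(name = name, E = E, H = H, dp = dp, rho = rho,
              vset = vset, vdep = vdep, U = U, T_K = T_K, Hpbl = Hpbl,
              stability = stability, scheme = .as_scheme(scheme)$name,
              climatology = climatology, xmax = xmax, z_ref = z_ref,
              years = years, soil = soil, pnec_substance = pnec_substance)
  class(out) <- "scenario"
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  cat(sprintf("  source: E = %g g/s, H = %g m\n", x$E, x$H))
  if (!is.null(x$dp)) {
    cat(sprintf("  particle: dp = %g nm, rho = %g kg/m3\n", x$dp, x$rho))
  } else {
    cat(sprintf("  fixed velocities: vset = %g m/s, vdep = %g m/s\n",
                x$vset, x$vdep))
  }
  cat(sprintf("  atmosphere: U = %g m/s, T = %g K, Hpbl = %g m, %s, class(es) %s\n",
              x$U, x$T_K, x$Hpbl, x$scheme,
              paste(x$stability, collapse = ",")))
  cat(sprintf("  domain: %g km, PNEC substance: %s\n",
              x$xmax / 1000, x$pnec_substance))
  invisible(x)
}

#' Read and write scenario files
#'
#' Scenario files are YAML with explicit unit suffixes, e.g. `emission_rate:
#' 29 ug/s`, `diameter: 260 nm`, `boundary_layer: 1 km`. Parsing converts to
#' SI at the boundary; `write_scenario()` serializes back with canonical SI
#' suffixes, so a parse/serialize round trip is idempotent.
#'
#' @param path file path.
#' @return `read_scenario()` a [scenario()]; `write_scenario()` the path,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  src <- y$source
  part <- y$particle
  vel <- y$velocities
  atm <- y$atmosphere
  clim <- NULL
  if (!is.null(y$climatology) && !identical(y$climatology, "default")) {
    clim <- stability_climatology(unlist(y$climatology))
  }
  stability <- atm$stability
  if (is.null(stability)) stability <- "d"
  soil <- soil_scenario()
  years <- c(10, 20, 30, 100)
  pnec_substance <- "nano-TiO2"
  if (!is.null(y$soil)) {
    soil <- soil_scenario(
      Hsoil = parse_quantity(y$soil$mixing_depth %||% 0.05, "m"),
      rho_soil = parse_quantity(y$soil$density %||% 1500, "kg/m3"),
      pnec = if (!is.null(y$soil$pnec_substance))
        pnec_registry(y$soil$pnec_substance) else 1e-3)
    if (!is.null(y$soil$years)) years <- unlist(y$soil$years)
    if (!is.null(y$soil$pnec_substance)) pnec_substance <- y$soil$pnec_substance
  }
  scenario(
    name = y$name %||% basename(path),
    E = parse_quantity(src$emission_rate, "g/s"),
    H = parse_quantity(src$height, "m"),
    dp = if (!is.null(part)) parse_quantity(part$diameter, "m") * 1e9,
    rho = if (!is.null(part)) parse_quantity(part$density, "kg/m3"),
    vset = if (!is.null(vel)) parse_quantity(vel$settling, "m/s"),
    vdep = if (!is.null(vel)) parse_quantity(vel$deposition, "m/s"),
    U = parse_quantity(atm$wind_speed, "m/s"),
    T_K = parse_quantity(atm$temperature %||% 288.15, "K"),
    Hpbl = parse_quantity(atm$boundary_layer %||% 1000, "m"),
    stability = unlist(stability),
    scheme = atm$scheme %||% "davidson",
    climatology = clim,
    xmax = parse_quantity((y$domain %||% list())$xmax %||% 5e5, "m"),
    years = years, soil = soil, pnec_substance = pnec_substance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_scenario
#' @param sc a [scenario()].
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  y <- list(
    name = sc$name,
    source = list(emission_rate = .format_quantity(sc$E, "g/s"),
                  height = .format_quantity(sc$H, "m")))
  if (!is.null(sc$dp)) {
    y$particle <- list(diameter = .format_quantity(sc$dp * 1e-9, "m"),
                       density = .format_quantity(sc$rho, "kg/m3"))
  } else {
    y$velocities <- list(settling = .format_quantity(sc$vset, "m/s"),
                         deposition = .format_quantity(sc$vdep, "m/s"))
  }
  y$atmosphere <- list(wind_speed = .format_quantity(sc$U, "m/s"),
                       temperature = .format_quantity(sc$T_K, "K"),
                       boundary_layer = .format_quantity(sc$Hpbl, "m"),
                       stability = as.list(sc$stability),
                       scheme = sc$scheme)
  if (!is.null(sc$climatology)) {
    y$climatology <- as.list(unclass(sc$climatology))
  }
  y$domain <- list(xmax = .format_quantity(sc$xmax, "m"))
  y$soil <- list(mixing_depth = .format_quantity(sc$soil$Hsoil, "m"),
                 density = .format_quantity(sc$soil$rho_soil, "kg/m3"),
                 years = as.list(sc$years),
                 pnec_substance = sc$pnec_substance)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Built-in TiO2 case studies
#'
#' Scenario presets for the two measured nano-TiO2 atmospheric releases used
#' as case studies: a paint factory (`"fonseca"`; stack 7.8 m, 260 nm,
#' 940 kg/m3, yearly average 29 ug/s, powder-pouring activity 0.14 mg/s) and
#' a spray-coating facility (`"koivisto"`; exhaust at 3 m, 280 nm,
#' 2100 kg/m3, yearly 3.5 ug/s, spraying activity 0.33 mg/s). Both use wind
#' 2.5 m/s, 288.15 K, a 1 km boundary layer, the Davidson parametrization and
#' all six stability classes with the packaged climatology.
#'
#' @param name `"fonseca"` or `"koivisto"`.
#' @param emission `"yearly"` average rate or short-term `"activity"` rate.
#' @return A [scenario()].
#' @export
case_study <- function(name = c("fonseca", "koivisto"),
                       emission = c("yearly", "activity")) {
  name <- match.arg(name)
  emission <- match.arg(emission)
  if (name == "fonseca") {
    E <- if (emission == "yearly") 29e-6 else 0.14e-3
    sc <- scenario(paste0("fonseca-", emission), E = E, H = 7.8,
                   dp = 260, rho = 940, U = 2.5, T_K = 288.15, Hpbl = 1000,
                   stability = stability_classes(), scheme = "davidson")
  } else {
    E <- if (emission == "yearly") 3.5e-6 else 0.33e-3
    sc <- scenario(paste0("koivisto-", emission), E = E, H = 3,
                   dp = 280, rho = 2100, U = 2.5, T_K = 288.15, Hpbl = 1000,
                   stability = stability_classes(), scheme = "davidson")
  }
  sc
}

.scenario_velocity_model <- function(sc) {
  if (!is.null(sc$dp)) rannik_model() else fixed_velocities(sc$vset, sc$vdep)
}

#' Run a scenario
#'
#' Fits one [plume_model()] per requested stability class, forms the
#' climatology-weighted yearly average profiles when all six classes are
#' present, and assembles an exposure report: per-class and worst-case maximum
#' ground concentrations with their distances, deposited fraction within the
#' domain, x50, near-field/far-field compartment concentrations (when x50 is
#' inside the domain), and PECsoil / PEC-PNEC ratios at the requested
#' accumulation times (evaluated at the distance of maximum flux on the plume
#' centerline, a fixed-wind-direction worst case).
#'
#' @param sc a [scenario()].
#' @param grid downwind grid m, see [plume_grid()].
#' @param model plume variant, see [plume_model()].
#' @param quiet suppress solver warnings (image-series clamping) during batch
#'   runs.
#' @return Object of class `"scenario_report"`.
#' @export
run_scenario <- function(sc, grid = plume_grid(10, sc$xmax, 50),
                         model = "rao_mass_balanced", quiet = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  src <- point_source(sc$E, sc$H)
  vm <- .scenario_velocity_model(sc)
  p <- if (!is.null(sc$dp)) particle(sc$dp, sc$rho)
  fits <- list()
  for (cl in sc$stability) {
    atm <- atmosphere(sc$U, sc$T_K, sc$Hpbl, cl, sc$scheme)
    f <- function() plume_model(src, atm, particle = p, velocities = vm,
                                model = model, grid = grid, z_ref = sc$z_ref)
    fits[[cl]] <- if (quiet) suppressWarnings(f()) else f()
  }
  per_class <- do.call(rbind, lapply(names(fits), function(cl) {
    s <- summary(fits[[cl]])
    data.frame(class = cl, cmax = s$cmax, x_at_max = s$x_at_max,
               x50 = s$x50, fdep_total = s$fdep_total)
  }))
  iworst <- which.max(per_class$cmax)
  vel <- fits[[1L]]$velocities
  report <- list(scenario = sc, fits = fits, per_class = per_class,
                 worst = as.list(per_class[iworst, ]),
                 vset = vel$vset, vdep = vel$vdep)

  weighted <- NULL
  if (length(fits) == 6L && !is.null(sc$climatology)) {
    avg <- stability_average(fits, sc$climatology)
    i_c <- which.max(avg$conc_ground)
    i_f <- which.max(avg$flux)
    n <- nrow(avg)
    weighted <- list(profile = avg,
                     cmax = avg$conc_ground[i_c], x_at_max = avg$x[i_c],
                     flux_max = avg$flux[i_f], x_at_flux_max = avg$x[i_f],
                     fdep_total = avg$fdep[n],
                     x50 = .log_crossing(avg$x, cummax(avg$fdep), 0.5))
  }
  report$weighted <- weighted

  # soil accumulation at the flux maximum (centerline worst case)
  flux_for_soil <- if (!is.null(weighted)) weighted$flux_max
                   else max(fits[[1L]]$flux)
  pec <- pec_soil(flux_for_soil, sc$years, sc$soil)
  report$pec <- data.frame(years = sc$years, pec_g_per_kg = pec,
                           pec_pnec = pec_pnec_ratio(pec, sc$soil$pnec))

  x50_for_nf <- if (!is.null(weighted)) weighted$x50 else per_class$x50[1L]
  if (is.finite(x50_for_nf) && vel$vdep > 0 && x50_for_nf < sc$xmax) {
    report$nf_ff <- nf_ff_concentrations(sc$E, vel$vdep, x50_for_nf, sc$xmax)
  }
  class(report) <- "scenario_report"
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("== Scenario report:", x$scenario$name, "==\n")
  cat(sprintf("vset = %.3g m/s, vdep = %.3g m/s\n", x$vset, x$vdep))
  cat("\nPer stability class:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("\nWorst class %s: Cmax = %.4g g/m3 at %.4g m\n",
              x$worst$class, x$worst$cmax, x$worst$x_at_max))
  if (!is.null(x$weighted)) {
    w <- x$weighted
    cat(sprintf("Climatology-weighted: Cmax = %.4g g/m3 at %.4g m; deposited within domain %.1f%%; x50 %s\n",
                w$cmax, w$x_at_max, 100 * w$fdep_total,
                if (is.finite(w$x50)) sprintf("%.4g m", w$x50) else "beyond domain"))
    cat(sprintf("  max deposition flux %.4g g/m2/s at %.4g m\n",
                w$flux_max, w$x_at_flux_max))
  }
  cat("\nSoil accumulation at the flux maximum:\n")
  print(x$pec, row.names = FALSE, digits = 4)
  if (!is.null(x$nf_ff)) {
    cat(sprintf("\nNF/FF compartments: CN = %.4g g/m3, CF = %.4g g/m3\n",
                x$nf_ff$CN, x$nf_ff$CF))
  }
  invisible(x)
}

#' Serialize a scenario report to JSON
#'
#' Writes the scalar results (per-class table, worst case, weighted summary,
#' PECsoil table, NF/FF concentrations, velocities, units) as JSON. Profiles
#' are exported separately with [utils::write.csv()] on
#' `as.data.frame(fit)` if needed. The output carries no timestamps, so
#' identical runs produce byte-identical reports.
#'
#' @param report a `"scenario_report"`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "scenario_report"))
  w <- report$weighted
  obj <- list(
    scenario = report$scenario$name,
    units = list(concentration = "g/m3", flux = "g/m2/s", distance = "m",
                 velocity = "m/s", pec = "g/kg"),
    vset = report$vset, vdep = report$vdep,
    per_class = report$per_class,
    worst = report$worst,
    weighted = if (!is.null(w)) w[setdiff(names(w), "profile")],
    pec = report$pec,
    nf_ff = report$nf_ff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
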