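# Physical constants used by the aerosol mechanics. Mean free path reference
# value 66.4 nm at 293.15 K and 101325 Pa; Sutherland constant 110.4 K.
.const <- list(
  g = 9.80665,          # m/s^2
  kB = 1.380649e-23,    # J/K
  P0 = 101325,          # Pa
  T0 = 293.15,          # K
  lambda0 = 66.4e-9,    # m
  sutherland = 110.4,   # K
  R_air = 287.05        # J/(kg K)
)

#' Particle specification
#'
#' @param dp particle diameter in nm (> 0).
#' @param rho material or effective particle density in kg/m3 (> 0).
#' @return An object of class `"particle"` (diameter stored in m).
#' @examples
#' particle(dp = 280, rho = 2100)
#' @export
particle <- function(dp, rho) {
  stopifnot(is.numeric(dp), length(dp) == 1L, dp > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0)
  out <- list(dp = dp * 1e-9, dp_nm = dp, rho = rho)
  class(out) <- "particle"
  out
}

#' @export
print.particle <- function(x, ...) {
  cat(sprintf("Particle: dp = %g nm, rho = %g kg/m3\n", x$dp_nm, x$rho))
  invisible(x)
}

#' Dynamic viscosity of air
#'
#' Sutherland's law, valid over the tropospheric temperature range.
#'
#' @param T_K temperature in K.
#' @return Viscosity in Pa s.
#' @export
air_viscosity <- function(T_K) {
  stopifnot(all(T_K > 0))
  1.458e-6 * T_K^1.5 / (T_K + .const$sutherland)
}

#' Mean free path of air molecules
#'
#' Scaled from the reference value 66.4 nm (293.15 K, 101325 Pa) with the
#' Sutherland temperature correction.
#'
#' @param T_K temperature in K.
#' @param P pressure in Pa.
#' @return Mean free path in m.
#' @export
mean_free_path <- function(T_K, P = .const$P0) {
  stopifnot(all(T_K > 0), all(P > 0))
  .const$lambda0 * (.const$P0 / P) * (T_K / .const$T0) *
    (1 + .const$sutherland / .const$T0) / (1 + .const$sutherland / T_K)
}

#' Cunningham slip correction factor
#'
#' Allen-Raabe form `1 + Kn (1.257 + 0.4 exp(-1.1/Kn))` with Knudsen number
#' `Kn = 2 lambda / dp`. Always >= 1; tends to 1 for particles much larger
#' than the gas mean free path.
#'
#' @param dp_m particle diameter in m (vectorised).
#' @param T_K temperature in K.
#' @param P pressure in Pa.
#' @return Dimensionless slip correction factor.
#' @export
cunningham_slip <- function(dp_m, T_K = 288.15, P = .const$P0) {
  stopifnot(all(dp_m > 0))
  Kn <- 2 * mean_free_path(T_K, P) / dp_m
  1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
}

#' Gravitational settling velocity
#'
#' Stokes settling with Cunningham slip correction,
#' \eqn{v_{set} = g \rho C_c d_p^2 / (18 \eta)}.
#'
#' @param p a [particle()].
#' @param T_K air temperature in K.
#' @param P ambient pressure in Pa.
#' @return Settling velocity in m/s (>= 0, linear in `rho`).
#' @examples
#' settling_velocity(particle(1000, 1000), T_K = 293.15)  # ~3.5e-5 m/s
#' @export
settling_velocity <- function(p, T_K = 288.15, P = .const$P0) {
  stopifnot(inherits(p, "particle"), T_K > 0)
  Cc <- cunningham_slip(p$dp, T_K, P)
  .const$g * p$rho * Cc * p$dp^2 / (18 * air_viscosity(T_K))
}

.brownian_diffusivity <- function(dp_m, T_K, P = .const$P0) {
  Cc <- cunningham_slip(dp_m, T_K, P)
  .const$kB * T_K * Cc / (3 * pi * air_viscosity(T_K) * dp_m)
}

#' Deposition velocity models
#'
#' A pluggable description of how the dry deposition velocity is obtained:
#'
#' * `fixed_velocities(vset, vdep)` - both velocities are user inputs
#'   (generic-pollutant mode); they are returned unchanged.
#' * `rannik_model(...)` - resistance model for a rough vegetated canopy,
#'   `vdep = vset + 1/(ra + rc)`. The aerodynamic resistance is the neutral
#'   logarithmic profile `ra = ln(zref/z0)/(kappa ustar)` and the canopy
#'   (surface) resistance is `rc = 1/(ustar * eff)` with collection efficiency
#'   `eff = Sc^(-2/3) + (St/(1+St))^2 + 0.5 (dp/A_in)^2`: Brownian diffusion,
#'   inertial impaction on needle-scale obstacles (`impactor`, Stokes number
#'   `St = vset ustar / (g impactor)`), and interception on fine canopy
#'   micro-elements of scale `collector` (`A_in`). Defaults are calibrated for
#'   a pine-forest-like surface so that vdep(dp) over 10-500 nm is U-shaped
#'   with its minimum near 100 nm in the 0.05-0.5 cm/s decade and
#'   vdep(10 nm)/vdep(100 nm) of order 10.
#' * `lookup_velocities(table)` - user-supplied dp (nm) to vdep (m/s) table,
#'   interpolated linearly in log(dp); settling is computed from Stokes law.
#'
#' @param vset,vdep fixed settling and deposition velocities in m/s.
#' @param ustar friction velocity in m/s.
#' @param z0 roughness length in m.
#' @param zref reference (measurement) height in m.
#' @param collector characteristic interception scale of fine canopy
#'   micro-elements in m.
#' @param impactor characteristic obstacle size governing inertial impaction
#'   in m (needle scale).
#' @param kappa von Karman constant.
#' @param table data frame or matrix with columns `dp_nm`, `vdep_m_s`, or a
#'   path to a two-column CSV.
#' @return An object of class `"velocity_model"`.
#' @seealso [particle_velocities()]
#' @export
fixed_velocities <- function(vset, vdep) {
  stopifnot(is.numeric(vset), length(vset) == 1L, vset >= 0,
            is.numeric(vdep), length(vdep) == 1L, vdep >= 0)
  structure(list(mode = "fixed", vset = vset, vdep = vdep),
            class = "velocity_model")
}

#' @rdname fixed_velocities
#' @export
rannik_model <- function(ustar = 0.45, z0 = 1, zref = 10,
                         collector = 5e-6, impactor = 1e-3, kappa = 0.4) {
  stopifnot(ustar > 0, z0 > 0, zref > z0, collector > 0, impactor > 0,
            kappa > 0)
  structure(list(mode = "rannik", ustar = ustar, z0 = z0, zref = zref,
                 collector = collector, impactor = impactor, kappa = kappa),
            class = "velocity_model")
}

#' @rdname fixed_velocities
#' @export
lookup_velocities <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table)
  table <- as.data.frame(table)
  if (ncol(table) < 2L) stop("lookup table needs columns dp_nm, vdep_m_s")
  names(table)[1:2] <- c("dp_nm", "vdep_m_s")
  stopifnot(all(table$dp_nm > 0), all(table$vdep_m_s >= 0), nrow(table) >= 2L)
  table <- table[order(table$dp_nm), ]
  structure(list(mode = "lookup", table = table), class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  switch(x$mode,
    fixed = cat(sprintf("Velocity model: fixed (vset = %g m/s, vdep = %g m/s)\n",
                        x$vset, x$vdep)),
    rannik = cat(sprintf(
      "Velocity model: canopy resistance (ustar = %g m/s, z0 = %g m, zref = %g m, collector = %g um)\n",
      x$ustar, x$z0, x$zref, x$collector * 1e6)),
    lookup = cat(sprintf("Velocity model: lookup table (%d sizes, %g-%g nm)\n",
                         nrow(x$table), min(x$table$dp_nm), max(x$table$dp_nm))))
  invisible(x)
}

#' Settling and deposition velocities for a particle
#'
#' Resolves a [velocity model][fixed_velocities] for a particle and ambient
#' temperature into the pair (vset, vdep) used by the plume solver. In
#' computed modes `vdep >= vset` by construction; in fixed mode the configured
#' values pass through unchanged (no particle needed).
#'
#' @param model a `"velocity_model"`.
#' @param p a [particle()] (required except in fixed mode).
#' @param T_K air temperature in K.
#' @param P ambient pressure in Pa.
#' @return List with components `vset` and `vdep` in m/s and, for the
#'   resistance model, `ra` and `rc` in s/m.
#' @examples
#' particle_velocities(rannik_model(), particle(100, 1000), T_K = 288.15)
#' @export
particle_velocities <- function(model, p = NULL, T_K = 288.15, P = .const$P0) {
  stopifnot(inherits(model, "velocity_model"))
  if (model$mode == "fixed") {
    return(list(vset = model$vset, vdep = model$vdep))
  }
  if (is.null(p)) {
    stop("a particle specification is required in '", model$mode, "' mode",
         call. = FALSE)
  }
  stopifnot(inherits(p, "particle"))
  vset <- settling_velocity(p, T_K, P)
  if (model$mode == "lookup") {
    tab <- model$table
    vdep <- stats::approx(log(tab$dp_nm), tab$vdep_m_s, xout = log(p$dp_nm),
                          rule = 2)$y
    return(list(vset = vset, vdep = max(vdep, vset)))
  }
  # canopy resistance mode
  eta <- air_viscosity(T_K)
  rho_air <- P / (.const$R_air * T_K)
  nu <- eta / rho_air
  Sc <- nu / .brownian_diffusivity(p$dp, T_K, P)
  St <- vset * model$ustar / (.const$g * model$impactor)
  eff <- Sc^(-2 / 3) + (St / (1 + St))^2 + 0.5 * (p$dp / model$collector)^2
  ra <- log(model$zref / model$z0) / (model$kappa * model$ustar)
  rc <- 1 / (model$ustar * eff)
  if (ra + rc <= 0) stop("total resistance must be positive", call. = FALSE)
  list(vset = vset, vdep = vset + 1 / (ra + rc), ra = ra, rc = rc)
}
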