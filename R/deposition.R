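#' Ground deposition flux
#'
#' Magnitude of the dry deposition flux to ground, `F(x, y) = vdep * C(x, y,
#' z_ref)`, evaluated from the corrected concentration field of a fitted
#' model. The sign convention is that magnitudes are reported; the flux is
#' directed towards the ground. The crosswind dependence is the plume's
#' Gaussian factor, so `flux(x, y) = flux(x, 0) * exp(-y^2 / (2 sigma_y^2))`.
#'
#' @param object a [plume_model()] fit.
#' @param x downwind distance m (> 0).
#' @param y crosswind offset m.
#' @return Flux in g/m2/s (>= 0).
#' @export
deposition_flux <- function(object, x, y = 0) {
  stopifnot(inherits(object, "plume_model"))
  object$velocities$vdep * predict(object, x, y, object$z_ref)
}

#' Cumulative deposition and the deposited fraction
#'
#' `net_deposition_rate()` returns the mass deposition rate (g/s) integrated
#' over the full crosswind extent from the source out to distance `x`;
#' `deposited_fraction()` divides it by the emission rate. Values are
#' interpolated (linearly in log x for the fraction) from the model grid.
#'
#' @param object a [plume_model()] fit.
#' @param x downwind distance m; must lie within the model grid.
#' @return g/s, respectively a dimensionless fraction.
#' @export
net_deposition_rate <- function(object, x) {
  stopifnot(inherits(object, "plume_model"))
  if (any(x < object$x[1] | x > object$xtot)) {
    stop("x outside the model grid [", object$x[1], ", ", object$xtot, "] m",
         call. = FALSE)
  }
  stats::approx(log10(object$x), object$Rdep, xout = log10(x))$y
}

#' @rdname net_deposition_rate
#' @export
deposited_fraction <- function(object, x) {
  net_deposition_rate(object, x) / object$src$E
}

#' Suspended mass fraction
#'
#' Fraction of the emitted mass still airborne while crossing the vertical
#' plane at `x`: the crosswind- and vertically-integrated horizontal flux
#' `U C` divided by the emission rate. Interpolated from the model grid.
#'
#' @param object a [plume_model()] fit.
#' @param x downwind distance m within the grid.
#' @return Dimensionless fraction.
#' @export
suspended_fraction <- function(object, x) {
  stopifnot(inherits(object, "plume_model"))
  if (any(x < object$x[1] | x > object$xtot)) {
    stop("x outside the model grid", call. = FALSE)
  }
  stats::approx(log10(object$x), object$fsusp, xout = log10(x))$y
}

#' Distance of 50 percent deposition (x50)
#'
#' The downwind distance at which half of the emitted mass has deposited,
#' `fdep(x50) = 0.5`, obtained by log-linear interpolation between the
#' bracketing grid points. When less than half the mass deposits within the
#' domain the result is `Inf` (beyond-domain sentinel). The deposited-fraction
#' profile must be nondecreasing.
#'
#' @param object a [plume_model()] fit, or a list/data frame with components
#'   `x` and `fdep`.
#' @param level crossing level (0.5 for x50).
#' @return Distance in m, or `Inf`.
#' @export
x50_distance <- function(object, level = 0.5) {
  if (inherits(object, "plume_model")) {
    x <- object$x; f <- object$fdep
  } else {
    x <- object$x; f <- object$fdep
    if (is.null(x) || is.null(f)) stop("need components x and fdep")
  }
  if (any(diff(f) < -1e-9)) {
    stop("deposited fraction profile is not monotone; internal inconsistency",
         call. = FALSE)
  }
  .log_crossing(x, cummax(f), level)
}
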