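#' Logarithmic downwind evaluation grid
#'
#' Geometric grid from `xmin` to `xmax` with a fixed number of points per
#' decade (the end point is always included). The default spans 10 m to
#' 500 km at 50 points per decade, the scale on which the deposition
#' integrals and the x50 metric are evaluated.
#'
#' @param xmin,xmax grid limits in m (0 < xmin < xmax).
#' @param points_per_decade grid density (>= 2).
#' @return Numeric vector of distances in m.
#' @export
plume_grid <- function(xmin = 10, xmax = 5e5, points_per_decade = 50) {
  stopifnot(xmin > 0, xmax > xmin, points_per_decade >= 2)
  lx <- seq(log10(xmin), log10(xmax), by = 1 / points_per_decade)
  x <- 10^lx
  if (x[length(x)] < xmax * (1 - 1e-12)) x <- c(x, xmax)
  x[length(x)] <- xmax
  x
}

.resolve_velocities <- function(velocities, particle, T_K) {
  if (is.null(velocities)) {
    if (is.null(particle)) stop("supply either 'velocities' or 'particle'")
    velocities <- rannik_model()
  }
  particle_velocities(velocities, particle, T_K)
}

#' Fit a dispersion-and-deposition plume model
#'
#' Solves a steady-state point-source plume on a logarithmic downwind grid and
#' derives the deposition bookkeeping used for exposure screening: the
#' centerline ground-level concentration, the ground deposition flux, the
#' cumulative deposited fraction `fdep(x)`, the suspended fraction `fsusp(x)`,
#' the half-deposited distance `x50`, and the maximum ground-level
#' concentration with its distance.
#'
#' Model variants: `"classic"` (no deposition, unbounded), `"ermak"`
#' (deposition, unbounded), `"rao"` (deposition plus boundary-layer image
#' reflections), and the default `"rao_mass_balanced"`, which additionally
#' rescales the concentration field at every grid distance by iterating
#' `C <- C/(fdep(x)+fsusp(x))` until deposited plus suspended mass fractions
#' balance the emission (|1 - fdep - fsusp| below `tol` at each x). The
#' correction marches outward in x so that the cumulative deposition integral
#' always uses already-balanced upstream fluxes.
#'
#' The suspended fraction integrates the crosswind-integrated horizontal flux
#' over z in [0, Hpbl] for the reflected solutions (image sources fold all
#' mass into the layer) and over [0, H + 12 sigma_z] for the unbounded ones.
#'
#' @param src a [point_source()] (E in g/s, H in m).
#' @param atm an [atmosphere()].
#' @param particle optionally a [particle()]; with `velocities = NULL` the
#'   default canopy resistance model [rannik_model()] is applied to it.
#' @param velocities optionally a [velocity model][fixed_velocities].
#' @param model one of `"rao_mass_balanced"`, `"rao"`, `"ermak"`, `"classic"`.
#' @param grid downwind grid in m, see [plume_grid()].
#' @param z_ref ground-level evaluation height in m (2 m convention).
#' @param j_max reflection truncation order for the image series.
#' @param tol mass-balance tolerance on |1 - fdep - fsusp|.
#' @param max_iter iteration cap per grid point for the correction.
#' @return An object of class `"plume_model"`; see [as.data.frame.plume_model()]
#'   for the per-distance profile and [summary.plume_model()] for the scalar
#'   summaries.
#' @examples
#' m <- plume_model(point_source(29e-6, 7.8),
#'                  atmosphere(2.5, 288.15, 1000, "d", "davidson"),
#'                  particle = particle(260, 940))
#' summary(m)
#' @export
plume_model <- function(src, atm, particle = NULL, velocities = NULL,
                        model = c("rao_mass_balanced", "rao", "ermak", "classic"),
                        grid = plume_grid(), z_ref = 2, j_max = 10L,
                        tol = 0.01, max_iter = 100L) {
  model <- match.arg(model)
  stopifnot(inherits(src, "point_source"), inherits(atm, "atmosphere"),
            z_ref >= 0, all(diff(grid) > 0))
  if (model == "classic") {
    vel <- list(vset = 0, vdep = 0)
  } else {
    vel <- .resolve_velocities(velocities, particle, atm$T_K)
  }
  x <- as.numeric(grid)
  sy <- sigma_y(x, atm$stability, atm$scheme)
  sz <- sigma_z(x, atm$stability, atm$scheme)
  j <- if (model %in% c("rao", "rao_mass_balanced")) seq.int(-j_max, j_max) else 0L

  # uncorrected centerline ground concentration
  c0 <- .conc_kernel(x, rep(z_ref, length(x)), src$E, src$H, atm$U, sy, sz,
                     vel$vset, vel$vdep, atm$Hpbl, j)

  # suspended fraction of the uncorrected field:
  # fsusp(x) = U sqrt(2 pi) sigma_y / E * int C(x,0,z) dz
  n <- length(x)
  susp0 <- numeric(n)
  for (i in seq_len(n)) {
    zmax <- if (length(j) > 1L) atm$Hpbl else max(atm$Hpbl, src$H + 12 * sz[i])
    nd <- .vertical_nodes(src$H, sz[i], zmax)
    cz <- .conc_kernel(rep(x[i], length(nd$z)), nd$z, src$E, src$H, atm$U,
                       rep(sy[i], length(nd$z)), rep(sz[i], length(nd$z)),
                       vel$vset, vel$vdep, atm$Hpbl, j)
    susp0[i] <- atm$U * sqrt(2 * pi) * sy[i] * sum(nd$w * cz) / src$E
  }

  # crosswind-integrated deposition flux of the uncorrected field, g/(m s)
  w0 <- vel$vdep * sqrt(2 * pi) * sy * c0

  phi <- rep(1, n)
  iters <- integer(n)
  if (model == "rao_mass_balanced") {
    # forward march: balance each grid point against converged upstream mass
    D <- 0            # cumulative deposition rate g/s up to previous point
    w_prev <- 0
    x_prev <- 0
    for (i in seq_len(n)) {
      dx <- x[i] - x_prev
      balance <- function(p) {
        (D + .flux_segment(w_prev, w0[i] * p, dx)) / src$E + susp0[i] * p
      }
      it <- 0L
      repeat {
        res <- balance(phi[i])
        if (abs(1 - res) < min(tol, 1e-6) || it >= max_iter) break
        phi[i] <- phi[i] / res
        it <- it + 1L
      }
      iters[i] <- it
      if (abs(1 - balance(phi[i])) >= min(tol, 1e-6) && w0[i] > 0) {
        # stalled fixed point (nearly exhausted plume); bracketed root solve
        root <- try(stats::uniroot(function(p) balance(p) - 1,
                                   lower = 0, upper = max(phi[i], 1) * 1e3,
                                   tol = 1e-12)$root, silent = TRUE)
        if (!inherits(root, "try-error")) phi[i] <- root
      }
      if (abs(1 - balance(phi[i])) >= tol) {
        warning(sprintf(
          "mass balance not converged at x = %.3g m (residual %.3g)",
          x[i], 1 - balance(phi[i])))
      }
      D <- D + .flux_segment(w_prev, w0[i] * phi[i], dx)
      w_prev <- w0[i] * phi[i]
      x_prev <- x[i]
    }
  }

  conc <- c0 * phi
  wflux <- w0 * phi                 # crosswind-integrated flux
  flux <- vel$vdep * conc           # centerline areal flux magnitude
  dxs <- diff(c(0, x))
  seg <- vapply(seq_len(n), function(i)
    .flux_segment(if (i == 1L) 0 else wflux[i - 1L], wflux[i], dxs[i]),
    numeric(1))
  Rdep <- cumsum(seg)
  fdep <- Rdep / src$E
  fsusp <- susp0 * phi
  imax <- which.max(conc)

  out <- list(
    call = match.call(), model = model, src = src, atm = atm,
    particle = particle, velocities = vel, z_ref = z_ref, j_max = j_max,
    x = x, sigma_y = sy, sigma_z = sz,
    conc_ground = conc, correction = phi, flux = flux,
    crosswind_flux = wflux, Rdep = Rdep, fdep = fdep, fsusp = fsusp,
    x50 = .log_crossing(x, fdep, 0.5), xtot = x[n],
    cmax = conc[imax], x_at_max = x[imax],
    worst_residual = if (model == "rao_mass_balanced")
      max(abs(1 - fdep - fsusp)) else NA_real_,
    iterations = iters)
  class(out) <- "plume_model"
  out
}

#' @export
print.plume_model <- function(x, digits = 4, ...) {
  cat("Point-source dispersion/deposition model (", x$model, ")\n", sep = "")
  print(x$src); print(x$atm)
  cat(sprintf("  vset = %.3g m/s, vdep = %.3g m/s\n",
              x$velocities$vset, x$velocities$vdep))
  cat(sprintf("  grid: %d points, %.3g m - %.3g km\n",
              length(x$x), x$x[1], x$xtot / 1000))
  cat(sprintf("  max ground conc (z = %g m): %.4g g/m3 at %.4g m\n",
              x$z_ref, x$cmax, x$x_at_max))
  if (is.finite(x$x50)) {
    cat(sprintf("  x50 (half deposited): %.4g m\n", x$x50))
  } else {
    cat(sprintf("  x50 beyond domain (fdep at %.0f km = %.1f%%)\n",
                x$xtot / 1000, 100 * max(x$fdep)))
  }
  invisible(x)
}

#' Summarise a plume model
#'
#' @param object a [plume_model()] fit.
#' @param ... unused.
#' @return A list of scalar summaries: `cmax` (g/m3), `x_at_max` (m), `x50`
#'   (m, `Inf` when half the mass is not deposited inside the domain),
#'   `fdep_total` and `fsusp_total` at the domain edge, the velocities, and
#'   the worst mass-balance residual.
#' @export
summary.plume_model <- function(object, ...) {
  n <- length(object$x)
  out <- list(model = object$model, cmax = object$cmax,
              x_at_max = object$x_at_max, x50 = object$x50,
              xtot = object$xtot,
              fdep_total = object$fdep[n], fsusp_total = object$fsusp[n],
              vset = object$velocities$vset, vdep = object$velocities$vdep,
              worst_residual = object$worst_residual)
  class(out) <- "summary.plume_model"
  out
}

#' @export
print.summary.plume_model <- function(x, ...) {
  cat(sprintf("model: %s\n", x$model))
  cat(sprintf("max ground concentration: %.4g g/m3 at %.4g m\n",
              x$cmax, x$x_at_max))
  cat(sprintf("x50: %s\n",
              if (is.finite(x$x50)) sprintf("%.4g m", x$x50)
              else sprintf("beyond %.0f km", x$xtot / 1000)))
  cat(sprintf("deposited within domain: %.2f%%, suspended: %.2f%%\n",
              100 * x$fdep_total, 100 * x$fsusp_total))
  cat(sprintf("vset = %.3g m/s, vdep = %.3g m/s\n", x$vset, x$vdep))
  invisible(x)
}

#' Per-distance profile of a plume model
#'
#' @param x a [plume_model()] fit.
#' @param row.names,optional,... passed on conventions of the generic; unused.
#' @return A data frame with one row per grid distance: dispersion parameters,
#'   corrected centerline ground concentration (g/m3), mass-balance
#'   correction factor, centerline deposition flux (g/m2/s),
#'   crosswind-integrated flux (g/m/s), cumulative deposition rate (g/s), and
#'   the deposited/suspended fractions.
#' @export
as.data.frame.plume_model <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(x = x$x, sigma_y = x$sigma_y, sigma_z = x$sigma_z,
             conc_ground = x$conc_ground, correction = x$correction,
             flux = x$flux, crosswind_flux = x$crosswind_flux,
             Rdep = x$Rdep, fdep = x$fdep, fsusp = x$fsusp)
}

#' Predict concentrations from a fitted plume model
#'
#' Evaluates the (mass-balance corrected, when applicable) concentration at
#' arbitrary receptor locations. The correction factor is interpolated
#' log-linearly in x between grid points.
#'
#' @param object a [plume_model()] fit.
#' @param x downwind distance m (> 0), vectorised.
#' @param y crosswind offset m.
#' @param z receptor height m; defaults to the model's ground reference.
#' @param ... unused.
#' @return Concentrations in g/m3.
#' @export
predict.plume_model <- function(object, x, y = 0, z = object$z_ref, ...) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  .check_query(x, z)
  atm <- object$atm
  sy <- sigma_y(x, atm$stability, atm$scheme)
  sz <- sigma_z(x, atm$stability, atm$scheme)
  j <- if (object$model %in% c("rao", "rao_mass_balanced"))
    seq.int(-object$j_max, object$j_max) else 0L
  conc <- .conc_kernel(x, z, object$src$E, object$src$H, atm$U, sy, sz,
                       object$velocities$vset, object$velocities$vdep,
                       atm$Hpbl, j) * .crosswind(y, sy)
  if (object$model == "rao_mass_balanced") {
    phi <- stats::approx(log10(object$x), object$correction, xout = log10(x),
                         rule = 2)$y
    conc <- conc * phi
  }
  conc
}

#' Plot a plume model profile
#'
#' Two-panel base-graphics display: centerline ground concentration and the
#' deposited/suspended fractions against downwind distance (log x).
#'
#' @param x a [plume_model()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plume_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$conc_ground, type = "l", log = "xy",
                 xlab = "downwind distance (m)",
                 ylab = sprintf("C(z = %g m) (g/m3)", x$z_ref), ...)
  graphics::plot(x$x, x$fdep, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "downwind distance (m)", ylab = "mass fraction")
  graphics::lines(x$x, x$fsusp, lty = 2)
  if (is.finite(x$x50)) graphics::abline(v = x$x50, col = "grey", lty = 3)
  graphics::legend("right", legend = c("deposited", "suspended"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
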