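#' Parameter sweep grids
#'
#' Full-factorial input grids spanning the physically relevant parameter
#' ranges for point-source releases:
#'
#' * `"enm"` - engineered nanomaterials, 1296 combinations: H in (2, 50) m,
#'   dp in (10, 100, 500) nm, rho in (1000, 4230, 18000) kg/m3, T in
#'   (243.15, 273.15, 303.15) K, U in (1, 10) m/s, Klug and Davidson schemes,
#'   Hpbl in (0.2, 2) km, classes (a, d, f); velocities from the canopy
#'   resistance model.
#' * `"generic"` - generic airborne pollutant, 486 combinations: H in
#'   (2, 10, 50) m, index-paired (vset, vdep) in ((0.0001, 0.01), (0.01, 0.1),
#'   (0.1, 1)) cm/s, U in (1, 2.5, 10) m/s, both schemes, Hpbl in (0.2, 1, 2)
#'   km, classes (a, d, f). The settling velocities are paired with the
#'   deposition velocities index-wise, not crossed (vset never exceeds vdep).
#'
#' Emission rate is 29 ug/s for both; results scale exactly linearly in E.
#'
#' @param type `"enm"` or `"generic"`.
#' @return Data frame, one row per combination (SI units).
#' @export
sweep_grid <- function(type = c("enm", "generic")) {
  type <- match.arg(type)
  if (type == "enm") {
    g <- expand.grid(
      H = c(2, 50), dp = c(10, 100, 500), rho = c(1000, 4230, 18000),
      T_K = c(243.15, 273.15, 303.15), U = c(1, 10),
      scheme = c("davidson", "klug"), Hpbl = c(200, 2000),
      class = c("a", "d", "f"),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    pair <- data.frame(vset = c(1e-6, 1e-4, 1e-3),
                       vdep = c(1e-4, 1e-3, 1e-2))  # m/s
    g <- expand.grid(
      H = c(2, 10, 50), pair = seq_len(nrow(pair)), U = c(1, 2.5, 10),
      scheme = c("davidson", "klug"), Hpbl = c(200, 1000, 2000),
      class = c("a", "d", "f"),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    g$vset <- pair$vset[g$pair]
    g$vdep <- pair$vdep[g$pair]
    g$pair <- NULL
    g$T_K <- 288.15
  }
  g$E <- 29e-6
  g
}

#' Run a parameter sweep
#'
#' Fits the mass-balance corrected plume model for every row of a sweep grid
#' and tabulates the screening metrics: maximum ground-level concentration and
#' its distance, the half-deposited distance x50 (`Inf` when beyond the
#' domain) and the total deposited fraction within the domain.
#'
#' @param grid a data frame from [sweep_grid()], or a sweep type name.
#' @param points_per_decade grid density of the downwind grid.
#' @param xmax domain radius m.
#' @param progress print a progress line every 100 combinations.
#' @return The input grid with columns `cmax` (g/m3), `x_at_max` (m), `x50`
#'   (m), `fdep_total`, `balanced` appended. Row order is the grid order;
#'   results are independent of execution order.
#' @export
run_sweep <- function(grid = "enm", points_per_decade = 50, xmax = 5e5,
                      progress = FALSE) {
  if (is.character(grid)) grid <- sweep_grid(grid)
  xg <- plume_grid(10, xmax, points_per_decade)
  n <- nrow(grid)
  cmax <- x_at_max <- x50 <- fdep_total <- numeric(n)
  balanced <- logical(n)
  fixed_mode <- !is.null(grid$vdep)
  for (i in seq_len(n)) {
    row <- grid[i, ]
    atm <- atmosphere(row$U, row$T_K, row$Hpbl, row$class, row$scheme)
    if (fixed_mode) {
      vm <- fixed_velocities(row$vset, row$vdep)
      p <- NULL
    } else {
      vm <- rannik_model()
      p <- particle(row$dp, row$rho)
    }
    fit <- suppressWarnings(
      plume_model(point_source(row$E, row$H), atm, particle = p,
                  velocities = vm, grid = xg))
    cmax[i] <- fit$cmax
    x_at_max[i] <- fit$x_at_max
    x50[i] <- fit$x50
    fdep_total[i] <- fit$fdep[length(fit$fdep)]
    balanced[i] <- fit$worst_residual < 0.01
    if (progress && i %% 100 == 0) {
      message(sprintf("sweep %d/%d", i, n))
    }
  }
  cbind(grid, data.frame(cmax = cmax, x_at_max = x_at_max, x50 = x50,
                         fdep_total = fdep_total, balanced = balanced))
}

#' Per-parameter sweep summary
#'
#' Median and quartiles of a sweep metric grouped by the values of one input
#' parameter (the sensitivity display of a sweep).
#'
#' @param results output of [run_sweep()].
#' @param param input column name to group by.
#' @param metric result column to summarise (default `"x50"`).
#' @return Data frame with value, n, and the 5/25/50/75/95 percentiles.
#' @export
sweep_summary <- function(results, param, metric = "x50") {
  stopifnot(param %in% names(results), metric %in% names(results))
  vals <- results[[metric]]
  out <- lapply(split(vals, results[[param]]), function(v) {
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(n = length(v), p05 = q[1], p25 = q[2], median = q[3],
               p75 = q[4], p95 = q[5])
  })
  data.frame(value = names(out), do.call(rbind, out), row.names = NULL)
}
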