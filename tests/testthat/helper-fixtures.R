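# Shared fixtures: everything is constructed in code, no stored data.

fx_src <- function(E = 29e-6, H = 7.8) point_source(E, H)

fx_atm <- function(class = "d", scheme = "davidson", U = 2.5, Hpbl = 1000,
                   T_K = 288.15) {
  atmosphere(U, T_K, Hpbl, class, scheme)
}

# quick mass-balanced fit on a coarser grid for property tests
fx_fit <- function(E = 29e-6, H = 2, vset = 1e-4, vdep = 1e-3, U = 2.5,
                   Hpbl = 1000, class = "f", scheme = "davidson",
                   ppd = 25, xmax = 5e5, model = "rao_mass_balanced") {
  suppressWarnings(plume_model(
    point_source(E, H), atmosphere(U, 288.15, Hpbl, class, scheme),
    velocities = fixed_velocities(vset, vdep), model = model,
    grid = plume_grid(10, xmax, ppd)))
}

# independently coded reflecting-plume (Yamartino-type) image sum used as the
# oracle for the depositing solution in the zero-velocity limit
yamartino_oracle <- function(x, y, z, E, H, U, sy, sz, Hpbl, j_max = 10) {
  s <- 0
  for (j in -j_max:j_max) {
    Hj <- H + 2 * j * Hpbl
    s <- s + exp(-(z - Hj)^2 / (2 * sz^2)) + exp(-(z + Hj)^2 / (2 * sz^2))
  }
  E / (2 * pi * U * sy * sz) * exp(-y^2 / (2 * sy^2)) * s
}
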