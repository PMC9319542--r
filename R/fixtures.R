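#' Generate packaged toy scenarios
#'
#' Writes a small set of ready-to-run scenario files used for examples and
#' oracle tests: the two TiO2 case-study configurations (Fonseca paint
#' factory, Koivisto spray coating) with their literature parameter values, a
#' three-combination mini sweep, and a synthetic constant-deposition-velocity
#' scenario whose cumulative deposited fraction follows the closed-form
#' well-mixed depletion law `fdep(x) = 1 - (1 - fdep(x1)) exp(-vdep (x - x1) /
#' (U Hpbl))` once the boundary layer is filled, which makes it an analytic
#' oracle for the deposition integrator.
#'
#' @param dir output directory (created if needed).
#' @param seed retained for optional randomised toys; the shipped fixtures are
#'   deterministic.
#' @return Named character vector of the files written.
#' @export
generate_fixtures <- function(dir = tempdir(), seed = 1L) {
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fonseca = file.path(dir, "fonseca.yaml"),
    koivisto = file.path(dir, "koivisto.yaml"),
    constant_vdep = file.path(dir, "constant_vdep_synthetic.yaml"),
    mini_sweep = file.path(dir, "mini_sweep.csv"))

  write_scenario(case_study("fonseca"), paths[["fonseca"]])
  write_scenario(case_study("koivisto"), paths[["koivisto"]])

  # synthetic: unstable atmosphere mixes the plume through a shallow layer
  # quickly, after which depletion is exponential with length U*Hpbl/vdep
  toy <- scenario("constant-vdep-synthetic", E = 1e-6, H = 2,
                  vset = 0, vdep = 1e-4, U = 5, T_K = 288.15, Hpbl = 200,
                  stability = "a", scheme = "klug")
  write_scenario(toy, paths[["constant_vdep"]])

  mini <- sweep_grid("generic")
  mini <- mini[c(1L, 200L, 400L), ]
  utils::write.csv(mini, paths[["mini_sweep"]], row.names = FALSE)
  paths
}
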