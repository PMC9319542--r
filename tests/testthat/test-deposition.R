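koivisto_fit <- function(class = "d", ppd = 25) {
  suppressWarnings(plume_model(
    point_source(3.5e-6, 3), fx_atm(class, Hpbl = 1000),
    particle = particle(280, 2100), grid = plume_grid(10, 5e5, ppd)))
}

test_that("deposition flux is vdep times the ground concentration", {
  fit <- koivisto_fit()
  expect_equal(fit$flux, fit$velocities$vdep * fit$conc_ground)
  expect_true(all(deposition_flux(fit, c(20, 2000), 0) >= 0))
})

test_that("zero deposition velocity gives identically zero flux", {
  fit <- fx_fit(vset = 0, vdep = 0, ppd = 10)
  expect_true(all(fit$flux == 0))
  expect_equal(max(fit$fdep), 0)
})

test_that("crosswind flux profile carries the plume's Gaussian factor", {
  fit <- koivisto_fit()
  for (x in c(20, 1000, 1e5)) {
    sy <- sigma_y(x, "d", "davidson")
    y <- c(0.5, 1, 3) * sy
    expect_equal(deposition_flux(fit, x, y) / deposition_flux(fit, x, 0),
                 exp(-y^2 / (2 * sy^2)), tolerance = 1e-9)
  }
})

test_that("analytic crosswind integration agrees with numerical quadrature", {
  fit <- koivisto_fit()
  for (x in c(20, 200, 2000, 2e4, 2e5)) {
    sy <- sigma_y(x, "d", "davidson")
    num <- stats::integrate(function(y) deposition_flux(fit, x, y),
                            -8 * sy, 8 * sy, rel.tol = 1e-10)$value
    ana <- sqrt(2 * pi) * sy * deposition_flux(fit, x, 0)
    expect_equal(num, ana, tolerance = 1e-3)
  }
})

test_that("cumulative deposition integrator matches adaptive quadrature", {
  # uncorrected solution so the reference can evaluate concentrations directly
  src <- point_source(3.5e-6, 3); atm <- fx_atm("f", Hpbl = 1000)
  fit <- suppressWarnings(plume_model(src, atm, particle = particle(280, 2100),
                                      model = "rao"))
  v <- fit$velocities
  ref <- stats::integrate(function(x)
    v$vdep * sqrt(2 * pi) * sigma_y(x, "f", "davidson") *
      conc_rao(x, 0, 2, src, atm, v$vset, v$vdep),
    10, 1e5, rel.tol = 1e-9)$value
  pkg <- net_deposition_rate(fit, 1e5) - net_deposition_rate(fit, 10)
  expect_equal(pkg, ref, tolerance = 1e-3)
})

test_that("deposition bookkeeping: fractions start at zero and grow monotonically", {
  fit <- koivisto_fit("f")
  expect_lt(fit$fdep[1], 1e-3)
  expect_true(all(diff(fit$Rdep) >= 0))
  expect_true(all(fit$fdep >= 0 & fit$fdep <= 1 + 1e-6))
  expect_error(deposited_fraction(fit, 1e7), "outside")
})

test_that("suspended fraction is one without deposition and near one close to the source", {
  nodep <- fx_fit(vset = 0, vdep = 0, class = "a", ppd = 15)
  expect_equal(nodep$fsusp, rep(1, length(nodep$x)), tolerance = 0.02)
  fit <- koivisto_fit("d")
  expect_equal(suspended_fraction(fit, 15), 1, tolerance = 0.02)
  # after correction the two fractions are complementary
  expect_equal(fit$fsusp, 1 - fit$fdep, tolerance = 0.01)
})

test_that("x50 interpolation is consistent with a 10x finer grid", {
  coarse <- fx_fit(H = 2, vset = 1e-3, vdep = 1e-2, U = 1, class = "f", ppd = 20)
  fine <- fx_fit(H = 2, vset = 1e-3, vdep = 1e-2, U = 1, class = "f", ppd = 200)
  expect_true(is.finite(coarse$x50))
  # within one coarse-grid step (factor 10^(1/20))
  expect_lt(abs(log10(coarse$x50) - log10(fine$x50)), 1 / 20)
})

test_that("x50 returns a grid point hit exactly and the beyond-domain sentinel", {
  prof <- list(x = c(10, 100, 1000), fdep = c(0.1, 0.5, 0.9))
  expect_equal(x50_distance(prof), 100)
  expect_equal(x50_distance(list(x = c(10, 100), fdep = c(0.01, 0.2))), Inf)
  expect_error(x50_distance(list(x = c(10, 100, 1000),
                                 fdep = c(0.4, 0.6, 0.3))), "monotone")
})

test_that("x50 shrinks with deposition velocity, grows with wind and stack height", {
  base <- list(H = 10, vdep = 1e-2, U = 2.5)
  f <- function(H = base$H, vdep = base$vdep, U = base$U) {
    fx_fit(H = H, vset = vdep / 10, vdep = vdep, U = U, class = "f",
           ppd = 20)$x50
  }
  x50_base <- f()
  expect_true(is.finite(x50_base))
  expect_gt(f(vdep = 1e-3), x50_base)       # less deposition -> further out
  expect_gt(f(U = 10), x50_base)            # more wind -> further out
  expect_gt(f(H = 50), x50_base)            # taller stack -> further out
  expect_lt(f(H = 2), x50_base)
})

test_that("a well-mixed constant-vdep plume follows the closed-form depletion law", {
  # unstable shallow layer: mixed within a few km, then
  # fdep(x) = 1 - (1 - fdep(x1)) exp(-vdep (x - x1)/(U Hpbl))
  fit <- suppressWarnings(plume_model(
    point_source(1e-6, 2), atmosphere(5, 288.15, 200, "a", "klug"),
    velocities = fixed_velocities(0, 1e-4)))
  x1 <- 2e4
  f1 <- deposited_fraction(fit, x1)
  x <- c(5e4, 1e5, 3e5, 5e5)
  closed <- 1 - (1 - f1) * exp(-1e-4 * (x - x1) / (5 * 200))
  expect_equal(deposited_fraction(fit, x), closed, tolerance = 5e-3)
  expect_true(all(abs(deposited_fraction(fit, x) - closed) < 0.005))
})
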