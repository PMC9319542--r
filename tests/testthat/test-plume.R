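test_that("scaled complementary error function matches reference values", {
  skip_if_not_installed("pracma")
  x <- c(-2, -0.5, 0, 0.3, 1, 5, 12, 24)
  expect_equal(erfcx_ <- nanoplume:::erfcx(x), pracma::erfcx(x),
               tolerance = 1e-12)
})

test_that("scaled erfc obeys the classical two-sided bound for large arguments", {
  # 2/(x + sqrt(x^2 + 2)) <= sqrt(pi) erfcx(x) <= 2/(x + sqrt(x^2 + 4/pi))
  x <- c(0.5, 1, 10, 24.9, 25.1, 100, 1e4)
  e <- sqrt(pi) * nanoplume:::erfcx(x)
  expect_true(all(e >= 2 / (x + sqrt(x^2 + 2))))
  expect_true(all(e <= 2 / (x + sqrt(x^2 + 4 / pi))))
})

test_that("classic plume is symmetric in y and vanishes off-axis", {
  src <- fx_src(); atm <- fx_atm("d")
  y <- c(0, 30, 120, 500)
  expect_equal(conc_classic(500, y, 2, src, atm),
               conc_classic(500, -y, 2, src, atm))
  expect_lt(conc_classic(500, 1e5, 2, src, atm), 1e-300)
})

test_that("classic plume conserves the emitted mass flux", {
  src <- fx_src(); atm <- fx_atm("d")
  for (x in c(100, 1000, 10000)) {
    sy <- sigma_y(x, "d", "davidson"); sz <- sigma_z(x, "d", "davidson")
    colz <- stats::integrate(function(z) conc_classic(x, 0, z, src, atm),
                             0, src$H + 12 * sz, rel.tol = 1e-10)$value
    expect_equal(atm$U * sqrt(2 * pi) * sy * colz / src$E, 1,
                 tolerance = 1e-6)
  }
})

test_that("depositing plume reduces exactly to the classic one at zero velocities", {
  src <- fx_src(); atm <- fx_atm("c")
  x <- c(50, 500, 5000); z <- c(0, 2, 40)
  expect_equal(conc_ermak(x, 10, z, src, atm, vset = 0, vdep = 0),
               conc_classic(x, 10, z, src, atm), tolerance = 1e-14)
})

test_that("deposition depletes the plume downwind relative to the classic solution", {
  src <- fx_src(); atm <- fx_atm("d")
  x <- 10^seq(2, 5, length.out = 20)
  ce <- conc_ermak(x, 0, 2, src, atm, vset = 1e-4, vdep = 1e-2)
  cc <- conc_classic(x, 0, 2, src, atm)
  expect_true(all(ce <= cc * (1 + 1e-12)))
  expect_lt(ce[20], 0.5 * cc[20])   # strictly smaller far downwind
  expect_true(all(ce >= 0))
})

test_that("reflected depositing solution matches an independent image-sum oracle at v = 0", {
  src <- fx_src(H = 30); atm <- fx_atm("d", Hpbl = 500)
  for (x in c(1000, 2e4, 2e5)) {
    sy <- sigma_y(x, "d", "davidson"); sz <- sigma_z(x, "d", "davidson")
    for (z in c(0, 2, 250, 499)) {
      expect_equal(conc_rao(x, 15, z, src, atm, 0, 0, j_max = 10),
                   yamartino_oracle(x, 15, z, src$E, 30, atm$U, sy, sz, 500, 10),
                   tolerance = 1e-12)
    }
  }
})

test_that("far downwind without deposition the layer is well mixed", {
  src <- fx_src(); atm <- fx_atm("a", Hpbl = 1000)
  x <- 2e5  # sigma_z capped at 5000 m >> Hpbl
  wm <- src$E / (sqrt(2 * pi) * sigma_y(x, "a", "davidson") * atm$U * 1000)
  for (z in c(0, 300, 700, 999)) {
    expect_equal(conc_rao(x, 0, z, src, atm, 0, 0, j_max = 40), wm,
                 tolerance = 0.01)
  }
})

test_that("reflection series is converged at j = +/-10 for a 1 km boundary layer", {
  src <- point_source(3.5e-6, 3)
  x <- plume_grid(10, 5e5, 10)
  for (cl in c("a", "d", "f")) {
    atm <- fx_atm(cl, Hpbl = 1000)
    c10 <- conc_rao(x, 0, 2, src, atm, 8e-6, 9e-4, j_max = 10)
    c50 <- conc_rao(x, 0, 2, src, atm, 8e-6, 9e-4, j_max = 50)
    expect_lt(max(abs(c10 - c50) / pmax(c50, max(c50) * 1e-12)), 0.01)
  }
})

test_that("all solutions agree near the source before the plume feels the lid", {
  src <- point_source(3.5e-6, 3)
  atm <- fx_atm("d", Hpbl = 1000)
  x <- plume_grid(10, 5e5, 25)
  x <- x[sigma_z(x, "d", "davidson") < 100]  # sigma_z < Hpbl/10
  vel <- particle_velocities(rannik_model(), particle(280, 2100), 288.15)
  cc <- conc_classic(x, 0, 2, src, atm)
  ce <- conc_ermak(x, 0, 2, src, atm, vel$vset, vel$vdep)
  cr <- conc_rao(x, 0, 2, src, atm, vel$vset, vel$vdep)
  keep <- cc > max(cc) * 1e-9
  expect_lt(max(abs(ce - cc)[keep] / cc[keep]), 0.05)
  expect_lt(max(abs(cr - cc)[keep] / cc[keep]), 0.05)
})

test_that("concentrations are nonnegative over a randomized query sample", {
  set.seed(42)
  src <- point_source(1e-3, 25); atm <- fx_atm("e", Hpbl = 800)
  x <- 10^runif(200, 1, 5.7)
  y <- rnorm(200, 0, 200)
  z <- runif(200, 0, 800)
  expect_true(all(conc_rao(x, y, z, src, atm, 1e-3, 1e-2) >= 0))
})

test_that("concentration scales exactly linearly with the emission rate", {
  f1 <- fx_fit(E = 29e-6, ppd = 15)
  f2 <- fx_fit(E = 58e-6, ppd = 15)
  expect_equal(f2$conc_ground, 2 * f1$conc_ground, tolerance = 1e-10)
  expect_identical(f2$x_at_max, f1$x_at_max)
  expect_equal(f2$fdep, f1$fdep, tolerance = 1e-10)
})

test_that("mass-balance correction closes the budget at every grid distance", {
  fit <- fx_fit(H = 2, vset = 1e-3, vdep = 1e-2, U = 1, class = "f", ppd = 25)
  expect_true(all(abs(1 - fit$fdep - fit$fsusp) < 0.01))
  expect_true(all(fit$correction > 0))
  expect_lt(fit$worst_residual, 0.01)
})

test_that("correction factors are near one when nothing deposits", {
  fit <- fx_fit(vset = 0, vdep = 0, class = "d", ppd = 15)
  expect_equal(fit$correction, rep(1, length(fit$x)), tolerance = 0.02)
  expect_equal(fit$fsusp, rep(1, length(fit$x)), tolerance = 0.02)
  expect_equal(max(fit$fdep), 0)
})

test_that("correction deflates the overpredicting uncorrected solution", {
  un <- fx_fit(H = 2, vset = 1e-3, vdep = 1e-2, U = 1, class = "f",
               ppd = 25, model = "rao")
  co <- fx_fit(H = 2, vset = 1e-3, vdep = 1e-2, U = 1, class = "f", ppd = 25)
  over <- un$fdep + un$fsusp > 1.02
  expect_gt(sum(over), 0)
  expect_true(all(co$conc_ground[over] <= un$conc_ground[over] * (1 + 1e-9)))
})

test_that("ground-level sources peak at the smallest simulated distance", {
  fit <- fx_fit(H = 2, vset = 0, vdep = 1e-3, class = "d", ppd = 25)
  expect_equal(fit$x_at_max, 10)
})

test_that("predict() reproduces the grid solution and the crosswind factor", {
  fit <- fx_fit(ppd = 25)
  i <- c(10, 60, 110)
  expect_equal(predict(fit, fit$x[i]), fit$conc_ground[i], tolerance = 1e-9)
  r <- predict(fit, 1000, y = 50) / predict(fit, 1000, y = 0)
  expect_equal(r, exp(-0.5 * (50 / sigma_y(1000, "f", "davidson"))^2),
               tolerance = 1e-9)
})

test_that("domain errors are raised for invalid queries", {
  src <- fx_src(); atm <- fx_atm()
  expect_error(conc_classic(-1, 0, 2, src, atm), "x must be")
  expect_error(conc_rao(100, 0, -2, src, atm), "z must be")
  expect_error(conc_rao(100, 0, 2, src, atm, j_max = 0))
})
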