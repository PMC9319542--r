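test_that("quantities with unit suffixes parse to SI", {
  expect_equal(parse_quantity("29 ug/s", "g/s"), 29e-6)
  expect_equal(parse_quantity("0.33 mg/s", "g/s"), 0.33e-3)
  expect_equal(parse_quantity("0.51 g/h", "g/s"), 0.51 / 3600)
  expect_equal(parse_quantity("20 mg/min", "g/s"), 20e-3 / 60)
  expect_equal(parse_quantity("1 km", "m"), 1000)
  expect_equal(parse_quantity("260 nm", "m"), 260e-9)
  expect_equal(parse_quantity("0.01 cm/s", "m/s"), 1e-4)
  expect_equal(parse_quantity("940 kg/m3", "kg/m3"), 940)
  expect_equal(parse_quantity("15 C", "K"), 288.15)
  expect_equal(parse_quantity(2.5, "m/s"), 2.5)
  expect_error(parse_quantity("29 stone/s", "g/s"), "unknown unit")
  expect_error(parse_quantity("fast", "m/s"), "cannot parse")
})

test_that("scenario validation enforces exactly one particle description", {
  expect_error(scenario("x", E = 1e-6, H = 2, U = 2), "exactly one")
  expect_error(scenario("x", E = 1e-6, H = 2, U = 2, dp = 100, rho = 1000,
                        vdep = 1e-3, vset = 0), "exactly one")
  expect_error(scenario("x", E = 1e-6, H = 2, U = 2, dp = 100), "both dp and rho")
  sc <- scenario("x", E = 1e-6, H = 2, U = 2, vset = 0, vdep = 1e-3)
  expect_s3_class(sc, "scenario")
})

test_that("scenario files round-trip through parse and serialize", {
  sc <- case_study("fonseca")
  p1 <- tempfile(fileext = ".yaml"); p2 <- tempfile(fileext = ".yaml")
  write_scenario(sc, p1)
  rt <- read_scenario(p1)
  for (field in c("E", "H", "dp", "rho", "U", "T_K", "Hpbl", "stability",
                  "scheme", "xmax")) {
    expect_equal(rt[[field]], sc[[field]], label = field)
  }
  # serialize(parse(serialize(...))) is idempotent
  write_scenario(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("case studies carry the literature parameter values", {
  fo <- case_study("fonseca")
  expect_equal(fo$E, 29e-6)
  expect_equal(fo$H, 7.8)
  expect_equal(fo$dp, 260)
  expect_equal(fo$rho, 940)
  fo_act <- case_study("fonseca", "activity")
  expect_equal(fo_act$E, 0.14e-3)
  ko <- case_study("koivisto")
  expect_equal(ko$E, 3.5e-6)
  expect_equal(ko$H, 3)
  expect_equal(ko$dp, 280)
  expect_equal(ko$rho, 2100)
  expect_equal(case_study("koivisto", "activity")$E, 0.33e-3)
  for (sc in list(fo, ko)) {
    expect_equal(sc$U, 2.5); expect_equal(sc$T_K, 288.15)
    expect_equal(sc$Hpbl, 1000); expect_equal(sc$scheme, "davidson")
    expect_equal(sc$stability, stability_classes())
  }
})

test_that("sweep grids expand to the documented combination counts", {
  enm <- sweep_grid("enm")
  expect_equal(nrow(enm), 1296)
  expect_equal(nrow(unique(enm)), 1296)
  gen <- sweep_grid("generic")
  expect_equal(nrow(gen), 486)
  # index-paired velocities: only the three (vset, vdep) pairs occur
  expect_equal(nrow(unique(gen[, c("vset", "vdep")])), 3)
  expect_true(all(gen$vdep > gen$vset))
})

test_that("sweep runner tabulates one row per combination", {
  mini <- sweep_grid("generic")[c(1, 200, 400), ]
  res <- run_sweep(mini, points_per_decade = 15)
  expect_equal(nrow(res), 3)
  expect_true(all(c("cmax", "x_at_max", "x50", "fdep_total") %in% names(res)))
  expect_true(all(res$cmax > 0))
  # row order is input order; rerunning a permutation gives the same table
  res2 <- run_sweep(mini[c(3, 1, 2), ], points_per_decade = 15)
  expect_equal(res2[order(res2$H, res2$vdep), ]$cmax,
               res[order(res$H, res$vdep), ]$cmax)
})

test_that("scenario reports are deterministic and serializable", {
  sc <- case_study("koivisto")
  g <- plume_grid(10, 5e5, 20)
  r1 <- run_scenario(sc, grid = g)
  r2 <- run_scenario(sc, grid = g)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  report_json(r1, f1); report_json(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(r1$per_class), 6)
  expect_true(is.finite(r1$weighted$cmax))
  expect_gt(r1$pec$pec_pnec[r1$pec$years == 100], 0)
})

test_that("fixture generator emits the documented scenario set", {
  dir <- file.path(tempdir(), "fixtures-test")
  paths <- generate_fixtures(dir, seed = 7)
  expect_true(all(file.exists(paths)))
  # the case-study configs re-read to the Table values
  fo <- read_scenario(paths[["fonseca"]])
  expect_equal(fo$E, 29e-6); expect_equal(fo$dp, 260)
  ko <- read_scenario(paths[["koivisto"]])
  expect_equal(ko$E, 3.5e-6); expect_equal(ko$H, 3)
  mini <- utils::read.csv(paths[["mini_sweep"]])
  expect_equal(nrow(mini), 3)
  # the synthetic constant-vdep toy parses and declares fixed velocities
  toy <- read_scenario(paths[["constant_vdep"]])
  expect_equal(toy$vdep, 1e-4)
  expect_null(toy$dp)
})
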