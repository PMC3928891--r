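scenarioFixture <- function(years = 2000:2010, pop = 1e7,
                            dC3 = 0, dC4 = 0, dTr = 0, gini = 0.30,
                            mderVal = 1800) {
  traj <- PopulationTrajectory(years, rep(pop, length(years))[seq_along(years)])
  ScenarioSpec("fix", years[1], years, dC3, dC4, dTr, traj,
               InequalityModel(gini = gini), mderVal)
}

baselineSheet <- function() {
  toyFbs(toyRecord(commodity_id = c("maize", "wheat", "fish"),
                   pathway = c("C4", "C3", "NONCROP"),
                   production = c(4e6, 1e6, 5e5),
                   imports = c(2e5, 1e5, 0), exports = c(1e5, 0, 5e4),
                   nonfood_use = c(2e5, 5e4, 0), losses = c(4e5, 1e5, 5e4),
                   energy_density = c(3650, 3300, 800)))
}

test_that("delta series interpolation is linear and range-checked", {
  expect_equal(interpolateSeries(c(2000, 2050), c(0, -0.375), c(2000, 2025, 2050)),
               c(0, -0.1875, -0.375))
  expect_equal(interpolateSeries(2000, 0.1, c(2000, 2000)), c(0.1, 0.1))
  expect_error(interpolateSeries(c(2000, 2010), c(0, 1), 2011), "outside")
})

test_that("scenario invariants are enforced at construction", {
  traj <- PopulationTrajectory(2000:2005, rep(1e6, 6))
  ok <- ScenarioSpec("s", 2000, 2000:2005, 0, 0, 0, traj,
                     InequalityModel(gini = 0.3), 1800)
  expect_s4_class(ok, "ScenarioSpec")
  # nonzero baseline delta
  expect_error(ScenarioSpec("s", 2000, 2000:2005, c(0.1, rep(0, 5)), 0, 0,
                            traj, InequalityModel(gini = 0.3), 1800),
               "baseline")
  # years not starting at baseline
  expect_error(ScenarioSpec("s", 2000, 2001:2005, 0, 0, 0, traj,
                            InequalityModel(gini = 0.3), 1800),
               "start at baselineYear")
  # trajectory not covering the horizon
  expect_error(ScenarioSpec("s", 2000, 2000:2010, 0, 0, 0, traj,
                            InequalityModel(gini = 0.3), 1800),
               "cover")
  # coarse data.frame delta is interpolated
  spec <- ScenarioSpec("s", 2000, 2000:2004,
                       yieldDeltaC4 = data.frame(year = c(2000, 2004),
                                                 value = c(0, -0.4)),
                       population = PopulationTrajectory(c(2000L, 2004L),
                                                         c(1e6, 1e6)),
                       inequality = InequalityModel(gini = 0.3),
                       mderFixed = 1800)
  expect_equal(spec@yieldDeltaC4, seq(0, -0.4, by = -0.1))
})

test_that("headcount rounds half-up to persons", {
  expect_equal(headcount(0.2, 15e6), 3e6)
  expect_equal(headcount(0, 1e6), 0)
  expect_equal(headcount(0.13, 15153846), 1970000)
  expect_equal(headcount(0.5, 3), 2)   # half-up, not banker's
  expect_error(headcount(1.2, 100), "\\[0, 1\\]")
  expect_error(headcount(0.5, -1), ">= 0")
})

test_that("identity scenario yields a constant series", {
  series <- as.data.frame(projectScenario(baselineSheet(), scenarioFixture()))
  expect_equal(nrow(series), 11L)
  for (col in c("des", "mder", "pou", "population", "undernourished"))
    expect_equal(length(unique(series[[col]])), 1L, info = col)
  expect_true(all(series$pou >= 0 & series$pou <= 1))
})

test_that("population growth with fixed supply raises PoU strictly", {
  years <- 2000:2010
  traj <- PopulationTrajectory(years, seq(1e7, 2e7, length.out = 11))
  spec <- ScenarioSpec("grow", 2000, years, 0, 0, 0, traj,
                       InequalityModel(gini = 0.30), 1800)
  series <- as.data.frame(projectScenario(baselineSheet(), spec))
  expect_true(all(diff(series$des) < 0))
  expect_true(all(diff(series$pou) > 0))
  # des halves when population doubles
  expect_equal(series$des[11], series$des[1] / 2)
})

test_that("projection matches a step-by-step long-hand recomputation", {
  fbs <- baselineSheet()
  years <- 2000:2050
  pop0 <- 13.1e6
  traj <- PopulationTrajectory(years, pop0 * 1.029^(0:50))
  dC4 <- seq(0, -0.375, length.out = 51)
  gini <- 0.30
  spec <- ScenarioSpec("malawi-like", 2000, years, 0, dC4, 0, traj,
                       InequalityModel(gini = gini), 1770)
  series <- as.data.frame(projectScenario(fbs, spec))

  rec <- fbsRecords(fbs)
  sigma <- sqrt(2) * qnorm((gini + 1) / 2)
  for (i in c(1, 6, 16, 26, 41, 51)) {
    prod <- rec$production * ifelse(rec$pathway == "C4", 1 + dC4[i], 1)
    net <- prod + rec$imports - rec$exports - rec$nonfood_use - rec$losses
    popY <- pop0 * 1.029^(i - 1)
    desY <- sum(net * 1000 * rec$energy_density) / (popY * 365)
    muLog <- log(desY) - sigma^2 / 2
    pouY <- pnorm((log(1770) - muLog) / sigma)
    expect_equal(series$des[i], desY, info = paste("year", years[i]))
    expect_equal(series$pou[i], pouY, info = paste("year", years[i]))
    expect_equal(series$undernourished[i], floor(pouY * popY + 0.5))
  }
})

test_that("more negative yield deltas never decrease PoU", {
  fbs <- baselineSheet()
  grid <- seq(0, -0.6, by = -0.1)
  pous <- vapply(grid, function(d) {
    spec <- scenarioFixture(years = c(2000L, 2001L), dC4 = c(0, d))
    as.data.frame(projectScenario(fbs, spec))$pou[2]
  }, numeric(1))
  expect_true(all(diff(pous) >= 0))
})

test_that("series is baseline-anchored: each year independent of the rest", {
  fbs <- baselineSheet()
  years <- 2000:2010
  dC4 <- seq(0, -0.5, length.out = 11)
  traj <- PopulationTrajectory(years, seq(1e7, 1.5e7, length.out = 11))
  full <- ScenarioSpec("full", 2000, years, 0, dC4, 0, traj,
                       InequalityModel(gini = 0.3), 1800)
  fullSeries <- as.data.frame(projectScenario(fbs, full))
  # a two-year scenario hitting only year 2007 reproduces the same row
  sub <- ScenarioSpec("sub", 2000, c(2000L, 2007L), c(0, 0),
                      c(0, dC4[8]), c(0, 0), traj,
                      InequalityModel(gini = 0.3), 1800)
  subSeries <- as.data.frame(projectScenario(fbs, sub))
  expect_equal(subSeries[2, ], fullSeries[8, ], ignore_attr = TRUE)
})

test_that("stage failures are annotated with the failing year", {
  # production collapse makes net supply negative from some year on
  fbs <- toyFbs(toyRecord(commodity_id = "maize", pathway = "C4",
                          production = 100, losses = 60,
                          energy_density = 3650))
  spec <- scenarioFixture(years = c(2000L, 2001L), dC4 = c(0, -0.9))
  expect_error(projectScenario(fbs, spec), "year 2001")
})

test_that("undernourished / population recovers pou at every year", {
  cfg <- synthConfig(seed = 4)
  series <- as.data.frame(projectScenario(makeFbs(cfg), makeScenario(cfg)))
  expect_equal(series$undernourished,
               floor(series$pou * series$population + 0.5))
  expect_true(all(abs(series$undernourished / series$population -
                        series$pou) <= 1 / series$population))
})

test_that("scenario config file round-trips through readScenario", {
  dir <- withr::local_tempdir()
  cfg <- synthConfig(seed = 8, horizon = 20L)
  writeBundle(cfg, dir)
  bundle <- readScenario(file.path(dir, "scenario.yaml"))
  fromFile <- as.data.frame(projectScenario(bundle$fbs, bundle$spec))
  inMem <- as.data.frame(projectScenario(makeFbs(cfg), makeScenario(cfg)))
  expect_equal(fromFile$pou, inMem$pou, tolerance = 1e-6)
  expect_equal(fromFile$population, inMem$population, tolerance = 1e-6)
  expect_error(readScenario(file.path(dir, "missing.yaml")), "not found")
})

test_that("projection file has one row per year and fixed formatting", {
  series <- projectScenario(baselineSheet(), scenarioFixture())
  path <- withr::local_tempfile(fileext = ".csv")
  writeProjection(series, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 11L)
  expect_equal(names(out),
               c("year", "des", "mder", "pou", "population", "undernourished"))
  raw <- readLines(path)[2]
  expect_match(raw, ",0\\.[0-9]{6},")   # pou printed with 6 decimals
})
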