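test_that("net food supply follows the balance identity", {
  expect_equal(unname(netFoodSupply(toyRecord(production = 100))), 100)
  expect_equal(unname(netFoodSupply(toyRecord(
    production = 100, imports = 20, exports = 30, nonfood_use = 10,
    losses = 5))), 75)
  expect_equal(unname(netFoodSupply(toyRecord(exports = 10))), -10)
})

test_that("DES converts tonnes and energy density to kcal/capita/day", {
  fbs <- toyFbs(toyRecord(production = 255500, energy_density = 3650))
  expect_equal(dietaryEnergySupply(fbs, 1e6), 2555)

  # zero energy density contributes nothing
  fbs0 <- toyFbs(toyRecord(production = 1000, energy_density = 0))
  expect_equal(dietaryEnergySupply(fbs0, 1e6), 0)

  # additivity: two records each worth 1000 kcal/capita/day
  one <- toyRecord(commodity_id = c("a", "b"), pathway = "C3",
                   production = 100000, energy_density = 3650)
  expect_equal(dietaryEnergySupply(toyFbs(one), 1e6), 2000)
})

test_that("DES rejects bad population and negative net supply", {
  fbs <- toyFbs(toyRecord(production = 10, energy_density = 1000))
  expect_error(dietaryEnergySupply(fbs, 0), "population")
  expect_error(dietaryEnergySupply(fbs, -5), "population")
  neg <- toyFbs(toyRecord(commodity_id = "cassava", exports = 10,
                          energy_density = 1000))
  expect_error(dietaryEnergySupply(neg, 1e6), "cassava")
})

test_that("DES is linear in net supplies and order-invariant", {
  set.seed(7)
  rec <- toyRecord(commodity_id = sprintf("c%d", 1:8),
                   pathway = sample(c("C3", "C4", "NONCROP"), 8, TRUE),
                   production = runif(8, 1e4, 1e6),
                   energy_density = runif(8, 500, 4000))
  fbs <- toyFbs(rec)
  doubled <- rec; doubled$production <- 2 * rec$production
  expect_equal(dietaryEnergySupply(toyFbs(doubled), 1e6),
               2 * dietaryEnergySupply(fbs, 1e6))
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(dietaryEnergySupply(toyFbs(shuffled), 1e6),
               dietaryEnergySupply(fbs, 1e6))
})

test_that("deltas scale the right fields by pathway", {
  rec <- rbind(toyRecord("maize", "C4", production = 100),
               toyRecord("wheat", "C3", production = 100),
               toyRecord("fish", "NONCROP", production = 100,
                         imports = 40, exports = 10))
  rec$energy_density <- 3000
  fbs <- toyFbs(rec)

  same <- applyFbsDeltas(fbs, 0, 0, 0)
  expect_equal(fbsRecords(same), fbsRecords(fbs))

  # C4 midpoint of the 35-40% maize yield reduction
  out <- fbsRecords(applyFbsDeltas(fbs, yieldDeltaC4 = -0.375))
  expect_equal(out$production[out$commodity_id == "maize"], 62.5)
  expect_equal(out$production[out$commodity_id == "wheat"], 100)
  expect_equal(out$production[out$commodity_id == "fish"], 100)

  # C3 untouched by a C4 delta
  iso <- fbsRecords(applyFbsDeltas(fbs, yieldDeltaC3 = 0, yieldDeltaC4 = -0.5))
  expect_equal(iso$production[iso$commodity_id == "wheat"], 100)

  # trade delta hits imports and exports only
  tr <- fbsRecords(applyFbsDeltas(fbs, tradeDelta = 0.25))
  expect_equal(tr$imports[tr$commodity_id == "fish"], 50)
  expect_equal(tr$exports[tr$commodity_id == "fish"], 12.5)
  expect_equal(tr$production, rec$production)

  # input sheet untouched
  expect_equal(fbsRecords(fbs), rec)
})

test_that("deltas <= -1 are rejected", {
  fbs <- toyFbs(toyRecord(production = 1))
  expect_error(applyFbsDeltas(fbs, yieldDeltaC3 = -1), "> -1")
  expect_error(applyFbsDeltas(fbs, tradeDelta = -1.5), "> -1")
})

test_that("sequential deltas compose multiplicatively on production", {
  set.seed(11)
  fbs <- toyFbs(toyRecord(commodity_id = c("a", "b"),
                          pathway = c("C3", "C4"),
                          production = c(120, 340), energy_density = 3000))
  for (i in 1:20) {
    d1 <- runif(1, -0.5, 0.5); d2 <- runif(1, -0.5, 0.5)
    once <- applyFbsDeltas(applyFbsDeltas(fbs, d1, d1), d2, d2)
    combined <- applyFbsDeltas(fbs, (1 + d1) * (1 + d2) - 1,
                               (1 + d1) * (1 + d2) - 1)
    expect_equal(fbsRecords(once)$production,
                 fbsRecords(combined)$production)
  }
})

test_that("DES of an all-C4 sheet scales by (1 + delta)", {
  fbs <- toyFbs(toyRecord(commodity_id = c("a", "b"), pathway = "C4",
                          production = c(1e5, 2e5),
                          energy_density = c(3650, 1500)))
  base <- dietaryEnergySupply(fbs, 1e6)
  for (d in c(-0.375, -0.1, 0.2)) {
    expect_equal(dietaryEnergySupply(applyFbsDeltas(fbs, 0, d), 1e6),
                 (1 + d) * base)
  }
})

test_that("FBS text round-trip preserves values to 6 significant figures", {
  set.seed(3)
  rec <- toyRecord(commodity_id = sprintf("c%d", 1:5),
                   pathway = sample(c("C3", "C4", "NONCROP"), 5, TRUE),
                   production = runif(5, 1, 1e6),
                   imports = runif(5, 0, 1e5), exports = runif(5, 0, 1e4),
                   nonfood_use = runif(5, 0, 1e4),
                   losses = runif(5, 0, 1e4),
                   energy_density = runif(5, 100, 4000))
  fbs <- toyFbs(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFbs(fbs, path)
  back <- readFbs(path, region = "toy", year = 2000L)
  for (col in c("production", "imports", "exports", "nonfood_use",
                "losses", "energy_density"))
    expect_equal(signif(fbsRecords(back)[[col]], 6), signif(rec[[col]], 6))
  expect_error(readFbs(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("sheet validity catches structural errors", {
  expect_error(FoodBalanceSheet("x", 2000, toyRecord(production = -1)),
               ">= 0")
  expect_error(FoodBalanceSheet("x", 2000,
                                toyRecord(commodity_id = c("a", "a"))),
               "unique")
  expect_error(FoodBalanceSheet("x", 2000, toyRecord(pathway = "CAM")),
               "pathway")
})
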