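# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Largest-remainder rounding: integer vector summing to total, proportional
# to shares.
.apportion <- function(shares, total) {
  raw <- shares / sum(shares) * total
  base <- floor(raw)
  short <- round(total - sum(base))
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  base
}

#' Configuration for the synthetic input generators
#'
#' Defaults describe the demo study conditions: a maize-dependent,
#' low-income country of 13.1 million people growing at 2.9 percent per
#' year over a 50-year horizon, baseline dietary energy supply 2200
#' kcal/capita/day, consumption Gini 0.30, and C4 crop productivity
#' declining linearly to -37.5 percent of baseline by the final year while
#' C3 yields and trade stay at baseline.
#'
#' @param seed integer RNG seed.
#' @param nCommodities number of commodities in the balance sheet.
#' @param c4Share probability a commodity is C4-pathway.
#' @param targetDes baseline DES to calibrate to (kcal/capita/day).
#' @param gini consumption Gini coefficient in (0, 1).
#' @param nCohorts number of age-sex cohorts.
#' @param population0 baseline population (persons).
#' @param growthRate annual population growth fraction.
#' @param horizon projection horizon (years).
#' @param terminalC4Delta C4 yield delta reached at the final year.
#' @param baselineYear first projection year.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(seed = 1L, nCommodities = 12L, c4Share = 0.6,
                        targetDes = 2200, gini = 0.30, nCohorts = 12L,
                        population0 = 13.1e6, growthRate = 0.029,
                        horizon = 50L, terminalC4Delta = -0.375,
                        baselineYear = 2000L) {
  new("SynthConfig", seed = as.integer(seed),
      nCommodities = as.integer(nCommodities), c4Share = c4Share,
      targetDes = targetDes, gini = gini, nCohorts = as.integer(nCohorts),
      population0 = population0, growthRate = growthRate,
      horizon = as.integer(horizon), terminalC4Delta = terminalC4Delta,
      baselineYear = as.integer(baselineYear))
}

#' Generate a synthetic food balance sheet
#'
#' Fabricates \code{nCommodities} commodity records whose dietary energy
#' supply at the baseline population equals \code{targetDes} exactly (by
#' construction; floating point aside). Energy shares, densities, trade
#' fractions and loss/non-food fractions are drawn at random; pathway labels
#' are C4 with probability \code{c4Share}, otherwise C3. Deterministic for a
#' fixed seed.
#'
#' @param cfg a [SynthConfig-class].
#' @return A [FoodBalanceSheet-class].
#' @export
makeFbs <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  .withSeed(cfg@seed, {
    n <- cfg@nCommodities
    pathway <- ifelse(runif(n) < cfg@c4Share, "C4", "C3")
    density <- runif(n, 800, 4000)                     # kcal/kg
    share <- rgamma(n, shape = 1.5)
    share <- share / sum(share)
    totalKcal <- cfg@targetDes * cfg@population0 * 365  # kcal/yr
    net <- share * totalKcal / density / 1000           # tonnes/yr
    impFrac <- runif(n, 0, 0.3)
    expFrac <- runif(n, 0, 0.1)
    lossFrac <- runif(n, 0.05, 0.15)
    nonfoodFrac <- runif(n, 0.02, 0.10)
    imports <- impFrac * net
    exports <- expFrac * net
    production <- (net - imports + exports) / (1 - lossFrac - nonfoodFrac)
    FoodBalanceSheet("synthetic", cfg@baselineYear, data.frame(
      commodity_id = sprintf("commodity_%02d", seq_len(n)),
      pathway = pathway, production = production, imports = imports,
      exports = exports, nonfood_use = nonfoodFrac * production,
      losses = lossFrac * production, energy_density = density,
      stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic cohort table
#'
#' Fabricates \code{nCohorts} age-sex cohorts with a young-skewed population
#' pyramid, plausible reference weights (10-80 kg, rising with age towards a
#' minimum-acceptable adult weight), light-activity PAL values in [1.4, 1.6]
#' and BMR coefficients taken from [defaultBmrTable()] by age and sex. Cohort counts sum exactly to \code{round(population0)}.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [SynthConfig-class].
#' @return A [CohortTable-class].
#' @export
makeCohorts <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  .withSeed(cfg@seed + 1L, {
    n <- cfg@nCohorts
    nBands <- ceiling(n / 2)
    band <- rep(seq_len(nBands), each = 2)[seq_len(n)]
    sex <- rep(c("F", "M"), length.out = n)
    width <- max(5, ceiling(80 / nBands))   # bands span ages 0 to ~80
    lo <- width * (band - 1)
    ageBand <- sprintf("%d-%d", lo, lo + width - 1)
    mid <- lo + width / 2
    bmrTab <- defaultBmrTable()
    idx <- vapply(seq_len(n), function(i) {
      which(bmrTab$sex == sex[i] & bmrTab$age_min <= mid[i] &
              mid[i] < bmrTab$age_max)[1]
    }, integer(1))
    # asymptotic growth toward a minimum-acceptable adult weight (~52 kg),
    # jittered, clamped to 10-80 kg; MDER is a minimum cut-off, so reference
    # weights encode minimality rather than average body mass
    weight <- pmin(pmax(9 + 44 * (1 - exp(-0.08 * mid)) + runif(n, -2, 2),
                        10), 80)
    # light-activity PAL band, as appropriate for a minimum requirement
    pal <- runif(n, 1.4, 1.6)
    # young-skewed population pyramid
    shares <- exp(-0.04 * mid) * runif(n, 0.85, 1.15)
    CohortTable("synthetic", cfg@baselineYear, data.frame(
      age_band = ageBand, sex = sex,
      count = .apportion(shares, round(cfg@population0)),
      reference_weight = weight,
      bmr_slope = bmrTab$bmr_slope[idx],
      bmr_intercept = bmrTab$bmr_intercept[idx],
      pal = pal, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic scenario
#'
#' Builds the demo projection scenario: an exponential population trajectory
#' \code{population0 * (1 + growthRate)^t}, a C4 yield delta declining
#' linearly from 0 at the baseline year to \code{terminalC4Delta} at the end
#' of the horizon, zero C3 and trade deltas, the configured Gini, and the
#' MDER of the synthetic cohort table — the latter two held fixed across the
#' horizon. The deltas are deterministic functions of the configuration;
#' randomness enters only through the cohort composition behind the MDER.
#'
#' @param cfg a [SynthConfig-class].
#' @return A [ScenarioSpec-class].
#' @export
makeScenario <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  years <- cfg@baselineYear + 0:cfg@horizon
  ct <- makeCohorts(cfg)
  traj <- PopulationTrajectory(
    years, cfg@population0 * (1 + cfg@growthRate)^(0:cfg@horizon), ct)
  ScenarioSpec(
    name = "synthetic", baselineYear = cfg@baselineYear, years = years,
    yieldDeltaC3 = 0,
    yieldDeltaC4 = seq(0, cfg@terminalC4Delta, length.out = cfg@horizon + 1),
    tradeDelta = 0, population = traj,
    inequality = InequalityModel(gini = cfg@gini), mderFixed = mder(ct))
}

#' Write a complete runnable input bundle
#'
#' Writes the synthetic balance sheet, cohort table, population trajectory
#' and a scenario config (YAML) to a directory, ready to be consumed by
#' [readScenario()] or the command-line interface.
#'
#' @param cfg a [SynthConfig-class].
#' @param dir output directory (created if absent).
#' @return Named list of the file paths written, invisibly.
#' @export
writeBundle <- function(cfg, dir) {
  stopifnot(is(cfg, "SynthConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fbs <- makeFbs(cfg)
  ct <- makeCohorts(cfg)
  spec <- makeScenario(cfg)
  paths <- list(
    fbs = file.path(dir, "fbs.csv"),
    cohorts = file.path(dir, "cohorts.csv"),
    trajectory = file.path(dir, "trajectory.csv"),
    scenario = file.path(dir, "scenario.yaml"))
  writeFbs(fbs, paths$fbs)
  writeCohorts(ct, paths$cohorts)
  writeTrajectory(spec@population, paths$trajectory)
  cfgList <- list(
    name = "synthetic", baseline_year = cfg@baselineYear,
    horizon = cfg@horizon, fbs = "fbs.csv", cohorts = "cohorts.csv",
    trajectory = "trajectory.csv", gini = cfg@gini,
    mder = mder(ct),
    yield_delta_c3 = 0,
    yield_delta_c4 = list(
      years = c(cfg@baselineYear, cfg@baselineYear + cfg@horizon),
      values = c(0, cfg@terminalC4Delta)),
    trade_delta = 0)
  writeLines(yaml::as.yaml(cfgList), paths$scenario)
  invisible(paths)
}
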