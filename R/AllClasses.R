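#' @import methods
#' @importFrom stats approx pnorm qnorm rlnorm setNames
#' @importFrom utils read.csv write.csv
NULL

.PATHWAYS <- c("C3", "C4", "NONCROP")

.FBS_COLUMNS <- c("commodity_id", "pathway", "production", "imports",
                  "exports", "nonfood_use", "losses", "energy_density")

.COHORT_COLUMNS <- c("age_band", "sex", "count", "reference_weight",
                     "bmr_slope", "bmr_intercept", "pal")

#' FoodBalanceSheet: commodity-level food availability account
#'
#' A food balance sheet records, for each commodity, the annual mass flows
#' that determine how much food energy is available to a population:
#' production, imports, exports, non-food uses (seed, feed, industrial) and
#' losses, together with the commodity's energy density. It is the source of
#' the mean dietary energy supply (DES, kcal/capita/day). Stock changes are
#' folded into \code{losses}.
#'
#' The \code{records} slot is a data.frame with columns
#' \code{commodity_id} (unique label), \code{pathway} (one of \code{"C3"},
#' \code{"C4"}, \code{"NONCROP"}; the photosynthetic-pathway class used to
#' route climate-scenario yield changes), \code{production}, \code{imports},
#' \code{exports}, \code{nonfood_use}, \code{losses} (all tonnes/yr, all
#' non-negative) and \code{energy_density} (kcal/kg, non-negative).
#'
#' @slot region character(1) region label.
#' @slot year integer(1) reference year.
#' @slot records data.frame of commodity records (see above).
#'
#' @seealso [dietaryEnergySupply()], [applyFbsDeltas()], [readFbs()]
#' @export
setClass("FoodBalanceSheet",
  representation(region = "character", year = "integer",
                 records = "data.frame"))

setValidity("FoodBalanceSheet", function(object) {
  msgs <- character()
  rec <- object@records
  if (length(object@region) != 1L) msgs <- c(msgs, "region must be length 1")
  if (length(object@year) != 1L || is.na(object@year))
    msgs <- c(msgs, "year must be a single integer")
  if (!all(.FBS_COLUMNS %in% names(rec)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(.FBS_COLUMNS, collapse = ", ")))
  else {
    if (nrow(rec) < 1L) msgs <- c(msgs, "at least one commodity record required")
    if (anyDuplicated(rec$commodity_id))
      msgs <- c(msgs, "commodity_id must be unique within a sheet")
    if (!all(rec$pathway %in% .PATHWAYS))
      msgs <- c(msgs, "pathway must be one of C3, C4, NONCROP")
    mass <- c("production", "imports", "exports", "nonfood_use", "losses",
              "energy_density")
    for (col in mass) {
      v <- rec[[col]]
      if (!is.numeric(v) || anyNA(v) || any(v < 0))
        msgs <- c(msgs, paste0(col, " must be numeric and >= 0"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortTable: age-sex population structure with energy requirements
#'
#' Holds the age-band by sex cohort counts of a population together with the
#' per-cohort inputs of the minimum dietary energy requirement: a reference
#' body weight, linear basal-metabolic-rate coefficients
#' (BMR = slope * weight + intercept, kcal/day) and a physical activity
#' level (PAL) multiplier.
#'
#' The \code{cohorts} slot is a data.frame with columns \code{age_band},
#' \code{sex} ("F"/"M"), \code{count} (persons, >= 0),
#' \code{reference_weight} (kg, > 0), \code{bmr_slope} (kcal/kg/day),
#' \code{bmr_intercept} (kcal/day) and \code{pal} (dimensionless, >= 1).
#' (age_band, sex) pairs must be unique and every cohort's BMR must be
#' positive.
#'
#' @slot region character(1) region label.
#' @slot year integer(1) reference year.
#' @slot cohorts data.frame of cohorts (see above).
#'
#' @seealso [mder()], [cohortRequirement()], [readCohorts()]
#' @export
setClass("CohortTable",
  representation(region = "character", year = "integer",
                 cohorts = "data.frame"))

setValidity("CohortTable", function(object) {
  msgs <- character()
  ch <- object@cohorts
  if (!all(.COHORT_COLUMNS %in% names(ch)))
    msgs <- c(msgs, paste("cohorts must have columns:",
                          paste(.COHORT_COLUMNS, collapse = ", ")))
  else {
    if (nrow(ch) < 1L) msgs <- c(msgs, "at least one cohort required")
    if (anyDuplicated(paste(ch$age_band, ch$sex)))
      msgs <- c(msgs, "(age_band, sex) pairs must be unique")
    if (!all(ch$sex %in% c("F", "M")))
      msgs <- c(msgs, "sex must be 'F' or 'M'")
    if (any(ch$count < 0)) msgs <- c(msgs, "count must be >= 0")
    if (any(ch$reference_weight <= 0))
      msgs <- c(msgs, "reference_weight must be > 0")
    if (any(ch$pal < 1)) msgs <- c(msgs, "pal must be >= 1")
    bmr <- ch$bmr_slope * ch$reference_weight + ch$bmr_intercept
    if (any(bmr <= 0)) msgs <- c(msgs, "BMR must be positive for every cohort")
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("CohortTableOrNULL", c("CohortTable", "NULL"))

#' PopulationTrajectory: total population over time
#'
#' An ordered set of (year, total) points. Totals at unlisted years within
#' the range are obtained by linear interpolation; extrapolation outside the
#' listed range is an error. An optional baseline cohort structure records
#' the age-sex shares, which projections hold fixed while totals evolve.
#'
#' @slot years integer vector, strictly increasing.
#' @slot totals numeric vector of person counts, all > 0.
#' @slot baseStructure a [CohortTable-class] or NULL.
#'
#' @seealso [populationAt()], [readTrajectory()]
#' @export
setClass("PopulationTrajectory",
  representation(years = "integer", totals = "numeric",
                 baseStructure = "CohortTableOrNULL"))

setValidity("PopulationTrajectory", function(object) {
  msgs <- character()
  if (length(object@years) < 1L) msgs <- c(msgs, "at least one year required")
  if (length(object@years) != length(object@totals))
    msgs <- c(msgs, "years and totals must have equal length")
  if (is.unsorted(object@years, strictly = TRUE))
    msgs <- c(msgs, "years must be strictly increasing")
  if (any(object@totals <= 0)) msgs <- c(msgs, "totals must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' InequalityModel: inequality of access to food
#'
#' Parameterizes the spread of the lognormal consumption distribution from a
#' single inequality statistic: either a Gini coefficient in (0, 1) or a
#' coefficient of variation (CV > 0). Exactly one of the two must be given;
#' the other, and the lognormal log-scale spread sigma, are derived through
#' the exact lognormal identities (see [sigmaFromGini()], [sigmaFromCv()]).
#'
#' @slot gini numeric(1) Gini coefficient in (0, 1).
#' @slot cv numeric(1) coefficient of variation, > 0.
#' @slot sigma numeric(1) lognormal log-scale standard deviation, > 0.
#'
#' @export
setClass("InequalityModel",
  representation(gini = "numeric", cv = "numeric", sigma = "numeric"))

setValidity("InequalityModel", function(object) {
  msgs <- character()
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0)
    msgs <- c(msgs, "sigma must be a single positive number")
  if (length(object@gini) != 1L || !is.finite(object@gini) ||
      object@gini <= 0 || object@gini >= 1)
    msgs <- c(msgs, "derived gini must lie in (0, 1)")
  if (length(object@cv) != 1L || !is.finite(object@cv) || object@cv <= 0)
    msgs <- c(msgs, "derived cv must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' ConsumptionDistribution: lognormal dietary energy consumption
#'
#' The habitual per-capita dietary energy consumption across the population
#' is modelled as lognormal. The distribution is pinned down by requiring its
#' arithmetic mean to equal the mean dietary energy supply (DES), so the
#' log-scale location is \code{muLog = log(meanDes) - sigma^2 / 2}.
#'
#' @slot meanDes numeric(1) mean dietary energy supply, kcal/capita/day, > 0.
#' @slot sigma numeric(1) log-scale spread, > 0.
#' @slot muLog numeric(1) derived log-scale location.
#'
#' @seealso [pou()], [sampleConsumption()]
#' @export
setClass("ConsumptionDistribution",
  representation(meanDes = "numeric", sigma = "numeric", muLog = "numeric"))

setValidity("ConsumptionDistribution", function(object) {
  msgs <- character()
  if (object@meanDes <= 0) msgs <- c(msgs, "meanDes must be > 0")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0")
  expected <- log(object@meanDes) - object@sigma^2 / 2
  if (abs(object@muLog - expected) > 1e-8)
    msgs <- c(msgs, "muLog must equal log(meanDes) - sigma^2/2")
  if (length(msgs)) msgs else TRUE
})

#' ScenarioSpec: a projection scenario
#'
#' Describes how a baseline food balance sheet and population evolve over a
#' projection horizon. Yield deltas (separately for C3 and C4 crops) and a
#' trade delta are fractional changes applied to the baseline sheet —
#' always relative to the baseline, never compounded year on year. The
#' inequality model and the minimum dietary energy requirement are held
#' fixed at their baseline values for the whole horizon, and imports/exports
#' stay at baseline unless a nonzero trade-delta series is supplied.
#'
#' @slot name character(1) scenario label.
#' @slot baselineYear integer(1); must equal the first projection year.
#' @slot years integer vector of projection years, strictly increasing.
#' @slot yieldDeltaC3 numeric, one fractional delta per year (> -1); 0 at
#'   the baseline year.
#' @slot yieldDeltaC4 numeric, as above, applied to C4-pathway commodities.
#' @slot tradeDelta numeric, as above, applied to imports and exports.
#' @slot population a [PopulationTrajectory-class] covering all years.
#' @slot inequality an [InequalityModel-class], held fixed.
#' @slot mderFixed numeric(1) minimum dietary energy requirement
#'   (kcal/capita/day), held fixed.
#'
#' @seealso [projectScenario()], [readScenario()]
#' @export
setClass("ScenarioSpec",
  representation(name = "character", baselineYear = "integer",
                 years = "integer", yieldDeltaC3 = "numeric",
                 yieldDeltaC4 = "numeric", tradeDelta = "numeric",
                 population = "PopulationTrajectory",
                 inequality = "InequalityModel", mderFixed = "numeric"))

setValidity("ScenarioSpec", function(object) {
  msgs <- character()
  ny <- length(object@years)
  if (ny < 1L) msgs <- c(msgs, "at least one projection year required")
  if (is.unsorted(object@years, strictly = TRUE))
    msgs <- c(msgs, "years must be strictly increasing")
  if (ny >= 1L && object@years[1L] != object@baselineYear)
    msgs <- c(msgs, "years must start at baselineYear")
  for (nm in c("yieldDeltaC3", "yieldDeltaC4", "tradeDelta")) {
    d <- slot(object, nm)
    if (length(d) != ny)
      msgs <- c(msgs, paste0(nm, " must have one value per year"))
    else {
      if (any(d <= -1)) msgs <- c(msgs, paste0(nm, " must be > -1"))
      if (d[1L] != 0) msgs <- c(msgs, paste0(nm, " must be 0 at the baseline year"))
    }
  }
  if (ny >= 1L &&
      (object@years[1L] < object@population@years[1L] ||
       object@years[ny] > object@population@years[length(object@population@years)]))
    msgs <- c(msgs, "population trajectory must cover all projection years")
  if (object@mderFixed <= 0) msgs <- c(msgs, "mderFixed must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' ProjectionSeries: per-year output of a scenario projection
#'
#' One row per projection year with the dietary energy supply (DES), the
#' (fixed) minimum dietary energy requirement, the prevalence of
#' undernourishment as a fraction, the total population and the
#' undernourished headcount.
#'
#' @slot series data.frame with columns \code{year}, \code{des},
#'   \code{mder}, \code{pou}, \code{population}, \code{undernourished}.
#'
#' @seealso [projectScenario()], [writeProjection()]
#' @export
setClass("ProjectionSeries", representation(series = "data.frame"))

setValidity("ProjectionSeries", function(object) {
  msgs <- character()
  need <- c("year", "des", "mder", "pou", "population", "undernourished")
  if (!all(need %in% names(object@series)))
    msgs <- c(msgs, paste("series must have columns:", paste(need, collapse = ", ")))
  else if (any(object@series$pou < 0 | object@series$pou > 1))
    msgs <- c(msgs, "pou must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SynthConfig: parameters of the synthetic input generator
#'
#' Controls the seeded generators that fabricate a complete, runnable input
#' bundle (balance sheet, cohort table, population trajectory, scenario).
#' Defaults emulate a low-income, maize-dependent country with rapid
#' population growth: 13.1 million people growing at 2.9 percent per year
#' over a 50-year horizon, baseline DES 2200 kcal/capita/day, Gini 0.30,
#' and a linear C4 yield decline reaching -37.5 percent at the end of the
#' horizon.
#'
#' @slot seed integer(1) RNG seed.
#' @slot nCommodities integer(1) number of commodities, >= 1.
#' @slot c4Share numeric(1) probability a commodity is C4-pathway, in [0, 1].
#' @slot targetDes numeric(1) baseline DES to calibrate to, kcal/capita/day.
#' @slot gini numeric(1) Gini coefficient in (0, 1).
#' @slot nCohorts integer(1) number of age-sex cohorts, >= 1.
#' @slot population0 numeric(1) baseline population, persons.
#' @slot growthRate numeric(1) annual population growth fraction.
#' @slot horizon integer(1) projection horizon in years, >= 1.
#' @slot terminalC4Delta numeric(1) C4 yield delta at the final year (> -1).
#' @slot baselineYear integer(1) first projection year.
#'
#' @seealso [synthConfig()], [makeFbs()], [makeCohorts()], [makeScenario()]
#' @export
setClass("SynthConfig",
  representation(seed = "integer", nCommodities = "integer",
                 c4Share = "numeric", targetDes = "numeric", gini = "numeric",
                 nCohorts = "integer", population0 = "numeric",
                 growthRate = "numeric", horizon = "integer",
                 terminalC4Delta = "numeric", baselineYear = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@nCommodities < 1L) msgs <- c(msgs, "nCommodities must be >= 1")
  if (object@nCohorts < 1L) msgs <- c(msgs, "nCohorts must be >= 1")
  if (object@horizon < 1L) msgs <- c(msgs, "horizon must be >= 1")
  if (object@c4Share < 0 || object@c4Share > 1)
    msgs <- c(msgs, "c4Share must lie in [0, 1]")
  if (object@targetDes <= 0) msgs <- c(msgs, "targetDes must be > 0")
  if (object@gini <= 0 || object@gini >= 1)
    msgs <- c(msgs, "gini must lie in (0, 1)")
  if (object@population0 <= 0) msgs <- c(msgs, "population0 must be > 0")
  if (object@growthRate <= -1) msgs <- c(msgs, "growthRate must be > -1")
  if (object@terminalC4Delta <= -1)
    msgs <- c(msgs, "terminalC4Delta must be > -1")
  if (length(msgs)) msgs else TRUE
})
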