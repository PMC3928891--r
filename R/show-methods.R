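#' @describeIn FoodBalanceSheet-class display a short summary.
#' @param object the object to display.
#' @export
setMethod("show", "FoodBalanceSheet", function(object) {
  cat("FoodBalanceSheet:", object@region, object@year, "\n")
  cat(" ", nrow(object@records), "commodities (",
      sum(object@records$pathway == "C3"), "C3,",
      sum(object@records$pathway == "C4"), "C4,",
      sum(object@records$pathway == "NONCROP"), "non-crop )\n")
  cat("  total net food supply:",
      format(sum(netFoodSupply(object)), big.mark = ","), "t/yr\n")
})

#' @describeIn CohortTable-class display a short summary.
#' @param object the object to display.
#' @export
setMethod("show", "CohortTable", function(object) {
  cat("CohortTable:", object@region, object@year, "\n")
  cat(" ", nrow(object@cohorts), "cohorts; total population",
      format(totalPopulation(object), big.mark = ","), "\n")
  cat("  MDER:", sprintf("%.1f", mder(object)), "kcal/capita/day\n")
})

#' @describeIn PopulationTrajectory-class display a short summary.
#' @param object the object to display.
#' @export
setMethod("show", "PopulationTrajectory", function(object) {
  n <- length(object@years)
  cat("PopulationTrajectory:", object@years[1], "-", object@years[n], "\n")
  cat("  totals:", format(object@totals[1], big.mark = ","), "->",
      format(object@totals[n], big.mark = ","), "\n")
})

#' @describeIn InequalityModel-class display the parameterization.
#' @param object the object to display.
#' @export
setMethod("show", "InequalityModel", function(object) {
  cat(sprintf("InequalityModel: gini = %.4f, cv = %.4f, sigma = %.4f\n",
              object@gini, object@cv, object@sigma))
})

#' @describeIn ConsumptionDistribution-class display the parameterization.
#' @param object the object to display.
#' @export
setMethod("show", "ConsumptionDistribution", function(object) {
  cat(sprintf(
    "ConsumptionDistribution: mean %.1f kcal/capita/day, sigma %.4f (muLog %.4f)\n",
    object@meanDes, object@sigma, object@muLog))
})

#' @describeIn ScenarioSpec-class display a short summary.
#' @param object the object to display.
#' @export
setMethod("show", "ScenarioSpec", function(object) {
  n <- length(object@years)
  cat("ScenarioSpec:", object@name, "|", object@years[1], "-",
      object@years[n], "\n")
  cat(sprintf("  terminal deltas: C3 %+.3f, C4 %+.3f, trade %+.3f\n",
              object@yieldDeltaC3[n], object@yieldDeltaC4[n],
              object@tradeDelta[n]))
  cat(sprintf("  fixed: gini %.3f, MDER %.1f kcal/capita/day\n",
              object@inequality@gini, object@mderFixed))
})

#' @describeIn ProjectionSeries-class display first and last years.
#' @param object the object to display.
#' @export
setMethod("show", "ProjectionSeries", function(object) {
  s <- object@series
  n <- nrow(s)
  cat("ProjectionSeries:", n, "years\n")
  idx <- unique(c(1L, n))
  print(s[idx, ], row.names = FALSE)
})

#' @describeIn SynthConfig-class display the generator settings.
#' @param object the object to display.
#' @export
setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: seed", object@seed, "\n")
  cat(sprintf("  %d commodities (C4 share %.2f), target DES %.0f, gini %.2f\n",
              object@nCommodities, object@c4Share, object@targetDes,
              object@gini))
  cat(sprintf("  population %.3g @ %.1f%%/yr, horizon %d yr, terminal C4 delta %+.3f\n",
              object@population0, 100 * object@growthRate, object@horizon,
              object@terminalC4Delta))
})
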