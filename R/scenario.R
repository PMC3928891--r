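#' Interpolate a coarse delta series to annual resolution
#'
#' Scenario drivers are often supplied at coarse time slices (for example
#' decadal crop-model output). This linearly interpolates the series onto a
#' set of target years; every target year must lie within the given range.
#'
#' @param years integer years at which \code{values} are given.
#' @param values numeric values, one per given year.
#' @param targetYears integer years to interpolate onto.
#' @return Numeric vector, one value per target year.
#' @export
interpolateSeries <- function(years, values, targetYears) {
  if (length(years) != length(values))
    stop("years and values must have equal length")
  if (length(years) == 1L) {
    if (any(targetYears != years)) stop("target years outside series range")
    return(rep(values, length(targetYears)))
  }
  if (any(targetYears < min(years)) || any(targetYears > max(years)))
    stop("target years outside series range [", min(years), ", ",
         max(years), "]")
  approx(years, values, xout = targetYears, method = "linear")$y
}

#' Construct a scenario specification
#'
#' Delta series may be given either as a numeric vector with one value per
#' projection year, or as a 2-column data.frame (\code{year}, \code{value})
#' at coarser steps, which is linearly interpolated to annual resolution.
#' Trade deltas default to zero for every year: food imports and exports
#' remain at baseline unless explicitly overridden. Inequality and the MDER
#' are scalar fields — structurally held fixed across the horizon.
#'
#' @param name scenario label.
#' @param baselineYear first projection year; deltas there must be 0.
#' @param years integer projection years, strictly increasing, starting at
#'   \code{baselineYear}.
#' @param yieldDeltaC3,yieldDeltaC4,tradeDelta fractional delta series
#'   (vector per year, or data.frame(year, value) to be interpolated).
#' @param population a [PopulationTrajectory-class] covering all years.
#' @param inequality an [InequalityModel-class].
#' @param mderFixed MDER in kcal/capita/day, held fixed.
#' @return A [ScenarioSpec-class].
#' @export
ScenarioSpec <- function(name, baselineYear, years, yieldDeltaC3 = 0,
                         yieldDeltaC4 = 0, tradeDelta = 0, population,
                         inequality, mderFixed) {
  years <- as.integer(years)
  expand <- function(d) {
    if (is.data.frame(d)) {
      cols <- if (all(c("year", "value") %in% names(d)))
        d[, c("year", "value")] else d[, 1:2]
      interpolateSeries(cols[[1L]], cols[[2L]], years)
    } else if (length(d) == 1L) rep(as.numeric(d), length(years))
    else as.numeric(d)
  }
  new("ScenarioSpec", name = as.character(name),
      baselineYear = as.integer(baselineYear), years = years,
      yieldDeltaC3 = expand(yieldDeltaC3),
      yieldDeltaC4 = expand(yieldDeltaC4),
      tradeDelta = expand(tradeDelta),
      population = population, inequality = inequality,
      mderFixed = as.numeric(mderFixed))
}

#' Undernourished headcount
#'
#' @param pou prevalence of undernourishment, fraction in [0, 1].
#' @param population total population, persons, >= 0.
#' @return \code{pou * population}, rounded half-up to whole persons.
#' @examples
#' headcount(0.13, 15153846)  # 1970000
#' @export
headcount <- function(pou, population) {
  if (!is.numeric(pou) || any(!is.finite(pou)) || any(pou < 0 | pou > 1))
    stop("pou must lie in [0, 1]")
  if (!is.numeric(population) || any(!is.finite(population)) ||
      any(population < 0))
    stop("population must be >= 0")
  floor(pou * population + 0.5)
}

#' Project undernourishment under a scenario
#'
#' For each projection year t, the baseline balance sheet is updated with
#' that year's yield and trade deltas (always relative to the baseline,
#' never compounded year on year), the dietary energy supply is recomputed
#' at the year's population, and the prevalence of undernourishment is
#' evaluated against the fixed MDER with the fixed inequality spread.
#'
#' @param baselineFbs the baseline [FoodBalanceSheet-class].
#' @param spec a [ScenarioSpec-class].
#' @return A [ProjectionSeries-class] with one row per year: \code{year},
#'   \code{des}, \code{mder}, \code{pou}, \code{population},
#'   \code{undernourished}.
#' @export
projectScenario <- function(baselineFbs, spec) {
  stopifnot(is(baselineFbs, "FoodBalanceSheet"), is(spec, "ScenarioSpec"))
  sigma <- spec@inequality@sigma
  n <- length(spec@years)
  des <- pouV <- popV <- numeric(n)
  for (i in seq_len(n)) {
    yr <- spec@years[i]
    res <- tryCatch({
      sheet <- applyFbsDeltas(baselineFbs, spec@yieldDeltaC3[i],
                              spec@yieldDeltaC4[i], spec@tradeDelta[i])
      p <- populationAt(spec@population, yr)
      d <- dietaryEnergySupply(sheet, p)
      list(des = d, pop = p,
           pou = pou(ConsumptionDistribution(d, sigma), spec@mderFixed))
    }, error = function(e) {
      stop("projection failed at year ", yr, ": ", conditionMessage(e),
           call. = FALSE)
    })
    des[i] <- res$des; popV[i] <- res$pop; pouV[i] <- res$pou
  }
  new("ProjectionSeries", series = data.frame(
    year = spec@years, des = des, mder = spec@mderFixed, pou = pouV,
    population = popV, undernourished = headcount(pouV, popV)))
}

#' @describeIn projectScenario coerce a projection to a data.frame.
#' @param x a ProjectionSeries.
#' @param row.names,optional,... passed on (unused).
#' @export
as.data.frame.ProjectionSeries <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  x@series
}

#' Read a scenario bundle from a structured config file
#'
#' The config (YAML or JSON, by extension) names the input files and
#' scalar parameters:
#' \preformatted{
#' name: demo
#' baseline_year: 2000
#' horizon: 50
#' fbs: fbs.csv
#' cohorts: cohorts.csv          # optional if mder given
#' trajectory: trajectory.csv
#' gini: 0.30                    # or cv: ...
#' mder: 1770                    # optional; computed from cohorts if absent
#' yield_delta_c4: {years: [2000, 2050], values: [0, -0.375]}
#' yield_delta_c3: 0             # scalar, series, or {years, values}
#' trade_delta: 0
#' }
#' Relative file paths are resolved against the config file's directory.
#' Delta series given at coarse years are interpolated to annual steps.
#'
#' @param path path to the YAML/JSON config.
#' @return A list with elements \code{fbs} ([FoodBalanceSheet-class]),
#'   \code{cohorts} ([CohortTable-class] or NULL) and \code{spec}
#'   ([ScenarioSpec-class]).
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop("scenario config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("scenario config missing field: ", field)
    cfg[[field]]
  }

  fbs <- readFbs(resolve(need("fbs")), year = need("baseline_year"))
  ct <- if (!is.null(cfg$cohorts))
    readCohorts(resolve(cfg$cohorts), year = cfg$baseline_year) else NULL
  traj <- readTrajectory(resolve(need("trajectory")), baseStructure = ct)

  ineq <- if (!is.null(cfg$gini)) InequalityModel(gini = cfg$gini)
  else if (!is.null(cfg$cv)) InequalityModel(cv = cfg$cv)
  else stop("scenario config must provide gini or cv")

  mderVal <- if (!is.null(cfg$mder)) cfg$mder
  else if (!is.null(ct)) mder(ct)
  else stop("scenario config must provide mder or a cohorts file")

  y0 <- as.integer(need("baseline_year"))
  years <- y0 + 0:as.integer(need("horizon"))
  delta <- function(field) {
    d <- cfg[[field]]
    if (is.null(d)) return(0)
    if (is.list(d)) data.frame(year = unlist(d$years),
                               value = unlist(d$values))
    else d
  }
  spec <- ScenarioSpec(
    name = if (!is.null(cfg$name)) cfg$name else "scenario",
    baselineYear = y0, years = years,
    yieldDeltaC3 = delta("yield_delta_c3"),
    yieldDeltaC4 = delta("yield_delta_c4"),
    tradeDelta = delta("trade_delta"),
    population = traj, inequality = ineq, mderFixed = mderVal)
  list(fbs = fbs, cohorts = ct, spec = spec)
}

#' Write a projection series as delimited text
#'
#' One row per year with columns
#' \code{year,des,mder,pou,population,undernourished}. For stable output,
#' fractions are written with 6 decimals, energies with 1, persons as
#' integers.
#'
#' @param series a [ProjectionSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProjection <- function(series, path) {
  stopifnot(is(series, "ProjectionSeries"))
  s <- series@series
  out <- data.frame(
    year = s$year,
    des = sprintf("%.1f", s$des),
    mder = sprintf("%.1f", s$mder),
    pou = sprintf("%.6f", s$pou),
    population = sprintf("%.0f", s$population),
    undernourished = sprintf("%.0f", s$undernourished))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a projection series
#'
#' Total population (left axis, millions) and prevalence of undernourishment
#' (right axis, percent) against year, on one panel.
#'
#' @param series a [ProjectionSeries-class].
#' @param main plot title.
#' @return Invisibly, the series data.frame.
#' @importFrom graphics axis legend lines mtext par
#' @export
plotProjection <- function(series, main = "Projected undernourishment") {
  stopifnot(is(series, "ProjectionSeries"))
  s <- series@series
  op <- par(mar = c(5, 4, 4, 4) + 0.1)
  on.exit(par(op))
  plot(s$year, s$population / 1e6, type = "l", lwd = 2, col = "steelblue",
       xlab = "Year", ylab = "Population (millions)", main = main)
  par(new = TRUE)
  plot(s$year, 100 * s$pou, type = "l", lwd = 2, col = "firebrick",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 100))
  axis(4)
  mtext("Undernourishment (%)", side = 4, line = 2.5)
  legend("topleft", legend = c("Population", "PoU"), lwd = 2,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(s)
}
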