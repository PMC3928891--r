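#' Construct a cohort table
#'
#' @param region character(1) region label.
#' @param year integer(1) reference year.
#' @param cohorts data.frame with columns \code{age_band}, \code{sex},
#'   \code{count}, \code{reference_weight}, \code{bmr_slope},
#'   \code{bmr_intercept}, \code{pal}.
#' @return A [CohortTable-class].
#' @export
CohortTable <- function(region, year, cohorts) {
  cohorts <- as.data.frame(cohorts, stringsAsFactors = FALSE)
  cohorts$age_band <- as.character(cohorts$age_band)
  cohorts$sex <- as.character(cohorts$sex)
  new("CohortTable", region = as.character(region), year = as.integer(year),
      cohorts = cohorts)
}

#' @describeIn CohortTable accessor for the cohort data.frame.
#' @param x a CohortTable.
#' @export
cohorts <- function(x) {
  stopifnot(is(x, "CohortTable"))
  x@cohorts
}

#' @describeIn CohortTable total population (sum of cohort counts).
#' @export
totalPopulation <- function(x) {
  stopifnot(is(x, "CohortTable"))
  sum(x@cohorts$count)
}

#' Per-cohort daily energy requirement
#'
#' The minimum energy requirement of one person in a cohort:
#' BMR x PAL, with the basal metabolic rate modelled linearly in body
#' weight, BMR = bmr_slope * reference_weight + bmr_intercept (kcal/day).
#'
#' @param x a [CohortTable-class] or a cohort data.frame (see
#'   [CohortTable()]).
#' @return Numeric vector of requirements (kcal/person/day), one per cohort.
#' @examples
#' # FAO/WHO/UNU-style coefficients, women 18-30, 50 kg, PAL 1.55
#' cohortRequirement(data.frame(age_band = "18-30", sex = "F", count = 1,
#'   reference_weight = 50, bmr_slope = 14.818, bmr_intercept = 486.6,
#'   pal = 1.55))  # 1902.625
#' @export
cohortRequirement <- function(x) {
  ch <- if (is(x, "CohortTable")) x@cohorts else x
  bmr <- ch$bmr_slope * ch$reference_weight + ch$bmr_intercept
  if (any(bmr <= 0))
    stop("nonpositive BMR for cohort(s): ",
         paste(paste(ch$age_band, ch$sex)[bmr <= 0], collapse = ", "))
  bmr * ch$pal
}

#' Minimum dietary energy requirement (MDER)
#'
#' The population-weighted mean of the per-cohort energy requirements: the
#' undernourishment cut-off in kcal per capita per day for the population
#' described by the cohort table.
#'
#' @param table a [CohortTable-class] with positive total population.
#' @return MDER in kcal/capita/day.
#' @export
mder <- function(table) {
  stopifnot(is(table, "CohortTable"))
  counts <- table@cohorts$count
  total <- sum(counts)
  if (total <= 0) stop("total population must be > 0 to compute MDER")
  sum(counts * cohortRequirement(table)) / total
}

#' Construct a population trajectory
#'
#' @param years integer vector of years, strictly increasing.
#' @param totals numeric vector of total population (> 0), one per year.
#' @param baseStructure optional [CohortTable-class] giving the baseline
#'   age-sex structure (held fixed under projection).
#' @return A [PopulationTrajectory-class].
#' @export
PopulationTrajectory <- function(years, totals, baseStructure = NULL) {
  new("PopulationTrajectory", years = as.integer(years),
      totals = as.numeric(totals), baseStructure = baseStructure)
}

#' Population at a given year
#'
#' Returns the trajectory total at a listed year, or the linear
#' interpolation between the two bracketing listed years. Years outside the
#' listed range are an error: no extrapolation.
#'
#' @param traj a [PopulationTrajectory-class].
#' @param year numeric(1) year within the trajectory's range.
#' @return Person count at \code{year}.
#' @export
populationAt <- function(traj, year) {
  stopifnot(is(traj, "PopulationTrajectory"))
  yrs <- traj@years
  if (length(year) != 1L || !is.finite(year))
    stop("year must be a single finite number")
  if (year < yrs[1L] || year > yrs[length(yrs)])
    stop("year ", year, " outside trajectory range [", yrs[1L], ", ",
         yrs[length(yrs)], "]; no extrapolation")
  if (length(yrs) == 1L) return(traj@totals[1L])
  approx(yrs, traj@totals, xout = year, method = "linear")$y
}

#' Default BMR coefficient table
#'
#' The standard FAO/WHO/UNU (Schofield) linear basal-metabolic-rate
#' equations, BMR = slope * weight + intercept in kcal/day, by age band and
#' sex. Shipped as an editable data.frame so the science is swappable
#' without code change; generators and examples draw their coefficients
#' from it.
#'
#' @return data.frame with columns \code{age_min}, \code{age_max},
#'   \code{sex}, \code{bmr_slope} (kcal/kg/day), \code{bmr_intercept}
#'   (kcal/day).
#' @export
defaultBmrTable <- function() {
  data.frame(
    age_min = rep(c(0, 3, 10, 18, 30, 60), 2),
    age_max = rep(c(3, 10, 18, 30, 60, Inf), 2),
    sex = rep(c("M", "F"), each = 6),
    bmr_slope = c(59.512, 22.706, 17.686, 15.057, 11.472, 11.711,
                  58.317, 20.315, 13.384, 14.818, 8.126, 9.082),
    bmr_intercept = c(-30.4, 504.3, 658.2, 692.2, 873.1, 587.7,
                      -31.1, 485.9, 692.6, 486.6, 845.6, 658.5),
    stringsAsFactors = FALSE
  )
}

#' Read / write cohort tables and population trajectories
#'
#' Cohort tables are comma-separated text with the header
#' \code{age_band,sex,count,reference_weight,bmr_slope,bmr_intercept,pal};
#' trajectories use the header \code{year,total}.
#'
#' @param path file path.
#' @param region,year metadata for the cohort table.
#' @return \code{readCohorts} returns a [CohortTable-class];
#'   \code{readTrajectory} a [PopulationTrajectory-class]; the writers
#'   return \code{path} invisibly.
#' @export
readCohorts <- function(path, region = "unknown", year = 0L) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  ch <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(age_band = "character", sex = "character"))
  missing <- setdiff(.COHORT_COLUMNS, names(ch))
  if (length(missing))
    stop("cohort file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  CohortTable(region, year, ch[, .COHORT_COLUMNS])
}

#' @rdname readCohorts
#' @param table a [CohortTable-class] to write.
#' @export
writeCohorts <- function(table, path) {
  stopifnot(is(table, "CohortTable"))
  write.csv(table@cohorts[, .COHORT_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname readCohorts
#' @param baseStructure optional [CohortTable-class] attached to the
#'   trajectory read from file.
#' @export
readTrajectory <- function(path, baseStructure = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "total") %in% names(tr)))
    stop("trajectory file ", path, " must have columns year,total")
  PopulationTrajectory(tr$year, tr$total, baseStructure)
}

#' @rdname readCohorts
#' @param traj a [PopulationTrajectory-class] to write.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "PopulationTrajectory"))
  write.csv(data.frame(year = traj@years, total = traj@totals), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
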