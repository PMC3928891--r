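#' Construct a food balance sheet
#'
#' @param region character(1) region label.
#' @param year integer(1) reference year.
#' @param records data.frame with columns \code{commodity_id},
#'   \code{pathway}, \code{production}, \code{imports}, \code{exports},
#'   \code{nonfood_use}, \code{losses}, \code{energy_density}. Mass flows
#'   are tonnes/yr; energy density is kcal/kg.
#'
#' @return A [FoodBalanceSheet-class].
#' @examples
#' fbs <- FoodBalanceSheet("demo", 2000, data.frame(
#'   commodity_id = "maize", pathway = "C4", production = 2.6e6,
#'   imports = 0, exports = 0, nonfood_use = 0, losses = 0,
#'   energy_density = 3650))
#' dietaryEnergySupply(fbs, 1e7)
#' @export
FoodBalanceSheet <- function(region, year, records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$commodity_id <- as.character(records$commodity_id)
  records$pathway <- as.character(records$pathway)
  new("FoodBalanceSheet", region = as.character(region),
      year = as.integer(year), records = records)
}

#' @describeIn FoodBalanceSheet accessor for the commodity record table.
#' @param x a FoodBalanceSheet.
#' @export
fbsRecords <- function(x) {
  stopifnot(is(x, "FoodBalanceSheet"))
  x@records
}

#' @describeIn FoodBalanceSheet accessor for the region label.
#' @export
fbsRegion <- function(x) {
  stopifnot(is(x, "FoodBalanceSheet"))
  x@region
}

#' @describeIn FoodBalanceSheet accessor for the reference year.
#' @export
fbsYear <- function(x) {
  stopifnot(is(x, "FoodBalanceSheet"))
  x@year
}

#' Net food supply per commodity
#'
#' The mass of each commodity available as food:
#' production + imports - exports - non-food use - losses (tonnes/yr).
#' Negative values are returned as-is; they are rejected with a diagnostic
#' when the dietary energy supply is computed.
#'
#' @param x a [FoodBalanceSheet-class] or its records data.frame.
#' @return Named numeric vector of net supplies (tonnes/yr), one per
#'   commodity.
#' @export
netFoodSupply <- function(x) {
  rec <- if (is(x, "FoodBalanceSheet")) x@records else x
  setNames(rec$production + rec$imports - rec$exports -
             rec$nonfood_use - rec$losses,
           rec$commodity_id)
}

#' Mean dietary energy supply (DES)
#'
#' Converts a food balance sheet into the mean dietary energy supply in
#' kcal per capita per day: the energy content of each commodity's net food
#' supply, summed and divided by population and 365 days.
#'
#' @param fbs a [FoodBalanceSheet-class].
#' @param population total population (persons), > 0.
#' @return DES in kcal/capita/day.
#' @examples
#' fbs <- FoodBalanceSheet("demo", 2000, data.frame(
#'   commodity_id = "maize", pathway = "C4", production = 255500,
#'   imports = 0, exports = 0, nonfood_use = 0, losses = 0,
#'   energy_density = 3650))
#' dietaryEnergySupply(fbs, 1e6)  # 2555
#' @export
dietaryEnergySupply <- function(fbs, population) {
  stopifnot(is(fbs, "FoodBalanceSheet"))
  if (!is.numeric(population) || length(population) != 1L ||
      !is.finite(population) || population <= 0)
    stop("population must be a single positive number")
  net <- netFoodSupply(fbs)
  if (any(net < 0)) {
    bad <- names(net)[net < 0]
    stop("negative net food supply for commodity: ",
         paste(bad, collapse = ", "))
  }
  # tonnes/yr -> kg/yr (x1000), kcal/yr -> kcal/capita/day
  sum(net * 1000 * fbs@records$energy_density) / (population * 365)
}

#' Apply scenario deltas to a food balance sheet
#'
#' Scales production by (1 + yield delta) according to each commodity's
#' photosynthetic pathway (C3 or C4; NONCROP production is left unscaled),
#' and imports and exports by (1 + trade delta). Non-food uses and losses
#' are held at their baseline absolute values. The input sheet is not
#' modified. Deltas are fractions of change from the baseline, e.g. -0.375
#' for a 37.5 percent reduction.
#'
#' @param fbs a [FoodBalanceSheet-class].
#' @param yieldDeltaC3,yieldDeltaC4 fractional production change for C3 and
#'   C4 commodities; must be > -1.
#' @param tradeDelta fractional change of imports and exports; must be > -1.
#' @return A new [FoodBalanceSheet-class].
#' @export
applyFbsDeltas <- function(fbs, yieldDeltaC3 = 0, yieldDeltaC4 = 0,
                           tradeDelta = 0) {
  stopifnot(is(fbs, "FoodBalanceSheet"))
  for (d in c(yieldDeltaC3, yieldDeltaC4, tradeDelta))
    if (!is.finite(d) || d <= -1)
      stop("deltas must be finite and > -1 (got ", d, ")")
  rec <- fbs@records
  scale <- rep(1, nrow(rec))
  scale[rec$pathway == "C3"] <- 1 + yieldDeltaC3
  scale[rec$pathway == "C4"] <- 1 + yieldDeltaC4
  rec$production <- rec$production * scale
  rec$imports <- rec$imports * (1 + tradeDelta)
  rec$exports <- rec$exports * (1 + tradeDelta)
  FoodBalanceSheet(fbs@region, fbs@year, rec)
}

#' Read / write food balance sheets as delimited text
#'
#' Comma-separated UTF-8 files with the header
#' \code{commodity_id,pathway,production,imports,exports,nonfood_use,losses,energy_density}.
#' Values round-trip to at least 6 significant figures.
#'
#' @param path file path.
#' @param region,year sheet metadata (not stored in the file).
#' @return \code{readFbs} returns a [FoodBalanceSheet-class];
#'   \code{writeFbs} returns \code{path} invisibly.
#' @export
readFbs <- function(path, region = "unknown", year = 0L) {
  if (!file.exists(path)) stop("FBS file not found: ", path)
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(commodity_id = "character",
                                 pathway = "character"))
  missing <- setdiff(.FBS_COLUMNS, names(rec))
  if (length(missing))
    stop("FBS file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  FoodBalanceSheet(region, year, rec[, .FBS_COLUMNS])
}

#' @rdname readFbs
#' @param fbs a [FoodBalanceSheet-class] to write.
#' @export
writeFbs <- function(fbs, path) {
  stopifnot(is(fbs, "FoodBalanceSheet"))
  rec <- fbs@records[, .FBS_COLUMNS]
  num <- vapply(rec, is.numeric, logical(1))
  rec[num] <- lapply(rec[num], signif, digits = 15)
  write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
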