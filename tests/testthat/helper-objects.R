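# Quick builders for toy objects used across test files.

toyRecord <- function(commodity_id = "maize", pathway = "C4",
                      production = 0, imports = 0, exports = 0,
                      nonfood_use = 0, losses = 0, energy_density = 0) {
  data.frame(commodity_id = commodity_id, pathway = pathway,
             production = production, imports = imports, exports = exports,
             nonfood_use = nonfood_use, losses = losses,
             energy_density = energy_density, stringsAsFactors = FALSE)
}

toyFbs <- function(records, region = "toy", year = 2000L) {
  FoodBalanceSheet(region, year, records)
}

# A cohort whose requirement is exactly `req` (slope 0, PAL 1).
flatCohort <- function(req, count = 1, age_band = "18-29", sex = "F") {
  data.frame(age_band = age_band, sex = sex, count = count,
             reference_weight = 50, bmr_slope = 0, bmr_intercept = req,
             pal = 1, stringsAsFactors = FALSE)
}

# Random cohort data.frame with n cohorts and valid parameters.
randomCohorts <- function(n) {
  data.frame(
    age_band = paste0("band", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    count = sample(0:5e5, n, replace = TRUE),
    reference_weight = runif(n, 10, 80),
    bmr_slope = runif(n, 8, 25),
    bmr_intercept = runif(n, 400, 900),
    pal = runif(n, 1, 2.4),
    stringsAsFactors = FALSE)
}
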