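#' Monte Carlo validation of the closed-form prevalence
#'
#' For every cell of a (mean DES, Gini, MDER) grid, compares the analytic
#' prevalence of undernourishment with the empirical fraction of \code{n}
#' lognormal draws below the cut-off. A cell passes when the deviation is
#' within \code{kSe} binomial standard errors,
#' \code{sqrt(p * (1 - p) / n)} — so smaller \code{n} automatically widens
#' the tolerance.
#'
#' @param meanDes,gini,mderGrid numeric vectors defining the grid.
#' @param n Monte Carlo sample size per cell.
#' @param seed integer seed; each cell uses a distinct derived seed.
#' @param kSe number of binomial standard errors allowed (default 3).
#' @return data.frame with one row per cell: the parameters, the analytic
#'   and empirical PoU, the binomial SE, the absolute deviation and a
#'   \code{pass} flag. The maximum deviation (in SE units) is attached as
#'   attribute \code{"max_se_units"}.
#' @export
validatePou <- function(meanDes = seq(1600, 3000, length.out = 5),
                        gini = seq(0.15, 0.55, length.out = 5),
                        mderGrid = seq(1400, 2100, length.out = 5),
                        n = 1e6, seed = 1L, kSe = 3) {
  grid <- expand.grid(mean_des = meanDes, gini = gini, mder = mderGrid,
                      KEEP.OUT.ATTRS = FALSE)
  m <- nrow(grid)
  analytic <- empirical <- se <- numeric(m)
  for (i in seq_len(m)) {
    dist <- ConsumptionDistribution(grid$mean_des[i],
                                    InequalityModel(gini = grid$gini[i]))
    analytic[i] <- pou(dist, grid$mder[i])
    draws <- sampleConsumption(dist, n, seed = (seed + i) %% .Machine$integer.max)
    empirical[i] <- mean(draws < grid$mder[i])
    se[i] <- sqrt(analytic[i] * (1 - analytic[i]) / n)
  }
  out <- cbind(grid, analytic = analytic, empirical = empirical, se = se,
               deviation = abs(analytic - empirical))
  out$pass <- out$deviation <= kSe * out$se
  attr(out, "max_se_units") <- max(out$deviation / out$se)
  out
}
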