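logisticSize <- function(t, r, K, n0) {
  cc <- (K - n0) / n0
  K / (1 + cc * exp(-r * t))
}

# closed-form integral of the logistic curve on [0, T]
logisticAuc <- function(tmax, r, K, n0) {
  cc <- (K - n0) / n0
  (K / r) * (log(exp(r * tmax) + cc) - log(1 + cc))
}

#' Simulate a colony-growth fitness screen with known effects
#'
#' Each kinase gets a WT and a DEAD strain; every plate carries a reference
#' strain without a kinase coding sequence. Colony sizes follow logistic
#' growth; the WT-specific fitness effect multiplies the growth rate by
#' \code{1 - effect}, which monotonically reduces the true AUC. Noise is
#' multiplicative log-normal per measurement.
#'
#' @param effects named numeric vector in [0,1]: per-kinase WT growth-rate
#'   reduction (0 = no fitness cost).
#' @param conditions character vector of growth-condition names.
#' @param replicates colonies per strain x condition.
#' @param timepoints number of measurements (every 1.5 h, as in automated
#'   plate imaging).
#' @param noiseCV multiplicative measurement noise CV.
#' @param baseline initial colony size added to every curve (removed by
#'   baseline subtraction downstream).
#' @param seed integer seed.
#' @return list: \code{curves} (data.frame as read by [readGrowthCurves()]),
#'   \code{truth} (per strain x condition: r, K, n0, true noiseless AUC,
#'   true WT-dead effect).
#' @export
genGrowthExperiment <- function(effects, conditions = "SC",
                                replicates = 16, timepoints = 20,
                                noiseCV = 0.05, baseline = 50, seed = 1) {
  stopifnot(all(effects >= 0 & effects <= 1), timepoints >= 3)
  kinases <- names(effects)
  withSeed(seed, {
    t <- seq(0, by = 1.5, length.out = timepoints)
    strains <- c("REF", paste0(kinases, "_WT"), paste0(kinases, "_DEAD"))
    rows <- list(); truthRows <- list()
    for (cond in conditions) {
      rBase <- runif(1, 0.35, 0.5); K <- runif(1, 800, 1200)
      for (s in strains) {
        eff <- 0
        if (grepl("_WT$", s)) eff <- effects[[sub("_WT$", "", s)]]
        r <- rBase * (1 - eff); n0 <- 10
        truthRows[[length(truthRows) + 1]] <- data.frame(
          strain = s, condition = cond, r = r, K = K, n0 = n0,
          effect = eff, true_auc = logisticAuc(max(t), r, K, n0))
        for (rep in seq_len(replicates)) {
          sz <- logisticSize(t, r, K, n0) * lnoise(length(t), noiseCV) +
            baseline
          rows[[length(rows) + 1]] <- data.frame(
            strain = s, condition = cond, replicate = rep, time_h = t,
            size = sz, circularity = runif(1, 0.75, 1))
        }
      }
    }
    list(curves = do.call(rbind, rows), truth = do.call(rbind, truthRows),
         params = list(effects = effects, noiseCV = noiseCV, seed = seed))
  })
}
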