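#' Baseline-correct and quality-filter one colony growth curve
#'
#' Subtracts the initial colony size from every time point (values dipping
#' below the baseline are clipped at 0 and counted) and flags the colony for
#' removal when its circularity is below the threshold.
#'
#' @param time strictly increasing time vector (hours), >= 3 points.
#' @param size colony sizes.
#' @param circularity colony circularity in [0,1].
#' @param circularityMin filter threshold (default 0.6).
#' @return list: time, size (corrected), n_clipped, keep.
#' @export
preprocessCurve <- function(time, size, circularity = 1,
                            circularityMin = 0.6) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(time) < 3) stop("need >= 3 time points")
  corrected <- size - size[1]
  nClip <- sum(corrected < 0)
  corrected[corrected < 0] <- 0
  list(time = time, size = corrected, n_clipped = nClip,
       keep = circularity >= circularityMin)
}

#' Composite Simpson area under a curve
#'
#' Uniform grids with an even number of intervals use the pure composite
#' Simpson rule (exact for cubics); non-uniform grids use the interval-wise
#' quadratic (Simpson-on-triples) generalisation; an odd trailing interval
#' falls back to the trapezoid on that interval. Two points degrade to the
#' trapezoid with a warning.
#'
#' @param time increasing abscissae.
#' @param value ordinates.
#' @return the area.
#' @export
aucSimpson <- function(time, value) {
  n <- length(time)
  stopifnot(n == length(value), all(diff(time) > 0))
  if (n == 2) {
    warning("only 2 points; using trapezoid")
    return(diff(time) * mean(value))
  }
  area <- 0
  i <- 1
  while (i + 2 <= n) {
    t0 <- time[i]; t1 <- time[i + 1]; t2 <- time[i + 2]
    f0 <- value[i]; f1 <- value[i + 1]; f2 <- value[i + 2]
    h0 <- t1 - t0; h1 <- t2 - t1
    # exact integral of the quadratic through the three points
    area <- area + (h0 + h1) / 6 *
      ((2 - h1 / h0) * f0 +
         (h0 + h1)^2 / (h0 * h1) * f1 +
         (2 - h0 / h1) * f2)
    i <- i + 2
  }
  if (i < n)  # one interval left
    area <- area + (time[n] - time[n - 1]) * (value[n] + value[n - 1]) / 2
  area
}

#' Rescale colony AUCs within plates and score WT-dead fitness
#'
#' Every colony AUC is divided by its plate's mean reference-strain AUC
#' (plates without the reference are excluded and logged). Per kinase and
#' condition the fitness score is delta = mean rescaled WT AUC - mean
#' rescaled DEAD AUC, tested by a two-sided Mann-Whitney U on the replicate
#' rescaled AUCs (exact for <= 20 per arm, normal approximation with tie
#' correction otherwise), with BH correction across all kinase x condition
#' pairs.
#'
#' @param aucs data.frame: strain, condition, replicate, plate, auc; strain
#'   names are \code{REF}, \code{<kinase>_WT}, \code{<kinase>_DEAD}.
#' @param refStrain reference strain name (default "REF").
#' @return data.frame per kinase x condition: auc_wt, auc_dead, delta, p, q,
#'   n_wt, n_dead; per-kinase minimum and median delta in
#'   \code{attr(,"perKinase")}.
#' @export
rescaleAndScore <- function(aucs, refStrain = "REF") {
  if (!"plate" %in% colnames(aucs)) aucs$plate <- aucs$condition
  refMean <- vapply(split(aucs, aucs$plate), function(d)
    mean(d$auc[d$strain == refStrain]), 0)
  bad <- names(refMean)[!is.finite(refMean)]
  if (length(bad)) {
    message("plate(s) without reference excluded: ",
            paste(bad, collapse = ", "))
    aucs <- aucs[!aucs$plate %in% bad, , drop = FALSE]
    if (!nrow(aucs)) return(NULL)
  }
  aucs$rescaled <- aucs$auc / refMean[as.character(aucs$plate)]
  kin <- aucs[aucs$strain != refStrain, , drop = FALSE]
  kin$kinase <- sub("_(WT|DEAD)$", "", kin$strain)
  kin$status <- sub("^.*_(WT|DEAD)$", "\\1", kin$strain)
  res <- do.call(rbind, lapply(
    split(kin, list(kin$kinase, kin$condition), drop = TRUE), function(d) {
      w <- d$rescaled[d$status == "WT"]; dd <- d$rescaled[d$status == "DEAD"]
      if (!length(w) || !length(dd)) return(NULL)
      exact <- length(w) <= 20 && length(dd) <= 20 &&
        !any(duplicated(c(w, dd)))
      p <- suppressWarnings(
        wilcox.test(w, dd, exact = exact, correct = TRUE)$p.value)
      if (is.nan(p)) p <- 1   # all values tied
      data.frame(kinase = d$kinase[1], condition = d$condition[1],
                 auc_wt = mean(w), auc_dead = mean(dd),
                 delta = mean(w) - mean(dd), p = p,
                 n_wt = length(w), n_dead = length(dd))
    }))
  res$q <- p.adjust(res$p, "BH")
  rownames(res) <- NULL
  perKinase <- do.call(rbind, lapply(split(res, res$kinase), function(d)
    data.frame(kinase = d$kinase[1], min_delta = min(d$delta),
               median_delta = median(d$delta), min_q = min(d$q))))
  attr(res, "perKinase") <- perKinase
  res
}

#' Full fitness stage from raw growth curves
#'
#' Applies [preprocessCurve()] per colony, [aucSimpson()], and
#' [rescaleAndScore()].
#'
#' @param curves data.frame from [readGrowthCurves()].
#' @param circularityMin circularity filter (default 0.6).
#' @param refStrain reference strain name.
#' @return see [rescaleAndScore()].
#' @export
fitnessScores <- function(curves, circularityMin = 0.6, refStrain = "REF") {
  key <- paste(curves$strain, curves$condition, curves$replicate, sep = "\r")
  aucs <- do.call(rbind, lapply(split(curves, key), function(d) {
    pc <- preprocessCurve(d$time_h, d$size, d$circularity[1], circularityMin)
    if (!pc$keep) return(NULL)
    data.frame(strain = d$strain[1], condition = d$condition[1],
               replicate = d$replicate[1], plate = d$condition[1],
               auc = aucSimpson(pc$time, pc$size))
  }))
  rescaleAndScore(aucs, refStrain = refStrain)
}

#' Correlate per-kinase fitness with regulated pY counts
#'
#' Pearson correlation between the number of upregulated pY sites per kinase
#' and the per-kinase fitness score (minimum or median WT-dead delta across
#' conditions). Optionally restrict counts to a flagged subset (e.g.
#' destabilising or conservation-deleterious sites).
#'
#' @param counts named numeric: regulated pY sites per kinase.
#' @param deltas named numeric: fitness delta per kinase.
#' @return list: r, p, n (NA r when either vector has zero variance).
#' @export
fitnessPhosphoCorrelation <- function(counts, deltas) {
  common <- intersect(names(counts), names(deltas))
  if (length(common) < 4) stop("need >= 4 kinases")
  x <- counts[common]; y <- deltas[common]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(common)))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
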