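#' maxLFQ protein profile from a peptide intensity matrix
#'
#' Cox et al label-free quantification: for every sample pair sharing at
#' least \code{minRatioCount} peptides, the median pairwise peptide log-ratio
#' is computed; sample log-intensities reproducing those ratios are the
#' least-squares solution of the ratio graph (solved per connected
#' component); each component is rescaled so its summed protein intensity
#' equals the summed peptide intensity of its samples. Samples with no
#' quantified peptides are undefined (NA).
#'
#' @param pepm numeric matrix (peptides x samples), linear intensities,
#'   NA = not quantified.
#' @param minRatioCount minimum shared peptides for a pairwise ratio edge.
#' @return list: \code{intensity} (named per-sample profile),
#'   \code{nPeptides} contributing peptide count per sample.
#' @export
maxLfq <- function(pepm, minRatioCount = 1) {
  pepm <- as.matrix(pepm)
  if (!nrow(pepm)) stop("no peptides")
  ns <- ncol(pepm)
  lg <- log(pepm)
  hasData <- colSums(!is.na(pepm)) > 0
  # pairwise median log ratios
  A <- matrix(0, ns, ns); cnt <- matrix(0L, ns, ns)
  for (j in seq_len(ns - 1)) for (k in (j + 1):ns) {
    sh <- !is.na(lg[, j]) & !is.na(lg[, k])
    if (sum(sh) >= minRatioCount) {
      A[j, k] <- median(lg[sh, j] - lg[sh, k])
      cnt[j, k] <- sum(sh)
    }
  }
  conn <- cnt + t(cnt) > 0
  comp <- .components(conn | diag(TRUE, ns))
  w <- rep(NA_real_, ns)
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp & hasData)
    if (!length(idx)) next
    if (length(idx) == 1) { w[idx] <- 0 } else {
      # least squares: minimise sum over edges (w_j - w_k - r_jk)^2, mean w = 0
      n <- length(idx)
      L <- matrix(0, n, n); rhs <- numeric(n)
      for (aj in seq_len(n - 1)) for (ak in (aj + 1):n) {
        j <- idx[aj]; k <- idx[ak]
        if (cnt[j, k] > 0 || cnt[k, j] > 0) {
          r <- if (cnt[j, k] > 0) A[j, k] else -A[k, j]
          L[aj, aj] <- L[aj, aj] + 1; L[ak, ak] <- L[ak, ak] + 1
          L[aj, ak] <- L[aj, ak] - 1; L[ak, aj] <- L[ak, aj] - 1
          rhs[aj] <- rhs[aj] + r; rhs[ak] <- rhs[ak] - r
        }
      }
      sol <- qr.solve(L + matrix(1 / n, n, n), rhs)
      w[idx] <- sol - mean(sol)
    }
    tot <- sum(pepm[, idx], na.rm = TRUE)
    prof <- exp(w[idx])
    w[idx] <- log(prof * tot / sum(prof))
  }
  intensity <- exp(w)
  intensity[!hasData] <- NA_real_
  names(intensity) <- colnames(pepm)
  list(intensity = intensity, nPeptides = colSums(!is.na(pepm)))
}

.components <- function(adj) {
  n <- nrow(adj); comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Per-protein maxLFQ profiles for a stoichiometry run
#'
#' Builds each protein's peptide matrix from non-phosphorylated precursors
#' whose phosphorylated counterparts (same stripped peptide) did not exhibit
#' significant regulation, plus unmodified peptides without any phospho
#' counterpart, and runs [maxLfq()].
#'
#' @param x a [PrecursorExperiment-class].
#' @param regulation RegulationResult data.frame (all contrasts) used for the
#'   exclusion rule; NULL disables it.
#' @return list per protein: maxLfq output.
#' @export
proteinLfq <- function(x, regulation = NULL) {
  rd <- rowData(x)
  m <- assay(x, "intensity")
  regPeptides <- character()
  if (!is.null(regulation) && nrow(regulation)) {
    sig <- regulation[regulation$direction %in% c("up", "down"), ,
                      drop = FALSE]
    regPeptides <- unique(paste(sig$protein,
                                sub("/.*$", "", sig$feature)))
  }
  useRow <- !rd$is_phospho &
    !(paste(rd$protein, rd$peptide) %in% regPeptides)
  lapply(split(which(useRow), rd$protein[useRow]), function(i) {
    maxLfq(m[i, , drop = FALSE])
  })
}

#' Assemble stoichiometry groups
#'
#' Applies, in order, the four admission filters on maxLFQ-normalised
#' precursors: (1) keep only the highest-abundant charge state per modified
#' peptide; (2) phosphorylated precursors must be fully quantified in at
#' least one condition; (3) non-phosphorylated precursors must be fully
#' quantified in all conditions; (4) keep only non-phosphorylated precursors
#' with exactly one phosphorylated counterpart (same stripped peptide) - the
#' "stoichiometry group". Remaining unquantified phospho intensities are
#' imputed to 0. Intensities are divided by the sample's protein maxLFQ value
#' before grouping; samples where the protein has no LFQ value are dropped
#' from the group.
#'
#' @param x a [PrecursorExperiment-class] already passed through the
#'   stoichiometry-stage [filterPrecursors()].
#' @param lfq output of [proteinLfq()].
#' @return list of groups, each with \code{site}, \code{protein},
#'   \code{phospho}, \code{nonphospho} (row keys) and numeric vectors
#'   \code{x} (phospho) and \code{y} (non-phospho) per usable sample;
#'   per-filter drop counts attached.
#' @export
buildStoichiometryGroups <- function(x, lfq) {
  rd <- rowData(x)
  m <- assay(x, "intensity")
  cd <- colData(x)
  condOf <- paste(cd$kinase, cd$status)
  counts <- c()

  # filter 1: highest-abundant charge state per modified peptide
  tot <- rowSums(m, na.rm = TRUE)
  keyMod <- paste(rd$protein, rd$modified)
  best <- unlist(lapply(split(seq_len(nrow(m)), keyMod),
                        function(i) i[which.max(tot[i])]))
  counts["charge_state"] <- nrow(m) - length(best)
  sel <- sort(unname(best))
  rd <- rd[sel, , drop = FALSE]; m <- m[sel, , drop = FALSE]

  fullIn <- function(v, cond) all(!is.na(v[condOf == cond]))
  conds <- unique(condOf)
  # filter 2: phospho fully quantified in >= 1 condition
  ph <- which(rd$is_phospho)
  ok2 <- vapply(ph, function(i)
    any(vapply(conds, function(cc) fullIn(m[i, ], cc), TRUE)), TRUE)
  counts["phospho_complete_one_condition"] <- sum(!ok2)
  dropPh <- ph[!ok2]
  # filter 3: non-phospho fully quantified in all conditions
  np <- which(!rd$is_phospho)
  ok3 <- vapply(np, function(i)
    all(vapply(conds, function(cc) fullIn(m[i, ], cc), TRUE)), TRUE)
  counts["nonphospho_complete_all"] <- sum(!ok3)
  dropNp <- np[!ok3]
  keep <- setdiff(seq_len(nrow(m)), c(dropPh, dropNp))
  rd <- rd[keep, , drop = FALSE]; m <- m[keep, , drop = FALSE]

  # filter 4: exactly one phospho counterpart per non-phospho precursor
  groups <- list()
  nAmbiguous <- 0L; nNoLfq <- 0L
  for (i in which(!rd$is_phospho)) {
    mates <- which(rd$is_phospho & rd$protein == rd$protein[i] &
                     rd$peptide == rd$peptide[i])
    if (length(mates) != 1) {
      if (length(mates) > 1) nAmbiguous <- nAmbiguous + 1L
      next
    }
    j <- mates
    prot <- rd$protein[i]
    norm <- lfq[[prot]]$intensity
    if (is.null(norm)) { nNoLfq <- nNoLfq + 1L; next }
    usable <- !is.na(norm)
    if (!any(usable)) { nNoLfq <- nNoLfq + 1L; next }
    xv <- m[j, ] / norm
    yv <- m[i, ] / norm
    xv[is.na(xv) & usable] <- 0   # zero-imputation of missing phospho
    groups[[length(groups) + 1]] <- list(
      site = paste0(prot, "_", rd$site_positions[j]),
      protein = prot,
      phospho = rownames(m)[j], nonphospho = rownames(m)[i],
      x = xv[usable], y = yv[usable],
      condition = condOf[usable])
  }
  counts["phospho_counterpart_not_unique"] <- nAmbiguous
  counts["protein_without_lfq"] <- nNoLfq
  withDropCounts(groups, counts)
}

#' Fit per-sample occupancy for one stoichiometry group
#'
#' Ordinary least squares of the non-phospho intensity y on the phospho
#' intensity x across samples. A non-negative slope makes the group
#' \code{"illegal_positive_slope"} (it would imply occupancies below 0\% or
#' above 100\%); otherwise the x-intercept \code{x_max = -a/b} is the
#' intensity of the fully phosphorylated pool and the per-sample occupancy is
#' \code{p_s = x_s / x_max}, clamped to [0,1] with the raw value retained.
#'
#' @param group one group from [buildStoichiometryGroups()] (needs \code{x},
#'   \code{y}, optionally \code{condition}).
#' @return the group extended with \code{a}, \code{b}, \code{x_max},
#'   \code{p} (clamped), \code{p_raw}, \code{status}, and (when conditions
#'   are present) \code{p_condition}, the per-condition mean occupancy.
#' @export
fitOccupancy <- function(group) {
  ok <- is.finite(group$x) & is.finite(group$y)
  if (sum(ok) < 3) {
    group$status <- "insufficient_data"
    return(group)
  }
  x <- group$x[ok]; y <- group$y[ok]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  group$a <- a; group$b <- b
  if (!is.finite(b) || b >= 0) {
    group$status <- "illegal_positive_slope"
    return(group)
  }
  xmax <- -a / b
  group$x_max <- xmax
  praw <- group$x / xmax
  group$p_raw <- praw
  group$p <- pmin(pmax(praw, 0), 1)
  group$status <- "valid"
  if (!is.null(group$condition))
    group$p_condition <- vapply(split(group$p[ok], group$condition[ok]),
                                mean, 0)
  group
}

#' Occupancy tables for a set of stoichiometry groups
#'
#' @param groups output of [buildStoichiometryGroups()].
#' @return list: \code{occupancy} (site, sample, condition, p, p_raw,
#'   status), \code{summary} (condition, median occupancy over valid sites,
#'   n_sites), \code{status} per group.
#' @export
occupancySummary <- function(groups) {
  fitted <- lapply(groups, fitOccupancy)
  occ <- do.call(rbind, lapply(fitted, function(g) {
    if (g$status != "valid") return(NULL)
    data.frame(site = g$site, sample = names(g$x) %||%
                 as.character(seq_along(g$x)),
               condition = g$condition %||% NA_character_,
               p = g$p, p_raw = g$p_raw, row.names = NULL)
  }))
  status <- vapply(fitted, `[[`, "", "status")
  summ <- NULL
  if (!is.null(occ) && nrow(occ)) {
    perSite <- lapply(split(occ, list(occ$site, occ$condition), drop = TRUE),
                      function(d) data.frame(site = d$site[1],
                                             condition = d$condition[1],
                                             p = mean(d$p)))
    perSite <- do.call(rbind, perSite)
    summ <- do.call(rbind, lapply(split(perSite, perSite$condition),
      function(d) data.frame(condition = d$condition[1],
                             median_occupancy = median(d$p),
                             n_sites = nrow(d))))
  }
  list(occupancy = occ, summary = summ, status = status, groups = fitted)
}
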