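#' Confidence-filter DIA precursors
#'
#' Regulation stage: keep records with \code{q_value <= 0.01} and
#' \code{global_q_value <= 0.01}, and (phosphorylated records only)
#' \code{ptm_site_confidence >= 0.75}. The stoichiometry stage additionally
#' requires \code{ptm_q_value <= 0.01} on phosphorylated records. Bounds are
#' inclusive. Per-filter drop counts are attached (see [dropCounts()]).
#'
#' @param x a [PrecursorExperiment-class].
#' @param stage \code{"regulation"} or \code{"stoichiometry"}.
#' @param fdr precursor FDR bound (default 0.01).
#' @param siteConfidence minimum localization confidence (default 0.75).
#' @return filtered [PrecursorExperiment-class].
#' @export
filterPrecursors <- function(x, stage = c("regulation", "stoichiometry"),
                             fdr = 0.01, siteConfidence = 0.75) {
  stage <- match.arg(stage)
  rd <- rowData(x)
  counts <- c()
  keep <- !is.na(rd$q_value) & rd$q_value <= fdr
  counts["q_value"] <- sum(!keep)
  k2 <- !is.na(rd$global_q_value) & rd$global_q_value <= fdr
  counts["global_q_value"] <- sum(keep & !k2)
  keep <- keep & k2
  k3 <- !rd$is_phospho |
    (!is.na(rd$ptm_site_confidence) & rd$ptm_site_confidence >= siteConfidence)
  counts["ptm_site_confidence"] <- sum(keep & !k3)
  keep <- keep & k3
  if (stage == "stoichiometry") {
    k4 <- !rd$is_phospho | (!is.na(rd$ptm_q_value) & rd$ptm_q_value <= fdr)
    counts["ptm_q_value"] <- sum(keep & !k4)
    keep <- keep & k4
  }
  withDropCounts(x[keep, ], counts)
}

#' Replicate-completeness filter for one contrast
#'
#' A feature is retained iff it was quantified in at least
#' \code{threshold} (default 75\%) of the replicates of at least one of the
#' two conditions. Among retained features, a condition is marked for
#' imputation iff all of its replicates are missing.
#'
#' @param m intensity matrix (features x samples, NA = not quantified).
#' @param groupA,groupB column indices/names of the two conditions
#'   (each >= 2 replicates).
#' @param threshold minimum quantified fraction.
#' @return list: \code{keep} logical per feature, \code{imputeA},
#'   \code{imputeB} logical per retained feature, \code{nDroppedEmpty}
#'   features absent in both conditions.
#' @export
completenessFilter <- function(m, groupA, groupB, threshold = 0.75) {
  a <- m[, groupA, drop = FALSE]; b <- m[, groupB, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 replicates per condition")
  fa <- rowMeans(!is.na(a)); fb <- rowMeans(!is.na(b))
  keep <- fa >= threshold | fb >= threshold
  list(keep = keep,
       imputeA = (fa == 0)[keep],
       imputeB = (fb == 0)[keep],
       nDroppedEmpty = sum(fa == 0 & fb == 0))
}

#' Perseus-style left-shifted imputation of an all-missing condition
#'
#' Masked feature-condition blocks are drawn from
#' \eqn{N(\mu - 1.8\sigma, (0.3\sigma)^2)} where \eqn{\mu} and \eqn{\sigma}
#' are the mean and sd of all observed log2 intensities pooled over both
#' conditions of the contrast. Observed cells are never altered.
#'
#' @param logm log2-intensity matrix of the two conditions (features x
#'   samples, NA = missing).
#' @param groupA,groupB column indices of the two conditions.
#' @param imputeA,imputeB logical per feature: impute that condition's block.
#' @param seed integer seed.
#' @param shift,scale imputation parameters (defaults 1.8 and 0.3).
#' @return completed matrix.
#' @export
imputeCondition <- function(logm, groupA, groupB, imputeA, imputeB,
                            seed = 1, shift = 1.8, scale = 0.3) {
  obs <- logm[, c(groupA, groupB), drop = FALSE]
  mu <- mean(obs, na.rm = TRUE)
  sdv <- sd(as.vector(obs), na.rm = TRUE)
  if (is.na(sdv) || sdv == 0) {
    warning("sd of observed data is 0; imputing the constant mean")
    sdv <- 0
  }
  withSeed(seed, {
    for (i in which(imputeA))
      logm[i, groupA] <- rnorm(length(groupA), mu - shift * sdv, scale * sdv)
    for (i in which(imputeB))
      logm[i, groupB] <- rnorm(length(groupB), mu - shift * sdv, scale * sdv)
  })
  logm
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per feature, the two-group linear model gives \code{log2FC = mean(A) -
#' mean(B)} and a residual variance \eqn{s_g^2} on \eqn{d_g} degrees of
#' freedom. The prior \eqn{(d_0, s_0^2)} is estimated from the distribution
#' of \eqn{\log s_g^2} by the closed-form moments method
#' (via \code{limma::squeezeVar}); the posterior variance
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} yields a moderated
#' t on \eqn{d_0 + d_g} df, two-sided p, and Benjamini-Hochberg q across
#' features. If the prior cannot be estimated (e.g. all features
#' zero-variance) the ordinary t-test is used with a warning.
#'
#' @param logm completed log2 matrix.
#' @param groupA,groupB column indices (>= 2 each); the contrast is A - B
#'   (conventionally WT - DEAD).
#' @param qThreshold q-value cutoff for the up/down/ns direction call.
#' @return data.frame: feature, log2fc, s2, t_mod, df_total, p, q, direction,
#'   with the shrinkage parameters in \code{attr(, "shrinkage")}.
#' @export
moderatedTest <- function(logm, groupA, groupB, qThreshold = 0.01) {
  a <- logm[, groupA, drop = FALSE]; b <- logm[, groupB, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 values per group")
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  rss <- rowSums((a - ma)^2, na.rm = TRUE) + rowSums((b - mb)^2, na.rm = TRUE)
  dg <- na + nb - 2
  s2 <- rss / dg
  sq <- tryCatch(limma::squeezeVar(s2, df = dg),
                 error = function(e) NULL)
  if (is.null(sq) || !is.finite(sq$var.prior)) {
    warning("prior variance estimation failed; using ordinary t")
    sq <- list(var.post = s2, var.prior = NA_real_, df.prior = 0)
  }
  d0 <- sq$df.prior
  stilde2 <- sq$var.post
  se <- sqrt(stilde2 * (1 / na + 1 / nb))
  lfc <- ma - mb
  t <- ifelse(se > 0, lfc / se, 0)
  # cap total df at the pooled residual df (information cannot exceed it)
  dfTotal <- pmin(d0 + dg, sum(dg))
  p <- 2 * pt(-abs(t), df = dfTotal)
  p[se == 0 & lfc == 0] <- 1
  q <- p.adjust(p, method = "BH")
  dir <- ifelse(q <= qThreshold, ifelse(lfc > 0, "up", "down"), "ns")
  res <- data.frame(feature = rownames(logm) %||%
                      as.character(seq_len(nrow(logm))),
                    log2fc = lfc, s2 = s2, t_mod = t, df_total = dfTotal,
                    p = p, q = q, direction = dir,
                    stringsAsFactors = FALSE)
  attr(res, "shrinkage") <- list(d0 = d0, s0_sq = sq$var.prior,
                                 s_tilde_sq = stilde2)
  res
}

#' Regulation analysis of one WT-vs-dead contrast
#'
#' Applies the regulation-stage confidence filter, the 75\%-completeness
#' filter, log2 transform, all-missing-condition imputation and the moderated
#' t-test for one kinase's WT vs DEAD contrast.
#'
#' @param x a [PrecursorExperiment-class] with a design in \code{colData}.
#' @param kinase kinase name present in the design.
#' @param qThreshold direction-call cutoff.
#' @param seed imputation seed.
#' @param phosphoOnly restrict to phosphorylated precursors (default TRUE).
#' @return RegulationResult data.frame (one row per retained precursor) with
#'   columns feature, protein, site_positions, kinase, log2fc, t_mod,
#'   df_total, p, q, direction, imputed_wt, imputed_dead.
#' @export
regulationContrast <- function(x, kinase, qThreshold = 0.01, seed = 1,
                               phosphoOnly = TRUE) {
  xf <- filterPrecursors(x, "regulation")
  if (phosphoOnly) xf <- xf[rowData(xf)$is_phospho, ]
  cd <- colData(xf)
  ga <- which(cd$kinase == kinase & cd$status == "WT")
  gb <- which(cd$kinase == kinase & cd$status == "DEAD")
  if (!length(ga) || !length(gb))
    stop("kinase ", kinase, " lacks WT or DEAD samples")
  m <- assay(xf, "intensity")
  cf <- completenessFilter(m, ga, gb)
  xf <- xf[cf$keep, ]
  logm <- log2(assay(xf, "intensity"))
  logm <- imputeCondition(logm, ga, gb, cf$imputeA, cf$imputeB, seed = seed)
  res <- moderatedTest(logm[, c(ga, gb), drop = FALSE],
                       seq_along(ga), length(ga) + seq_along(gb),
                       qThreshold = qThreshold)
  rd <- rowData(xf)
  res$protein <- rd$protein
  res$site_positions <- rd$site_positions
  res$kinase <- kinase
  res$imputed_wt <- cf$imputeA
  res$imputed_dead <- cf$imputeB
  res
}

#' Aggregate precursor-level regulation calls to phosphosites
#'
#' A site is up (down) for a kinase iff at least one covering precursor is
#' significantly up (down). A site called both up and down through different
#' precursors is flagged \code{"conflict"}, excluded from the counts, and
#' logged. Counts are reported per kinase split by acceptor class (Y vs
#' S/T), using the proteome to read the acceptor letter.
#'
#' @param reg RegulationResult data.frame from [regulationContrast()] (rows
#'   may span several kinases).
#' @param proteome named character vector of protein sequences.
#' @return list: \code{sites} (kinase, protein, position, acceptor, call),
#'   \code{counts} (kinase x direction x acceptor-class table as data.frame),
#'   \code{nConflicts}.
#' @export
aggregateToSites <- function(reg, proteome) {
  reg <- reg[nzchar(reg$site_positions), , drop = FALSE]
  expanded <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    pos <- parseSitePositions(reg$site_positions[i])
    if (!length(pos)) return(NULL)
    data.frame(kinase = reg$kinase[i], protein = reg$protein[i],
               position = pos, direction = reg$direction[i])
  }))
  if (is.null(expanded))
    return(list(sites = data.frame(), counts = data.frame(), nConflicts = 0L))
  key <- paste(expanded$kinase, expanded$protein, expanded$position)
  call1 <- vapply(split(expanded$direction, key), function(d) {
    up <- "up" %in% d; dn <- "down" %in% d
    if (up && dn) "conflict" else if (up) "up" else if (dn) "down" else "ns"
  }, "")
  first <- expanded[!duplicated(key), , drop = FALSE]
  first <- first[order(match(paste(first$kinase, first$protein,
                                   first$position), names(call1))), ]
  sites <- data.frame(first[c("kinase", "protein", "position")],
                      call = call1[paste(first$kinase, first$protein,
                                         first$position)])
  sites$acceptor <- vapply(seq_len(nrow(sites)), function(i) {
    sq <- proteome[[sites$protein[i]]]
    if (is.null(sq) || is.na(sq)) NA_character_
    else substring(sq, sites$position[i], sites$position[i])
  }, "")
  nConf <- sum(sites$call == "conflict")
  if (nConf) message(nConf, " site(s) with conflicting calls excluded")
  ok <- sites$call %in% c("up", "down")
  cls <- ifelse(sites$acceptor == "Y", "pY", "pST")
  counts <- as.data.frame(table(kinase = sites$kinase[ok],
                                direction = sites$call[ok],
                                class = cls[ok]))
  list(sites = sites, counts = counts, nConflicts = nConf)
}

#' Kinase-substrate (or any set) enrichment by Fisher's exact test
#'
#' For each annotation set, a two-sided Fisher exact test of the 2x2 table
#' (regulated & in set, regulated & not, in set & not regulated, rest) with
#' the whole measured phosphoproteome as the background; BH correction across
#' sets; sets kept iff q below the threshold.
#'
#' @param regulated character vector of regulated site ids.
#' @param sets named list of character vectors (annotation sets, subsets of
#'   the background).
#' @param background character vector: all measured sites.
#' @param qThreshold retention cutoff (default 0.01).
#' @return data.frame: set, n_set, n_overlap, odds_ratio, p, q, kept.
#' @export
kinaseSubstrateEnrichment <- function(regulated, sets, background,
                                      qThreshold = 0.01) {
  regulated <- intersect(regulated, background)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    if (!length(s)) {
      warning("empty annotation set ", nm, " skipped")
      return(NULL)
    }
    a <- length(intersect(regulated, s))
    b <- length(regulated) - a
    cc <- length(s) - a
    d <- length(background) - a - b - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    data.frame(set = nm, n_set = length(s), n_overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  res$q <- p.adjust(res$p, "BH")
  res$kept <- res$q < qThreshold
  res
}
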