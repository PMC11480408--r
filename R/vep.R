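#' Admission filter for a query-anchored alignment
#'
#' Drops any hit with a gap fraction of 0.5 or more over the query columns
#' (inclusive bound); the alignment is admissible iff at least
#' \code{minHits} (20) hits remain (the query does not count as a hit).
#'
#' @param panel an [OrthologPanel-class] or \code{AAStringSet} whose first /
#'   named query sequence anchors the columns.
#' @param query query sequence name (defaults to the panel's query).
#' @param minHits admissibility threshold.
#' @return list: \code{alignment} (retained sequences), \code{admissible},
#'   \code{nHits}, \code{dropped} (names of removed hits).
#' @export
admitAlignment <- function(panel, query = NULL, minHits = 20) {
  aln <- if (methods::is(panel, "OrthologPanel")) panel@alignment else panel
  if (is.null(query))
    query <- if (methods::is(panel, "OrthologPanel")) panel@query
             else names(aln)[1]
  if (!length(aln) || !query %in% names(aln)) {
    message("empty or query-less alignment: inadmissible")
    return(list(alignment = aln, admissible = FALSE, nHits = 0L,
                dropped = character()))
  }
  qchars <- strsplit(as.character(aln[[query]]), "")[[1]]
  qcols <- which(qchars != "-")
  hits <- setdiff(names(aln), query)
  gapFrac <- vapply(hits, function(h) {
    s <- strsplit(as.character(aln[[h]]), "")[[1]][qcols]
    mean(s == "-")
  }, 0)
  dropped <- hits[gapFrac >= 0.5]
  keep <- c(query, setdiff(hits, dropped))
  list(alignment = aln[keep], admissible = (length(keep) - 1) >= minHits,
       nHits = length(keep) - 1L, dropped = dropped)
}

#' Derive pY-similarity weights from a FoldX-style energy-term table
#'
#' For each energy term, the Pearson correlation over sites between each
#' substitution amino acid's ddG column and the pY column is computed; the
#' per-amino-acid weight is the mean correlation across terms, floored at 0
#' and renormalised to sum to 1. Zero-variance (term, amino acid) columns are
#' skipped in the mean and logged. pS/pT columns, if present, are parsed but
#' not weighted.
#'
#' @param energy data.frame with columns \code{site, substitution, term,
#'   ddg}; substitutions must include \code{pY} and the 19 non-Y amino acids.
#' @param minSites minimum number of sites (default 30).
#' @param floorNegative floor negative mean correlations at 0 before
#'   renormalising (default TRUE).
#' @return list: \code{weights} (named, sums to 1), \code{rho} (term x amino
#'   acid correlation matrix), \code{nSites}.
#' @export
deriveWeights <- function(energy, minSites = 30, floorNegative = TRUE) {
  aaSub <- setdiff(AA20, "Y")
  stopifnot(all(c("site", "substitution", "term", "ddg") %in%
                  colnames(energy)))
  if (!"pY" %in% energy$substitution) stop("energy table lacks a pY column")
  miss <- setdiff(aaSub, unique(energy$substitution))
  if (length(miss))
    stop("energy table lacks substitution(s): ", paste(miss, collapse = ","))
  terms <- unique(energy$term)
  sites <- unique(energy$site)
  if (length(sites) < minSites)
    stop("need >= ", minSites, " sites, got ", length(sites))
  rho <- matrix(NA_real_, length(terms), length(aaSub),
                dimnames = list(terms, aaSub))
  nSkip <- 0L
  for (t in terms) {
    et <- energy[energy$term == t, ]
    getCol <- function(subst) {
      d <- et[et$substitution == subst, ]
      d$ddg[match(sites, d$site)]
    }
    py <- getCol("pY")
    for (aa in aaSub) {
      v <- getCol(aa)
      if (sd(v, na.rm = TRUE) == 0 || sd(py, na.rm = TRUE) == 0) {
        nSkip <- nSkip + 1L
        next
      }
      rho[t, aa] <- cor(v, py, use = "complete.obs")
    }
  }
  if (nSkip) message(nSkip, " zero-variance (term, amino acid) columns skipped")
  w <- colMeans(rho, na.rm = TRUE)
  if (floorNegative) w <- pmax(w, 0)
  if (sum(w) <= 0) stop("all weights are zero after flooring")
  w <- w / sum(w)
  list(weights = w, rho = rho, nSites = length(sites))
}

#' pY-weighted mean of a per-substitution score row
#'
#' @param scores named numeric over the 19 non-Y amino acids (variant-effect
#'   scores at one site).
#' @param weights SimilarityWeights (list from [deriveWeights()]) or a named
#'   weight vector summing to 1.
#' @return single weighted score.
#' @export
weightedSiteScore <- function(scores, weights) {
  w <- if (is.list(weights)) weights$weights else weights
  miss <- setdiff(names(w), names(scores))
  if (length(miss))
    stop("score row lacks amino acid(s): ", paste(miss, collapse = ", "))
  if (any(is.na(scores[names(w)])))
    stop("score row has missing values; no silent partial means")
  sum(w * scores[names(w)])
}

#' Rank-normalise scores within a protein
#'
#' Ranks from least to most harmful, mapped to (rank - 1)/(n - 1): the most
#' harmful position gets 1, the least harmful 0; ties get the mean of their
#' ranks. A single scored position returns 0.5 with a warning. The output is
#' invariant under strictly monotone transforms of the raw scores.
#'
#' @param scores numeric raw scores for one protein.
#' @param lowerIsHarmful orientation flag: TRUE when a lower raw score means
#'   a more harmful substitution (the usual convention for log-odds
#'   conservation scores).
#' @return numeric in [0,1].
#' @export
rankNormalise <- function(scores, lowerIsHarmful) {
  stopifnot(is.logical(lowerIsHarmful), length(lowerIsHarmful) == 1)
  n <- length(scores)
  if (n == 1) {
    warning("single scored position; returning 0.5")
    return(0.5)
  }
  harm <- if (lowerIsHarmful) -scores else scores
  (rank(harm, ties.method = "average") - 1) / (n - 1)
}

#' Weighted, rank-normalised variant-effect scores for a score matrix
#'
#' @param scoreMatrix data.frame from [readScoreMatrix()] (protein, position,
#'   19 substitution columns).
#' @param weights output of [deriveWeights()].
#' @param lowerIsHarmful orientation flag (see [rankNormalise()]).
#' @return data.frame: protein, position, weighted, normalised.
#' @export
scoreSites <- function(scoreMatrix, weights, lowerIsHarmful) {
  w <- if (is.list(weights)) weights$weights else weights
  rows <- as.matrix(scoreMatrix[names(w)])
  weighted <- as.numeric(rows %*% w)
  out <- data.frame(protein = scoreMatrix$protein,
                    position = scoreMatrix$position, weighted = weighted)
  out$normalised <- NA_real_
  for (p in unique(out$protein)) {
    i <- which(out$protein == p)
    out$normalised[i] <- if (length(i) == 1) {
      warning("single scored position in ", p, "; returning 0.5")
      0.5
    } else rankNormalise(out$weighted[i], lowerIsHarmful)
  }
  out
}
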