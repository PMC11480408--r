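#' Ortholog coverage filter
#'
#' Keeps orthologs whose aligned (non-gap) fraction of query positions is at
#' least 0.5 (the boundary itself is kept; orthologs aligning to less than
#' half of the query are candidate false positives).
#'
#' @param panel an [OrthologPanel-class].
#' @param minCoverage coverage threshold (default 0.5).
#' @return the panel with low-coverage orthologs removed.
#' @export
coverageFilter <- function(panel, minCoverage = 0.5) {
  aln <- panel@alignment
  qcols <- panel@queryColumns
  cov <- vapply(names(aln), function(nm) {
    s <- strsplit(as.character(aln[[nm]]), "")[[1]][qcols]
    mean(s != "-")
  }, 0)
  keep <- names(aln)[cov >= minCoverage | names(aln) == panel@query]
  methods::initialize(panel, alignment = aln[keep],
                      clades = panel@clades[keep])
}

#' Site-specific pY conservation across ortholog panels
#'
#' A yeast pY site is conserved at window k iff some human (metazoan)
#' ortholog carries a pY within +/-k alignment columns of the yeast site's
#' column. Percentages are reported over three denominators: all yeast pY,
#' pY on proteins with at least one ortholog, and pY on proteins with at
#' least one pY-carrying ortholog.
#'
#' @param panels named list of [OrthologPanel-class] (names = protein ids).
#' @param yeastSites data.frame: protein, column.
#' @param humanPy data.frame: protein, seq, column.
#' @param windows integer windows (default c(0, 3, 5, 7, 9)).
#' @return data.frame: window, n_conserved, pct_all, pct_with_ortholog,
#'   pct_with_py_ortholog, plus denominators as attributes.
#' @export
siteConservation <- function(panels, yeastSites, humanPy,
                             windows = c(0, 3, 5, 7, 9)) {
  protHasOrtholog <- vapply(names(panels), function(p)
    sum(cladeLabels(panels[[p]]) == "metazoa") > 0, TRUE)
  protHasPyOrtholog <- vapply(names(panels), function(p)
    p %in% humanPy$protein, TRUE)
  nAll <- nrow(yeastSites)
  inPanel <- yeastSites$protein %in% names(panels)
  nOrtho <- sum(inPanel & protHasOrtholog[yeastSites$protein])
  nPyOrtho <- sum(inPanel & protHasPyOrtholog[yeastSites$protein])
  hpByProt <- split(humanPy$column, humanPy$protein)
  res <- lapply(windows, function(k) {
    cons <- vapply(seq_len(nrow(yeastSites)), function(i) {
      p <- yeastSites$protein[i]
      if (!p %in% names(panels)) return(FALSE)
      cols <- hpByProt[[p]]
      if (is.null(cols)) return(FALSE)
      any(abs(cols - yeastSites$column[i]) <= k)
    }, TRUE)
    data.frame(window = k, n_conserved = sum(cons),
               pct_all = 100 * sum(cons) / nAll,
               pct_with_ortholog = if (nOrtho) 100 * sum(cons) / nOrtho
                 else NA_real_,
               pct_with_py_ortholog = if (nPyOrtho)
                 100 * sum(cons) / nPyOrtho else NA_real_)
  })
  out <- do.call(rbind, res)
  attr(out, "denominators") <- c(all = nAll, with_ortholog = nOrtho,
                                 with_py_ortholog = nPyOrtho)
  out
}

#' Permutation null for site-specific conservation
#'
#' Permutes each human protein's pY labels uniformly at random among that
#' protein's tyrosine alignment columns, preserving per-protein pY counts,
#' and recomputes the conservation percentage. The empirical p uses the
#' add-one formula p = (1 + #(null >= observed)) / (1 + n_perm).
#'
#' @param panels,yeastSites,humanPy as in [siteConservation()].
#' @param window window k used for the observed and null statistic.
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed.
#' @param denominator which percentage to use (\code{"pct_all"} default).
#' @return list: observed, null (numeric nPerm), p.
#' @export
permutationNull <- function(panels, yeastSites, humanPy, window = 0,
                            nPerm = 100, seed = 1,
                            denominator = "pct_all") {
  stat <- function(hp) {
    sc <- siteConservation(panels, yeastSites, hp, windows = window)
    sc[[denominator]][1]
  }
  observed <- stat(humanPy)
  # tyrosine columns per (protein, ortholog)
  yCols <- lapply(split(humanPy, paste(humanPy$protein, humanPy$seq,
                                       sep = "\r")), function(d) {
    aln <- panels[[d$protein[1]]]@alignment
    s <- strsplit(as.character(aln[[d$seq[1]]]), "")[[1]]
    which(s == "Y")
  })
  keys <- split(seq_len(nrow(humanPy)),
                paste(humanPy$protein, humanPy$seq, sep = "\r"))
  null <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    hp <- humanPy
    for (ky in names(keys)) {
      idx <- keys[[ky]]
      pool <- yCols[[ky]]
      if (length(pool) < length(idx))
        stop("protein with more pY than Y residues")
      hp$column[idx] <- sample(pool, length(idx))
    }
    stat(hp)
  }, 0))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + nPerm))
}

#' Flag amino-acid deserts in a proteome
#'
#' A protein of length >= \code{minLen} (150) is an amino-acid desert for a
#' given residue iff it contains a contiguous stretch free of that residue
#' of length at least ceil(\code{fraction} * length) (fraction 0.5). Shorter
#' proteins are excluded.
#'
#' @param sequences named character vector of protein sequences.
#' @param aa single amino-acid letter.
#' @param minLen minimum protein length (default 150).
#' @param fraction minimum desert span as a fraction of length (default 0.5).
#' @return logical vector over proteins of length >= minLen (names kept).
#' @export
desertScan <- function(sequences, aa, minLen = 150, fraction = 0.5) {
  lens <- nchar(sequences)
  seqs <- sequences[lens >= minLen]
  vapply(seqs, function(s) {
    L <- nchar(s)
    pos <- c(0L, which(strsplit(s, "")[[1]] == aa), L + 1L)
    max(diff(pos) - 1L) >= ceiling(fraction * L)
  }, TRUE)
}


#' Amino-acid desert excess over a composition-preserving null
#'
#' Simulates the proteome \code{nSim} (100) times, preserving each protein's
#' length and per-residue order/disorder labels and drawing residues iid
#' from the proteome-wide state-specific amino-acid composition, then
#' compares the observed desert percentage per amino acid with the simulated
#' mean: excess = observed\% - mean(simulated\%).
#'
#' @param sequences named character vector of protein sequences.
#' @param disorder named character vector of "O"/"D" label strings (same
#'   lengths); NULL treats everything as ordered (logged).
#' @param nSim number of simulated proteomes.
#' @param seed integer seed.
#' @param aminoAcids amino acids to score (default all 20).
#' @param minLen,fraction desert definition (see [desertScan()]).
#' @param compOrdered,compDisordered optional named composition vectors over
#'   the 20 amino acids; by default the state-specific compositions are
#'   estimated from the observed proteome itself (overriding them lets a
#'   depleted proteome be compared against an undepleted null).
#' @return data.frame: aa, observed_pct, simulated_mean_pct, excess,
#'   n_proteins, plus the per-replicate simulated percentages as attribute
#'   \code{"simulated"}.
#' @export
desertExcess <- function(sequences, disorder = NULL, nSim = 100, seed = 1,
                         aminoAcids = AA20, minLen = 150, fraction = 0.5,
                         compOrdered = NULL, compDisordered = NULL) {
  if (is.null(disorder)) {
    message("no disorder labels; treating all residues as ordered")
    disorder <- vapply(sequences, function(s)
      paste(rep("O", nchar(s)), collapse = ""), "")
  }
  lens <- nchar(sequences)
  keep <- lens >= minLen
  seqs <- sequences[keep]; dis <- disorder[keep]
  resAll <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  labAll <- strsplit(paste(dis, collapse = ""), "")[[1]]
  compO <- table(factor(resAll[labAll == "O"], levels = AA20))
  compD <- table(factor(resAll[labAll == "D"], levels = AA20))
  compO <- as.numeric(compO) / max(1, sum(compO))
  compD <- as.numeric(compD) / max(1, sum(compD))
  if (!is.null(compOrdered)) compO <- unname(compOrdered[AA20])
  if (!is.null(compDisordered)) compD <- unname(compDisordered[AA20])
  for (aa in aminoAcids) {
    if (compO[match(aa, AA20)] == 0 && any(labAll == "O"))
      message("amino acid ", aa, " absent from ordered composition")
  }
  aaIdx <- match(aminoAcids, AA20)
  protLen <- nchar(seqs)
  obs <- .desertPctAllC(match(resAll, AA20), protLen, fraction)[aaIdx]
  dAll <- as.integer(labAll == "D")
  sim <- withSeed(seed, {
    vapply(seq_len(nSim), function(b)
      .desertSimPctC(dAll, protLen, compO, compD, fraction)[aaIdx],
      numeric(length(aminoAcids)))
  })
  sim <- matrix(sim, nrow = length(aminoAcids))
  out <- data.frame(aa = aminoAcids, observed_pct = obs,
                    simulated_mean_pct = rowMeans(sim),
                    excess = obs - rowMeans(sim),
                    n_proteins = length(seqs))
  attr(out, "simulated") <- sim
  out
}

#' Phylogenetic independent contrasts correlation
#'
#' Felsenstein's contrasts of two tip traits on a rooted, fully bifurcating
#' tree (polytomies are resolved to zero-length branches with a message),
#' followed by the correlation through the origin
#' \eqn{r = \sum xy / \sqrt{\sum x^2 \sum y^2}} with a t-test on
#' n_contrasts - 1 degrees of freedom.
#'
#' @param tree \code{phylo} object with positive branch lengths.
#' @param x,y named tip trait vectors.
#' @return list: contrasts (data.frame x, y), r, r2, p, df.
#' @export
picCorrelation <- function(tree, x, y) {
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss) || length(setdiff(tree$tip.label, names(y))))
    stop("trait values missing for tip(s): ",
         paste(union(miss, setdiff(tree$tip.label, names(y))),
               collapse = ", "))
  if (!ape::is.binary(tree)) {
    message("resolving polytomies to zero-length branches")
    tree <- ape::multi2di(tree)
  }
  cx <- ape::pic(x[tree$tip.label], tree)
  cy <- ape::pic(y[tree$tip.label], tree)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- length(cx) - 1
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t), df)
  list(contrasts = data.frame(x = cx, y = cy), r = r, r2 = r^2, p = p,
       df = df)
}

#' Clade equilibrium-frequency shift at phosphosites
#'
#' For each site with a significant amino-acid profile change (adjusted p <
#' \code{fdr}), the tyrosine shift is
#' \eqn{\Delta\pi_Y = \pi_{fungi}(Y) - \pi_{metazoa}(Y)}. Shifts are
#' stratified by burial class and the pY and non-pY distributions compared
#' by a two-sample two-tailed Kolmogorov-Smirnov test per stratum (skipped
#' with NA below 5 sites per arm).
#'
#' @param piTable data.frame (see [readPiFrequencies()]) with columns
#'   protein, site, clade, Y (among the amino-acid columns), adjusted_p.
#' @param siteClass data.frame: protein, site, is_py (logical), burial.
#' @param fdr significance filter on adjusted p (default 0.05).
#' @return list: \code{sites} (per-site delta_pi_Y with class and stratum),
#'   \code{tests} (per-stratum KS D and p).
#' @export
deltaPi <- function(piTable, siteClass, fdr = 0.05) {
  f <- piTable[piTable$clade == "fungi", ]
  m <- piTable[piTable$clade == "metazoa", ]
  key <- paste(f$protein, f$site)
  mi <- match(key, paste(m$protein, m$site))
  d <- data.frame(protein = f$protein, site = f$site,
                  delta_pi_y = f$Y - m$Y[mi],
                  adjusted_p = f$adjusted_p)
  d <- d[!is.na(d$delta_pi_y) & d$adjusted_p < fdr, ]
  ci <- match(paste(d$protein, d$site),
              paste(siteClass$protein, siteClass$site))
  d$is_py <- siteClass$is_py[ci]
  d$burial <- siteClass$burial[ci]
  d <- d[!is.na(d$is_py), ]
  tests <- do.call(rbind, lapply(split(d, d$burial), function(s) {
    a <- s$delta_pi_y[s$is_py]; b <- s$delta_pi_y[!s$is_py]
    if (length(a) < 5 || length(b) < 5)
      return(data.frame(burial = s$burial[1], n_py = length(a),
                        n_non_py = length(b), D = NA_real_, p = NA_real_))
    ks <- suppressWarnings(ks.test(a, b))
    data.frame(burial = s$burial[1], n_py = length(a), n_non_py = length(b),
               D = unname(ks$statistic), p = ks$p.value)
  }))
  list(sites = d, tests = tests)
}

#' Fisher tests of protein-level indicators
#'
#' Two-sided Fisher exact test and odds ratio of two binary indicators over
#' a protein universe (e.g. "has human ortholog" vs "is a spurious pY
#' substrate").
#'
#' @param a,b logical vectors over the same proteins.
#' @return list: table, odds_ratio, p.
#' @export
conservationFisher <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Per-domain phosphorylation frequency in log10 parts per million
#'
#' ppm_d = 1e6 * count_d / total; reported as log10(ppm). Domains are kept
#' iff supported by at least \code{minSites} (5) unique sites in either
#' species.
#'
#' @param counts data.frame: domain, species, n_sites.
#' @param minSites support filter.
#' @return data.frame: domain, species, ppm, log10_ppm.
#' @export
domainPhosphoFrequency <- function(counts, minSites = 5) {
  keepDom <- unique(counts$domain[counts$n_sites >= minSites])
  out <- do.call(rbind, lapply(split(counts, counts$species), function(d) {
    tot <- sum(d$n_sites)
    d$ppm <- 1e6 * d$n_sites / tot
    d$log10_ppm <- log10(d$ppm)
    d
  }))
  out <- out[out$domain %in% keepDom, , drop = FALSE]
  rownames(out) <- NULL
  out
}
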