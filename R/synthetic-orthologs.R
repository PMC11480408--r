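rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a query-anchored ortholog panel with planted Y-preference shifts
#'
#' Two clades (fungi, metazoa) are joined at the root; within each clade the
#' topology is coalescent-like. Residues are drawn per alignment column from
#' clade-specific categorical distributions: non-planted columns share one
#' distribution across clades, planted columns have the metazoan tyrosine
#' frequency reduced by \code{deltaPiY} relative to the fungal frequency
#' \code{piYFungal} (mass redistributed proportionally over the other amino
#' acids). The query is the first fungal sequence and carries Y at every
#' planted site.
#'
#' @param nFungal,nMetazoan sequences per clade.
#' @param alignLen alignment length (columns; the query is ungapped so
#'   columns and query positions coincide).
#' @param plantedSites integer columns receiving the Y-preference shift.
#' @param deltaPiY fungal-minus-metazoan Y equilibrium-frequency shift,
#'   in [0, \code{piYFungal}].
#' @param piYFungal fungal Y frequency at planted sites.
#' @param concentration Dirichlet concentration of non-planted column
#'   distributions (smaller = more conserved columns).
#' @param mode \code{"oracle"} writes the generating distributions into the
#'   equilibrium-frequency table; \code{"empirical"} writes the observed
#'   column frequencies.
#' @param seed integer seed.
#' @return list: \code{panel} ([OrthologPanel-class]) and \code{truth}
#'   (planted sites and the generating clade distributions).
#' @export
genOrthologPanel <- function(nFungal = 20, nMetazoan = 20, alignLen = 150,
                             plantedSites = integer(), deltaPiY = 0.5,
                             piYFungal = 0.9, concentration = 1,
                             mode = c("oracle", "empirical"), seed = 1) {
  mode <- match.arg(mode)
  if (alignLen < length(plantedSites))
    stop("alignment shorter than the number of planted sites")
  stopifnot(deltaPiY >= 0, deltaPiY <= piYFungal,
            all(plantedSites >= 1 & plantedSites <= alignLen))
  withSeed(seed, {
    base <- defaultComposition("ordered")
    pF <- matrix(0, alignLen, 20, dimnames = list(NULL, AA20))
    pM <- pF
    for (j in seq_len(alignLen)) {
      d <- rdirichlet1(concentration * 20 * base)
      pF[j, ] <- d; pM[j, ] <- d
    }
    for (j in plantedSites) {
      rest <- base[AA20 != "Y"] / sum(base[AA20 != "Y"])
      pF[j, ] <- c(rest * (1 - piYFungal), Y = piYFungal)[AA20]
      names(rest) <- setdiff(AA20, "Y")
      vf <- setNames(numeric(20), AA20)
      vf[names(rest)] <- rest * (1 - piYFungal); vf["Y"] <- piYFungal
      pF[j, ] <- vf
      vm <- setNames(numeric(20), AA20)
      piYMet <- piYFungal - deltaPiY
      vm[names(rest)] <- rest * (1 - piYMet); vm["Y"] <- piYMet
      pM[j, ] <- vm
    }
    speciesF <- c("query", sprintf("fungi%02d", seq_len(max(0, nFungal - 1))))
    speciesM <- sprintf("metazoa%02d", seq_len(nMetazoan))
    draw <- function(p) paste(
      vapply(seq_len(alignLen), function(j) sample(AA20, 1, prob = p[j, ]),
             ""), collapse = "")
    seqs <- c(vapply(speciesF, function(s) draw(pF), ""),
              vapply(speciesM, function(s) draw(pM), ""))
    names(seqs) <- c(speciesF, speciesM)
    if (length(plantedSites)) {
      q <- strsplit(seqs[["query"]], "")[[1]]
      q[plantedSites] <- "Y"
      seqs[["query"]] <- paste(q, collapse = "")
    }
    clades <- setNames(c(rep("fungi", length(speciesF)),
                         rep("metazoa", length(speciesM))), names(seqs))
    treeF <- ape::rcoal(length(speciesF), tip.label = speciesF)
    treeM <- ape::rcoal(length(speciesM), tip.label = speciesM)
    tree <- ape::bind.tree(.stemmed(treeF), .stemmed(treeM), position = 0.5)
    emp <- function(cl) {
      sub <- seqs[clades == cl]
      t(vapply(seq_len(alignLen), function(j) {
        col <- substring(sub, j, j)
        tab <- table(factor(col, levels = AA20))
        as.numeric(tab) / sum(tab)
      }, numeric(20)))
    }
    fr <- if (mode == "oracle") list(fungi = pF, metazoa = pM)
          else { e <- list(fungi = emp("fungi"), metazoa = emp("metazoa"))
                 colnames(e$fungi) <- colnames(e$metazoa) <- AA20; e }
    adjp <- runif(alignLen)
    adjp[plantedSites] <- runif(length(plantedSites), 0, 1e-4)
    piTable <- do.call(rbind, lapply(c("fungi", "metazoa"), function(cl)
      data.frame(protein = "query", site = seq_len(alignLen), clade = cl,
                 fr[[cl]], adjusted_p = adjp, check.names = FALSE)))
    panel <- methods::new("OrthologPanel", query = "query",
                          alignment = Biostrings::AAStringSet(seqs),
                          clades = clades,
                          queryColumns = seq_len(alignLen), tree = tree,
                          piTable = piTable)
    list(panel = panel,
         truth = list(plantedSites = plantedSites, deltaPiY = deltaPiY,
                      piFungal = pF, piMetazoa = pM, seed = seed))
  })
}

.stemmed <- function(tr) {
  tr$root.edge <- 0.5
  tr
}

#' Simulate ortholog panels with planted site-specific pY conservation
#'
#' Generates ungapped query-anchored panels (one yeast query plus human
#' orthologs), yeast pY sites, and human pY annotations. A chosen fraction of
#' yeast pY sites is "conserved": a human ortholog carries a pY in exactly the
#' aligned column; all other human pY are placed uniformly at random among
#' that ortholog's tyrosines, which is the null the permutation test resamples
#' from.
#'
#' @param nProteins number of panels.
#' @param nOrthologs human orthologs per panel.
#' @param protLen alignment length per panel.
#' @param pyPerProtein yeast pY sites per panel.
#' @param humanPyPerOrtholog background human pY per ortholog.
#' @param conservedFraction fraction of yeast pY with a planted human match.
#' @param seed integer seed.
#' @return list: \code{panels} (list of [OrthologPanel-class]),
#'   \code{yeastSites} (protein, column), \code{humanPy} (protein, seq,
#'   column), \code{truth} (which yeast sites are conserved).
#' @export
genConservationData <- function(nProteins = 20, nOrthologs = 3,
                                protLen = 120, pyPerProtein = 3,
                                humanPyPerOrtholog = 3,
                                conservedFraction = 0, seed = 1) {
  withSeed(seed, {
    comp <- defaultComposition("ordered")
    comp["Y"] <- 0.12            # Y-rich so every sequence offers acceptors
    comp <- comp / sum(comp)
    panels <- list(); ys <- list(); hp <- list(); conserved <- list()
    for (i in seq_len(nProteins)) {
      prot <- sprintf("panel%03d", i)
      nm <- c("query", sprintf("human%02d", seq_len(nOrthologs)))
      seqs <- vapply(nm, function(s)
        paste(sample(AA20, protLen, TRUE, comp), collapse = ""), "")
      qY <- which(strsplit(seqs[["query"]], "")[[1]] == "Y")
      py <- sort(sample(qY, min(pyPerProtein, length(qY))))
      isCons <- runif(length(py)) < conservedFraction
      for (k in which(isCons)) {
        tgt <- sample(nm[-1], 1)
        s <- strsplit(seqs[[tgt]], "")[[1]]
        s[py[k]] <- "Y"
        seqs[[tgt]] <- paste(s, collapse = "")
      }
      hprows <- list()
      for (o in nm[-1]) {
        oY <- which(strsplit(seqs[[o]], "")[[1]] == "Y")
        n <- min(humanPyPerOrtholog, length(oY))
        if (n) hprows[[o]] <- data.frame(
          protein = prot, seq = o, column = sample(oY, n))
      }
      for (k in which(isCons)) {
        tgt <- which(vapply(hprows, function(d)
          any(substring(seqs[[d$seq[1]]], py[k], py[k]) == "Y"), TRUE))
        # plant the conserved human pY in the first ortholog carrying Y there
        o <- nm[-1][vapply(nm[-1], function(s)
          substring(seqs[[s]], py[k], py[k]) == "Y", TRUE)][1]
        hprows[[paste0(o, "_c", k)]] <- data.frame(
          protein = prot, seq = o, column = py[k])
      }
      clades <- setNames(c("fungi", rep("metazoa", nOrthologs)), nm)
      panels[[prot]] <- methods::new("OrthologPanel", query = "query",
        alignment = Biostrings::AAStringSet(seqs), clades = clades,
        queryColumns = seq_len(protLen), tree = NULL,
        piTable = data.frame())
      ys[[prot]] <- data.frame(protein = prot, column = py)
      hp[[prot]] <- unique(do.call(rbind, hprows))
      conserved[[prot]] <- data.frame(protein = prot, column = py,
                                      conserved = isCons)
    }
    list(panels = panels,
         yeastSites = do.call(rbind, ys),
         humanPy = do.call(rbind, hp),
         truth = do.call(rbind, conserved))
  })
}
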