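AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# baseline compositions for globular (ordered) and intrinsically disordered
# residues; disordered regions enriched in S/P/E/K/Q/N/G and depleted in
# aromatics and hydrophobics, as in proteome-wide disorder scaffolds
.COMP_ORDERED <- c(A = 0.080, C = 0.014, D = 0.058, E = 0.062, F = 0.046,
                   G = 0.066, H = 0.022, I = 0.066, K = 0.068, L = 0.098,
                   M = 0.021, N = 0.058, P = 0.040, Q = 0.038, R = 0.045,
                   S = 0.082, T = 0.058, V = 0.072, W = 0.011, Y = 0.035)
.COMP_DISORDERED <- c(A = 0.075, C = 0.004, D = 0.070, E = 0.095, F = 0.018,
                      G = 0.075, H = 0.018, I = 0.030, K = 0.085, L = 0.045,
                      M = 0.012, N = 0.070, P = 0.090, Q = 0.060, R = 0.045,
                      S = 0.115, T = 0.065, V = 0.040, W = 0.003, Y = 0.015)

#' Default ordered/disordered amino-acid composition vectors
#'
#' Normalised 20-vectors over the standard alphabet (alphabetical one-letter
#' order) used by [genProteome()].
#'
#' @param state \code{"ordered"} or \code{"disordered"}.
#' @return named numeric vector summing to 1.
#' @export
defaultComposition <- function(state = c("ordered", "disordered")) {
  state <- match.arg(state)
  v <- if (state == "ordered") .COMP_ORDERED else .COMP_DISORDERED
  v / sum(v)
}

checkComposition <- function(comp, what) {
  if (!setequal(names(comp), AA20))
    stop(what, " must be named over the 20 standard amino acids")
  comp <- comp[AA20]
  if (any(comp < 0)) stop(what, " has negative frequencies")
  if (abs(sum(comp) - 1) > 1e-8) stop(what, " must sum to 1")
  if (any(comp == 1))
    message(what, ": degenerate composition (one amino acid has frequency 1)")
  comp
}

#' Generate a synthetic proteome with known disorder segmentation
#'
#' Proteins are built as alternating ordered/disordered segments; segment
#' lengths are geometric with the given means, residues are drawn iid from
#' the state-specific composition. This is exactly the null model under which
#' [desertExcess()] simulates, so a proteome drawn here is the
#' self-calibration input for the amino-acid desert test.
#'
#' @param nProteins number of proteins.
#' @param lengthSampler function(n) returning n protein lengths; default
#'   log-normal around 350 residues, clipped to [150, 1500].
#' @param compOrdered,compDisordered composition vectors over the 20 amino
#'   acids (must sum to 1).
#' @param disorderFraction long-run fraction of disordered residues (sets the
#'   segment-length ratio).
#' @param meanSegment mean ordered-segment length (geometric).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with \code{sequences} (named character), \code{disorder}
#'   (named character of "O"/"D" strings, same lengths) and \code{truth}
#'   (the generating parameters).
#' @export
genProteome <- function(nProteins = 50,
                        lengthSampler = NULL,
                        compOrdered = defaultComposition("ordered"),
                        compDisordered = defaultComposition("disordered"),
                        disorderFraction = 0.3,
                        meanSegment = 80,
                        seed = 1) {
  compOrdered <- checkComposition(compOrdered, "compOrdered")
  compDisordered <- checkComposition(compDisordered, "compDisordered")
  stopifnot(disorderFraction >= 0, disorderFraction < 1)
  withSeed(seed, {
    if (is.null(lengthSampler))
      lengthSampler <- function(n)
        pmin(pmax(round(rlnorm(n, log(350), 0.35)), 150L), 1500L)
    lens <- as.integer(lengthSampler(nProteins))
    meanDis <- if (disorderFraction > 0)
      meanSegment * disorderFraction / (1 - disorderFraction) else 0
    seqs <- character(nProteins); dis <- character(nProteins)
    for (i in seq_len(nProteins)) {
      L <- lens[i]
      lab <- character(0)
      state <- sample(c("O", "D"), 1,
                      prob = c(1 - disorderFraction,
                               max(disorderFraction, 1e-9)))
      while (length(lab) < L) {
        m <- if (state == "O") meanSegment else meanDis
        if (m <= 0) { state <- "O"; m <- meanSegment }
        seg <- 1L + stats::rgeom(1, 1 / m)
        lab <- c(lab, rep(state, seg))
        state <- if (state == "O") "D" else "O"
      }
      lab <- lab[seq_len(L)]
      if (disorderFraction == 0) lab <- rep("O", L)
      res <- character(L)
      nO <- sum(lab == "O"); nD <- L - nO
      if (nO) res[lab == "O"] <- sample(AA20, nO, TRUE, compOrdered)
      if (nD) res[lab == "D"] <- sample(AA20, nD, TRUE, compDisordered)
      seqs[i] <- paste(res, collapse = "")
      dis[i] <- paste(lab, collapse = "")
    }
    names(seqs) <- names(dis) <- sprintf("prot%03d", seq_len(nProteins))
    list(sequences = seqs, disorder = dis,
         truth = list(compOrdered = compOrdered,
                      compDisordered = compDisordered,
                      disorderFraction = disorderFraction, seed = seed))
  })
}

#' Generate C-alpha structure tracks for a synthetic proteome
#'
#' Each protein's C-alpha chain is a fixed-bond-length (3.8 Angstrom)
#' self-avoiding random walk: collapsed (biased toward the running centroid)
#' in ordered segments and persistent/extended in disordered segments. SASA
#' is then computed from these coordinates with this package's own
#' Shrake-Rupley implementation ([computeSasa()]), so the structural stage is
#' internally consistent with the generator. pLDDT is drawn >= 85 in ordered
#' and <= 60 in disordered residues.
#'
#' @param proteome output of [genProteome()].
#' @param seed integer seed.
#' @param nPoints sphere-sampling points for SASA.
#' @param maxRetries walk restarts before giving up on a protein.
#' @return named list of [StructureTrack-class].
#' @export
genStructureTracks <- function(proteome, seed = 1, nPoints = 240,
                               maxRetries = 20) {
  withSeed(seed, {
    lapply(setNames(names(proteome$sequences), names(proteome$sequences)),
           function(id) {
      aa <- strsplit(proteome$sequences[[id]], "")[[1]]
      lab <- strsplit(proteome$disorder[[id]], "")[[1]]
      xyz <- NULL
      for (try in seq_len(maxRetries)) {
        xyz <- .caWalk(lab)
        if (!is.null(xyz)) break
      }
      if (is.null(xyz))
        stop("self-avoiding walk failed for protein ", id)
      atoms <- data.frame(residue = seq_along(aa), element = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
      pl <- ifelse(lab == "O", runif(length(aa), 85, 98),
                   runif(length(aa), 30, 60))
      tr <- StructureTrack(id, aa = aa, plddt = pl, atoms = atoms)
      s <- computeSasa(tr, nPoints = nPoints)
      tr@residues$sasa <- s$sasa
      tr
    })
  })
}

# fixed-bond self-avoiding C-alpha walk; ordered residues are pulled toward
# the centroid of the chain so far, disordered residues persist in direction.
# A trapped head backtracks a few residues and re-grows.
.caWalk <- function(lab, bond = 3.8, minDist = 3.2, maxStepTries = 60,
                    maxBacktracks = 2000) {
  L <- length(lab)
  xyz <- matrix(0, L, 3)
  dir <- c(1, 0, 0)
  i <- 2; backtracks <- 0
  while (i <= L) {
    placed <- FALSE
    for (k in seq_len(maxStepTries)) {
      noise <- rnorm(3)
      if (lab[i] == "D") {
        d <- dir * 3 + noise * 0.55
      } else {
        cen <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
        pull <- cen - xyz[i - 1, ]
        np <- sqrt(sum(pull^2))
        if (np > 1e-9) pull <- pull / np
        d <- dir * 0.5 + pull * 1.5 + noise * 0.8
      }
      d <- d / sqrt(sum(d^2))
      cand <- xyz[i - 1, ] + bond * d
      if (i > 2) {
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        dd <- sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                          byrow = TRUE))^2))
        if (min(dd) < minDist) next
      }
      xyz[i, ] <- cand; dir <- d; placed <- TRUE; break
    }
    if (!placed) {
      # a trapped head first tries to step outward from the centroid
      cen <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
      for (k in seq_len(maxStepTries)) {
        out <- xyz[i - 1, ] - cen + rnorm(3)
        no <- sqrt(sum(out^2))
        if (no < 1e-9) next
        cand <- xyz[i - 1, ] + bond * out / no
        prev <- xyz[seq_len(max(1, i - 2)), , drop = FALSE]
        dd <- sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                          byrow = TRUE))^2))
        if (i > 2 && min(dd) < minDist) next
        xyz[i, ] <- cand; dir <- out / no; placed <- TRUE; break
      }
    }
    if (placed) { i <- i + 1; next }
    backtracks <- backtracks + 1   # then backtracks and re-grows
    if (backtracks > maxBacktracks) return(NULL)
    i <- max(2, i - 6)
    if (i > 2)
      dir <- (xyz[i - 1, ] - xyz[i - 2, ]) / bond
  }
  xyz
}
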