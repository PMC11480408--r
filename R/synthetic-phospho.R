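#' Build a balanced WT/kinase-dead sample design
#'
#' @param kinases character vector of kinase names.
#' @param replicates replicates per (kinase, status); must be >= 2.
#' @return design data.frame (see [readSampleDesign()]).
#' @export
makeDesign <- function(kinases, replicates = 5) {
  stopifnot(replicates >= 2)
  d <- expand.grid(replicate = seq_len(replicates), status = c("WT", "DEAD"),
                   kinase = kinases, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_r%d", d$kinase, d$status, d$replicate)
  d[c("sample_id", "kinase", "status", "replicate")]
}

#' Simulate a DIA phosphoproteomics experiment with known ground truth
#'
#' Per phosphosite the generative model is the mixture the occupancy
#' regression inverts: with per-sample total protein amount \eqn{T_s},
#' occupancy \eqn{p_s}, and ionization efficiencies \eqn{\kappa} (phospho)
#' and \eqn{\kappa'} (non-phospho), the noiseless intensities are
#' \eqn{x_s = \kappa p_s T_s} and \eqn{y_s = \kappa' (1 - p_s) T_s}.
#' Multiplicative log-normal noise with the requested coefficient of
#' variation and completely-at-random missingness are then applied
#' (optionally intensity-dependent missingness, logistic in log intensity).
#' Regulated sites receive elevated occupancy in WT samples of their kinase;
#' unregulated sites share a low baseline occupancy in all samples.
#'
#' Each protein additionally emits unmodified "proteome" peptides (no
#' phospho counterpart) so that maxLFQ protein profiles are estimable.
#'
#' @param proteome output of [genProteome()].
#' @param design sample design data.frame (see [makeDesign()]).
#' @param nSitesPerKinase truly regulated phosphosites per kinase (scalar or
#'   vector recycled over kinases).
#' @param nNullSites unregulated phosphosites (background).
#' @param occupancyWT sampler or single value in (0,1]: true WT occupancy of
#'   regulated sites.
#' @param occupancyBase baseline occupancy of unregulated sites / DEAD arm.
#' @param kappaSdlog log-sd of the per-precursor ionization efficiencies.
#' @param noiseCV multiplicative noise CV (0.253 reflects a typical DIA
#'   replicate CV of 25.3\%).
#' @param proteinCV between-sample CV of the true protein amounts
#'   \eqn{T_s} (defaults to \code{noiseCV}); protein-abundance variation is
#'   what the maxLFQ normalisation step removes.
#' @param missingness completely-at-random missing fraction.
#' @param missingMode \code{"mcar"} or \code{"intensity"} (logistic in log
#'   intensity, same marginal rate target).
#' @param nProteomePeptides unmodified peptides per protein.
#' @param acceptors phosphoacceptor letters eligible for site placement.
#' @param seed integer seed.
#' @return list: \code{experiment} ([PrecursorExperiment-class]),
#'   \code{truth} (data.frame per site x sample with true occupancy, kappa,
#'   kappaPrime, T; plus per-site regulated flag, kinase, true log2FC).
#' @export
genPhosphoExperiment <- function(proteome, design,
                                 nSitesPerKinase = 30, nNullSites = 30,
                                 occupancyWT = 0.5, occupancyBase = 0.05,
                                 kappaSdlog = 0.5,
                                 noiseCV = 0.253, proteinCV = noiseCV,
                                 missingness = 0.05,
                                 missingMode = c("mcar", "intensity"),
                                 nProteomePeptides = 15,
                                 acceptors = c("S", "T", "Y"), seed = 1) {
  missingMode <- match.arg(missingMode)
  validateSampleDesign(design)
  kinases <- unique(design$kinase)
  withSeed(seed, {
    sites <- .placeSites(proteome, kinases, nSitesPerKinase, nNullSites,
                         acceptors)
    nSamp <- nrow(design)
    sampleIds <- design$sample_id
    rows <- list(); intens <- list(); truthRows <- list()
    protT <- lapply(setNames(unique(sites$protein), unique(sites$protein)),
                    function(p) rlnorm(1, log(1e7), 0.4) *
                      lnoise(nSamp, proteinCV))
    for (i in seq_len(nrow(sites))) {
      st <- sites[i, ]
      Ts <- protT[[st$protein]]
      kap <- rlnorm(1, 0, kappaSdlog); kapP <- rlnorm(1, 0, kappaSdlog)
      p <- rep(occupancyBase, nSamp)
      if (st$regulated) {
        wt <- design$kinase == st$kinase & design$status == "WT"
        pWT <- if (is.function(occupancyWT)) occupancyWT(1) else occupancyWT
        p[wt] <- pWT
      }
      x <- kap * p * Ts * lnoise(nSamp, noiseCV)
      y <- kapP * (1 - p) * Ts * lnoise(nSamp, noiseCV)
      pep <- substring(proteome$sequences[[st$protein]],
                       max(1, st$position - 7),
                       min(nchar(proteome$sequences[[st$protein]]),
                           st$position + 7))
      base <- list(protein = st$protein, peptide = pep, charge = 2L,
                   q_value = runif(1, 0, 0.005),
                   global_q_value = runif(1, 0, 0.005))
      rows[[length(rows) + 1]] <- c(base, list(
        ptm_q_value = runif(1, 0, 0.005),
        ptm_site_confidence = runif(1, 0.85, 1),
        modified = paste0(pep, "(UniMod:21@", st$position, ")"),
        site_positions = as.character(st$position)))
      intens[[length(intens) + 1]] <- x
      rows[[length(rows) + 1]] <- c(base, list(
        ptm_q_value = NA_real_, ptm_site_confidence = NA_real_,
        modified = pep, site_positions = ""))
      intens[[length(intens) + 1]] <- y
      truthRows[[length(truthRows) + 1]] <- data.frame(
        site = st$site, protein = st$protein, position = st$position,
        acceptor = st$acceptor, kinase = st$kinase,
        regulated = st$regulated,
        true_log2fc = if (st$regulated)
          log2((if (is.function(occupancyWT)) p[design$kinase == st$kinase &
                design$status == "WT"][1] else occupancyWT) / occupancyBase)
          else 0,
        sample_id = sampleIds, occupancy = p, kappa = kap,
        kappa_prime = kapP, total = Ts)
    }
    # unmodified proteome peptides (for maxLFQ)
    for (prot in unique(sites$protein)) {
      Ts <- protT[[prot]]
      L <- nchar(proteome$sequences[[prot]])
      for (j in seq_len(nProteomePeptides)) {
        a <- sample.int(max(1, L - 12), 1)
        pep <- substring(proteome$sequences[[prot]], a, min(L, a + 11))
        kap <- rlnorm(1, 0, kappaSdlog)
        rows[[length(rows) + 1]] <- list(
          protein = prot, peptide = pep, charge = 2L,
          q_value = runif(1, 0, 0.005), global_q_value = runif(1, 0, 0.005),
          ptm_q_value = NA_real_, ptm_site_confidence = NA_real_,
          modified = paste0(pep, "#", j), site_positions = "")
        intens[[length(intens) + 1]] <- kap * Ts * lnoise(nSamp, noiseCV)
      }
    }
    meta <- do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    m <- do.call(rbind, intens)
    colnames(m) <- sampleIds
    if (missingness > 0) {
      if (missingMode == "mcar") {
        drop <- matrix(runif(length(m)) < missingness, nrow(m))
      } else {
        lx <- log(m); lx[!is.finite(lx)] <- min(lx[is.finite(lx)])
        z <- scale(as.vector(lx))
        pr <- stats::plogis(-z * 1.5)
        pr <- pr * missingness / mean(pr)
        drop <- matrix(runif(length(m)) < pr, nrow(m))
      }
      m[drop] <- NA_real_
    }
    m[!is.na(m) & m <= 0] <- NA_real_
    pe <- PrecursorExperiment(meta, m, design)
    truth <- do.call(rbind, truthRows)
    list(experiment = pe, truth = truth,
         sites = sites, params = list(noiseCV = noiseCV,
                                      missingness = missingness,
                                      occupancyWT = occupancyWT,
                                      occupancyBase = occupancyBase,
                                      seed = seed))
  })
}

.placeSites <- function(proteome, kinases, nSitesPerKinase, nNullSites,
                        acceptors) {
  all <- do.call(rbind, lapply(names(proteome$sequences), function(id) {
    s <- strsplit(proteome$sequences[[id]], "")[[1]]
    pos <- which(s %in% acceptors)
    if (!length(pos)) return(NULL)
    data.frame(protein = id, position = pos, acceptor = s[pos])
  }))
  nSitesPerKinase <- rep_len(nSitesPerKinase, length(kinases))
  need <- sum(nSitesPerKinase) + nNullSites
  if (nrow(all) < need)
    stop("requested ", need, " sites but proteome offers only ", nrow(all),
         " S/T/Y acceptors")
  pick <- all[sample.int(nrow(all), need), ]
  pick$site <- paste0(pick$protein, "_", pick$acceptor, pick$position)
  pick$kinase <- c(rep(kinases, times = nSitesPerKinase),
                   rep(kinases[1], nNullSites))
  pick$regulated <- c(rep(TRUE, sum(nSitesPerKinase)),
                      rep(FALSE, nNullSites))
  rownames(pick) <- NULL
  pick
}
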