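#' Default pipeline configuration
#'
#' Study conditions of the default synthetic cohort: four kinases with
#' decreasing numbers of regulated phosphosites and matched fitness effects,
#' five replicates per arm, multiplicative intensity noise at a 25.3\%
#' replicate CV, 5\% missingness, 16 growth replicates over three conditions.
#'
#' @return named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    n_proteins = 30,
    kinases = c("SRC", "EPHB1", "FYN", "TEC"),
    sites_per_kinase = c(30, 20, 10, 3),
    n_null_sites = 25,
    replicates = 5,
    occupancy_wt = 0.5,
    occupancy_base = 0.05,
    noise_cv = 0.253,
    missingness = 0.05,
    regulation_q = 0.01,
    growth_effects = c(SRC = 0.30, EPHB1 = 0.20, FYN = 0.10, TEC = 0),
    growth_conditions = c("SC", "SC_NaCl", "YPD"),
    growth_replicates = 16,
    growth_noise_cv = 0.05,
    ortholog_planted = 24,
    ortholog_align_len = 480,
    ortholog_delta_pi = 0.5,
    desert_proteins = 6000,
    conservation_proteins = 25,
    conserved_fraction = 0.3,
    desert_sims = 100,
    n_perm = 100,
    n_species = 26,
    sasa_points = 240)
}

stagePaths <- function(runDir) {
  list(inputs = file.path(runDir, "inputs"),
       truth = file.path(runDir, "truth"),
       out = file.path(runDir, "out"))
}

writeManifest <- function(runDir, stage, seed, params, inputs, outputs) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         version = as.character(utils::packageVersion("spurphos")),
         parameters = params, inputs = inputs, outputs = outputs),
    file.path(runDir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} writes every synthetic input plus ground truth
#' under the run directory; \code{quantify}, \code{stoichiometry},
#' \code{structure}, \code{vep}, \code{evolution} and \code{fitness} each
#' read the inputs, run their module and write TSV outputs under
#' \code{out/}; \code{report} scores every stage output against the ground
#' truth and writes \code{out/report.json}. Each stage writes a
#' machine-readable manifest (inputs, seed, version, parameters).
#'
#' @param stage stage name.
#' @param runDir run directory.
#' @param seed integer seed (all stage randomness derives from it).
#' @param config named list overriding [defaultConfig()] entries.
#' @return invisibly, the stage's main output object.
#' @export
runStage <- function(stage = c("simulate", "quantify", "stoichiometry",
                               "structure", "vep", "evolution", "fitness",
                               "report"),
                     runDir, seed = 1, config = list()) {
  stage <- match.arg(stage)
  cfg <- utils::modifyList(defaultConfig(), config)
  p <- stagePaths(runDir)
  fn <- switch(stage,
    simulate = .stageSimulate, quantify = .stageQuantify,
    stoichiometry = .stageStoichiometry, structure = .stageStructure,
    vep = .stageVep, evolution = .stageEvolution,
    fitness = .stageFitness, report = .stageReport)
  res <- fn(p, seed, cfg)
  writeManifest(runDir, stage, seed, cfg,
                inputs = list.files(p$inputs),
                outputs = list.files(p$out))
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate, quantify, stoichiometry, structure, vep, evolution, fitness,
#' report, in order, under one run directory and one master seed.
#'
#' @inheritParams runStage
#' @return the report list (see \code{out/report.json}).
#' @export
runPipeline <- function(runDir, seed = 1, config = list()) {
  for (s in c("simulate", "quantify", "stoichiometry", "structure", "vep",
              "evolution", "fitness"))
    runStage(s, runDir, seed = seed, config = config)
  runStage("report", runDir, seed = seed, config = config)
}

.stageSimulate <- function(p, seed, cfg) {
  for (d in unlist(p)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (d in file.path(p$inputs, "panels")) dir.create(d, showWarnings = FALSE)
  prot <- genProteome(cfg$n_proteins, seed = seed)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(prot$sequences),
    file.path(p$inputs, "proteome.fasta"))
  writeTsv(data.frame(protein = names(prot$disorder),
                      labels = unname(prot$disorder)),
           file.path(p$inputs, "disorder.tsv"))
  tracks <- genStructureTracks(prot, seed = seed + 1,
                               nPoints = cfg$sasa_points)
  atoms <- do.call(rbind, lapply(tracks, function(t)
    cbind(protein = t@protein, t@atoms,
          aa = t@residues$aa[t@atoms$residue],
          plddt = t@residues$plddt[t@atoms$residue])))
  writeTsv(atoms, file.path(p$inputs, "atoms.tsv"))

  design <- makeDesign(cfg$kinases, cfg$replicates)
  writeTsv(design, file.path(p$inputs, "design.tsv"))
  phos <- genPhosphoExperiment(prot, design,
    nSitesPerKinase = cfg$sites_per_kinase,
    nNullSites = cfg$n_null_sites,
    occupancyWT = cfg$occupancy_wt, occupancyBase = cfg$occupancy_base,
    noiseCV = cfg$noise_cv, missingness = cfg$missingness,
    seed = seed + 2)
  writePrecursorReport(phos$experiment, file.path(p$inputs, "report.tsv"))
  writeTsv(phos$truth, file.path(p$truth, "phospho.tsv"))
  writeTsv(phos$sites, file.path(p$truth, "sites.tsv"))

  growth <- genGrowthExperiment(cfg$growth_effects,
    conditions = cfg$growth_conditions,
    replicates = cfg$growth_replicates,
    noiseCV = cfg$growth_noise_cv, seed = seed + 3)
  utils::write.csv(growth$curves, file.path(p$inputs, "growth.csv"),
                   row.names = FALSE)
  writeTsv(growth$truth, file.path(p$truth, "growth.tsv"))

  vep <- genVepTables(seed = seed + 4)
  writeTsv(vep$energy, file.path(p$inputs, "energy_terms.tsv"))
  writeTsv(vep$scores, file.path(p$inputs, "scores.tsv"))
  writeTsv(vep$truth$deleterious, file.path(p$truth, "deleterious.tsv"))

  op <- genOrthologPanel(
    alignLen = cfg$ortholog_align_len,
    plantedSites = seq_len(cfg$ortholog_planted) *
      (cfg$ortholog_align_len %/% (cfg$ortholog_planted + 1)),
    deltaPiY = cfg$ortholog_delta_pi, seed = seed + 5)
  writeTsv(op$panel@piTable, file.path(p$inputs, "pi_frequencies.tsv"))
  burial <- withSeed(seed + 6,
    sample(c("buried", "intermediate", "exposed"),
           length(op$panel@queryColumns), TRUE))
  writeTsv(data.frame(protein = "query", site = op$panel@queryColumns,
                      is_py = op$panel@queryColumns %in%
                        op$truth$plantedSites,
                      burial = burial),
           file.path(p$inputs, "site_class.tsv"))
  writeTsv(data.frame(planted = op$truth$plantedSites,
                      delta_pi_y = op$truth$deltaPiY),
           file.path(p$truth, "delta_pi.tsv"))

  cons <- genConservationData(cfg$conservation_proteins,
    conservedFraction = cfg$conserved_fraction, seed = seed + 7)
  for (nm in names(cons$panels))
    Biostrings::writeXStringSet(cons$panels[[nm]]@alignment,
      file.path(p$inputs, "panels", paste0(nm, ".fasta")))
  writeTsv(cons$yeastSites, file.path(p$inputs, "yeast_py.tsv"))
  writeTsv(cons$humanPy, file.path(p$inputs, "human_py.tsv"))
  writeTsv(cons$truth, file.path(p$truth, "conserved.tsv"))

  withSeed(seed + 8, {
    tree <- ape::rcoal(cfg$n_species)
    xk <- as.numeric(ape::rTraitCont(tree, sigma = 3)) + 10
    yc <- -0.02 * xk + as.numeric(ape::rTraitCont(tree, sigma = 0.05)) + 3
    ape::write.tree(tree, file.path(p$inputs, "species_tree.nwk"))
    writeTsv(data.frame(species = tree$tip.label, n_kinases = xk,
                        y_content = yc),
             file.path(p$inputs, "species_traits.tsv"))
  })
  invisible(TRUE)
}

.readInputs <- function(p) {
  list(pe = readPrecursorReport(file.path(p$inputs, "report.tsv"),
                                design = file.path(p$inputs, "design.tsv")),
       proteome = readProteomeFasta(file.path(p$inputs, "proteome.fasta")))
}

.stageQuantify <- function(p, seed, cfg) {
  if (!file.exists(file.path(p$inputs, "report.tsv")))
    stop("no simulated inputs found; run the simulate stage first")
  inp <- .readInputs(p)
  design <- readSampleDesign(file.path(p$inputs, "design.tsv"))
  reg <- do.call(rbind, lapply(unique(design$kinase), function(k)
    regulationContrast(inp$pe, k, qThreshold = cfg$regulation_q,
                       seed = seed + match(k, unique(design$kinase)))))
  writeTsv(reg[, c("feature", "protein", "site_positions", "kinase",
                   "log2fc", "t_mod", "df_total", "p", "q", "direction")],
           file.path(p$out, "regulation.tsv"))
  agg <- aggregateToSites(reg, inp$proteome)
  writeTsv(agg$sites, file.path(p$out, "sites.tsv"))
  writeTsv(agg$counts, file.path(p$out, "site_counts.tsv"))
  invisible(reg)
}

.stageStoichiometry <- function(p, seed, cfg) {
  inp <- .readInputs(p)
  reg <- read.delim(file.path(p$out, "regulation.tsv"))
  xf <- filterPrecursors(inp$pe, "stoichiometry")
  lfq <- proteinLfq(xf, regulation = reg)
  groups <- buildStoichiometryGroups(xf, lfq)
  res <- occupancySummary(groups)
  if (!is.null(res$occupancy))
    writeTsv(res$occupancy, file.path(p$out, "occupancy.tsv"))
  if (!is.null(res$summary))
    writeTsv(res$summary, file.path(p$out, "occupancy_summary.tsv"))
  invisible(res)
}

.stageStructure <- function(p, seed, cfg) {
  atoms <- read.delim(file.path(p$inputs, "atoms.tsv"))
  sites <- read.delim(file.path(p$out, "sites.tsv"))
  up <- sites[sites$call == "up", , drop = FALSE]
  maxRef <- maxSasaReference("calpha")
  profs <- list()
  for (prot in unique(up$protein)) {
    a <- atoms[atoms$protein == prot, , drop = FALSE]
    s <- computeSasa(a[, c("residue", "element", "x", "y", "z")],
                     nPoints = cfg$sasa_points)
    aa <- a$aa[match(seq_along(s$sasa), a$residue)]
    rsa <- relativeAccessibility(s$sasa, aa, maxRef)
    for (pos in up$position[up$protein == prot]) {
      cl <- classifySite(rsa, pos)
      profs[[length(profs) + 1]] <- data.frame(
        protein = prot, position = pos,
        acceptor = up$acceptor[up$protein == prot & up$position == pos][1],
        sasa = s$sasa[pos], rsa = cl$rsa, windowed_rsa = cl$windowed_rsa,
        disorder = cl$disorder, burial = cl$burial,
        plddt = a$plddt[match(pos, a$residue)],
        length = length(rsa))
    }
  }
  profiles <- do.call(rbind, profs)
  writeTsv(profiles, file.path(p$out, "site_profiles.tsv"))
  profiles$group <- "pY"
  profiles$destabilising_fold <- NA
  writeTsv(profileSummary(profiles), file.path(p$out, "profile_summary.tsv"))
  tb <- terminiBias(profiles$position, profiles$length)
  writeTsv(data.frame(ks_stat = tb$ks_stat, p = tb$p,
                      n = nrow(profiles)),
           file.path(p$out, "termini_bias.tsv"))
  invisible(profiles)
}

.stageVep <- function(p, seed, cfg) {
  energy <- read.delim(file.path(p$inputs, "energy_terms.tsv"))
  scores <- readScoreMatrix(file.path(p$inputs, "scores.tsv"))
  w <- deriveWeights(energy)
  out <- scoreSites(scores, w, lowerIsHarmful = TRUE)
  writeTsv(out, file.path(p$out, "vep_weighted.tsv"))
  writeTsv(data.frame(aa = names(w$weights), weight = w$weights),
           file.path(p$out, "vep_weights.tsv"))
  invisible(out)
}

.stageEvolution <- function(p, seed, cfg) {
  # the desert self-calibration needs proteome-scale sampling precision, so
  # it runs on a dedicated null proteome rather than the small cohort one
  nullProt <- genProteome(cfg$desert_proteins,
    lengthSampler = function(n) sample(800:1200, n, TRUE),
    seed = seed + 10)
  deserts <- desertExcess(nullProt$sequences, nullProt$disorder,
                          nSim = cfg$desert_sims, seed = seed + 11)
  writeTsv(deserts, file.path(p$out, "deserts.tsv"))

  panelFiles <- list.files(file.path(p$inputs, "panels"),
                           full.names = TRUE)
  panels <- lapply(panelFiles, function(f) {
    aln <- Biostrings::readAAStringSet(f)
    methods::new("OrthologPanel", query = "query", alignment = aln,
                 clades = setNames(ifelse(names(aln) == "query", "fungi",
                                          "metazoa"), names(aln)),
                 queryColumns = seq_len(Biostrings::width(aln)[1]),
                 tree = NULL, piTable = data.frame())
  })
  names(panels) <- sub("\\.fasta$", "", basename(panelFiles))
  ys <- read.delim(file.path(p$inputs, "yeast_py.tsv"))
  hp <- read.delim(file.path(p$inputs, "human_py.tsv"))
  cons <- siteConservation(panels, ys, hp)
  writeTsv(cons, file.path(p$out, "conservation.tsv"))
  pn <- permutationNull(panels, ys, hp, window = 0, nPerm = cfg$n_perm,
                        seed = seed + 12)
  writeTsv(data.frame(observed = pn$observed, p = pn$p,
                      null_mean = mean(pn$null)),
           file.path(p$out, "conservation_permutation.tsv"))

  pi <- readPiFrequencies(file.path(p$inputs, "pi_frequencies.tsv"))
  sc <- read.delim(file.path(p$inputs, "site_class.tsv"))
  dp <- deltaPi(pi, sc)
  writeTsv(dp$sites, file.path(p$out, "delta_pi.tsv"))
  writeTsv(dp$tests, file.path(p$out, "delta_pi_tests.tsv"))

  tree <- ape::read.tree(file.path(p$inputs, "species_tree.nwk"))
  tr <- read.delim(file.path(p$inputs, "species_traits.tsv"))
  pc <- picCorrelation(tree, setNames(tr$n_kinases, tr$species),
                       setNames(tr$y_content, tr$species))
  writeTsv(data.frame(r = pc$r, r2 = pc$r2, p = pc$p, df = pc$df),
           file.path(p$out, "pic.tsv"))
  invisible(list(deserts = deserts, conservation = cons, permutation = pn,
                 delta_pi = dp, pic = pc))
}

.stageFitness <- function(p, seed, cfg) {
  curves <- readGrowthCurves(file.path(p$inputs, "growth.csv"))
  fit <- fitnessScores(curves)
  writeTsv(fit, file.path(p$out, "fitness.tsv"))
  perK <- attr(fit, "perKinase")
  writeTsv(perK, file.path(p$out, "fitness_per_kinase.tsv"))
  counts <- read.delim(file.path(p$out, "site_counts.tsv"))
  upY <- counts[counts$direction == "up" & counts$class == "pY", ,
                drop = FALSE]
  nUp <- setNames(upY$Freq, upY$kinase)
  nUp <- tapply(upY$Freq, upY$kinase, sum)
  corr <- tryCatch(
    fitnessPhosphoCorrelation(nUp,
                              setNames(perK$min_delta, perK$kinase)),
    error = function(e) list(r = NA_real_, p = NA_real_, n = 0))
  writeTsv(data.frame(r = corr$r, p = corr$p, n = corr$n),
           file.path(p$out, "fitness_correlation.tsv"))
  invisible(list(fitness = fit, correlation = corr))
}

.stageReport <- function(p, seed, cfg) {
  if (!length(list.files(p$out)))
    stop("no stage outputs found in ", p$out)
  rpt <- list()
  truthSites <- read.delim(file.path(p$truth, "sites.tsv"))
  sites <- read.delim(file.path(p$out, "sites.tsv"))
  tkey <- paste(truthSites$kinase, truthSites$protein, truthSites$position)
  skey <- paste(sites$kinase, sites$protein, sites$position)
  called <- skey[sites$call == "up"]
  regTrue <- tkey[truthSites$regulated]
  rpt$regulation <- list(
    sensitivity = mean(regTrue %in% called),
    fdr = if (length(called)) mean(!(called %in% regTrue)) else 0,
    n_called = length(called), n_true = length(regTrue))

  occPath <- file.path(p$out, "occupancy.tsv")
  if (file.exists(occPath)) {
    occ <- read.delim(occPath)
    tr <- read.delim(file.path(p$truth, "phospho.tsv"))
    tr$site_id <- paste0(tr$protein, "_", tr$position)
    key <- paste(occ$site, occ$sample)
    m <- match(key, paste(tr$site_id, tr$sample_id))
    err <- abs(occ$p - tr$occupancy[m])
    rpt$occupancy <- list(median_abs_error = median(err, na.rm = TRUE),
                          n = sum(!is.na(err)))
    summ <- read.delim(file.path(p$out, "occupancy_summary.tsv"))
    rpt$occupancy$median_by_condition <- setNames(
      as.list(summ$median_occupancy), summ$condition)
  }

  prof <- read.delim(file.path(p$out, "site_profiles.tsv"))
  dis <- read.delim(file.path(p$inputs, "disorder.tsv"))
  lab <- setNames(dis$labels, dis$protein)
  trueDis <- vapply(seq_len(nrow(prof)), function(i)
    substring(lab[[prof$protein[i]]], prof$position[i],
              prof$position[i]) == "D", TRUE)
  rpt$structure <- list(
    buried_fraction = mean(prof$burial == "buried"),
    disorder_accuracy = mean(prof$disorder == trueDis),
    n_sites = nrow(prof))

  vw <- read.delim(file.path(p$out, "vep_weighted.tsv"))
  del <- read.delim(file.path(p$truth, "deleterious.tsv"))
  m <- match(paste(vw$protein, vw$position),
             paste(del$protein, del$position))
  top <- vw$normalised >= quantile(vw$normalised, 0.9)
  rpt$vep <- list(
    top_decile_recovery = sum(top & del$deleterious[m]) /
      sum(del$deleterious[m]),
    n_planted = sum(del$deleterious[m]))

  des <- read.delim(file.path(p$out, "deserts.tsv"))
  pn <- read.delim(file.path(p$out, "conservation_permutation.tsv"))
  dpt <- read.delim(file.path(p$out, "delta_pi_tests.tsv"))
  pic <- read.delim(file.path(p$out, "pic.tsv"))
  rpt$evolution <- list(
    max_abs_desert_excess = max(abs(des$excess)),
    desert_excess_Y = des$excess[des$aa == "Y"],
    conservation_observed_pct = pn$observed,
    conservation_permutation_p = pn$p,
    delta_pi_min_ks_p = suppressWarnings(min(dpt$p, na.rm = TRUE)),
    pic_r = pic$r, pic_r2 = pic$r2, pic_p = pic$p)

  fit <- read.delim(file.path(p$out, "fitness.tsv"))
  gt <- read.delim(file.path(p$truth, "growth.tsv"))
  effByK <- setNames(gt$effect[grepl("_WT$", gt$strain)],
                     sub("_WT$", "", gt$strain[grepl("_WT$", gt$strain)]))
  effByK <- effByK[!duplicated(names(effByK))]
  pos <- names(effByK)[effByK > 0]
  neg <- names(effByK)[effByK == 0]
  detected <- unique(fit$kinase[fit$q < 0.05 & fit$delta < 0])
  nullTests <- fit[fit$kinase %in% neg, , drop = FALSE]
  fc <- read.delim(file.path(p$out, "fitness_correlation.tsv"))
  rpt$fitness <- list(
    power = mean(pos %in% detected),
    null_rejections = sum(nullTests$p < 0.05),
    n_null_tests = nrow(nullTests),
    correlation_r = fc$r, correlation_p = fc$p)

  jsonlite::write_json(rpt, file.path(p$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rpt
}

#' Command-line entry point
#'
#' \code{spurphos <subcommand> --run-dir DIR [--seed N] [--config FILE]}
#' with subcommands simulate, quantify, stoichiometry, structure, vep,
#' evolution, fitness, report, or \code{all} for the full pipeline. Returns
#' an exit code (0 success; 2 usage error; 1 stage failure) rather than
#' calling \code{quit()}, so it is testable in-process.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return integer exit code.
#' @export
runCli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: spurphos <simulate|quantify|stoichiometry|structure|vep|",
    "        evolution|fitness|report|all> --run-dir DIR [--seed N]",
    "        [--config FILE]", sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  sub <- argv[1]
  valid <- c("simulate", "quantify", "stoichiometry", "structure", "vep",
             "evolution", "fitness", "report", "all")
  if (!sub %in% valid) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(2L)
  }
  opts <- list(seed = 1L, runDir = NULL, config = list())
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    getval <- function() {
      if (i + 1 > length(argv)) stop("missing value for ", a)
      argv[i + 1]
    }
    if (a == "--run-dir") { opts$runDir <- getval(); i <- i + 2 }
    else if (a == "--seed") { opts$seed <- as.integer(getval()); i <- i + 2 }
    else if (a == "--config") {
      opts$config <- readConfig(getval()); i <- i + 2
    } else { message("unknown flag: ", a, "\n", usage); return(2L) }
  }
  if (is.null(opts$runDir)) { message("--run-dir is required"); return(2L) }
  res <- tryCatch({
    if (sub == "all")
      runPipeline(opts$runDir, seed = opts$seed, config = opts$config)
    else runStage(sub, opts$runDir, seed = opts$seed, config = opts$config)
    0L
  }, error = function(e) {
    message("stage failed: ", conditionMessage(e))
    1L
  })
  res
}
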