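test_that("ortholog coverage filter keeps the 50% boundary", {
  q <- paste(rep("A", 100), collapse = "")
  mk <- function(nAligned) paste(c(rep("A", nAligned),
                                   rep("-", 100 - nAligned)), collapse = "")
  aln <- Biostrings::AAStringSet(c(query = q, o49 = mk(49), o50 = mk(50),
                                   o80 = mk(80)))
  panel <- methods::new("OrthologPanel", query = "query", alignment = aln,
                        clades = setNames(c("fungi", rep("metazoa", 3)),
                                          names(aln)),
                        queryColumns = 1:100, tree = NULL,
                        piTable = data.frame())
  kept <- coverageFilter(panel)
  expect_setequal(names(kept@alignment), c("query", "o50", "o80"))
})

test_that("site conservation respects alignment windows and denominators", {
  cons <- genConservationData(nProteins = 1, nOrthologs = 1, protLen = 60,
                              pyPerProtein = 1, humanPyPerOrtholog = 0,
                              conservedFraction = 0, seed = 7)
  p <- cons$panels[[1]]
  site <- cons$yeastSites$column[1]
  hp <- function(col) data.frame(protein = cons$yeastSites$protein[1],
                                 seq = "human01", column = col)
  exact <- siteConservation(cons$panels, cons$yeastSites, hp(site))
  expect_equal(exact$pct_all[exact$window == 0], 100)
  # a human pY 4 columns away: missed at k=3, hit at k=5
  near <- siteConservation(cons$panels, cons$yeastSites, hp(site + 4))
  expect_equal(near$n_conserved[near$window == 3], 0)
  expect_equal(near$n_conserved[near$window == 5], 1)
  # windows are nested: conservation is non-decreasing in k
  expect_true(all(diff(near$n_conserved) >= 0))
  # no orthologs with pY: zero conserved, denominators still bookkeept
  none <- siteConservation(cons$panels, cons$yeastSites,
                           hp(site)[0, , drop = FALSE])
  expect_equal(none$n_conserved, rep(0L, 5))
  expect_equal(attr(none, "denominators")[["all"]], 1)
})

test_that("the permutation null uses the add-one empirical p", {
  cons <- genConservationData(nProteins = 8, nOrthologs = 2, protLen = 80,
                              pyPerProtein = 2, humanPyPerOrtholog = 2,
                              conservedFraction = 1, seed = 8)
  pn <- permutationNull(cons$panels, cons$yeastSites, cons$humanPy,
                        window = 0, nPerm = 100, seed = 9)
  expect_equal(pn$observed, 100)
  expect_length(pn$null, 100)
  # fully planted conservation beats every permutation
  expect_equal(pn$p, 1 / 101)
  # observed no better than any null value gives p = 1
  pnFlat <- list(observed = 5, null = rep(5, 100))
  expect_equal((1 + sum(pnFlat$null >= pnFlat$observed)) / 101, 1)
})

test_that("desert scanning applies length and span rules exactly", {
  noY <- paste(rep("A", 150), collapse = "")
  expect_true(desertScan(c(p = noY), "Y")[["p"]])
  # single Y at position 100 of 200 leaves a 100-residue desert = ceil(100)
  s <- paste(c(rep("A", 99), "Y", rep("A", 100)), collapse = "")
  expect_true(desertScan(c(p = s), "Y")[["p"]])
  # a Y at the exact centre of 201 leaves only 100 < ceil(100.5)
  s2 <- paste(c(rep("A", 100), "Y", rep("A", 100)), collapse = "")
  expect_false(desertScan(c(p = s2), "Y")[["p"]])
  short <- paste(rep("A", 149), collapse = "")
  expect_length(desertScan(c(p = short), "Y"), 0)
})

test_that("removing residues never un-flags a desert (monotonicity)", {
  set.seed(14)
  pr <- genProteome(25, lengthSampler = function(n) rep(200L, n), seed = 15)
  seqs <- pr$sequences
  before <- desertScan(seqs, "Y")
  for (i in 1:1000) {
    id <- sample(names(seqs), 1)
    chars <- strsplit(seqs[[id]], "")[[1]]
    ys <- which(chars == "Y")
    if (!length(ys)) next
    chars[sample(ys, 1)] <- "A"
    seqs[[id]] <- paste(chars, collapse = "")
  }
  after <- desertScan(seqs, "Y")
  expect_true(all(after[before]))
})

test_that("desert excess self-calibrates on null proteomes and flags
          constructed depletion", {
  pr <- genProteome(400, lengthSampler = function(n) rep(300L, n), seed = 16)
  stripped <- gsub("Y", "A", pr$sequences)
  de <- suppressMessages(desertExcess(
    stripped, pr$disorder, nSim = 30, seed = 17, aminoAcids = "Y",
    compOrdered = defaultComposition("ordered"),
    compDisordered = defaultComposition("disordered")))
  expect_equal(de$observed_pct, 100)
  expect_equal(de$excess, 100 - de$simulated_mean_pct)
  expect_gt(de$excess, 50)
  de2 <- suppressMessages(desertExcess(
    stripped, pr$disorder, nSim = 30, seed = 17, aminoAcids = "Y",
    compOrdered = defaultComposition("ordered"),
    compDisordered = defaultComposition("disordered")))
  expect_identical(de, de2)
})

test_that("independent contrasts match closed forms and the GLS oracle", {
  # two tips, unit branches: single contrast of size (x1-x2)/sqrt(2)
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  pc <- picCorrelation(t2, c(a = 2, b = 4), c(a = 1, b = 0))
  expect_equal(abs(pc$contrasts$x[1]), sqrt(2))

  set.seed(18)
  for (n in c(4, 5, 6)) {
    tr <- ape::rcoal(n)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(rnorm(n), tr$tip.label)
    pc <- picCorrelation(tr, x, y)
    expect_equal(nrow(pc$contrasts), n - 1)
    expect_equal(pc$r, as.numeric(glsCorOracle(tr, x, y)),
                 tolerance = 1e-10)
  }
  expect_error(picCorrelation(t2, c(a = 1), c(a = 1, b = 2)), "missing")
})

test_that("contrast correlations are calibrated under independent Brownian
          motion", {
  set.seed(19)
  ps <- replicate(300, {
    tr <- ape::rcoal(8)
    x <- ape::rTraitCont(tr); y <- ape::rTraitCont(tr)
    picCorrelation(tr, x, y)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("equilibrium-frequency shifts are computed, filtered and compared
          per stratum", {
  pi <- data.frame(protein = "q", site = 1:2, clade = "fungi",
                   Y = c(0.9, 0.5), adjusted_p = c(0.01, 0.5))
  pi <- rbind(pi, within(pi, { clade <- "metazoa"; Y <- c(0.1, 0.5) }))
  cls <- data.frame(protein = "q", site = 1:2, is_py = c(TRUE, FALSE),
                    burial = "exposed")
  dp <- deltaPi(pi, cls)
  expect_equal(dp$sites$delta_pi_y, 0.8)       # only the significant site
  expect_equal(nrow(dp$sites), 1)

  # identical pY and non-pY distributions: KS p ~ 1; planted shift: p < 0.01
  mkPi <- function(deltas, isPy) {
    n <- length(deltas)
    rbind(data.frame(protein = "q", site = 1:n, clade = "fungi",
                     Y = 0.9, adjusted_p = 0.001),
          data.frame(protein = "q", site = 1:n, clade = "metazoa",
                     Y = 0.9 - deltas, adjusted_p = 0.001))
  }
  same <- suppressWarnings(deltaPi(
    mkPi(rep(c(0.1, 0.2), each = 50)),
    data.frame(protein = "q", site = 1:100,
               is_py = rep(c(TRUE, FALSE), 50), burial = "buried")))
  expect_gt(same$tests$p, 0.9)
  set.seed(20)
  shifted <- deltaPi(
    mkPi(c(rnorm(200, 0.5, 0.05), rnorm(200, 0, 0.05))),
    data.frame(protein = "q", site = 1:400,
               is_py = rep(c(TRUE, FALSE), each = 200),
               burial = "buried"))
  expect_lt(shifted$tests$p, 0.01)
  # strata below 5 sites per arm are skipped with NA
  tiny <- deltaPi(mkPi(rep(0.1, 4)),
                  data.frame(protein = "q", site = 1:4,
                             is_py = c(TRUE, TRUE, FALSE, FALSE),
                             burial = "exposed"))
  expect_true(is.na(tiny$tests$p))
})

test_that("protein-level Fisher tests match the enumeration oracle", {
  a <- rep(c(TRUE, FALSE), c(100, 100))
  b <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 90))
  cf <- conservationFisher(a, b)
  expect_equal(cf$p, fisherOracle(matrix(c(20, 80, 10, 90), 2,
                                         byrow = TRUE)),
               tolerance = 1e-12)
  # empty cell: odds ratio 0, finite p
  cf0 <- conservationFisher(rep(c(TRUE, FALSE), c(10, 90)),
                            c(rep(FALSE, 10), rep(c(TRUE, FALSE),
                                                  c(30, 60))))
  expect_equal(cf0$odds_ratio, 0)
  expect_true(is.finite(cf0$p))
})

test_that("domain phosphorylation frequencies are ppm-scaled and
          support-filtered", {
  one <- data.frame(domain = "PK", species = "yeast", n_sites = 12)
  d1 <- domainPhosphoFrequency(one)
  expect_equal(d1$ppm, 1e6)
  expect_equal(d1$log10_ppm, 6)
  two <- data.frame(domain = c("A", "B"), species = "yeast",
                    n_sites = c(5, 5))
  d2 <- domainPhosphoFrequency(two)
  expect_equal(d2$ppm, c(5e5, 5e5))
  mixed <- data.frame(domain = c("A", "B", "B"),
                      species = c("yeast", "yeast", "human"),
                      n_sites = c(10, 4, 4))
  d3 <- domainPhosphoFrequency(mixed)
  expect_false("B" %in% d3$domain)   # <5 sites in both species
})
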