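test_that("maxLFQ reproduces single-peptide and ratio-consistent profiles", {
  one <- matrix(c(100, 200), 1, dimnames = list("p1", c("a", "b")))
  lfq <- maxLfq(one)
  expect_equal(lfq$intensity[["b"]] / lfq$intensity[["a"]], 2)

  # two peptides with a common ratio 2 across three samples
  two <- rbind(c(10, 20, 40), c(30, 60, 120))
  colnames(two) <- c("a", "b", "c")
  lfq2 <- maxLfq(two)
  expect_equal(unname(lfq2$intensity / lfq2$intensity[1]), c(1, 2, 4),
               tolerance = 1e-12)
  # total intensity is preserved
  expect_equal(sum(lfq2$intensity), sum(two))
})

test_that("maxLFQ matches the least-squares oracle on ratio-consistent
          matrices", {
  set.seed(9)
  for (rep in 1:5) {
    a <- rlnorm(6, 2, 1)          # peptide effects
    b <- rlnorm(4, 10, 1)         # sample effects
    m <- a %o% b
    m[sample(length(m), 5)] <- NA # punch holes, keep connectivity likely
    if (any(colSums(!is.na(m)) == 0)) next
    lfq <- maxLfq(m)
    ok <- !is.na(lfq$intensity)
    est <- log(lfq$intensity[ok]) - log(b[ok])
    expect_lt(max(est) - min(est), 1e-9) # equal up to one scale
  }
})

test_that("peptides with regulated phospho counterparts are excluded from
          protein profiles", {
  meta <- data.frame(
    protein = "P1",
    peptide = c("AAAK", "AAAK", "CCCK", "DDDK"),
    charge = 2,
    modified = c("AAAK(ph)", "AAAK", "CCCK", "DDDK"),
    q_value = 0.001, global_q_value = 0.001,
    ptm_q_value = 0.001, ptm_site_confidence = 0.9,
    site_positions = c("2", "", "", ""))
  m <- matrix(c(8, 4,
                10, 20,
                30, 60,
                50, 100), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  pe <- PrecursorExperiment(meta, m)
  reg <- data.frame(feature = "AAAK/2/AAAK(ph)", protein = "P1",
                    direction = "up")
  lfq <- proteinLfq(pe, regulation = reg)
  # AAAK (non-phospho) must be excluded: profile ratio comes from CCC/DDD = 2
  expect_equal(unname(lfq$P1$intensity[2] / lfq$P1$intensity[1]), 2,
               tolerance = 1e-12)
  lfqAll <- proteinLfq(pe, regulation = NULL)
  expect_false(isTRUE(all.equal(lfqAll$P1$intensity, lfq$P1$intensity)))
})

test_that("stoichiometry groups apply the four admission filters in order", {
  des <- makeDesign("SRC", replicates = 2)   # 4 samples, 2 conditions
  sid <- des$sample_id
  meta <- data.frame(
    protein = "P1",
    peptide  = c("AAAK", "AAAK", "AAAK", "CCCK", "CCCK", "DDDK", "DDDK",
                 "DDDK", "EEEK"),
    charge   = c(2, 3, 2, 2, 2, 2, 2, 2, 2),
    modified = c("AAAK(ph5)", "AAAK(ph5)", "AAAK", "CCCK(ph9)", "CCCK",
                 "DDDK(ph13)", "DDDK(ph14)", "DDDK", "EEEK"),
    q_value = 0.001, global_q_value = 0.001, ptm_q_value = 0.001,
    ptm_site_confidence = 0.9,
    site_positions = c("5", "5", "", "9", "", "13", "14", "", ""))
  m <- rbind(
    c(900, 900, 100, 100),   # AAAK(ph5) z2, the abundant charge state
    c(400, 400, 50, 50),     # AAAK(ph5) z3, dropped by filter 1
    c(1000, 1000, 1000, 1000),
    c(500, 500, 500, 500),   # CCCK(ph9)
    c(800, 800, 800, NA),    # CCCK non-phospho missing once: filter 3
    c(100, 100, 100, 100),   # DDDK has two phospho forms: filter 4
    c(100, 100, 100, 100),
    c(1000, 1000, 1000, 1000),
    c(1000, 1000, 1000, 1000))
  colnames(m) <- sid
  pe <- PrecursorExperiment(meta, m, des)
  lfq <- list(P1 = list(intensity = setNames(rep(1, 4), sid)))
  groups <- suppressMessages(buildStoichiometryGroups(pe, lfq))
  expect_length(groups, 1)
  expect_equal(groups[[1]]$site, "P1_5")
  expect_equal(unname(groups[[1]]$x), c(900, 900, 100, 100))
  dc <- dropCounts(groups)
  expect_equal(unname(dc["charge_state"]), 1L)
  expect_gte(dc[["nonphospho_complete_all"]], 1L)
  expect_equal(unname(dc["phospho_counterpart_not_unique"]), 1L)
})

test_that("zero-imputation applies to unquantified phospho precursors", {
  des <- makeDesign("SRC", replicates = 2)
  meta <- data.frame(
    protein = "P1", peptide = c("AAAK", "AAAK"), charge = 2,
    modified = c("AAAK(ph)", "AAAK"), q_value = 0.001,
    global_q_value = 0.001, ptm_q_value = 0.001, ptm_site_confidence = 0.9,
    site_positions = c("5", ""))
  m <- rbind(c(500, 500, NA, NA), c(500, 500, 1000, 1000))
  colnames(m) <- des$sample_id
  pe <- PrecursorExperiment(meta, m, des)
  lfq <- list(P1 = list(intensity = setNames(rep(1, 4), des$sample_id)))
  g <- suppressMessages(buildStoichiometryGroups(pe, lfq))[[1]]
  expect_equal(unname(g$x), c(500, 500, 0, 0))
})

test_that("occupancy fitting solves the exact line and rejects illegal
          slopes", {
  g <- list(site = "s", x = c(0, 250, 500), y = c(1000, 750, 500))
  f <- fitOccupancy(g)
  expect_equal(f$a, 1000)
  expect_equal(f$b, -1)
  expect_equal(f$x_max, 1000)
  expect_equal(unname(f$p), c(0, 0.25, 0.50))
  expect_equal(f$status, "valid")

  bad <- fitOccupancy(list(x = c(100, 200, 300), y = c(100, 200, 300)))
  expect_equal(bad$status, "illegal_positive_slope")
  expect_null(bad$p)

  few <- fitOccupancy(list(x = c(1, 2), y = c(2, 1)))
  expect_equal(few$status, "insufficient_data")
})

test_that("occupancy is invariant to ionization efficiencies and rescaling", {
  p <- c(0.1, 0.35, 0.6, 0.8, 0.05)
  Tt <- 1e6
  for (k in c(0.3, 1, 4)) for (kp in c(0.5, 2)) {
    x <- k * p * Tt; y <- kp * (1 - p) * Tt
    f <- fitOccupancy(list(x = x, y = y))
    expect_equal(unname(f$p), p, tolerance = 1e-9)
    f2 <- fitOccupancy(list(x = 7 * x, y = 0.1 * y))
    expect_equal(unname(f2$p), p, tolerance = 1e-9)
  }
})

test_that("occupancy recovery degrades gracefully with noise and tracks the
          generator", {
  pr <- genProteome(15, seed = 51)
  des <- makeDesign("SRC", replicates = 5)   # 10 samples
  g <- genPhosphoExperiment(pr, des, nSitesPerKinase = 40, nNullSites = 0,
                            occupancyWT = function(n) runif(n, 0.3, 0.9),
                            occupancyBase = 0.08,
                            noiseCV = 0.25, missingness = 0, seed = 52)
  xf <- suppressMessages(filterPrecursors(g$experiment, "stoichiometry"))
  lfq <- proteinLfq(xf, regulation = NULL)
  groups <- suppressMessages(buildStoichiometryGroups(xf, lfq))
  res <- occupancySummary(groups)
  tr <- g$truth
  tr$site_id <- paste0(tr$protein, "_", tr$position)
  m <- match(paste(res$occupancy$site, res$occupancy$sample),
             paste(tr$site_id, tr$sample_id))
  err <- abs(res$occupancy$p - tr$occupancy[m])
  expect_gt(sum(!is.na(err)), 50)
  expect_lt(median(err, na.rm = TRUE), 0.05)

  # median cohort occupancy is monotone in the generator's parameter
  meds <- vapply(c(0.2, 0.5, 0.8), function(pw) {
    gi <- genPhosphoExperiment(pr, des, nSitesPerKinase = 25, nNullSites = 0,
                               occupancyWT = pw, occupancyBase = 0.05,
                               noiseCV = 0, missingness = 0, seed = 53)
    xi <- suppressMessages(filterPrecursors(gi$experiment, "stoichiometry"))
    gr <- suppressMessages(buildStoichiometryGroups(
      xi, proteinLfq(xi, NULL)))
    s <- occupancySummary(gr)$summary
    s$median_occupancy[s$condition == "SRC WT"]
  }, 0)
  expect_true(all(diff(meds) > 0))
})
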