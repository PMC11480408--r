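mkPE <- function(meta, m, design = NULL) PrecursorExperiment(meta, m, design)

test_that("confidence filters apply inclusive bounds per stage", {
  meta <- data.frame(
    protein = "P1", peptide = paste0("PEP", 1:5), charge = 2,
    modified = paste0("PEP", 1:5),
    q_value = c(0.02, 0.01, 0.005, 0.005, 0.005),
    global_q_value = c(0.001, 0.001, 0.02, 0.001, 0.001),
    ptm_q_value = c(0.001, 0.001, 0.001, 0.05, 0.001),
    ptm_site_confidence = c(0.9, 0.9, 0.9, 0.9, 0.75),
    site_positions = "3")
  m <- matrix(1, 5, 2, dimnames = list(NULL, c("a", "b")))
  pe <- mkPE(meta, m)
  reg <- suppressMessages(filterPrecursors(pe, "regulation"))
  # q 0.02 dropped; global 0.02 dropped; confidence 0.75 kept (inclusive);
  # ptm_q 0.05 still allowed at the regulation stage
  expect_setequal(SummarizedExperiment::rowData(reg)$peptide,
                  c("PEP2", "PEP4", "PEP5"))
  sto <- suppressMessages(filterPrecursors(pe, "stoichiometry"))
  expect_setequal(SummarizedExperiment::rowData(sto)$peptide,
                  c("PEP2", "PEP5"))
  expect_named(dropCounts(sto), c("q_value", "global_q_value",
                                  "ptm_site_confidence", "ptm_q_value"))
  # boundary: exactly 0.75 confidence and exactly 0.01 FDR are kept
  meta2 <- meta[2, ]; meta2$q_value <- 0.01
  pe2 <- mkPE(meta2, m[2, , drop = FALSE])
  expect_equal(nrow(suppressMessages(filterPrecursors(pe2, "regulation"))), 1)
})

test_that("completeness filter keeps >=75% in one condition and flags
          all-missing conditions", {
  m <- rbind(
    c(1, 1, 1, 1, NA,  NA, NA, NA, NA, NA),  # 4/5 WT, 0/5 DEAD
    c(1, 1, 1, NA, NA,  1, 1, 1, NA, NA),    # 3/5 both
    c(1, 1, 1, 1, 1,    1, 1, 1, 1, 1),      # complete
    c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA))
  cf <- completenessFilter(m, 1:5, 6:10)
  expect_equal(cf$keep, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cf$imputeB, c(TRUE, FALSE))
  expect_equal(cf$imputeA, c(FALSE, FALSE))
  expect_equal(cf$nDroppedEmpty, 1L)
  expect_error(completenessFilter(m, 1, 6:10), "replicates")
})

test_that("left-shifted imputation has the Perseus moments and never touches
          observed cells", {
  set.seed(1)
  n <- 2500
  logm <- matrix(rnorm(n * 8, 20, 2), n, 8)
  imputeA <- rep(c(TRUE, FALSE), length.out = n)
  saved <- logm
  out <- imputeCondition(logm, 1:4, 5:8, imputeA,
                         imputeB = rep(FALSE, n), seed = 3)
  expect_equal(out[!imputeA, ], saved[!imputeA, ])
  expect_equal(out[, 5:8], saved[, 5:8])
  imp <- out[imputeA, 1:4]
  mu <- mean(saved); sdv <- sd(as.vector(saved))
  # 1e4 imputed draws: CLT bounds on mean and sd
  expect_equal(length(imp), 5000 * 1)
  expect_lt(abs(mean(imp) - (mu - 1.8 * sdv)), 0.03)
  expect_lt(abs(sd(imp) - 0.3 * sdv), 0.02)
  out2 <- imputeCondition(saved, 1:4, 5:8, imputeA,
                          imputeB = rep(FALSE, n), seed = 3)
  expect_identical(out, out2)
  # formula spot check: mean 20, sd 2 -> N(16.4, 0.6^2)
  expect_equal(20 - 1.8 * 2, 16.4)
  expect_equal(0.3 * 2, 0.6)
})

test_that("moderated test matches its contracts and the limma cross-check", {
  # identical group means: zero effect, p = 1
  m <- matrix(rep(c(1, 2, 1, 2), 3), 3, 4, byrow = TRUE)
  res <- moderatedTest(m, 1:2, 3:4)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$t_mod, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  # all equal residual variances: moderated t equals the pooled ordinary t
  set.seed(7)
  base <- matrix(rnorm(20 * 6), 20, 6)
  base <- base - rowMeans(base[, 1:3]) %o% c(1, 1, 1, 0, 0, 0) -
    rowMeans(base[, 4:6]) %o% c(0, 0, 0, 1, 1, 1)
  scalef <- sqrt(1 / rowSums(base[, 1:3]^2 + base[, 4:6]^2) * 4)
  eq <- base * scalef          # every feature now has s_g^2 = 1
  eq <- eq + rnorm(20) %o% c(1, 1, 1, 0, 0, 0)
  resEq <- moderatedTest(eq, 1:3, 4:6)
  sg2 <- resEq$s2
  expect_true(all(abs(sg2 - sg2[1]) < 1e-12))
  tOrd <- resEq$log2fc / sqrt(sg2 * (1 / 3 + 1 / 3))
  expect_equal(resEq$t_mod, tOrd, tolerance = 1e-8)

  # limma's lmFit + eBayes as an independent oracle
  set.seed(8)
  y <- matrix(rnorm(200 * 10, 20), 200, 10)
  y[1:20, 1:5] <- y[1:20, 1:5] + 2
  mine <- moderatedTest(y, 1:5, 6:10)
  design <- cbind(WT = rep(c(1, 0), each = 5), DEAD = rep(c(0, 1), each = 5))
  fit <- limma::lmFit(y, design)
  fit <- limma::contrasts.fit(fit, c(1, -1))
  fit <- limma::eBayes(fit)
  expect_equal(mine$t_mod, as.numeric(fit$t), tolerance = 1e-8)
  expect_equal(mine$p, as.numeric(fit$p.value), tolerance = 1e-8)
  expect_equal(attr(mine, "shrinkage")$d0, fit$df.prior, tolerance = 1e-6)
})

test_that("the moderated test is calibrated under the null and monotone in
          effect size", {
  set.seed(21)
  y <- matrix(rnorm(5000 * 10, 20, 1), 5000, 10)
  res <- moderatedTest(y, 1:5, 6:10)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.01)
  # |t| increases with |log2FC| at fixed posterior variance
  ord <- order(attr(res, "shrinkage")$s_tilde_sq)[1:100]
  sub <- res[ord, ]
  expect_gt(cor(abs(sub$log2fc), abs(sub$t_mod)), 0.99)
})

test_that("BH q-values are step-up monotone and control FDR under the null", {
  set.seed(31)
  qs <- replicate(50, {
    p <- runif(300)
    q <- p.adjust(p, "BH")
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    any(q <= 0.05)
  })
  # under a complete null every rejection is false: the realised FDR is the
  # fraction of repeats with any q <= 0.05, which must not exceed nominal
  # beyond Monte-Carlo error
  expect_lt(mean(qs), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("site aggregation dedups, propagates and excludes conflicts", {
  prot <- c(P1 = "AAASYTK")
  reg <- data.frame(
    feature = c("a", "b", "c", "d", "e"),
    kinase = "SRC", protein = "P1",
    site_positions = c("5", "5", "5,6", "4", "4"),
    direction = c("up", "up", "up", "up", "down"))
  agg <- suppressMessages(aggregateToSites(reg, prot))
  calls <- setNames(agg$sites$call, agg$sites$position)
  expect_equal(calls[["5"]], "up")      # two up precursors, one site
  expect_equal(calls[["6"]], "up")      # multi-site precursor covers both
  expect_equal(calls[["4"]], "conflict")
  expect_equal(agg$nConflicts, 1L)
  expect_false("conflict" %in%
                 agg$counts$direction[agg$counts$Freq > 0])
  expect_equal(agg$sites$acceptor[agg$sites$position == 5], "Y")
})

test_that("set enrichment matches the exhaustive hypergeometric oracle", {
  bg <- paste0("s", 1:10)
  regulated <- bg[1:5]
  sets <- list(hit = bg[c(1:4, 6)], indep = bg[c(1, 6, 7)],
               same = bg[1:5])
  res <- suppressWarnings(kinaseSubstrateEnrichment(regulated, sets, bg,
                                                    qThreshold = 0.01))
  # table for "hit" is [[4,1],[1,4]]
  expect_equal(res$p[res$set == "hit"],
               fisherOracle(matrix(c(4, 1, 1, 4), 2, byrow = TRUE)))
  expect_equal(res$odds_ratio[res$set == "same"], Inf)
  expect_lt(res$p[res$set == "same"], 1)
  expect_warning(
    kinaseSubstrateEnrichment(regulated, list(empty = character()), bg),
    "empty")
})

test_that("independent annotation sets pass the q<0.01 gate at the nominal
          rate", {
  set.seed(5)
  bg <- paste0("s", 1:400)
  hits <- integer(400)
  for (b in 1:40) {
    regulated <- sample(bg, 80)
    sets <- lapply(1:10, function(i) sample(bg, 40))
    names(sets) <- paste0("set", 1:10)
    res <- kinaseSubstrateEnrichment(regulated, sets, bg, qThreshold = 0.01)
    hits[b] <- sum(res$kept)
  }
  expect_lt(mean(hits), 0.2)   # far below 1 set in 10 at a 1% threshold
})

test_that("a full regulation contrast recovers planted sites", {
  pr <- genProteome(12, seed = 41)
  des <- makeDesign("SRC", replicates = 5)
  g <- genPhosphoExperiment(pr, des, nSitesPerKinase = 25, nNullSites = 25,
                            occupancyWT = 0.4, occupancyBase = 0.1,
                            noiseCV = 0.253, missingness = 0.05, seed = 42)
  reg <- suppressMessages(regulationContrast(g$experiment, "SRC", seed = 43))
  agg <- suppressMessages(aggregateToSites(reg, pr$sequences))
  upKey <- with(agg$sites[agg$sites$call == "up", ],
                paste(protein, position))
  trueKey <- with(g$sites[g$sites$regulated, ], paste(protein, position))
  expect_gte(mean(trueKey %in% upKey), 0.9)
  if (length(upKey)) expect_lte(mean(!(upKey %in% trueKey)), 0.05)
})
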