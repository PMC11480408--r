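test_that("curve preprocessing subtracts baseline, clips and filters shape", {
  pc <- preprocessCurve(c(0, 1.5, 3), c(100, 150, 220), circularity = 0.9)
  expect_equal(pc$size, c(0, 50, 120))
  expect_true(pc$keep)
  expect_false(preprocessCurve(c(0, 1, 2), c(10, 20, 30), 0.3,
                               circularityMin = 0.6)$keep)
  dip <- preprocessCurve(c(0, 1, 2), c(100, 80, 150))
  expect_equal(dip$size, c(0, 0, 50))
  expect_equal(dip$n_clipped, 1L)
  expect_error(preprocessCurve(c(0, 1, 1), c(1, 2, 3)), "increasing")
})

test_that("composite Simpson is exact for polynomials and handles odd
          trailing intervals", {
  expect_equal(aucSimpson(0:2, (0:2)^2), 8 / 3)
  expect_equal(aucSimpson(0:10, rep(5, 11)), 50)
  expect_equal(aucSimpson(0:2, (0:2)^3), 4)  # Simpson is exact for cubics
  # random cubics on uniform grids, 1e-9
  set.seed(33)
  for (i in 1:25) {
    cf <- rnorm(4)
    t <- seq(0, 3, length.out = 2 * sample(2:6, 1) + 1)
    f <- cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
    exact <- cf[1] * 3 + cf[2] * 9 / 2 + cf[3] * 9 + cf[4] * 81 / 4
    expect_equal(aucSimpson(t, f), exact, tolerance = 1e-9)
  }
  # non-uniform triples are exact for quadratics
  t <- c(0, 1, 3.5, 4, 6.2)
  f <- 2 + t - 0.5 * t^2
  exact <- 2 * 6.2 + 6.2^2 / 2 - 0.5 * 6.2^3 / 3
  expect_equal(aucSimpson(t, f), exact, tolerance = 1e-9)
  # an odd trailing interval uses the trapezoid
  t4 <- c(0, 1, 2, 3)
  f4 <- c(0, 1, 4, 9)
  expect_equal(aucSimpson(t4, f4), 8 / 3 + (4 + 9) / 2)
  expect_warning(a2 <- aucSimpson(c(0, 2), c(1, 3)), "2 points")
  expect_equal(a2, 4)
})

test_that("plate rescaling and the Mann-Whitney score behave at the
          boundaries", {
  mk <- function(w, d, plate = "SC") {
    rbind(data.frame(strain = "REF", condition = plate, replicate = 1:4,
                     plate = plate, auc = 2),
          data.frame(strain = "K1_WT", condition = plate,
                     replicate = seq_along(w), plate = plate, auc = w),
          data.frame(strain = "K1_DEAD", condition = plate,
                     replicate = seq_along(d), plate = plate, auc = d))
  }
  # identical replicate sets: delta 0, p 1 under tie handling
  same <- rescaleAndScore(mk(c(3, 3, 3), c(3, 3, 3)))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # reference mean 2, colony AUC 3 rescales to 1.5
  expect_equal(same$auc_wt, 1.5)

  # WT strictly below DEAD, 16 vs 16: exact two-sided minimum p
  set.seed(41)
  w <- runif(16, 1, 2); d <- runif(16, 3, 4)
  sep <- rescaleAndScore(mk(w, d))
  expect_lt(sep$delta, 0)
  expect_equal(sep$p, 2 / choose(32, 16), tolerance = 1e-12)

  # multiplying all sizes on a plate by a constant changes nothing
  tab <- mk(w, d)
  tab2 <- tab; tab2$auc <- tab2$auc * 37
  expect_equal(rescaleAndScore(tab2)$delta, sep$delta)
})

test_that("plates without a reference are excluded with a message", {
  tab <- data.frame(strain = c("K1_WT", "K1_WT", "K1_DEAD", "K1_DEAD"),
                    condition = "SC", replicate = c(1, 2, 1, 2),
                    plate = "SC", auc = c(1, 2, 3, 4))
  expect_message(res <- rescaleAndScore(tab), "without reference")
  expect_null(res)
})

test_that("the fitness screen recovers injected effects with power and
          controls false positives", {
  g <- genGrowthExperiment(c(A = 0.3, B = 0.3, C = 0.3, D = 0),
                           conditions = c("c1", "c2"),
                           replicates = 16, noiseCV = 0.05, seed = 43)
  fit <- fitnessScores(g$curves)
  hits <- fit$kinase[fit$q < 0.05 & fit$delta < 0]
  power <- mean(c("A", "B", "C") %in% hits)
  expect_gte(power, 0.9)
  expect_false("D" %in% hits)
  # the injected effect reduces the measured AUC in the right direction
  perK <- attr(fit, "perKinase")
  expect_lt(max(perK$min_delta[perK$kinase != "D"]),
            perK$min_delta[perK$kinase == "D"])
})

test_that("under a null generator the WT-dead rejection rate is nominal", {
  set.seed(44)
  rejections <- unlist(lapply(1:8, function(i) {
    g <- genGrowthExperiment(c(A = 0, B = 0, C = 0), replicates = 8,
                             noiseCV = 0.08, seed = 100 + i)
    fit <- fitnessScores(g$curves)
    fit$p < 0.05
  }))
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 /
                                                 length(rejections)))
})

test_that("fitness-phosphocount correlation is exact on collinear input and
          calibrated under the null", {
  counts <- c(K1 = 0, K2 = 10, K3 = 20, K4 = 30)
  deltas <- c(K1 = 0, K2 = -1, K3 = -2, K4 = -3)
  expect_equal(fitnessPhosphoCorrelation(counts, deltas)$r, -1)
  expect_error(fitnessPhosphoCorrelation(counts[1:3], deltas[1:3]), ">= 4")
  zero <- fitnessPhosphoCorrelation(counts, c(K1 = 1, K2 = 1, K3 = 1,
                                              K4 = 1))
  expect_true(is.na(zero$r))

  set.seed(45)
  ps <- replicate(200, {
    x <- setNames(rpois(8, 20), paste0("k", 1:8))
    y <- setNames(rnorm(8), paste0("k", 1:8))
    fitnessPhosphoCorrelation(x, y)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # planted coupling is recovered within its analytic confidence interval
  set.seed(46)
  n <- 40
  x <- setNames(rpois(n, 30), paste0("k", 1:n))
  y <- setNames(-0.01 * x + rnorm(n, 0, 0.1), paste0("k", 1:n))
  est <- fitnessPhosphoCorrelation(x, y)
  rho <- -0.01 * sd(x) / sqrt((0.01 * sd(x))^2 + 0.1^2)
  z <- atanh(est$r) - atanh(rho)
  expect_lt(abs(z) * sqrt(n - 3), qnorm(0.995))
})

test_that("the mixture threshold sits at the weighted density crossing", {
  set.seed(47)
  x <- c(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  g <- gmmThreshold(x)
  expect_lt(abs(g$threshold - 5), 0.15)   # symmetric case: midpoint
  # asymmetric weights push the threshold toward the light component
  xa <- c(rnorm(3600, 0, 1), rnorm(400, 10, 1))
  ga <- gmmThreshold(xa)
  expect_gt(ga$threshold, 5)
  # the fitted threshold matches the analytic crossing of the fitted
  # components within 1%
  f <- function(t) ga$weight[1] * dnorm(t, ga$mu[1], ga$sigma[1]) -
    ga$weight[2] * dnorm(t, ga$mu[2], ga$sigma[2])
  root <- uniroot(f, c(ga$mu[1], ga$mu[2]), tol = 1e-12)$root
  expect_lt(abs(ga$threshold - root) / root, 0.01)
  expect_error(gmmThreshold(rnorm(50)), ">= 100")
})

test_that("competition frequencies discard doublets and double-negatives", {
  set.seed(48)
  n <- 600
  gfp <- c(rnorm(n, 0), rnorm(n, 10))
  mch <- c(rnorm(n, 10), rnorm(n, 0))
  res <- competitionFrequency(gfp, mch)
  expect_equal(res$frequency, mean(!(mch > res$thresholds[["mcherry"]])[
    xor(gfp > res$thresholds[["gfp"]], mch > res$thresholds[["mcherry"]])]))
  # all GFP+ mCherry- events: frequency 1
  allPos <- competitionFrequency(c(rnorm(300, 0), rnorm(300, 10)),
                                 c(rnorm(300, 10), rnorm(300, 0)))
  expect_true(allPos$frequency > 0.45 && allPos$frequency < 0.55)
  gfp2 <- c(rnorm(150, 0, 0.5), rnorm(450, 10, 0.5))
  mch2 <- rep(c(10, 0), c(150, 450)) + rnorm(600, 0, 0.5)
  res2 <- competitionFrequency(gfp2, mch2)
  expect_equal(res2$frequency, 0.75)
})
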