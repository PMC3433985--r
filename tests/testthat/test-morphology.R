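make_morph <- function(scores1, scores2, sex = "male") {
  ## scores*: matrices (individuals x 9) for the two species
  n1 <- nrow(scores1); n2 <- nrow(scores2)
  df <- data.frame(
    individual_id = sprintf("m%02d", seq_len(n1 + n2)),
    population = rep(c("P1", "P2"), c(n1, n2)),
    species = rep(c("S1", "S2"), c(n1, n2)),
    sex = sex,
    rbind(scores1, scores2))
  colnames(df)[5:13] <- letters[1:9]
  df
}

test_that("exact U test equals exhaustive assignment enumeration", {
  ## all-1 vs all-0 with n = 5 vs 5: only the two extreme assignments are
  ## as extreme, so p = 2 / C(10,5) = 0.0079
  res <- mannWhitneyU(rep(1, 5), rep(0, 5))
  expect_equal(res$method, "exact")
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  ## identical score distributions give p = 1
  expect_equal(mannWhitneyU(c(0, 0.5, 1), c(0, 0.5, 1))$p, 1)
  ## direct enumeration oracle on an asymmetric tied dataset
  x <- c(0, 0.5, 0.5, 1); y <- c(0, 0, 0.5, 0)
  res2 <- mannWhitneyU(x, y)
  pooled <- c(x, y)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  mu <- length(x) * length(y) / 2
  uObs <- uOf(seq_along(x))
  all_u <- apply(combn(8, 4), 2, uOf)
  expect_equal(res2$p, mean(abs(all_u - mu) >= abs(uObs - mu) - 1e-9),
               tolerance = 1e-12)
})

test_that("U test p is invariant under monotone relabeling of scores", {
  x <- c(0, 0.5, 0.5, 1, 1); y <- c(0, 0, 0.5, 0.5, 0)
  mono <- function(v) v^3 + 2 * v   # strictly increasing
  expect_equal(mannWhitneyU(x, y)$p, mannWhitneyU(mono(x), mono(y))$p)
  ## also on the normal-approximation path
  x2 <- rep(c(0, 0.5, 1), c(8, 4, 3)); y2 <- rep(c(0, 0.5, 1), c(3, 4, 8))
  expect_equal(mannWhitneyU(x2, y2)$method, "normal")
  expect_equal(mannWhitneyU(x2, y2)$p, mannWhitneyU(mono(x2), mono(y2))$p)
})

test_that("per-character tests apply the 18-test Bonferroni threshold", {
  set.seed(2)
  s1 <- matrix(rbinom(5 * 9, 2, 0.9) / 2, 5)   # species 1 mostly present
  s2 <- matrix(rbinom(5 * 9, 2, 0.1) / 2, 5)   # species 2 mostly absent
  recs <- rbind(make_morph(s1, s2, "male"), make_morph(s1, s2, "female"))
  recs$individual_id <- sprintf("i%02d", seq_len(nrow(recs)))
  res <- characterUTests(recs)
  expect_equal(nrow(res), 18L)
  expect_equal(unique(res$bonferroniThreshold), 0.05 / 18)
  expect_equal(unique(res$bonferroniThreshold), 0.0028, tolerance = 0.02)
  ## a constant character in both groups is untestable with p = 1
  recs2 <- recs
  recs2$a <- 1
  res2 <- characterUTests(recs2)
  aRows <- res2[res2$character == "a", ]
  expect_true(all(aRows$untestable))
  expect_true(all(aRows$p == 1))
})

test_that("Ward merges match exhaustive agglomeration on a 6-point set", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)  # generic positions, no tied merge costs
  hc <- hclust(dist(X), method = "ward.D2")
  ## identical partitions at every cut level (labels may swap)
  for (k in 2:4)
    expect_equal(length(unique(paste(oracle_ward_cut(X, k),
                                     cutree(hc, k)))), k)
  ## merge heights equal sqrt(2 * within-SS increment) of the greedy
  ## minimum-variance agglomeration
  expect_equal(hc$height, sqrt(2 * oracle_ward_increments(X)),
               tolerance = 1e-10)
})

test_that("well-separated score blocks cluster perfectly; identical ones at height zero", {
  ones <- matrix(1, 6, 9); zeros <- matrix(0, 6, 9)
  set.seed(8)
  ones[sample(54, 5)] <- 0.5  # slight jitter
  recs <- make_morph(ones, zeros)
  wc <- wardCluster(recs, "male")
  expect_equal(wc$purity, 1.0)
  same <- make_morph(matrix(0.5, 4, 9), matrix(0.5, 4, 9))
  wc2 <- wardCluster(same, "male")
  expect_true(all(wc2$hclust$height == 0))
})

test_that("reference distances equal the brute-force double average", {
  set.seed(10)
  foc <- matrix(rbinom(6 * 9, 2, 0.5) / 2, 6)
  ref <- matrix(rbinom(4 * 9, 2, 0.5) / 2, 4)
  recs <- make_morph(foc, ref)
  recs$population[1:6] <- rep(c("siteA", "siteB"), each = 3)
  out <- morphDistanceToReference(recs, "S2", "male")
  for (site in c("siteA", "siteB")) {
    rows <- which(recs$population == site)
    perInd <- sapply(rows, function(i) {
      mean(sapply(7:10, function(j)
        sqrt(sum((as.numeric(recs[i, letters[1:9]]) -
                    as.numeric(recs[j, letters[1:9]]))^2))))
    })
    expect_equal(out$meanDistance[out$population == site], mean(perInd),
                 tolerance = 1e-12)
  }
  ## focal identical to every reference record -> distance 0
  recs0 <- make_morph(matrix(0.5, 2, 9), matrix(0.5, 3, 9))
  out0 <- morphDistanceToReference(recs0, "S2", "male")
  expect_equal(out0$meanDistance, 0)
  ## single focal vs single reference differing by 1 in one character
  a <- matrix(0, 1, 9); b <- matrix(0, 1, 9); a[1, 3] <- 1
  out1 <- morphDistanceToReference(make_morph(a, b), "S2", "male")
  expect_equal(out1$meanDistance, 1)
})

test_that("morphology-genetics regression flags significance at 0.05/2", {
  ## exact line: r2 = 1
  md <- data.frame(population = paste0("P", 1:5),
                   meanDistance = 0.1 + 100 * (1:5) / 1000)
  g <- setNames((1:5) / 1000, md$population)
  fit <- regressMorphOnGenetic(md, g)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 100, tolerance = 1e-9)
  expect_true(fit$significant)
  ## constant predictor errors
  expect_error(regressMorphOnGenetic(md, setNames(rep(1e-3, 5),
                                                  md$population)),
               "constant")
  expect_error(regressMorphOnGenetic(md[1:2, ], g[1:2]), "three")
})

test_that("summary t test reproduces printed body-size statistics", {
  ## landlocked males 50.4 +/- 5.0 (n=17) vs source males 79.2 +/- 11.1 (n=13)
  res <- sizeTTest(50.4, 5.0, 17, 79.2, 11.1, 13)
  expect_equal(res$df, 28)
  expect_equal(round(abs(res$t), 1), 9.5)
  expect_lt(res$p, 1e-4)
  ## equal means give t = 0; antisymmetry in group order
  expect_equal(sizeTTest(10, 1, 5, 10, 1, 5)$t, 0)
  a <- sizeTTest(44.6, 4.9, 20, 59.3, 7.9, 12)
  b <- sizeTTest(59.3, 7.9, 12, 44.6, 4.9, 20)
  expect_equal(a$t, -b$t)
  expect_error(sizeTTest(1, 0, 1, 2, 0, 1), "exceed")
})

test_that("summary t equals t from moment-matched raw data", {
  ## construct raw samples with exactly the stated means and SDs
  mk <- function(m, s, n) {
    x <- scale(rnorm(n))[, 1]  # mean 0, sd 1 exactly
    m + s * x
  }
  set.seed(12)
  x <- mk(50.4, 5.0, 17); y <- mk(79.2, 11.1, 13)
  raw <- t.test(x, y, var.equal = TRUE)
  res <- sizeTTest(mean(x), sd(x), 17, mean(y), sd(y), 13)
  expect_equal(res$t, unname(raw$statistic), tolerance = 1e-9)
  expect_equal(res$df, unname(raw$parameter))
})

test_that("synthetic morphology recovers the configured slope", {
  ## regression of simulated morphological distance on the generating
  ## genetic distances recovers morph_slope within 25% (averaged over
  ## replicates, both sexes pooled into male fits)
  slopes <- vapply(1:60, function(k) {
    cfg <- simulationConfig(seed = 6000L + k)
    tr <- simulationTruth(cfg)
    morph <- simulateMorphology(cfg, tr)
    md <- morphDistanceToReference(morph, "BR", "male")
    g <- setNames(tr$expected_distances,
                  paste0("YB_", names(tr$expected_distances)))
    regressMorphOnGenetic(md, g)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 120) / 120, 0.25)
})

test_that("zero-noise synthetic morphology is perfectly clusterable", {
  cfg <- simulationConfig(seed = 61L, morph_noise_sd = 0)
  morph <- simulateMorphology(cfg)
  wc <- wardCluster(morph, "female")
  expect_equal(wc$purity, 1.0)
})

test_that("capped drift with zero noise reaches the all-present profile", {
  ## a population far beyond the cap: delta = 1 exactly
  cfg <- simulationConfig(heights_m = c(Huge = 1e5), morph_noise_sd = 0,
                          seed = 3L)
  morph <- simulateMorphology(cfg)
  yb <- morph[morph$species == "YB", letters[1:9]]
  expect_true(all(yb == 1))
})
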