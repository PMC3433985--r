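test_that("Firth fit is finite under complete separation, unlike plain ML", {
  x <- c(0, 0, 1, 1); y <- c(0, 0, 1, 1)
  fit <- firthLogistic(y, cbind(x = x))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(fit$coefficients["x"], 0)
  ## the unpenalized MLE diverges on the same data
  suppressWarnings(g <- glm(y ~ x, family = binomial()))
  expect_gt(abs(coef(g)["x"]), abs(fit$coefficients["x"]) * 5)
  ## constant response: finite negative intercept
  fit0 <- firthLogistic(rep(0, 8))
  expect_true(is.finite(fit0$coefficients[1]))
  expect_lt(fit0$coefficients[1], 0)
})

test_that("Firth estimates maximize the penalized likelihood", {
  set.seed(14)
  n <- 25
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + X[, 1] - 0.5 * X[, 2]))
  fit <- firthLogistic(y, X, standardize = FALSE)
  Xd <- cbind(1, X)
  opt <- optim(rep(0, 3), function(b) -oracle_firth_pll(b, y, Xd),
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  expect_equal(as.numeric(fit$logLikPenalized), -opt$value,
               tolerance = 1e-8)
  ## aic bookkeeping
  expect_equal(fit$aic, -2 * fit$logLikPenalized + 2 * fit$npar)
})

test_that("standardization does not change the reported fit", {
  set.seed(16)
  n <- 40
  X <- cbind(a = 100 + 30 * rnorm(n), b = runif(n, 0, 0.01))
  y <- rbinom(n, 1, plogis(-1 + 0.02 * (X[, 1] - 100)))
  f1 <- firthLogistic(y, X, standardize = TRUE)
  f2 <- firthLogistic(y, X, standardize = FALSE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-5)
  expect_equal(f1$se, f2$se, tolerance = 1e-4)
})

test_that("Firth estimates stay finite over random separated designs", {
  set.seed(18)
  for (rep in 1:20) {
    n <- 20
    x <- sort(rnorm(n))
    y <- as.numeric(seq_len(n) > sample(5:15, 1))  # separated on x
    z <- rnorm(n)
    fit <- firthLogistic(y, cbind(x = x, z = z))
    expect_true(all(is.finite(fit$coefficients)))
    expect_true(all(is.finite(fit$se)))
  }
})

test_that("rank-deficient designs raise a collinearity error", {
  set.seed(20)
  x <- rnorm(10)
  expect_error(firthLogistic(rbinom(10, 1, 0.5),
                             cbind(a = x, b = 2 * x)),
               "rank deficient")
})

test_that("AUC equals the all-pairs count and is rank-invariant", {
  y <- c(0, 0, 1, 1, 0, 1, 0, 1)
  p <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.9, 0.2, 0.4)
  pairsAuc <- {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg)
      s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  expect_equal(aucScore(p, y), pairsAuc)
  ## strictly monotone transform leaves AUC unchanged
  expect_equal(aucScore(qlogis(p * 0.9 + 0.05), y), aucScore(p, y))
  ## degenerate cases
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(aucScore(p, rep(1, 8)), "both classes")
  skip_if_not_installed("pROC")
  expect_equal(aucScore(p, y),
               as.numeric(suppressMessages(pROC::auc(y, p))))
})

test_that("all-subsets selection matches manual enumeration on a 2-pool", {
  set.seed(22)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.5 * d$x1))
  res <- allSubsetsAIC(d, "y", c("x1", "x2"))
  manual <- c(
    "(null)" = firthLogistic(d$y)$aic,
    "x1" = firthLogistic(d$y, as.matrix(d[, "x1", drop = FALSE]))$aic,
    "x2" = firthLogistic(d$y, as.matrix(d[, "x2", drop = FALSE]))$aic,
    "x1+x2" = firthLogistic(d$y, as.matrix(d[, c("x1", "x2")]))$aic)
  expect_equal(nrow(res$table), 4L)
  got <- setNames(res$table$aic, res$table$subset)
  expect_equal(got[names(manual)], manual, tolerance = 1e-10)
  expect_equal(res$table$subset[1L],
               names(manual)[which.min(manual)])
  ## null-only pool returns the intercept model
  res0 <- allSubsetsAIC(d, "y", character(0))
  expect_equal(res0$bestPredictors, character(0))
})

test_that("AIC ranking is invariant to predictor column order", {
  set.seed(24)
  n <- 50
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- rbinom(n, 1, plogis(d$a - d$c))
  r1 <- allSubsetsAIC(d, "y", c("a", "b", "c"))
  r2 <- allSubsetsAIC(d, "y", c("c", "a", "b"))
  expect_equal(r1$table$subset, r2$table$subset)
  expect_equal(r1$table$aic, r2$table$aic, tolerance = 1e-10)
  expect_equal(sort(r1$bestPredictors), sort(r2$bestPredictors))
})

test_that("a strong true predictor is selected over pure noise", {
  hits <- vapply(1:60, function(k) {
    set.seed(8000L + k)
    n <- 60
    d <- data.frame(true = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-0.3 + 2 * d$true))
    "true" %in% allSubsetsAIC(d, "y",
                              c("true", "n1", "n2", "n3"))$bestPredictors
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Poisson GLMM marginal likelihood matches refined quadrature", {
  skip_if_not_installed("pracma")
  set.seed(26)
  nRiver <- 3L; perRiver <- 8L
  river <- rep(paste0("R", 1:nRiver), each = perRiver)
  u <- rnorm(nRiver, 0, 0.4)
  x <- rnorm(nRiver * perRiver)
  lambda <- exp(1.2 + 0.4 * x + u[as.integer(factor(river))])
  y <- rpois(length(x), lambda)
  fit <- poissonGlmm(y, data.frame(x = x), "x", river, nAGQ = 25L)
  ll64 <- oracle_glmm_loglik(fit$coefficients, max(fit$ranefSD, 1e-8),
                             y, cbind(1, x), river, nNodes = 64L)
  expect_equal(fit$logLik, ll64, tolerance = 1e-6)
})

test_that("zero random-effect variance reduces the GLMM to a Poisson GLM", {
  set.seed(28)
  river <- rep(paste0("R", 1:5), each = 6)
  x <- rnorm(30)
  y <- rpois(30, exp(1 + 0.5 * x))  # no river effect at all
  fit <- poissonGlmm(y, data.frame(x = x), "x", river)
  g <- glm(y ~ x, family = poisson())
  expect_lt(fit$ranefSD, 0.2)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 0.05)
  ## single river: exact reduction
  fit1 <- poissonGlmm(y, data.frame(x = x), "x", rep("R1", 30))
  expect_equal(fit1$model, "glm")
  expect_equal(unname(fit1$coefficients), unname(coef(g)), tolerance = 1e-10)
  expect_error(poissonGlmm(y + 0.5, data.frame(x = x), "x", river),
               "integers")
})

test_that("synthetic richness with zero between-river SD recovers ~0 variance", {
  cfg <- simulationConfig(seed = 77L, richness_random_sd = 0,
                          n_sites = 120L)
  sites <- simulateHabitat(cfg)
  fit <- poissonGlmm(sites$richness, sites, "waterfall", sites$river)
  expect_lt(fit$ranefSD, 0.15)
})

test_that("Wilks lambda matches the determinant-ratio definition", {
  set.seed(30)
  n <- 10
  Y <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  Y[1:n, ] <- Y[1:n, ] + matrix(rep(c(0.5, -0.3, 0.2), each = n), n, 3)
  g <- rep(c("above", "below"), each = n)
  res <- manovaWilks(Y, g)
  ## direct linear algebra: W = within-group scatter, T = total scatter
  W <- matrix(0, 3, 3)
  for (lev in unique(g)) {
    sub <- Y[g == lev, , drop = FALSE]
    cen <- sweep(sub, 2L, colMeans(sub), "-")
    W <- W + crossprod(cen)
  }
  Tm <- crossprod(sweep(Y, 2L, colMeans(Y), "-"))
  expect_equal(res$lambda, det(W) / det(Tm), tolerance = 1e-10)
  ## agrees with the standard MANOVA summary on a regular design
  sm <- summary(manova(Y ~ factor(g)), test = "Wilks")$stats
  expect_equal(res$lambda, unname(sm[1, "Wilks"]), tolerance = 1e-10)
  expect_equal(res$fStatistic, unname(sm[1, "approx F"]), tolerance = 1e-8)
  expect_equal(res$p, unname(sm[1, "Pr(>F)"]), tolerance = 1e-8)
  ## lambda -> 0 when a coordinate separates the groups perfectly with no
  ## within-group variance on it
  Y2 <- Y; Y2[, 1] <- rep(c(0, 1), each = n)
  res2 <- manovaWilks(Y2, g)
  expect_lt(res2$lambda, 1e-10)
  expect_error(manovaWilks(Y[c(1:2, 11:12), ], g[c(1:2, 11:12)]),
               "too few")
})

test_that("synthetic occupancy recovers coefficient signs by Firth fitting", {
  ## the study design scaled x4: n = 120 sites
  coefs <- c("(Intercept)" = -1.5, waterfall = 3.5,
             distance_from_sea_km = -0.8)
  ok <- vapply(1:100, function(k) {
    cfg <- simulationConfig(seed = 9000L + k, n_sites = 120L)
    sites <- simulateHabitat(cfg)
    X <- cbind(waterfall = sites$waterfall,
               distance_from_sea_km = scale(sites$distance_from_sea_km)[, 1])
    fit <- firthLogistic(sites$presence_focal, X)
    all(sign(fit$coefficients[c("waterfall", "distance_from_sea_km")]) ==
          sign(coefs[c("waterfall", "distance_from_sea_km")]))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
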