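## habitat: occupancy and richness modelling. Firth's bias-reduced
## logistic regression keeps estimates finite under the perfect separation
## that waterfall presence/absence induces; model selection is exhaustive
## over predictor subsets by AIC; species richness uses a Poisson model
## with a Gaussian random intercept per river system.

#' Firth bias-reduced logistic regression
#'
#' Penalized-likelihood logistic fit with Jeffreys-prior (Firth)
#' adjustment: the score is modified by half the hat-diagonal leverage
#' term, U*(beta) = X'(y - p + h(1/2 - p)), and the penalized
#' log-likelihood is l(beta) + 1/2 log det(X'WX). Estimates are finite for
#' any full-rank design, including complete separation. Continuous
#' predictors are standardized internally for conditioning and
#' coefficients are reported on the original scale. Convergence when the
#' largest modified-score component falls below \code{tol} or after
#' \code{maxIter} Newton steps.
#'
#' @param y binary 0/1 response.
#' @param X design matrix of predictors, without intercept (an intercept
#'   is always added). May be NULL/zero-column for the null model.
#' @param standardize standardize predictor columns internally
#'   (default TRUE).
#' @param maxIter,tol iteration controls.
#' @return list: coefficients, se, logLikPenalized, logLik, aic, fitted,
#'   auc, converged, iterations, npar
#' @export
firthLogistic <- function(y, X = NULL, standardize = TRUE,
                          maxIter = 100L, tol = 1e-8) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  if (is.null(X) || NCOL(X) == 0L) {
    Xr <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    Xr <- as.matrix(X)
    if (is.null(colnames(Xr)))
      colnames(Xr) <- paste0("x", seq_len(ncol(Xr)))
  }
  std <- if (standardize && ncol(Xr))
    .standardizeColumns(Xr) else list(x = Xr, center = numeric(ncol(Xr)),
                                      scale = rep(1, ncol(Xr)))
  Xd <- cbind("(Intercept)" = 1, std$x)
  p <- ncol(Xd)
  if (qr(Xd)$rank < p) {
    qrd <- qr(Xd)
    bad <- colnames(Xd)[setdiff(seq_len(p), qrd$pivot[seq_len(qrd$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(Xd * w, Xd)
    XtWXinv <- solve(XtWX)
    h <- rowSums((Xd %*% XtWXinv) * Xd) * w
    Ustar <- drop(crossprod(Xd, y - mu + h * (0.5 - mu)))
    if (max(abs(Ustar)) < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    step <- drop(XtWXinv %*% Ustar)
    ## dampen huge first steps for numeric safety
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    iter <- iter + 1L
  }
  eta <- drop(Xd %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(Xd * w, Xd)
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  pll <- ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  seStd <- sqrt(diag(solve(XtWX)))
  ## back-transform to the original predictor scale
  A <- diag(p)
  if (p > 1L) {
    A[1L, -1L] <- -std$center / std$scale
    diag(A)[-1L] <- 1 / std$scale
  }
  coefOrig <- drop(A %*% beta)
  covOrig <- A %*% solve(XtWX) %*% t(A)
  names(coefOrig) <- colnames(Xd)
  seOrig <- sqrt(diag(covOrig))
  names(seOrig) <- colnames(Xd)
  aucVal <- if (length(unique(y)) == 2L) aucScore(mu, y) else NA_real_
  list(coefficients = coefOrig, se = seOrig,
       logLikPenalized = as.numeric(pll), logLik = ll,
       aic = -2 * as.numeric(pll) + 2 * p,
       fitted = mu, auc = aucVal, converged = converged,
       iterations = iter, npar = p)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that
#' a random positive outranks a random negative; ties count 1/2. Invariant
#' under strictly monotone transformation of the scores.
#'
#' @param prob fitted probabilities or any monotone score.
#' @param y binary 0/1 outcomes (both classes must be present).
#' @return AUC in [0, 1]
#' @export
aucScore <- function(prob, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  r <- rank(prob)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exhaustive all-subsets model selection by AIC
#'
#' Fits every subset of the predictor pool (2^k models, from the null to
#' the full model) and ranks them by AIC; the lowest AIC wins, with ties
#' broken by fewer parameters and then lexicographic predictor order. A
#' subset whose fit fails is recorded and excluded; the run continues.
#' For the Firth fit, AIC uses the penalized log-likelihood, matching the
#' fitting criterion.
#'
#' @param data data.frame holding response and predictors.
#' @param response response column name (binary for the default fitter).
#' @param predictors character vector of predictor column names
#'   (at most 15).
#' @param fitter function(data, response, predictors) returning a list
#'   with at least \code{aic}; defaults to a \code{\link{firthLogistic}}
#'   wrapper.
#' @return list: \code{best} (refit of the winning subset),
#'   \code{bestPredictors}, \code{table} (ranked data.frame with subset,
#'   k, aic), \code{failures}
#' @export
allSubsetsAIC <- function(data, response, predictors,
                          fitter = firthFitter) {
  k <- length(predictors)
  if (k > 15L) stop("predictor pool too large for exhaustive search")
  nSub <- 2^k
  subsets <- vector("list", nSub)
  aics <- rep(NA_real_, nSub)
  failures <- character()
  for (m in seq_len(nSub) - 1L) {
    sel <- predictors[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L]
    subsets[[m + 1L]] <- sel
    fit <- tryCatch(fitter(data, response, sel), error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, paste0("{", paste(sel, collapse = ","),
                                     "}: ", conditionMessage(fit)))
    } else {
      aics[m + 1L] <- fit$aic
    }
  }
  label <- vapply(subsets, function(s)
    if (length(s)) paste(sort(s), collapse = "+") else "(null)", character(1))
  ok <- !is.na(aics)
  if (!any(ok)) stop("every candidate fit failed")
  tab <- data.frame(subset = label[ok],
                    k = lengths(subsets)[ok],
                    aic = aics[ok])
  tab <- tab[order(tab$aic, tab$k, tab$subset), , drop = FALSE]
  rownames(tab) <- NULL
  bestSel <- subsets[ok][[order(aics[ok], lengths(subsets)[ok],
                                label[ok])[1L]]]
  list(best = fitter(data, response, bestSel),
       bestPredictors = bestSel, table = tab, failures = failures)
}

#' Firth-logistic fitter for \code{\link{allSubsetsAIC}}
#' @param data,response,predictors see \code{\link{allSubsetsAIC}}.
#' @return a \code{\link{firthLogistic}} fit
#' @export
firthFitter <- function(data, response, predictors) {
  X <- if (length(predictors)) as.matrix(data[, predictors, drop = FALSE])
       else NULL
  firthLogistic(data[[response]], X)
}

#' Poisson random-intercept model for species richness
#'
#' Poisson log-link regression with a Gaussian random intercept per river
#' system, integrated by adaptive Gauss-Hermite quadrature
#' (\code{nAGQ >= 8} nodes, via \code{lme4::glmer}). With a single river
#' (or zero random-effect variance) this reduces to a plain Poisson GLM.
#' Subset selection can reuse \code{\link{allSubsetsAIC}} with
#' \code{\link{glmmFitter}}.
#'
#' @param counts non-negative integer response.
#' @param data data.frame of predictors.
#' @param predictors character vector of predictor column names (may be
#'   empty).
#' @param river factor/character of river-system ids.
#' @param nAGQ number of adaptive Gauss-Hermite nodes (default 8).
#' @return list: coefficients, se, ranefSD, logLik, aic, npar, fitted,
#'   model ("glmm" or "glm"), fit (the underlying object)
#' @export
poissonGlmm <- function(counts, data, predictors = character(), river,
                        nAGQ = 8L) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  df <- data.frame(..count = as.integer(counts), data,
                   ..river = factor(river), check.names = FALSE)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (nlevels(df$..river) < 2L) {
    fit <- glm(as.formula(paste("..count ~", rhs)), data = df,
               family = poisson())
    co <- coef(fit)
    return(list(coefficients = co,
                se = sqrt(diag(vcov(fit))),
                ranefSD = NA_real_, logLik = as.numeric(logLik(fit)),
                aic = AIC(fit), npar = length(co),
                fitted = fitted(fit), model = "glm", fit = fit))
  }
  fml <- as.formula(paste("..count ~", rhs, "+ (1 | ..river)"))
  ## a zero variance estimate (singular fit) is a legitimate outcome here
  fit <- suppressMessages(
    lme4::glmer(fml, data = df, family = poisson(), nAGQ = nAGQ))
  vc <- lme4::VarCorr(fit)
  sdRiver <- attr(vc[["..river"]], "stddev")[[1L]]
  co <- lme4::fixef(fit)
  ## lme4 reports the quadrature log-likelihood relative to the saturated
  ## model; add the saturated Poisson term back to get the absolute
  ## marginal log-likelihood
  llAbs <- as.numeric(logLik(fit)) +
    sum(stats::dpois(counts, pmax(counts, 0), log = TRUE))
  npar <- length(co) + 1L
  list(coefficients = co,
       se = sqrt(diag(as.matrix(vcov(fit)))),
       ranefSD = unname(sdRiver),
       logLik = llAbs,
       aic = -2 * llAbs + 2 * npar, npar = npar,
       fitted = fitted(fit), model = "glmm", fit = fit)
}

#' Poisson-GLMM fitter for \code{\link{allSubsetsAIC}}
#'
#' Expects \code{data} to carry the river id in a \code{river} column.
#' @param data,response,predictors see \code{\link{allSubsetsAIC}}.
#' @param nAGQ quadrature nodes.
#' @return a \code{\link{poissonGlmm}} fit
#' @export
glmmFitter <- function(data, response, predictors, nAGQ = 8L) {
  poissonGlmm(data[[response]], data, predictors, data$river, nAGQ = nAGQ)
}

#' MANOVA with Wilks' lambda for site environments
#'
#' Tests whether the integrated multivariate environment differs between
#' site groups (above vs below/without waterfalls): Wilks' lambda
#' = det(W)/det(T) with Rao's F approximation; with two groups this equals
#' the Hotelling T-squared transformation.
#'
#' @param env numeric matrix/data.frame of environmental factors.
#' @param groups two-level factor/character of group labels.
#' @return list: lambda, fStatistic, dfNum, dfDen, p
#' @export
manovaWilks <- function(env, groups) {
  Y <- as.matrix(env)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  n <- nrow(Y); p <- ncol(Y); ng <- nlevels(g)
  if (n <= p + ng - 1L)
    stop("too few sites for ", p, " responses")
  W <- matrix(0, p, p)
  for (lev in levels(g)) {
    sub <- Y[g == lev, , drop = FALSE]
    cen <- sweep(sub, 2L, colMeans(sub), "-")
    W <- W + crossprod(cen)
  }
  Tm <- crossprod(sweep(Y, 2L, colMeans(Y), "-"))
  detT <- det(Tm)
  if (!is.finite(detT) || detT <= 0) stop("singular total scatter")
  lambda <- max(det(W), 0) / detT
  ## Rao's F approximation (with 2 groups this is exact and equals the
  ## Hotelling T-squared transformation)
  q <- ng - 1L
  dfRes <- n - ng
  tmp1 <- dfRes - (p - q + 1) / 2
  tmp2 <- (p * q - 2) / 4
  tmp3 <- p^2 + q^2 - 5
  s <- if (tmp3 > 0) sqrt(((p * q)^2 - 4) / tmp3) else 1
  dfNum <- p * q
  dfDen <- tmp1 * s - 2 * tmp2
  fStat <- if (lambda > 0) (lambda^(-1 / s) - 1) * dfDen / dfNum else Inf
  list(lambda = lambda, fStatistic = fStat, dfNum = dfNum, dfDen = dfDen,
       p = pf(fStat, dfNum, dfDen, lower.tail = FALSE))
}
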