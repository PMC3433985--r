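# Small in-code fixtures and independent oracle implementations used
# across the suite. Oracles are deliberately naive (loops, enumeration,
# direct formula evaluation) and independent of the package's code paths.

rand_seq <- function(L, freqs = c(A = .26, C = .31, G = .14, T = .29)) {
  paste(sample(names(freqs), L, TRUE, prob = freqs), collapse = "")
}

mutate_seq <- function(s, positions, to) {
  v <- strsplit(s, "")[[1]]
  v[positions] <- to
  paste(v, collapse = "")
}

toy_table <- function(seqs, pops = NULL, species = NULL, sex = NULL) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("ind%02d", seq_len(n))
  meta <- data.frame(
    individual_id = names(seqs),
    population = if (is.null(pops)) rep("P1", n) else pops,
    species = if (is.null(species)) rep("SP", n) else species,
    sex = if (is.null(sex)) rep_len(c("male", "female"), n) else sex)
  sequenceTable(seqs, meta)
}

# Direct scalar transcription of the TN93 closed form (and its
# continuous-gamma analogue), evaluated from raw proportions.
oracle_tn93 <- function(P1, P2, Q, g, shape = NULL) {
  gA <- g[1]; gC <- g[2]; gG <- g[3]; gT <- g[4]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (min(w1, w2, w3) <= 0) return(NA_real_)
  if (is.null(shape))
    -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  else
    shape * (k1 * (w1^(-1 / shape) - 1) + k2 * (w2^(-1 / shape) - 1) +
               k3 * (w3^(-1 / shape) - 1))
}

# Two-level AMOVA variance decomposition evaluated directly from the
# textbook definitions (no shared code with the package implementation).
oracle_amova <- function(m, pop) {
  pop <- factor(pop)
  N <- nrow(m); P <- nlevels(pop)
  d2 <- m^2
  ssTot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ssTot <- ssTot + d2[i, j]
  ssTot <- ssTot / N
  ssW <- 0
  for (lev in levels(pop)) {
    rows <- which(pop == lev); nk <- length(rows)
    if (nk > 1)
      for (a in seq_along(rows)[-length(rows)])
        for (b in (a + 1):nk)
          ssW <- ssW + d2[rows[a], rows[b]] / nk
  }
  ssA <- ssTot - ssW
  sizes <- table(pop)
  s2w <- ssW / (N - P)
  nprime <- (N - sum(sizes^2) / N) / (P - 1)
  s2a <- (ssA / (P - 1) - s2w) / nprime
  list(ssA = ssA, ssW = ssW, s2a = s2a, s2w = s2w,
       phi = s2a / (s2a + s2w))
}

# Exhaustive greedy Ward agglomeration: at each step merge the pair of
# clusters whose union minimally increases total within-cluster sum of
# squared deviations from cluster means.
oracle_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  wss <- function(rows) {
    if (length(rows) == 1L) return(0)
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; bestInc <- Inf
    for (a in seq_along(clusters)[-length(clusters)])
      for (b in (a + 1):length(clusters)) {
        inc <- wss(c(clusters[[a]], clusters[[b]])) -
          wss(clusters[[a]]) - wss(clusters[[b]])
        if (inc < bestInc - 1e-12) { bestInc <- inc; best <- c(a, b) }
      }
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))[1:2]
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Within-cluster SS increments of exhaustive greedy Ward agglomeration,
# in merge order (ward.D2 heights equal sqrt(2 * increment)).
oracle_ward_increments <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  wss <- function(rows) {
    if (length(rows) == 1L) return(0)
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }
  incs <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bestInc <- Inf
    for (a in seq_along(clusters)[-length(clusters)])
      for (b in (a + 1):length(clusters)) {
        inc <- wss(c(clusters[[a]], clusters[[b]])) -
          wss(clusters[[a]]) - wss(clusters[[b]])
        if (inc < bestInc - 1e-12) { bestInc <- inc; best <- c(a, b) }
      }
    incs <- c(incs, bestInc)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  incs
}

# Partition at k clusters from exhaustive greedy Ward agglomeration.
oracle_ward_cut <- function(X, k) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  wss <- function(rows) {
    if (length(rows) == 1L) return(0)
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }
  while (length(clusters) > k) {
    best <- NULL; bestInc <- Inf
    for (a in seq_along(clusters)[-length(clusters)])
      for (b in (a + 1):length(clusters)) {
        inc <- wss(c(clusters[[a]], clusters[[b]])) -
          wss(clusters[[a]]) - wss(clusters[[b]])
        if (inc < bestInc - 1e-12) { bestInc <- inc; best <- c(a, b) }
      }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  assign <- integer(nrow(X))
  for (c_i in seq_along(clusters)) assign[clusters[[c_i]]] <- c_i
  assign
}

# Firth penalized log-likelihood, for direct numerical maximization.
oracle_firth_pll <- function(beta, y, Xd) {
  eta <- drop(Xd %*% beta)
  mu <- plogis(eta)
  W <- mu * (1 - mu)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * determinant(crossprod(Xd * W, Xd), logarithm = TRUE)$modulus
}

# Marginal Poisson random-intercept log-likelihood by plain (64-node)
# Gauss-Hermite quadrature, independent of lme4.
oracle_glmm_loglik <- function(beta, sdRiver, y, Xd, river, nNodes = 64L) {
  gh <- pracma::gaussHermite(nNodes)
  total <- 0
  for (r in unique(river)) {
    rows <- which(river == r)
    etas <- drop(Xd[rows, , drop = FALSE] %*% beta)
    contrib <- vapply(seq_along(gh$x), function(q) {
      u <- sqrt(2) * sdRiver * gh$x[q]
      sum(dpois(y[rows], exp(etas + u), log = TRUE))
    }, numeric(1))
    mx <- max(contrib)
    total <- total + mx + log(sum(gh$w * exp(contrib - mx) / sqrt(pi)))
  }
  total
}
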