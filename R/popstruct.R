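## popstruct: two-level AMOVA with phi-statistics permutation test, and a
## statistical parsimony haplotype network.

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise molecular distances into among- and
#' within-population components (Excoffier-Smouse-Quattro decomposition).
#' Sums of squared distances: SSD(total) = sum over all unordered pairs of
#' d^2 / N, SSD(within) summed per population with its own size, SSD(among)
#' by difference. Variance components use the method of moments with the
#' standard unequal-size coefficient n' = (N - sum(n_k^2)/N) / (P - 1).
#' phi-ST = sigma2_among / (sigma2_among + sigma2_within). The permutation
#' test reassigns individuals to populations (sizes fixed) and reports
#' p = (1 + #{phi* >= phi_obs}) / (B + 1).
#'
#' A negative among-population component is clamped to zero and flagged.
#' If all distances are zero, both components are zero and phi-ST is
#' reported as \code{NA} (undefined).
#'
#' @param d a \code{DistanceMatrix} or plain symmetric matrix over
#'   individuals.
#' @param populations factor/character of population assignments, aligned
#'   with the matrix labels (or named by them).
#' @param nPermutations number of permutations (default 10000; 0 skips the
#'   test).
#' @param seed optional integer seed for the permutations.
#' @return an \code{\link{AmovaResult-class}}
#' @export
amovaTwoLevel <- function(d, populations, nPermutations = 10000L,
                          seed = NULL) {
  m <- if (is(d, "DistanceMatrix")) as.matrix(d) else as.matrix(d)
  n <- nrow(m)
  if (!is.null(names(populations)) && !is.null(rownames(m)))
    populations <- populations[rownames(m)]
  pop <- factor(as.character(populations))
  if (length(pop) != n) stop("populations must align with the matrix")
  if (nlevels(pop) < 2L) stop("need at least two populations")
  if (any(table(pop) < 1L)) stop("empty population")
  if (anyNA(m)) stop("AMOVA requires a complete (non-saturated) matrix")
  d2 <- m^2
  sizes <- as.vector(table(pop))
  P <- nlevels(pop); N <- n

  ssdWithinOf <- function(popIdx) {
    s <- 0
    for (k in seq_len(P)) {
      rows <- popIdx[[k]]
      nk <- length(rows)
      if (nk > 1L) s <- s + sum(d2[rows, rows]) / (2 * nk)
    }
    s
  }
  popIdx <- split(seq_len(N), pop)
  ssdTotal <- sum(d2) / (2 * N)
  ssdWithin <- ssdWithinOf(popIdx)
  ssdAmong <- ssdTotal - ssdWithin
  dfAmong <- P - 1
  dfWithin <- N - P
  sigmaWithin <- ssdWithin / dfWithin
  nPrime <- (N - sum(sizes^2) / N) / dfAmong
  sigmaAmong <- (ssdAmong / dfAmong - sigmaWithin) / nPrime
  clamped <- FALSE
  if (sigmaAmong < 0) { sigmaAmong <- 0; clamped <- TRUE }
  tot <- sigmaAmong + sigmaWithin
  phi <- if (tot > 0) sigmaAmong / tot else NA_real_
  percent <- if (tot > 0) 100 * c(sigmaAmong, sigmaWithin) / tot
             else c(NA_real_, NA_real_)

  pval <- NA_real_
  B <- as.integer(nPermutations)
  if (B > 0L && !is.na(phi)) {
    if (!is.null(seed)) set.seed(seed)
    phiPerm <- function(w) {
      sa <- ((ssdTotal - w) / dfAmong - w / dfWithin) / nPrime
      sa <- max(sa, 0)
      t2 <- sa + w / dfWithin
      if (t2 > 0) sa / t2 else NA_real_
    }
    count <- 0L
    for (b in seq_len(B)) {
      perm <- sample.int(N)
      idx <- split(perm, rep.int(seq_len(P), sizes))
      phiB <- phiPerm(ssdWithinOf(idx))
      if (!is.na(phiB) && phiB >= phi - 1e-12) count <- count + 1L
    }
    pval <- (count + 1L) / (B + 1L)
  }
  new("AmovaResult",
      ssd = c(among = ssdAmong, within = ssdWithin, total = ssdTotal),
      df = c(among = dfAmong, within = dfWithin),
      sigma2 = c(among = sigmaAmong, within = sigmaWithin),
      percent = c(among = percent[1L], within = percent[2L]),
      phiST = phi, pValue = pval, nPermutations = B, clamped = clamped)
}

#' Statistical parsimony connection limit
#'
#' Largest number of mutational steps j such that a j-step connection
#' between two haplotypes is credibly free of hidden multiple hits at the
#' given confidence. Following the statistical-parsimony logic, the
#' per-site substitution intensity lambda is estimated from the observed
#' difference fraction p = j/m by Jukes-Cantor inversion
#' (lambda = -3/4 log(1 - 4p/3)); with Poisson hit counts per site the
#' probability that every differing site was hit exactly once and every
#' identical site not at all is
#' \deqn{P_j = \left[\frac{\lambda e^{-\lambda}}{\frac34(1-e^{-4\lambda/3})}\right]^j
#'   \left[\frac{e^{-\lambda}}{\frac14+\frac34 e^{-4\lambda/3}}\right]^{m-j}.}
#' The limit is the largest j with \eqn{P_j \ge} \code{confidence}. It is
#' non-decreasing in sequence length and in (1 - confidence).
#'
#' @param seqLength alignment length m (comparable sites).
#' @param confidence parsimony confidence, default 0.95.
#' @return integer connection limit (steps)
#' @export
parsimonyConnectionLimit <- function(seqLength, confidence = 0.95) {
  stopifnot(seqLength >= 1, confidence > 0, confidence < 1)
  j <- 0L
  while (j < seqLength) {
    pj <- parsimonyProbability(j + 1L, seqLength)
    if (pj < confidence) break
    j <- j + 1L
  }
  j
}

#' Probability that a j-step connection is fully parsimonious
#'
#' @param steps observed number of differing sites j.
#' @param seqLength alignment length m.
#' @return probability in [0, 1]
#' @export
parsimonyProbability <- function(steps, seqLength) {
  j <- steps; m <- seqLength
  if (j == 0L) return(1)
  p <- j / m
  if (p >= 0.75) return(0)
  lambda <- -0.75 * log(1 - 4 * p / 3)
  prDiffOne <- lambda * exp(-lambda) / (0.75 * (1 - exp(-4 * lambda / 3)))
  prSameZero <- exp(-lambda) / (0.25 + 0.75 * exp(-4 * lambda / 3))
  prDiffOne^j * prSameZero^(m - j)
}

#' Build a statistical parsimony haplotype network
#'
#' Haplotype pairs are joined in rounds of increasing mutational step count
#' s = 1, 2, ...: at the start of each round the connected components of
#' the graph built so far are frozen, and each pair of frozen components
#' with a link at exactly s steps is joined by one such link (pairs
#' processed in lexicographic haplotype-id order, so ties break
#' deterministically). Links between haplotypes already connected by at
#' most s steps are redundant and omitted; reticulations therefore arise
#' only when three or more components close a cycle of equally
#' parsimonious links within one round. Rounds stop at the connection
#' limit, so the output may be disconnected. A multi-step link implies
#' steps - 1 inferred intermediate (unsampled) haplotypes, recorded on
#' the edge.
#'
#' @param haps a \code{HaplotypeSet}, or an integer step matrix (site
#'   mismatches after complete deletion) with dimnames.
#' @param limit connection limit in steps; by default computed from the
#'   haplotype alignment length at \code{confidence}.
#' @param confidence parsimony confidence used when \code{limit} is NULL.
#' @return a \code{\link{HaploNetwork-class}}
#' @export
buildParsimonyNetwork <- function(haps, limit = NULL, confidence = 0.95) {
  if (is(haps, "HaplotypeSet")) {
    steps <- mismatchMatrix(haps)
    if (is.null(limit)) {
      L <- ncol(.completeDeletion(.seqIntMatrix(haps)))
      limit <- parsimonyConnectionLimit(L, confidence)
    }
  } else {
    steps <- as.matrix(haps)
    if (is.null(limit))
      stop("supply a connection limit when passing a raw step matrix")
  }
  if (is.null(rownames(steps)))
    dimnames(steps) <- list(paste0("H", seq_len(nrow(steps))),
                            paste0("H", seq_len(nrow(steps))))
  limit <- as.integer(limit)
  ids <- rownames(steps)
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (n > 1L) {
    pairs <- which(upper.tri(steps), arr.ind = TRUE)
    ord <- order(steps[pairs], ids[pairs[, 1L]], ids[pairs[, 2L]])
    pairs <- pairs[ord, , drop = FALSE]
    svals <- steps[pairs]
    for (s in unique(svals[svals >= 1L & svals <= limit])) {
      comp <- igraph::components(g)$membership  # frozen for this round
      inRound <- pairs[svals == s, , drop = FALSE]
      usedPairs <- character(0)
      for (r in seq_len(nrow(inRound))) {
        i <- inRound[r, 1L]; jj <- inRound[r, 2L]
        if (comp[i] == comp[jj]) next  # redundant: already joined by
                                       # fewer or equal steps
        key <- paste(sort(c(comp[i], comp[jj])), collapse = "-")
        if (key %in% usedPairs) next   # one link per component pair and
                                       # round; ties broken lexicographically
        usedPairs <- c(usedPairs, key)
        g <- igraph::add_edges(g, c(i, jj),
                               attr = list(steps = s,
                                           intermediates = s - 1L))
      }
    }
  }
  if (is(haps, "HaplotypeSet")) {
    igraph::V(g)$frequency <- rowSums(haplotypeFrequencies(haps))[ids]
    igraph::V(g)$species <- haps@species[ids]
  }
  new("HaploNetwork", graph = g, steps = steps, connectionLimit = limit)
}

#' Export a haplotype network
#'
#' Writes GraphML plus an edge-list CSV (from, to, steps, intermediates).
#'
#' @param net a \code{HaploNetwork}.
#' @param graphmlPath,edgeCsvPath output paths (either may be NULL).
#' @return invisibly, the edge-list data.frame
#' @export
writeNetwork <- function(net, graphmlPath = NULL, edgeCsvPath = NULL) {
  g <- net@graph
  el <- igraph::as_data_frame(g, what = "edges")
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeCsvPath)) write.csv(el, edgeCsvPath, row.names = FALSE)
  invisible(el)
}
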