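test_that("AMOVA components match direct evaluation on a hand-built design", {
  ## 2 populations x 3 individuals, arbitrary symmetric distances
  set.seed(3)
  labs <- paste0("i", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(labs, labs))
  m[upper.tri(m)] <- runif(15, 0.001, 0.02)
  m <- m + t(m)
  pop <- rep(c("A", "B"), each = 3)
  res <- amovaTwoLevel(m, pop, nPermutations = 0L)
  ora <- oracle_amova(m, pop)
  expect_equal(unname(res@ssd["among"]), ora$ssA, tolerance = 1e-12)
  expect_equal(unname(res@ssd["within"]), ora$ssW, tolerance = 1e-12)
  expect_equal(unname(res@sigma2["within"]), ora$s2w, tolerance = 1e-12)
  if (ora$s2a >= 0) {
    expect_equal(unname(res@sigma2["among"]), ora$s2a, tolerance = 1e-12)
    expect_equal(res@phiST, ora$phi, tolerance = 1e-12)
  }
  expect_equal(sum(res@percent), 100, tolerance = 1e-9)
})

test_that("AMOVA permutation p equals exhaustive enumeration on 2x3 toys", {
  set.seed(9)
  labs <- paste0("i", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(labs, labs))
  m[upper.tri(m)] <- c(1, 5, 6, 5, 6, 2, 6, 5, 6, 5, 1, 2, 6, 6, 1) / 100
  m <- m + t(m)
  pop <- rep(c("A", "B"), each = 3)
  obs <- amovaTwoLevel(m, pop, nPermutations = 0L)@phiST
  ## exhaustive: all C(6,3) = 20 assignments of individuals to populations
  combos <- combn(6, 3)
  phis <- apply(combos, 2, function(ga) {
    assign <- ifelse(seq_len(6) %in% ga, "A", "B")
    amovaTwoLevel(m, assign, nPermutations = 0L)@phiST
  })
  pEnum <- mean(phis >= obs - 1e-12)
  ## Monte-Carlo permutation p converges to the enumeration value
  pPerm <- amovaTwoLevel(m, pop, nPermutations = 4000L, seed = 1L)@pValue
  expect_lt(abs(pPerm - pEnum), 3 * sqrt(pEnum * (1 - pEnum) / 4000) + 5e-4)
})

test_that("fixed private haplotypes give 100% among-population variation", {
  labs <- paste0("i", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(labs, labs))
  m[1:3, 4:6] <- 0.01
  m[4:6, 1:3] <- 0.01
  res <- amovaTwoLevel(m, rep(c("A", "B"), each = 3), nPermutations = 0L)
  expect_equal(unname(res@percent["among"]), 100)
  expect_equal(res@phiST, 1)
})

test_that("identical sequences give zero components and undefined phi", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  res <- amovaTwoLevel(m, c("A", "A", "B", "B"), nPermutations = 100L)
  expect_equal(unname(res@sigma2), c(0, 0))
  expect_true(is.na(res@phiST))
})

test_that("phi-ST is invariant to uniform distance scaling", {
  set.seed(15)
  labs <- paste0("i", 1:8)
  m <- matrix(0, 8, 8, dimnames = list(labs, labs))
  m[upper.tri(m)] <- runif(28, 0.001, 0.01)
  m <- m + t(m)
  pop <- rep(c("A", "B"), each = 4)
  phi1 <- amovaTwoLevel(m, pop, nPermutations = 0L)@phiST
  phi2 <- amovaTwoLevel(7.3 * m, pop, nPermutations = 0L)@phiST
  expect_equal(phi1, phi2, tolerance = 1e-12)
})

test_that("permutation p is roughly uniform under exchangeable labels", {
  ## under no structure the +1/(B+1)-corrected p lives on {1/(B+1), ..., 1}
  set.seed(31)
  ps <- replicate(40, {
    labs <- paste0("i", 1:8)
    m <- matrix(0, 8, 8, dimnames = list(labs, labs))
    m[upper.tri(m)] <- runif(28, 0.001, 0.01)
    m <- m + t(m)
    amovaTwoLevel(m, sample(rep(c("A", "B"), each = 4)),
                  nPermutations = 99L)@pValue
  })
  expect_true(all(ps >= 1 / 100 & ps <= 1))
  ## mean of a uniform on (0,1] is ~0.5; allow generous Monte-Carlo slack
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("parsimony probability and connection limit behave monotonically", {
  expect_equal(parsimonyProbability(0, 1000), 1)
  ## monotone decreasing in steps
  pj <- vapply(1:30, parsimonyProbability, numeric(1), seqLength = 1000L)
  expect_true(all(diff(pj) < 0))
  ## limit non-decreasing in sequence length at fixed confidence
  lims <- vapply(c(200L, 500L, 1000L, 2086L, 5000L),
                 parsimonyConnectionLimit, integer(1), confidence = 0.95)
  expect_true(all(diff(lims) >= 0))
  ## limit grows as confidence is relaxed
  l95 <- parsimonyConnectionLimit(2086L, 0.95)
  l50 <- parsimonyConnectionLimit(2086L, 0.50)
  l999 <- parsimonyConnectionLimit(2086L, 0.999)
  expect_true(l999 <= l95 && l95 <= l50)
  ## the limit reproduces a literal scalar evaluation of the probability
  expect_gte(parsimonyProbability(l95, 2086L), 0.95)
  expect_lt(parsimonyProbability(l95 + 1L, 2086L), 0.95)
})

test_that("network construction follows the round-based parsimony rule", {
  ## chain: the 2-step link is redundant, not an alternative
  steps <- matrix(c(0, 1, 2,
                    1, 0, 1,
                    2, 1, 0), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net <- buildParsimonyNetwork(steps, limit = 5L)
  g <- net@graph
  expect_equal(igraph::ecount(g), 2L)
  expect_false(igraph::are_adjacent(g, "A", "C"))
  ## two clusters beyond the limit stay disconnected
  steps2 <- matrix(c(0, 1, 9, 9,
                     1, 0, 9, 9,
                     9, 9, 0, 1,
                     9, 9, 1, 0), 4, 4,
                   dimnames = list(letters[1:4], letters[1:4]))
  net2 <- buildParsimonyNetwork(steps2, limit = 5L)
  expect_equal(igraph::components(net2@graph)$no, 2L)
  ## equally parsimonious links in one round are both retained
  steps3 <- matrix(c(0, 1, 2, 2,
                     1, 0, 2, 2,
                     2, 2, 0, 1,
                     2, 2, 1, 0), 4, 4,
                   dimnames = list(letters[1:4], letters[1:4]))
  net3 <- buildParsimonyNetwork(steps3, limit = 5L)
  ## a-b, c-d, and exactly one of the tied 2-step cross links (the
  ## lexicographically first, a-c)
  expect_equal(igraph::ecount(net3@graph), 3L)
  expect_true(igraph::are_adjacent(net3@graph, "a", "c"))
  ## a multi-step link records its inferred intermediates
  e <- igraph::as_data_frame(net3@graph)
  expect_equal(sort(unique(e$intermediates)), c(0, 1))
})

test_that("network agrees with brute-force minimum spanning structure", {
  set.seed(19)
  for (rep in 1:6) {
    base <- rand_seq(40)
    haps <- vapply(1:6, function(i)
      mutate_seq(base, sample(40, sample(1:3, 1)),
                 sample(c("A", "C", "G", "T"), 1)), character(1))
    names(haps) <- paste0("H", 1:6)
    haps <- haps[!duplicated(haps)]
    if (length(haps) < 3) next
    steps <- mismatchMatrix(haps)
    net <- buildParsimonyNetwork(steps, limit = max(steps))
    g <- net@graph
    ## single-step adjacency: at one step nothing can be closer-connected,
    ## so the MSN contains exactly the 1-step pairs
    got1 <- igraph::as_adjacency_matrix(
      igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$steps == 1],
                                  delete.vertices = FALSE),
      sparse = FALSE) > 0
    expect_equal(got1, steps == 1L)
    ## the network spans with minimum total weight: its minimum spanning
    ## tree weighs the same as the MST of the complete step graph
    full <- igraph::graph_from_adjacency_matrix(steps, mode = "undirected",
                                                weighted = TRUE,
                                                diag = FALSE)
    mstFull <- sum(igraph::E(igraph::mst(full))$weight)
    mstNet <- sum(igraph::E(igraph::mst(g,
                                        weights = igraph::E(g)$steps))$steps)
    expect_true(igraph::is_connected(g))
    expect_equal(mstNet, mstFull)
  }
})

test_that("landlocked populations sit on the network periphery", {
  ## each landlocked population's haplotypes should attach to the rest of
  ## the network through a single articulation, in most replicates
  hits <- 0L; total <- 0L
  for (k in 1:12) {
    cfg <- simulationConfig(seed = 5000L + k, n_source = 30L,
                            n_source_sites = 3L)
    st <- simulateSequences(cfg)
    haps <- collapseHaplotypes(st)
    net <- buildParsimonyNetwork(haps)
    g <- net@graph
    pops <- populations(st)
    mem <- haplotypeMembership(haps)
    for (p in unique(pops[speciesLabels(st) == "YB"])) {
      popHaps <- unique(mem[names(pops)[pops == p]])
      others <- setdiff(igraph::V(g)$name, popHaps)
      ## only consider populations with private haplotypes
      shared <- intersect(popHaps, unique(mem[names(pops)[pops != p]]))
      if (length(shared) || !length(others)) next
      total <- total + 1L
      sub <- igraph::induced_subgraph(g, popHaps)
      crossing <- sum(igraph::ends(g, igraph::E(g))[, 1] %in% popHaps !=
                        igraph::ends(g, igraph::E(g))[, 2] %in% popHaps)
      if (igraph::is_connected(sub) && crossing == 1L) hits <- hits + 1L
    }
  }
  expect_gt(total, 20L)
  expect_gte(hits / total, 0.8)
})
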