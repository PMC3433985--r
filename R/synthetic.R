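## synthetic_data: generate complete datasets with the statistical
## structure the analysis assumes -- star-like divergence of landlocked
## populations from a panmictic source pool at times proportional to
## waterfall height, finite-sites TN93 mutation with per-site gamma rate
## multipliers, morphology drift proportional to divergence, and
## waterfall-dependent site occupancy -- so every downstream stage is
## testable by parameter recovery, with no field data.

.DEFAULT_HEIGHTS <- c(Nakara = 27.9, Mariudo = 19.4, Pinai = 58.7,
                      Nishida = 7.2, Kura = 7.6, Geta = 32.7,
                      YuchinRight = 44.2, YuchinLeft = 42.5)

.ENV_FACTORS <- c("watershed_area_km2", "elevation_m", "distance_from_sea_km",
                  "river_width_m", "water_depth_cm", "water_velocity_cm_s",
                  "pebble_size_cm", "slope_angle_deg", "canopy_cover_pct")

#' Build a simulation configuration
#'
#' Defaults encode the study conditions: the eight dated waterfall heights;
#' a true erosion rate of 0.00067 m/yr; a pairwise divergence rate of
#' 3.8e-8 substitutions/site/year (3.8 percent per million years); a
#' 2086-site alignment split 945 + 1141 between two mtDNA regions; source
#' pool mean pairwise diversity 0.00184; gamma shape 0.14 for among-site
#' rate variation. Occupancy coefficients are on the standardized-predictor
#' scale and include the waterfall dummy.
#'
#' @param heights_m named positive heights (m) of the dated waterfalls.
#' @param erosion_rate_true true erosion rate E (m/yr).
#' @param subst_rate pairwise divergence rate R (substitutions/site/yr).
#' @param seq_length alignment length (sites).
#' @param source_pool_diversity expected mean pairwise distance within the
#'   panmictic source pool.
#' @param within_pop_diversity expected mean pairwise distance within each
#'   landlocked population (the study reports none; free parameter).
#' @param n_per_population individuals sampled per landlocked population.
#' @param n_source individuals sampled from the source pool.
#' @param n_source_sites number of sites the source sample is spread over
#'   (panmictic, so assignment is arbitrary).
#' @param base_frequencies A,C,G,T equilibrium frequencies (sum to 1).
#' @param kappa1,kappa2 purine / pyrimidine transition:transversion
#'   factors.
#' @param gamma_shape gamma shape for site-rate multipliers.
#' @param morph_slope morphological Euclidean-distance units per genetic
#'   distance unit.
#' @param morph_base baseline propensity shift shared by all landlocked
#'   populations (the parallel-evolution similarity of the phenotype).
#' @param morph_noise_sd SD of per-individual character-propensity noise.
#' @param occupancy_coefs named logistic coefficients for focal-species
#'   presence: "(Intercept)", "waterfall", then any of the nine
#'   environmental factors (standardized scale).
#' @param source_occupancy_coefs same, for the amphidromous source
#'   species.
#' @param richness_coefs named Poisson log-link coefficients for species
#'   richness.
#' @param richness_random_sd between-river SD of the richness random
#'   intercept.
#' @param n_sites,n_rivers survey size.
#' @param seed master seed; component sub-streams are derived
#'   deterministically from it.
#' @return a validated \code{\link{SimulationConfig-class}}
#' @export
simulationConfig <- function(heights_m = .DEFAULT_HEIGHTS,
                             erosion_rate_true = 0.00067,
                             subst_rate = 3.8e-8,
                             seq_length = 2086L,
                             source_pool_diversity = 0.00184,
                             within_pop_diversity = 3e-4,
                             n_per_population = 10L,
                             n_source = 80L,
                             n_source_sites = 8L,
                             base_frequencies = c(A = 0.26, C = 0.31,
                                                  G = 0.14, T = 0.29),
                             kappa1 = 8, kappa2 = 8,
                             gamma_shape = 0.14,
                             morph_slope = 120,
                             morph_base = 0.55,
                             morph_noise_sd = 0.08,
                             occupancy_coefs = c("(Intercept)" = -1.5,
                                                 waterfall = 3.5,
                                                 distance_from_sea_km = -0.8),
                             source_occupancy_coefs = c("(Intercept)" = 1.5,
                                                        waterfall = -2.3),
                             richness_coefs = c("(Intercept)" = 2.1,
                                                waterfall = -1.3),
                             richness_random_sd = 0.3,
                             n_sites = 30L, n_rivers = 11L,
                             seed = 1L) {
  if (is.null(names(heights_m)))
    names(heights_m) <- paste0("WF", seq_along(heights_m))
  new("SimulationConfig",
      heights_m = heights_m,
      erosion_rate_true = erosion_rate_true,
      subst_rate = subst_rate,
      seq_length = as.integer(seq_length),
      source_pool_diversity = source_pool_diversity,
      within_pop_diversity = within_pop_diversity,
      n_per_population = as.integer(n_per_population),
      n_source = as.integer(n_source),
      n_source_sites = as.integer(n_source_sites),
      base_frequencies = base_frequencies,
      kappa1 = kappa1, kappa2 = kappa2,
      gamma_shape = gamma_shape,
      morph_slope = morph_slope, morph_base = morph_base,
      morph_noise_sd = morph_noise_sd,
      occupancy_coefs = occupancy_coefs,
      source_occupancy_coefs = source_occupancy_coefs,
      richness_coefs = richness_coefs,
      richness_random_sd = richness_random_sd,
      n_sites = as.integer(n_sites), n_rivers = as.integer(n_rivers),
      seed = as.integer(seed))
}

#' Ground-truth divergence times and expected clade distances
#'
#' Divergence times are exactly heights / erosion_rate_true. The expected
#' distance between landlocked population i and the source pool is
#' intercept + subst_rate * t_i, where the intercept is the standing
#' diversity contribution: each of the two lineages carries half the pool's
#' mean pairwise diversity, plus half the within-population diversity on
#' the landlocked side.
#'
#' @param config a \code{SimulationConfig}.
#' @return list: times (yr), intercept, expected_distances
#' @export
simulationTruth <- function(config) {
  times <- config@heights_m / config@erosion_rate_true
  intercept <- config@source_pool_diversity +
    config@within_pop_diversity / 2
  list(times = times,
       intercept = intercept,
       expected_distances = intercept + config@subst_rate * times)
}

## --- TN93 mutation machinery -------------------------------------------

## Normalized TN93 rate matrix (rows = from, cols = to) and the
## uniformization constant mu = max total leave-rate.
.tn93RateMatrix <- function(freqs, kappa1, kappa2) {
  A <- 1; C <- 2; G <- 3; T <- 4
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    rate <- freqs[j]
    if ((i == A && j == G) || (i == G && j == A)) rate <- rate * kappa1
    if ((i == C && j == T) || (i == T && j == C)) rate <- rate * kappa2
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))  # expected substitutions per unit time
  Q <- Q / scale
  mu <- max(-diag(Q))
  P <- Q / mu
  diag(P) <- 1 + diag(Q) / mu  # uniformized jump matrix (self-jumps kept)
  list(Q = Q, P = P, mu = mu)
}

## Evolve an integer sequence along a branch of expected length `depth`
## substitutions/site, with per-site rate multipliers `rates` (mean 1).
## Exact CTMC simulation by uniformization.
.evolve <- function(seqInt, depth, rates, P, mu) {
  if (depth <= 0) return(seqInt)
  nHits <- rpois(length(seqInt), depth * rates * mu)
  hit <- which(nHits > 0L)
  for (s in hit) {
    st <- seqInt[s]
    for (k in seq_len(nHits[s])) st <- sample.int(4L, 1L, prob = P[st, ])
    seqInt[s] <- st
  }
  seqInt
}

#' Simulate aligned mtDNA sequences for the synthetic system
#'
#' Source-pool individuals hang from a star genealogy with exponential
#' branch depths (mean = half the target pool diversity), so the realized
#' mean pairwise distance approximates \code{source_pool_diversity}. Each
#' landlocked population is founded by one fresh pool lineage at time
#' t_i = h_i / E_true and accrues substitutions so that the expected
#' source-to-population distance is intercept + subst_rate * t_i; its
#' members add a small within-population star on top. Mutation is
#' finite-sites TN93 with gamma site-rate multipliers drawn once per site,
#' simulated exactly by uniformization. The alignment is split into two
#' recorded regions in the 945:1141 ratio.
#'
#' @param config a \code{SimulationConfig}.
#' @return a \code{SequenceTable}; attribute \code{"truth"} carries the
#'   divergence times and expected distances
#' @export
simulateSequences <- function(config) {
  validObject(config)
  set.seed(.subSeed(config@seed, 1L))
  L <- config@seq_length
  tn <- .tn93RateMatrix(config@base_frequencies, config@kappa1,
                        config@kappa2)
  rates <- rgamma(L, shape = config@gamma_shape, rate = config@gamma_shape)
  root <- sample.int(4L, L, replace = TRUE, prob = config@base_frequencies)
  truth <- simulationTruth(config)
  branch <- config@subst_rate * truth$times
  if (any(!is.finite(branch)))
    stop("non-finite expected substitution count")
  if (any(branch > 0 & branch * L < 0.5))
    warning("alignment too short to carry the expected substitutions on ",
            "some branches; realized divergence will be noisy")
  poolDepth <- config@source_pool_diversity / 2
  popDepth <- config@within_pop_diversity / 2

  ids <- character(0); seqs <- list()
  pop <- character(0); spp <- character(0)
  ## source pool sample, spread over arbitrary source sites
  siteOf <- rep_len(paste0("BR", seq_len(config@n_source_sites)),
                    config@n_source)
  for (i in seq_len(config@n_source)) {
    d <- if (poolDepth > 0) rexp(1L, rate = 1 / poolDepth) else 0
    seqs[[length(seqs) + 1L]] <- .evolve(root, d, rates, tn$P, tn$mu)
    ids <- c(ids, sprintf("BR_%03d", i))
    pop <- c(pop, siteOf[i]); spp <- c(spp, "BR")
  }
  ## landlocked populations: founder lineage + divergence branch + star
  for (w in seq_along(config@heights_m)) {
    nm <- names(config@heights_m)[w]
    fd <- if (poolDepth > 0) rexp(1L, rate = 1 / poolDepth) else 0
    founder <- .evolve(root, fd, rates, tn$P, tn$mu)
    ancestor <- .evolve(founder, branch[w], rates, tn$P, tn$mu)
    for (i in seq_len(config@n_per_population)) {
      d <- if (popDepth > 0) rexp(1L, rate = 1 / popDepth) else 0
      seqs[[length(seqs) + 1L]] <- .evolve(ancestor, d, rates, tn$P, tn$mu)
      ids <- c(ids, sprintf("YB_%s_%02d", nm, i))
      pop <- c(pop, paste0("YB_", nm)); spp <- c(spp, "YB")
    }
  }
  sm <- do.call(rbind, seqs)
  rownames(sm) <- ids
  dna <- .intMatrixToDNAStringSet(sm)
  w1 <- round(L * 945 / 2086)
  meta <- data.frame(individual_id = ids, population = pop, species = spp,
                     sex = rep_len(c("male", "female"), length(ids)))
  st <- sequenceTable(setNames(as.character(dna), ids), meta,
                      regionName = "ND5+cytb",
                      regions = c(ND5 = w1, cytb = L - w1))
  attr(st, "truth") <- truth
  st
}

#' Simulate morphological character scores
#'
#' Source-species individuals are centred on the all-absent character
#' profile. Landlocked individuals share a common baseline shift toward
#' the all-present profile (\code{morph_base}; the parallel-evolution
#' similarity of the landlocked phenotype), plus a finer per-character
#' shift proportional to divergence: propensity_i = min(1, morph_base +
#' morph_slope * D_i / 3), where D_i is the expected genetic distance of
#' population i from the source, so the expected Euclidean distance over
#' the nine characters grows by approximately morph_slope per unit of
#' genetic distance. With \code{morph_noise_sd = 0} scores are the
#' propensity rounded to the nearest half -- fully deterministic, and
#' equal to the all-present profile once the cap is reached (t to
#' infinity). With positive noise, each character score is the mean of two
#' Bernoulli draws at the individual's jittered propensity, giving scores
#' in \{0, 0.5, 1\} with expectation equal to the propensity. Both sexes
#' are generated by the same process.
#'
#' @param config a \code{SimulationConfig}.
#' @param truth output of \code{\link{simulationTruth}} (recomputed if
#'   NULL).
#' @return morphology data.frame (individual_id, population, species, sex,
#'   a..i)
#' @export
simulateMorphology <- function(config, truth = NULL) {
  validObject(config)
  if (is.null(truth)) truth <- simulationTruth(config)
  set.seed(.subSeed(config@seed, 2L))
  nChar <- length(.MORPH_CHARS)
  drawScores <- function(propensity, n) {
    if (config@morph_noise_sd == 0)
      return(matrix(round(2 * rep(propensity, each = n)) / 2, nrow = n))
    p <- matrix(pmin(1, pmax(0, rep(propensity, each = n) +
                                  rnorm(n * nChar, 0,
                                        config@morph_noise_sd))),
                nrow = n)
    (matrix(rbinom(n * nChar, 1L, p), nrow = n) +
       matrix(rbinom(n * nChar, 1L, p), nrow = n)) / 2
  }
  rows <- list()
  addGroup <- function(popName, species, delta, n) {
    sc <- drawScores(rep(delta, nChar), n)
    colnames(sc) <- .MORPH_CHARS
    data.frame(individual_id = sprintf("%s_m%02d", popName, seq_len(n)),
               population = popName, species = species,
               sex = rep_len(c("male", "female"), n), sc)
  }
  siteOf <- rep_len(paste0("BR", seq_len(config@n_source_sites)),
                    config@n_source)
  for (s in unique(siteOf))
    rows[[length(rows) + 1L]] <- addGroup(s, "BR", 0, sum(siteOf == s))
  for (w in seq_along(config@heights_m)) {
    nm <- names(config@heights_m)[w]
    delta <- min(1, config@morph_base +
                   config@morph_slope * truth$expected_distances[w] / 3)
    rows[[length(rows) + 1L]] <-
      addGroup(paste0("YB_", nm), "YB", delta, config@n_per_population)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the site survey: environments, occupancy and richness
#'
#' Generates a per-site table of the waterfall dummy plus nine continuous
#' environmental factors (independent of waterfall status, mirroring the
#' null MANOVA result), draws focal- and source-species presence from
#' logistic models with the configured coefficients (standardized
#' predictor scale), and species richness from a Poisson model with a
#' Gaussian river-level random intercept of SD \code{richness_random_sd}.
#'
#' @param config a \code{SimulationConfig}.
#' @param nSites number of sites (default \code{config@n_sites}).
#' @return sites data.frame: site_id, river, waterfall, nine factors,
#'   presence_focal, presence_source, richness
#' @export
simulateHabitat <- function(config, nSites = config@n_sites) {
  validObject(config)
  set.seed(.subSeed(config@seed, 3L))
  n <- as.integer(nSites)
  river <- rep_len(paste0("R", sprintf("%02d", seq_len(config@n_rivers))), n)
  env <- data.frame(
    watershed_area_km2 = rlnorm(n, log(5), 0.8),
    elevation_m = runif(n, 2, 250),
    distance_from_sea_km = rlnorm(n, log(2), 0.7),
    river_width_m = rlnorm(n, log(6), 0.5),
    water_depth_cm = rlnorm(n, log(30), 0.4),
    water_velocity_cm_s = rlnorm(n, log(20), 0.5),
    pebble_size_cm = rlnorm(n, log(8), 0.6),
    slope_angle_deg = runif(n, 0.5, 15),
    canopy_cover_pct = runif(n, 10, 95))
  waterfall <- rbinom(n, 1L, 0.4)
  Xs <- cbind(waterfall = waterfall,
              as.matrix(as.data.frame(lapply(env, scale))))
  linpred <- function(coefs) {
    eta <- rep(coefs[["(Intercept)"]], n)
    for (nm in setdiff(names(coefs), "(Intercept)"))
      eta <- eta + coefs[[nm]] * Xs[, nm]
    eta
  }
  presFocal <- rbinom(n, 1L, plogis(linpred(config@occupancy_coefs)))
  presSource <- rbinom(n, 1L, plogis(linpred(config@source_occupancy_coefs)))
  riverEff <- setNames(rnorm(length(unique(river)), 0,
                             config@richness_random_sd), unique(river))
  richness <- rpois(n, exp(linpred(config@richness_coefs) +
                             riverEff[river]))
  data.frame(site_id = sprintf("S%02d", seq_len(n)), river = river,
             waterfall = waterfall, env,
             presence_focal = presFocal, presence_source = presSource,
             richness = richness)
}

#' Simulate the complete synthetic system
#'
#' Runs the sequence, morphology and habitat generators off deterministic
#' sub-streams of the master seed and bundles them with the ground truth.
#' Identical seeds give bit-identical systems.
#'
#' @param config a \code{SimulationConfig}.
#' @return a \code{\link{SyntheticSystem-class}}
#' @export
simulateSystem <- function(config = simulationConfig()) {
  validObject(config)
  truth <- simulationTruth(config)
  seqs <- simulateSequences(config)
  morph <- simulateMorphology(config, truth)
  sites <- simulateHabitat(config)
  truth$occupancy_coefs <- config@occupancy_coefs
  truth$source_occupancy_coefs <- config@source_occupancy_coefs
  truth$richness_coefs <- config@richness_coefs
  truth$richness_random_sd <- config@richness_random_sd
  truth$erosion_rate_true <- config@erosion_rate_true
  truth$subst_rate <- config@subst_rate
  new("SyntheticSystem", config = config, truth = truth,
      sequences = seqs, morphology = morph, sites = sites)
}

#' Write a synthetic system to disk
#'
#' FASTA for the alignment, CSV for metadata, morphology and sites, JSON
#' for the ground-truth record.
#'
#' @param system a \code{SyntheticSystem}.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written
#' @export
writeSyntheticData <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- system@sequences
  files <- file.path(dir, c("alignment.fasta", "metadata.csv",
                            "morphology.csv", "sites.csv", "truth.json"))
  writeXStringSet(sequences(st), files[1L])
  write.csv(data.frame(individual_id = rownames(sampleInfo(st)),
                       as.data.frame(sampleInfo(st))),
            files[2L], row.names = FALSE)
  write.csv(system@morphology, files[3L], row.names = FALSE)
  write.csv(system@sites, files[4L], row.names = FALSE)
  tr <- system@truth
  tr$times <- as.list(tr$times)
  jsonlite::write_json(tr, files[5L], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
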