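## Central S4 containers. Accessors rather than slot access everywhere.

setClassUnion("igraphOrNULL", "ANY")

#' SequenceTable: aligned mtDNA sequences with sample metadata
#'
#' Holds an alignment as a \code{DNAStringSet} (one region or several
#' concatenated regions) together with per-individual metadata (population,
#' species label, sex). All sequences must have equal width and unique ids
#' shared with the metadata rows.
#'
#' @slot seqs \code{DNAStringSet}, named by individual id.
#' @slot meta \code{DataFrame} with rownames = individual ids and columns
#'   \code{population}, \code{species}, \code{sex}.
#' @slot regionName single character label for the region(s).
#' @slot regions named integer vector of region widths summing to the
#'   alignment length (e.g. \code{c(ND5 = 945, cytb = 1141)}).
#' @exportClass SequenceTable
setClass("SequenceTable",
  representation(
    seqs = "DNAStringSet",
    meta = "DataFrame",
    regionName = "character",
    regions = "integer"
  )
)

setValidity("SequenceTable", function(object) {
  msg <- character()
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must have the same aligned length")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be present and unique")
  if (!identical(ids, rownames(object@meta)))
    msg <- c(msg, "metadata rownames must match sequence ids in order")
  need <- c("population", "species", "sex")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("metadata must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(object@regions) && length(w) &&
      sum(object@regions) != w[1L])
    msg <- c(msg, "region widths must sum to the alignment length")
  if (length(msg)) msg else TRUE
})

#' HaplotypeSet: unique sequences with per-population frequencies
#'
#' @slot haplotypes \code{DNAStringSet} of distinct sequences, named
#'   \code{H01, H02, ...} in first-occurrence order.
#' @slot membership named character vector mapping individual id to
#'   haplotype id.
#' @slot freqs integer matrix, haplotypes x populations.
#' @slot species character matrix-compatible lookup: for each haplotype, the
#'   species labels (comma-collapsed) of its carriers.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(
    haplotypes = "DNAStringSet",
    membership = "character",
    freqs = "matrix",
    species = "character"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (anyDuplicated(as.character(object@haplotypes)))
    msg <- c(msg, "haplotype sequences must be pairwise distinct")
  if (!identical(rownames(object@freqs), names(object@haplotypes)))
    msg <- c(msg, "frequency rows must match haplotype ids")
  if (any(object@freqs < 0))
    msg <- c(msg, "frequencies must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise evolutionary distances with model metadata
#'
#' Symmetric, zero-diagonal matrix of substitutions/site. Pairs whose
#' log-correction is undefined (saturation) are stored as \code{NA} and
#' counted in \code{nSaturated}.
#'
#' @slot mat symmetric numeric matrix with dimnames.
#' @slot model one of \code{"p"}, \code{"TN93"}, \code{"TN93+G"}.
#' @slot gammaShape gamma shape used (\code{NA} unless model is TN93+G).
#' @slot nSaturated number of saturated (NA) unordered pairs.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(
    mat = "matrix",
    model = "character",
    gammaShape = "numeric",
    nSaturated = "integer"
  )
)

setValidity("DistanceMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "matrix must carry matching dimnames")
  if (any(diag(m) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
  if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "matrix must be symmetric")
  if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AmovaResult: two-level analysis of molecular variance
#'
#' @slot ssd named numeric: sums of squared distances (among, within, total).
#' @slot df named numeric degrees of freedom.
#' @slot sigma2 named numeric variance components (among, within).
#' @slot percent named numeric percentages of variation (sums to 100).
#' @slot phiST fixation index (NA when total variance is zero).
#' @slot pValue permutation p value (NA if no permutations run).
#' @slot nPermutations integer.
#' @slot clamped TRUE if a negative among-group component was clamped to 0.
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(
    ssd = "numeric", df = "numeric", sigma2 = "numeric",
    percent = "numeric", phiST = "numeric", pValue = "numeric",
    nPermutations = "integer", clamped = "logical"
  )
)

#' HaploNetwork: statistical parsimony haplotype network
#'
#' @slot graph igraph object over sampled haplotypes; edge attribute
#'   \code{steps} gives mutational steps, \code{intermediates} the number of
#'   inferred unsampled nodes on the link (steps - 1).
#' @slot steps integer matrix of pairwise mutational steps.
#' @slot connectionLimit parsimony connection limit used.
#' @exportClass HaploNetwork
setClass("HaploNetwork",
  representation(
    graph = "ANY",
    steps = "matrix",
    connectionLimit = "integer"
  )
)

#' ClockFit: the waterfall erosion clock
#'
#' Regression of genetic distance D on waterfall height h
#' (D = intercept + C h), the erosion rate E = R / C for an independent
#' substitution rate R, and the per-waterfall isolation ages h / E.
#'
#' @slot points data.frame (name, height_m, distance) actually fitted.
#' @slot excluded names dropped before fitting (downstream-drift sites).
#' @slot slope regression slope C, per metre.
#' @slot intercept dimensionless intercept.
#' @slot fStatistic F for the slope, with \code{dfNum}, \code{dfDen}.
#' @slot dfNum,dfDen numerator/denominator degrees of freedom.
#' @slot r2 coefficient of determination.
#' @slot pValue p for the slope F test.
#' @slot rate substitution (divergence) rate R per year.
#' @slot erosionRate E = R / C in metres/year.
#' @slot ages data.frame (name, height_m, age_yr) for dated waterfalls.
#' @exportClass ClockFit
setClass("ClockFit",
  representation(
    points = "data.frame", excluded = "character",
    slope = "numeric", intercept = "numeric",
    fStatistic = "numeric", dfNum = "numeric", dfDen = "numeric",
    r2 = "numeric", pValue = "numeric",
    rate = "numeric", erosionRate = "numeric",
    ages = "data.frame"
  )
)

setValidity("ClockFit", function(object) {
  msg <- character()
  if (length(object@erosionRate) && length(object@rate) &&
      length(object@slope) && is.finite(object@erosionRate) &&
      abs(object@erosionRate - object@rate / object@slope) >
        1e-12 * object@erosionRate)
    msg <- c(msg, "erosionRate must equal rate / slope")
  if (nrow(object@ages) && is.finite(object@erosionRate)) {
    expect <- object@ages$height_m / object@erosionRate
    if (any(abs(object@ages$age_yr - expect) > 1e-6 * pmax(1, expect)))
      msg <- c(msg, "ages must equal height / erosionRate")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: ground-truth parameters for the synthetic system
#'
#' Defaults encode the study conditions: the eight dated waterfall heights,
#' a true erosion rate of 0.00067 m/yr (0.67 mm/yr), a divergence rate of
#' 3.8\% per million years (3.8e-8 /yr), 2086 aligned sites, source-pool
#' mean pairwise diversity 0.00184, and gamma shape 0.14.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    heights_m = "numeric",
    erosion_rate_true = "numeric",
    subst_rate = "numeric",
    seq_length = "integer",
    source_pool_diversity = "numeric",
    within_pop_diversity = "numeric",
    n_per_population = "integer",
    n_source = "integer",
    n_source_sites = "integer",
    base_frequencies = "numeric",
    kappa1 = "numeric",
    kappa2 = "numeric",
    gamma_shape = "numeric",
    morph_slope = "numeric",
    morph_base = "numeric",
    morph_noise_sd = "numeric",
    occupancy_coefs = "numeric",
    source_occupancy_coefs = "numeric",
    richness_coefs = "numeric",
    richness_random_sd = "numeric",
    n_sites = "integer",
    n_rivers = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@heights_m <= 0)) msg <- c(msg, "heights_m must be positive")
  pos <- c(erosion_rate_true = object@erosion_rate_true,
           seq_length = object@seq_length,
           gamma_shape = object@gamma_shape)
  if (any(pos <= 0) || any(!is.finite(pos)))
    msg <- c(msg, "erosion rate, length and gamma_shape must be positive")
  if (!is.finite(object@subst_rate) || object@subst_rate < 0)
    msg <- c(msg, "subst_rate must be non-negative")
  if (object@source_pool_diversity < 0 || object@within_pop_diversity < 0)
    msg <- c(msg, "diversities must be non-negative")
  if (length(object@base_frequencies) != 4L ||
      abs(sum(object@base_frequencies) - 1) > 1e-12 ||
      any(object@base_frequencies <= 0))
    msg <- c(msg, "base_frequencies must be 4 positive values summing to 1")
  if (object@kappa1 <= 0 || object@kappa2 <= 0)
    msg <- c(msg, "kappa factors must be positive")
  if (object@morph_noise_sd < 0 || object@richness_random_sd < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  if (object@n_per_population < 1L || object@n_source < 2L)
    msg <- c(msg, "sample sizes too small")
  if (length(msg)) msg else TRUE
})

#' SyntheticSystem: generated datasets paired with their ground truth
#'
#' @slot config the \code{SimulationConfig} used.
#' @slot truth list: \code{times} (years per waterfall, exactly
#'   heights / erosion_rate_true), \code{expected_distances},
#'   \code{intercept}, plus the occupancy/richness coefficients.
#' @slot sequences \code{SequenceTable} (concatenated regions).
#' @slot morphology data.frame of 9-character scores.
#' @slot sites data.frame of site environments, occupancy and richness.
#' @exportClass SyntheticSystem
setClass("SyntheticSystem",
  representation(
    config = "SimulationConfig",
    truth = "list",
    sequences = "SequenceTable",
    morphology = "data.frame",
    sites = "data.frame"
  )
)

setValidity("SyntheticSystem", function(object) {
  tr <- object@truth
  cfg <- object@config
  if (!is.null(tr$times) &&
      !isTRUE(all.equal(unname(tr$times),
                        unname(cfg@heights_m / cfg@erosion_rate_true),
                        tolerance = 0)))
    return("truth times must equal heights_m / erosion_rate_true exactly")
  TRUE
})
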