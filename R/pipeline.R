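## pipeline: orchestrate the stages end-to-end with one config and a
## single reproducible report. Stage outputs are pure functions of inputs
## + seed; rerunning with the same config gives an identical report.

#' Build a pipeline configuration
#'
#' Either \code{simulate} carries a \code{\link{simulationConfig}} (the
#' default), or \code{input} names the files to analyse: \code{fasta} +
#' \code{metadata} (single concatenated alignment) or \code{fastaND5} +
#' \code{fastaCytb} + \code{metadata}, plus \code{morphology},
#' \code{sites} and \code{waterfalls} CSVs as available. Every analysis
#' constant is a named field with the study default: TN93+Gamma distances
#' with shape 0.14, 10000 AMOVA permutations, 0.95 parsimony confidence, a
#' 3.8 percent/Myr divergence rate, and Bonferroni divisors 18 (characters
#' x sexes) and 2 (sexes) applied inside the morphology stage.
#'
#' @param simulate a \code{SimulationConfig} or NULL.
#' @param input named list of file paths (see above) or NULL.
#' @param distanceModel \code{"TN93+G"}, \code{"TN93"} or \code{"p"} for
#'   group distances and the clock.
#' @param gammaShape gamma shape for TN93+G.
#' @param amovaModel distance model for AMOVA (gamma off by default).
#' @param amovaPermutations permutations for the phi-ST test.
#' @param parsimonyConfidence connection-limit confidence.
#' @param clockRatePercentPerMyr divergence rate (percent/Myr).
#' @param exclude population names excluded from the clock fit
#'   (downstream-drift descendants).
#' @param occupancyPredictors predictor pool for the presence model
#'   (default: waterfall dummy + the nine environmental factors).
#' @param richnessPredictors predictor pool for the richness model.
#' @param outDir optional directory for report + artifacts.
#' @param seed integer seed (used for AMOVA permutations and any
#'   simulation).
#' @return a list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(simulate = simulationConfig(),
                           input = NULL,
                           distanceModel = "TN93+G",
                           gammaShape = 0.14,
                           amovaModel = "TN93",
                           amovaPermutations = 10000L,
                           parsimonyConfidence = 0.95,
                           clockRatePercentPerMyr = 3.8,
                           exclude = character(),
                           occupancyPredictors = c("waterfall",
                                                   .ENV_FACTORS),
                           richnessPredictors = c("waterfall",
                                                  .ENV_FACTORS),
                           outDir = NULL,
                           seed = 1L) {
  cfg <- list(simulate = simulate, input = input,
              distanceModel = distanceModel, gammaShape = gammaShape,
              amovaModel = amovaModel,
              amovaPermutations = as.integer(amovaPermutations),
              parsimonyConfidence = parsimonyConfidence,
              clockRatePercentPerMyr = clockRatePercentPerMyr,
              exclude = exclude,
              occupancyPredictors = occupancyPredictors,
              richnessPredictors = richnessPredictors,
              outDir = outDir, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param config a \code{PipelineConfig}.
#' @return invisibly TRUE; errors describe the problem
#' @export
validatePipelineConfig <- function(config) {
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either a simulate block or an input block")
  if (!is.null(config$input)) {
    need <- if (!is.null(config$input$fasta)) "fasta" else
      c("fastaND5", "fastaCytb")
    paths <- unlist(config$input[c(need, "metadata")], use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  if (is.null(config$seed)) stop("a seed must be set")
  invisible(TRUE)
}

.stageWrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes seqdata -> gendist -> popstruct -> morphology -> habitat ->
#' clock on simulated or file inputs and returns one report carrying every
#' statistic. A stage failure aborts with the stage name and cause;
#' already-computed stages are returned in the condition-free partial
#' report written to \code{outDir} (when set). Rerunning with the same
#' config and seed reproduces the report exactly.
#'
#' @param config a \code{\link{pipelineConfig}} (or arguments for it).
#' @param stages which stages to run (dependencies are implied: gendist
#'   needs seqdata, clock needs gendist).
#' @return a named list report of class \code{"gobyclockReport"}
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("seqdata", "gendist", "popstruct",
                                   "morphology", "habitat", "clock")) {
  validatePipelineConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = config$seed)

  ## ---- inputs ----------------------------------------------------------
  morph <- NULL; sites <- NULL; waterfalls <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    simCfg <- config$simulate
    simCfg@seed <- config$seed
    system <- .stageWrap("simulate", simulateSystem(simCfg))
    st <- system@sequences
    morph <- system@morphology
    sites <- system@sites
    truth <- system@truth
    waterfalls <- data.frame(name = names(simCfg@heights_m),
                             height_m = as.numeric(simCfg@heights_m))
    report$truth <- list(erosion_rate_true = simCfg@erosion_rate_true,
                         times = as.list(truth$times))
  } else {
    inp <- config$input
    st <- .stageWrap("input", {
      if (!is.null(inp$fasta)) {
        readAlignment(inp$fasta, inp$metadata, regionName = "alignment")
      } else {
        concatenateRegions(
          readAlignment(inp$fastaND5, inp$metadata, regionName = "ND5"),
          readAlignment(inp$fastaCytb, inp$metadata, regionName = "cytb"))
      }
    })
    if (!is.null(inp$morphology))
      morph <- read.csv(inp$morphology, stringsAsFactors = FALSE)
    if (!is.null(inp$sites))
      sites <- read.csv(inp$sites, stringsAsFactors = FALSE)
    waterfalls <- if (!is.null(inp$waterfalls))
      read.csv(inp$waterfalls, stringsAsFactors = FALSE) else waterfallTable()
  }
  spp <- speciesLabels(st)
  pops <- populations(st)
  focal <- names(spp)[spp == "YB"]; source <- names(spp)[spp == "BR"]

  ## ---- seqdata ---------------------------------------------------------
  haps <- NULL
  if ("seqdata" %in% stages) {
    report$seqdata <- .stageWrap("seqdata", {
      regions <- regionWidths(st)
      regionStats <- lapply(names(regions), function(rn)
        variableSiteStats(splitRegion(st, rn)))
      names(regionStats) <- names(regions)
      fisherP <- if (length(regionStats) == 2L)
        compareVariableRates(regionStats[[1L]], regionStats[[2L]])
        else NA_real_
      haps <- collapseHaplotypes(st)
      hapBySpecies <- table(haps@species)
      list(nIndividuals = length(st),
           alignmentLength = alignmentLength(st),
           regions = as.list(regions),
           variableSites = lapply(regionStats, function(s)
             list(nVariable = s$nVariable, nSites = s$nSites,
                  proportion = s$proportion)),
           fisherP = fisherP,
           nHaplotypes = length(haps),
           haplotypesPerSpecies = as.list(hapBySpecies))
    })
  }

  ## ---- gendist ---------------------------------------------------------
  dmat <- NULL
  if ("gendist" %in% stages || "clock" %in% stages ||
      "popstruct" %in% stages || "morphology" %in% stages) {
    dmat <- .stageWrap("gendist",
      pairwiseDistances(st, model = config$distanceModel,
                        gammaShape = config$gammaShape))
  }
  popDist <- NULL
  if ("gendist" %in% stages) {
    report$gendist <- .stageWrap("gendist", {
      yPops <- sort(unique(pops[focal]))
      popDist <- vapply(yPops, function(p)
        groupMeanDistance(dmat, names(pops)[pops == p], source),
        numeric(1))
      list(model = distanceModel(dmat),
           sourceDiversity = withinGroupDiversity(dmat, source),
           populationToSource = as.list(popDist))
    })
  }

  ## ---- popstruct -------------------------------------------------------
  if ("popstruct" %in% stages) {
    report$popstruct <- .stageWrap("popstruct", {
      amovaD <- pairwiseDistances(st, model = config$amovaModel,
                                  gammaShape = config$gammaShape)
      am <- as.matrix(amovaD)
      amovaOf <- function(ids, offset) {
        if (length(unique(pops[ids])) < 2L) return(NULL)
        amovaTwoLevel(am[ids, ids], pops[ids],
                      nPermutations = config$amovaPermutations,
                      seed = .subSeed(config$seed, offset))
      }
      amYB <- amovaOf(focal, 11L)
      amBR <- amovaOf(source, 12L)
      if (is.null(haps)) haps <- collapseHaplotypes(st)
      net <- buildParsimonyNetwork(haps,
                                   confidence = config$parsimonyConfidence)
      asList <- function(a) if (is.null(a)) NULL else
        list(percentAmong = unname(a@percent["among"]),
             percentWithin = unname(a@percent["within"]),
             phiST = a@phiST, p = a@pValue)
      list(amovaFocal = asList(amYB), amovaSource = asList(amBR),
           connectionLimit = net@connectionLimit,
           nComponents = igraph::components(net@graph)$no)
    })
  }

  ## ---- morphology ------------------------------------------------------
  if ("morphology" %in% stages && !is.null(morph)) {
    report$morphology <- .stageWrap("morphology", {
      u <- characterUTests(morph)
      refSpecies <- "BR"
      if (is.null(popDist)) {
        yPops <- sort(unique(pops[focal]))
        popDist <- vapply(yPops, function(p)
          groupMeanDistance(dmat, names(pops)[pops == p], source),
          numeric(1))
      }
      perSex <- lapply(c("male", "female"), function(sx) {
        wc <- wardCluster(morph, sx)
        md <- morphDistanceToReference(morph, refSpecies, sx)
        reg <- tryCatch(
          regressMorphOnGenetic(md, popDist),
          error = function(e) NULL)
        list(wardPurity = wc$purity,
             regression = if (is.null(reg)) NULL else
               reg[c("slope", "fStatistic", "r2", "p", "significant")])
      })
      names(perSex) <- c("male", "female")
      list(nSignificantCharacters = sum(u$significant),
           nTests = nrow(u), bySex = perSex)
    })
  }

  ## ---- habitat ---------------------------------------------------------
  if ("habitat" %in% stages && !is.null(sites)) {
    report$habitat <- .stageWrap("habitat", {
      occ <- allSubsetsAIC(sites, "presence_focal",
                           config$occupancyPredictors)
      rich <- allSubsetsAIC(sites, "richness", config$richnessPredictors,
                            fitter = glmmFitter)
      manova <- manovaWilks(sites[, .ENV_FACTORS], sites$waterfall)
      list(occupancy = list(predictors = occ$bestPredictors,
                            coefficients = as.list(occ$best$coefficients),
                            aic = occ$best$aic, auc = occ$best$auc),
           richness = list(predictors = rich$bestPredictors,
                           coefficients = as.list(rich$best$coefficients),
                           ranefSD = rich$best$ranefSD,
                           aic = rich$best$aic),
           manova = manova)
    })
  }

  ## ---- clock -----------------------------------------------------------
  if ("clock" %in% stages) {
    report$clock <- .stageWrap("clock", {
      if (is.null(popDist)) {
        yPops <- sort(unique(pops[focal]))
        popDist <- vapply(yPops, function(p)
          groupMeanDistance(dmat, names(pops)[pops == p], source),
          numeric(1))
      }
      ## match populations to waterfall heights by name
      popNames <- sub("^YB_", "", names(popDist))
      hIdx <- match(popNames, waterfalls$name)
      pts <- data.frame(name = popNames,
                        height_m = waterfalls$height_m[hIdx],
                        distance = as.numeric(popDist))
      pts <- pts[!is.na(pts$height_m), , drop = FALSE]
      fit <- clockAnalysis(pts,
                           rate = substitutionRate(
                             config$clockRatePercentPerMyr),
                           exclude = config$exclude,
                           heights = setNames(waterfalls$height_m,
                                              waterfalls$name))
      list(slope = fit@slope, intercept = fit@intercept,
           fStatistic = fit@fStatistic, r2 = fit@r2, p = fit@pValue,
           erosion_m_per_yr = fit@erosionRate,
           erosion_mm_per_yr = 1000 * fit@erosionRate,
           ages = setNames(as.list(fit@ages$age_yr), fit@ages$name))
    })
  }

  class(report) <- "gobyclockReport"
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' End-to-end erosion-rate recovery experiment
#'
#' Simulates replicate synthetic systems at the configured study
#' conditions, runs the sequence -> distance -> clock chain on each, and
#' collects the estimated erosion rate. A replicate whose height-distance
#' slope comes out non-positive (possible under the heavy-tailed
#' site-rate model) yields no rate estimate and is recorded as NA; the
#' summary median is taken over the valid replicates.
#'
#' @param nReplicates number of replicate systems (default 50).
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param config the \code{SimulationConfig} shared by all replicates
#'   (each replicate reseeded).
#' @return list: \code{estimates} (mm/yr, NA where the slope was
#'   non-positive), \code{median} (mm/yr), \code{trueValue} (mm/yr),
#'   \code{relativeError}, \code{nFailed}
#' @export
erosionRecovery <- function(nReplicates = 50L, seed = 1L,
                            config = simulationConfig()) {
  ests <- vapply(seq_len(nReplicates), function(k) {
    cfg <- config
    cfg@seed <- .subSeed(seed, 100L + k) %% 1000000L
    rep <- runPipeline(pipelineConfig(simulate = cfg, seed = cfg@seed),
                       stages = "gendist")
    pd <- unlist(rep$gendist$populationToSource)
    nm <- sub("^YB_", "", names(pd))
    pts <- data.frame(name = nm, height_m = config@heights_m[nm],
                      distance = as.numeric(pd))
    fit <- fitHeightDistance(pts)
    if (fit$slope <= 0) return(NA_real_)
    erosionRate(fit$slope, config@subst_rate)$mm_per_yr
  }, numeric(1))
  med <- median(ests, na.rm = TRUE)
  trueVal <- 1000 * config@erosion_rate_true
  list(estimates = ests, median = med, trueValue = trueVal,
       relativeError = abs(med - trueVal) / trueVal,
       nFailed = sum(is.na(ests)))
}

#' @export
print.gobyclockReport <- function(x, ...) {
  cat("gobyclock pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$seqdata))
    cat("  seqdata : ", x$seqdata$nIndividuals, " individuals, ",
        x$seqdata$nHaplotypes, " haplotypes, ",
        x$seqdata$alignmentLength, " bp\n", sep = "")
  if (!is.null(x$popstruct) && !is.null(x$popstruct$amovaFocal))
    cat(sprintf("  AMOVA   : %.1f%% among landlocked populations\n",
                x$popstruct$amovaFocal$percentAmong))
  if (!is.null(x$clock))
    cat(sprintf("  clock   : E = %.2g mm/yr (r2 = %.2f)\n",
                x$clock$erosion_mm_per_yr, x$clock$r2))
  invisible(x)
}
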