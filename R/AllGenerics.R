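## Generics and accessors for the S4 containers.

#' @rdname SequenceTable-class
#' @param object,x an object
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))
#' @rdname SequenceTable-class
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))
#' @rdname SequenceTable-class
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))
#' @rdname SequenceTable-class
#' @export
setGeneric("speciesLabels", function(object) standardGeneric("speciesLabels"))
#' @rdname SequenceTable-class
#' @export
setGeneric("alignmentLength", function(object) standardGeneric("alignmentLength"))
#' @rdname SequenceTable-class
#' @export
setGeneric("regionWidths", function(object) standardGeneric("regionWidths"))

#' @rdname HaplotypeSet-class
#' @param object an object
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))
#' @rdname HaplotypeSet-class
#' @export
setGeneric("haplotypeMembership", function(object) standardGeneric("haplotypeMembership"))
#' @rdname HaplotypeSet-class
#' @export
setGeneric("haplotypeFrequencies", function(object) standardGeneric("haplotypeFrequencies"))

#' @rdname DistanceMatrix-class
#' @param object an object
#' @export
setGeneric("distanceModel", function(object) standardGeneric("distanceModel"))

setMethod("sequences", "SequenceTable", function(object) object@seqs)
setMethod("sampleInfo", "SequenceTable", function(object) object@meta)
setMethod("populations", "SequenceTable", function(object)
  setNames(as.character(object@meta$population), rownames(object@meta)))
setMethod("speciesLabels", "SequenceTable", function(object)
  setNames(as.character(object@meta$species), rownames(object@meta)))
setMethod("alignmentLength", "SequenceTable", function(object)
  if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L)
setMethod("regionWidths", "SequenceTable", function(object) object@regions)

#' @describeIn SequenceTable-class number of individuals
#' @export
setMethod("length", "SequenceTable", function(x) length(x@seqs))

#' @describeIn SequenceTable-class subset individuals by index or id
#' @param i index, logical or id vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "SequenceTable", function(x, i, j, ..., drop = FALSE) {
  new("SequenceTable", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE],
      regionName = x@regionName, regions = x@regions)
})

setMethod("haplotypes", "HaplotypeSet", function(object) object@haplotypes)
setMethod("haplotypeMembership", "HaplotypeSet", function(object) object@membership)
setMethod("haplotypeFrequencies", "HaplotypeSet", function(object) object@freqs)

#' @describeIn HaplotypeSet-class number of haplotypes
#' @param x a HaplotypeSet
#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@haplotypes))

setMethod("distanceModel", "DistanceMatrix", function(object)
  list(model = object@model, gammaShape = object@gammaShape))

#' @describeIn DistanceMatrix-class coerce to a plain matrix
#' @param x a DistanceMatrix
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@mat)

#' Labels of a DistanceMatrix
#' @param object a DistanceMatrix
#' @return character vector of row labels
#' @export
distanceLabels <- function(object) rownames(object@mat)

setMethod("show", "SequenceTable", function(object) {
  cat("SequenceTable with", length(object@seqs), "sequences of",
      alignmentLength(object), "sites\n")
  if (length(object@regions))
    cat("  regions:", paste(names(object@regions), object@regions,
                            sep = "=", collapse = ", "), "\n")
  cat("  populations:", length(unique(object@meta$population)),
      " species:", paste(unique(object@meta$species), collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@haplotypes), "haplotypes from",
      length(object@membership), "individuals across",
      ncol(object@freqs), "populations\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@model,
      if (!is.na(object@gammaShape)) paste0(", shape=", object@gammaShape),
      "): ", nrow(object@mat), " x ", ncol(object@mat), sep = "")
  if (object@nSaturated > 0L)
    cat(";", object@nSaturated, "saturated pair(s)")
  cat("\n")
})

setMethod("show", "AmovaResult", function(object) {
  cat("Two-level AMOVA\n")
  cat(sprintf("  among populations : %6.2f%%  (sigma2 = %.6g)\n",
              object@percent["among"], object@sigma2["among"]))
  cat(sprintf("  within populations: %6.2f%%  (sigma2 = %.6g)\n",
              object@percent["within"], object@sigma2["within"]))
  cat(sprintf("  phi-ST = %s", format(object@phiST, digits = 4)))
  if (!is.na(object@pValue))
    cat(sprintf("  (P = %.4g, %d permutations)",
                object@pValue, object@nPermutations))
  cat("\n")
})

setMethod("show", "HaploNetwork", function(object) {
  g <- object@graph
  cat("Statistical parsimony network:", igraph::vcount(g), "haplotypes,",
      igraph::ecount(g), "links,",
      igraph::components(g)$no, "component(s); connection limit",
      object@connectionLimit, "steps\n")
})

setMethod("show", "ClockFit", function(object) {
  cat("Waterfall clock fit on", nrow(object@points), "populations")
  if (length(object@excluded))
    cat(" (excluded:", paste(object@excluded, collapse = ", "), ")")
  cat("\n")
  cat(sprintf("  D = %.4g + %.3g * h   (F[%d,%d] = %.3g, r2 = %.3f, P = %.3g)\n",
              object@intercept, object@slope, object@dfNum, object@dfDen,
              object@fStatistic, object@r2, object@pValue))
  cat(sprintf("  rate R = %.3g /yr  ->  erosion rate E = %.2g mm/yr\n",
              object@rate, 1000 * object@erosionRate))
  if (nrow(object@ages))
    cat("  ages:", paste(sprintf("%s=%s yr", object@ages$name,
                                 format(round(object@ages$age_yr))),
                         collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@heights_m), "waterfalls,",
      "E_true =", object@erosion_rate_true, "m/yr, R =", object@subst_rate,
      "/yr, L =", object@seq_length, "sites, seed =", object@seed, "\n")
})

setMethod("show", "SyntheticSystem", function(object) {
  cat("SyntheticSystem (seed", object@config@seed, ")\n")
  cat("  sequences :", length(object@sequences), "individuals\n")
  cat("  morphology:", nrow(object@morphology), "records\n")
  cat("  sites     :", nrow(object@sites), "sites\n")
})
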