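## seqdata: alignment + metadata IO, region concatenation, haplotype
## collapsing and variable-site statistics.

#' Build a SequenceTable from in-memory sequences and metadata
#'
#' @param seqs named character vector or \code{DNAStringSet} of aligned
#'   sequences (equal length). U is mapped to T; case-insensitive.
#' @param meta data.frame with columns \code{individual_id},
#'   \code{population}, \code{species} and optionally \code{sex}.
#' @param regionName label for the region.
#' @param regions optional named integer vector of region widths.
#' @return a \code{\link{SequenceTable-class}} object
#' @export
sequenceTable <- function(seqs, meta, regionName = "region",
                          regions = integer()) {
  if (!is(seqs, "XStringSet")) {
    s <- toupper(as.character(seqs))
    s <- gsub("U", "T", s, fixed = TRUE)
    seqs <- DNAStringSet(setNames(s, names(seqs)))
  }
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by individual id")
  if (!"individual_id" %in% colnames(meta))
    stop("metadata must contain an 'individual_id' column")
  missing <- setdiff(ids, meta$individual_id)
  if (length(missing))
    stop("metadata missing for individuals: ", paste(missing, collapse = ", "))
  meta <- meta[match(ids, meta$individual_id), , drop = FALSE]
  if (!"sex" %in% colnames(meta)) meta$sex <- NA_character_
  df <- DataFrame(population = as.character(meta$population),
                  species = as.character(meta$species),
                  sex = as.character(meta$sex),
                  row.names = ids)
  w <- Biostrings::width(seqs)
  if (length(w) && length(unique(w)) != 1L) {
    bad <- ids[w != stats::median(w)]
    stop("alignment length mismatch for: ", paste(bad, collapse = ", "))
  }
  if (!length(regions) && length(w))
    regions <- setNames(w[1L], regionName)
  new("SequenceTable", seqs = seqs, meta = df,
      regionName = regionName,
      regions = setNames(as.integer(regions), names(regions)))
}

#' Read an aligned FASTA plus a sample metadata CSV
#'
#' The metadata CSV must have header columns \code{individual_id},
#' \code{population}, \code{species} and optionally \code{sex}; every FASTA
#' id must resolve to a metadata row. Sequences with a deviating length
#' raise an alignment error naming the offending ids.
#'
#' @param fastaPath path to an aligned FASTA file.
#' @param metadataPath path to the metadata CSV.
#' @param regionName region label stored on the result.
#' @return a \code{\link{SequenceTable-class}}
#' @export
readAlignment <- function(fastaPath, metadataPath, regionName = "region") {
  raw <- readBStringSet(fastaPath)
  meta <- read.csv(metadataPath, stringsAsFactors = FALSE)
  sequenceTable(setNames(as.character(raw), names(raw)), meta,
                regionName = regionName)
}

#' Concatenate two aligned regions individual-by-individual
#'
#' Both tables must cover exactly the same individuals. The result's
#' alignment length is the sum of the two region lengths (e.g. a 945-site
#' ND5 table plus an 1141-site cyt-b table gives 2086 sites) and the first
#' table's metadata is preserved.
#'
#' @param x,y \code{SequenceTable}s over the same individuals.
#' @return a \code{SequenceTable} with both regions recorded
#' @export
concatenateRegions <- function(x, y) {
  stopifnot(is(x, "SequenceTable"), is(y, "SequenceTable"))
  idsX <- names(sequences(x)); idsY <- names(sequences(y))
  onlyX <- setdiff(idsX, idsY); onlyY <- setdiff(idsY, idsX)
  if (length(onlyX) || length(onlyY))
    stop("individuals present in one region only: ",
         paste(c(onlyX, onlyY), collapse = ", "))
  sy <- sequences(y)[idsX]
  combined <- DNAStringSet(paste0(as.character(sequences(x)),
                                  as.character(sy)))
  names(combined) <- idsX
  regions <- c(regionWidths(x), regionWidths(y))
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    names(regions) <- make.unique(c(x@regionName, y@regionName))
  new("SequenceTable", seqs = combined, meta = x@meta,
      regionName = paste(x@regionName, y@regionName, sep = "+"),
      regions = regions)
}

#' Extract one region from a concatenated SequenceTable
#'
#' @param x a \code{SequenceTable} with recorded region widths.
#' @param region region name.
#' @return a \code{SequenceTable} restricted to that region
#' @export
splitRegion <- function(x, region) {
  w <- regionWidths(x)
  if (!region %in% names(w)) stop("unknown region: ", region)
  idx <- match(region, names(w))
  from <- if (idx == 1L) 1L else sum(w[seq_len(idx - 1L)]) + 1L
  to <- from + w[idx] - 1L
  seqs <- DNAStringSet(substr(as.character(sequences(x)), from, to))
  names(seqs) <- names(sequences(x))
  new("SequenceTable", seqs = seqs, meta = x@meta, regionName = region,
      regions = setNames(w[idx], region))
}

#' Collapse identical sequences into haplotypes
#'
#' Sites containing gaps or ambiguity codes in any individual are excluded
#' alignment-wide (complete deletion) before comparison, so haplotype
#' identity is unambiguous. Haplotypes are numbered in first-occurrence
#' order (H01, H02, ...).
#'
#' @param x a \code{SequenceTable}.
#' @return a \code{\link{HaplotypeSet-class}}
#' @export
collapseHaplotypes <- function(x) {
  stopifnot(is(x, "SequenceTable"))
  sm <- .completeDeletion(.seqIntMatrix(x))
  key <- apply(sm, 1L, paste0, collapse = "")
  firstIdx <- which(!duplicated(key))
  hapIds <- sprintf("H%02d", seq_along(firstIdx))
  membership <- setNames(hapIds[match(key, key[firstIdx])],
                         names(sequences(x)))
  haps <- .intMatrixToDNAStringSet(sm[firstIdx, , drop = FALSE])
  names(haps) <- hapIds
  pops <- populations(x)
  freqs <- table(factor(membership, levels = hapIds),
                 factor(pops, levels = unique(pops)))
  freqs <- matrix(as.integer(freqs), nrow = length(hapIds),
                  dimnames = list(hapIds, colnames(freqs)))
  spp <- speciesLabels(x)
  hapSpecies <- vapply(hapIds, function(h)
    paste(sort(unique(spp[membership == h])), collapse = ","), character(1))
  new("HaplotypeSet", haplotypes = haps, membership = membership,
      freqs = freqs, species = hapSpecies)
}

#' Count variable sites in an alignment
#'
#' A site is variable iff at least two distinct unambiguous nucleotide
#' states are observed there. Sites with gaps/ambiguities in any sequence
#' are excluded alignment-wide first (complete deletion), matching the
#' haplotype-collapsing convention.
#'
#' @param x a \code{SequenceTable} (or anything coercible to an alignment).
#' @return list with \code{nVariable}, \code{nSites} and \code{proportion}
#'   (unrounded; round only for display)
#' @export
variableSiteStats <- function(x) {
  sm <- .completeDeletion(.seqIntMatrix(x))
  if (nrow(sm) < 2L) stop("need at least two sequences")
  if (ncol(sm) == 0L) stop("no comparable sites after complete deletion")
  nVar <- sum(apply(sm, 2L, function(col) length(unique(col))) > 1L)
  list(nVariable = as.integer(nVar), nSites = ncol(sm),
       proportion = nVar / ncol(sm))
}

#' Compare variable-site rates of two regions by Fisher's exact test
#'
#' Builds the 2x2 table (variable vs invariant sites, region A vs B) and
#' returns the two-sided exact p value.
#'
#' @param statsA,statsB outputs of \code{\link{variableSiteStats}} or lists
#'   with \code{nVariable} and \code{nSites}.
#' @return two-sided Fisher exact p value
#' @export
compareVariableRates <- function(statsA, statsB) {
  if (statsA$nSites == 0L || statsB$nSites == 0L)
    stop("zero-length region")
  tab <- matrix(c(statsA$nVariable, statsA$nSites - statsA$nVariable,
                  statsB$nVariable, statsB$nSites - statsB$nVariable),
                nrow = 2L)
  stats::fisher.test(tab)$p.value
}

#' Write a haplotype table as CSV
#'
#' One row per haplotype: id, sequence, then per-population counts.
#'
#' @param haps a \code{HaplotypeSet}.
#' @param path output CSV path.
#' @return the written data.frame, invisibly
#' @export
writeHaplotypeTable <- function(haps, path) {
  df <- data.frame(haplotype_id = names(haplotypes(haps)),
                   sequence = as.character(haplotypes(haps)),
                   as.data.frame.matrix(haplotypeFrequencies(haps)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
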