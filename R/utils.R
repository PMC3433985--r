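## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

## DNAStringSet / character vector -> integer matrix (A=1,C=2,G=3,T=4, NA
## for gaps and ambiguity codes). Case-insensitive, U mapped to T.
.seqIntMatrix <- function(x) {
  if (is(x, "SequenceTable")) x <- sequences(x)
  if (is(x, "HaplotypeSet")) x <- haplotypes(x)
  if (is(x, "XStringSet")) {
    m <- as.matrix(x)
  } else {
    nm <- names(x)
    x <- as.character(x)
    if (length(unique(nchar(x))) != 1L)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(x, ""))
    rownames(m) <- nm
  }
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  out <- matrix(match(m, .BASES), nrow = nrow(m),
                dimnames = list(rownames(m), NULL))
  out
}

## Complete deletion: drop every site where any sequence carries a gap or
## ambiguity code. Returns the reduced integer matrix.
.completeDeletion <- function(sm) {
  keep <- colSums(is.na(sm)) == 0L
  sm[, keep, drop = FALSE]
}

## Deterministic sub-stream seeds derived from one master seed.
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

.intMatrixToDNAStringSet <- function(sm) {
  chars <- matrix(.BASES[sm], nrow = nrow(sm))
  DNAStringSet(setNames(apply(chars, 1L, paste0, collapse = ""),
                        rownames(sm)))
}

## Standardize columns of a design matrix; returns list(x, center, scale).
.standardizeColumns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(x = Xs, center = ctr, scale = scl)
}
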