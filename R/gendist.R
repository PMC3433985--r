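## gendist: Tamura-Nei (1993) distances, optionally with continuous gamma
## rate correction, plus between-group means and within-group diversity.
##
## TN93 separates purine transitions (A<->G, proportion P1), pyrimidine
## transitions (C<->T, P2) and transversions (Q), with base frequencies
## gA..gT. Writing gR = gA+gG, gY = gC+gT,
##   k1 = 2 gA gG / gR,  k2 = 2 gT gC / gY,
##   k3 = 2 (gR gY - gA gG gY/gR - gT gC gR/gY),
##   w1 = 1 - P1/k1 - Q/(2 gR),  w2 = 1 - P2/k2 - Q/(2 gY),
##   w3 = 1 - Q/(2 gR gY),
##   d  = -k1 log(w1) - k2 log(w2) - k3 log(w3).
## Under gamma-distributed site rates of shape a each -k log(w) becomes
## a k (w^(-1/a) - 1), the continuous-gamma analogue.

.tn93Core <- function(P1, P2, Q, gA, gC, gG, gT, model, gammaShape) {
  if (model == "p") return(list(d = P1 + P2 + Q, saturated = FALSE))
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  sat <- (w1 <= 0) | (w2 <= 0) | (w3 <= 0)
  ## saturated entries evaluate to NaN below and are masked right after
  if (model == "TN93") {
    d <- suppressWarnings(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
  } else { # TN93+G
    a <- gammaShape
    d <- suppressWarnings(
      a * (k1 * (w1^(-1 / a) - 1) + k2 * (w2^(-1 / a) - 1) +
             k3 * (w3^(-1 / a) - 1)))
  }
  d[sat] <- NA_real_
  d[!sat & d < 0] <- 0  # guard tiny negative round-off on near-zero pairs
  list(d = d, saturated = sat)
}

.checkModel <- function(model, gammaShape) {
  model <- match.arg(model, c("TN93+G", "TN93", "p"))
  if (model == "TN93+G" && (!is.finite(gammaShape) || gammaShape <= 0))
    stop("gammaShape must be a positive number for TN93+G")
  model
}

#' Tamura-Nei distance between two aligned sequences
#'
#' Computes the TN93 closed-form distance (substitutions/site) from the
#' observed purine-transition, pyrimidine-transition and transversion
#' proportions. Base frequencies are estimated from the two sequences
#' pooled (default) or supplied. Under \code{model = "TN93+G"} each
#' logarithmic term is replaced by its continuous-gamma analogue with shape
#' \code{gammaShape}. Pairs whose log/power argument is non-positive are
#' saturated: the distance is returned as \code{NA} (no exception).
#'
#' @param a,b aligned sequences (character strings, \code{DNAString}s, or
#'   length-1 \code{DNAStringSet}s) of equal length.
#' @param model \code{"TN93+G"} (default), \code{"TN93"} or \code{"p"}.
#' @param gammaShape gamma shape parameter (default 0.14).
#' @param baseFreq optional 4-vector (A,C,G,T) of base frequencies; by
#'   default estimated from the pooled pair.
#' @return distance in substitutions/site (\code{NA} if saturated)
#' @export
tn93Distance <- function(a, b, model = c("TN93+G", "TN93", "p"),
                         gammaShape = 0.14, baseFreq = NULL) {
  model <- .checkModel(model, gammaShape)
  sm <- .completeDeletion(.seqIntMatrix(c(as.character(a),
                                          as.character(b))))
  L <- ncol(sm)
  if (L == 0L) stop("no comparable sites after complete deletion")
  s1 <- sm[1L, ]; s2 <- sm[2L, ]
  P1 <- sum((s1 == 1 & s2 == 3) | (s1 == 3 & s2 == 1)) / L
  P2 <- sum((s1 == 2 & s2 == 4) | (s1 == 4 & s2 == 2)) / L
  Q <- sum(s1 != s2) / L - P1 - P2
  if (is.null(baseFreq)) {
    counts <- tabulate(c(s1, s2), nbins = 4L)
    baseFreq <- counts / sum(counts)
  }
  if (model != "p" && any(baseFreq <= 0))
    stop("all four bases must be present to evaluate the TN93 form")
  res <- .tn93Core(P1, P2, Q, baseFreq[1L], baseFreq[2L], baseFreq[3L],
                   baseFreq[4L], model, gammaShape)
  unname(res$d)
}

#' Pairwise distance matrix for a set of sequences
#'
#' All unordered pairs, computed after alignment-wide complete deletion.
#' By default base frequencies are estimated per pair from the two
#' sequences pooled; \code{freqEstimate = "global"} uses the frequencies of
#' the whole alignment instead. Saturated pairs are \code{NA} and counted.
#'
#' @param x a \code{SequenceTable}, \code{HaplotypeSet}, named character
#'   vector or \code{DNAStringSet}.
#' @param model,gammaShape distance model, as in \code{\link{tn93Distance}}.
#' @param freqEstimate \code{"pair"} (default) or \code{"global"}.
#' @return a \code{\link{DistanceMatrix-class}}
#' @export
pairwiseDistances <- function(x, model = c("TN93+G", "TN93", "p"),
                              gammaShape = 0.14,
                              freqEstimate = c("pair", "global")) {
  model <- .checkModel(model, gammaShape)
  freqEstimate <- match.arg(freqEstimate)
  sm <- .completeDeletion(.seqIntMatrix(x))
  n <- nrow(sm); L <- ncol(sm)
  if (n < 2L) stop("need at least two sequences")
  if (L == 0L) stop("no comparable sites after complete deletion")
  ind <- lapply(1:4, function(b) (sm == b) * 1)
  ## cross-tabulated site counts for every ordered pair, via crossprod
  cnt <- function(i, j) tcrossprod(ind[[i]], ind[[j]])
  AG <- cnt(1, 3) + cnt(3, 1)
  CT <- cnt(2, 4) + cnt(4, 2)
  same <- cnt(1, 1) + cnt(2, 2) + cnt(3, 3) + cnt(4, 4)
  P1 <- AG / L
  P2 <- CT / L
  Q <- (L - same - AG - CT) / L
  rowCounts <- vapply(ind, rowSums, numeric(n))  # n x 4 base counts
  if (freqEstimate == "pair") {
    g <- lapply(1:4, function(b)
      outer(rowCounts[, b], rowCounts[, b], "+") / (2 * L))
  } else {
    gf <- colSums(rowCounts) / (n * L)
    g <- lapply(1:4, function(b) matrix(gf[b], n, n))
  }
  res <- .tn93Core(P1, P2, Q, g[[1]], g[[2]], g[[3]], g[[4]],
                   model, gammaShape)
  d <- res$d
  diag(d) <- 0
  d <- (d + t(d)) / 2  # symmetrize exact round-off
  dimnames(d) <- list(rownames(sm), rownames(sm))
  nSat <- if (model == "p") 0L else sum(res$saturated[upper.tri(d)])
  new("DistanceMatrix", mat = d, model = model,
      gammaShape = if (model == "TN93+G") gammaShape else NA_real_,
      nSaturated = as.integer(nSat))
}

.resolveGroup <- function(d, group) {
  labs <- rownames(d)
  if (is.logical(group)) labs[group]
  else if (is.numeric(group)) labs[group]
  else {
    miss <- setdiff(group, labs)
    if (length(miss)) stop("unknown labels: ", paste(miss, collapse = ", "))
    group
  }
}

#' Mean between-group distance
#'
#' Arithmetic mean of all inter-group pairwise distances (e.g. a landlocked
#' population against all source-species individuals pooled). Saturated
#' (NA) pairs are excluded with a warning.
#'
#' @param d a \code{DistanceMatrix} or plain symmetric matrix.
#' @param groupA,groupB disjoint, non-empty label (or index/logical)
#'   vectors.
#' @return mean inter-group distance
#' @export
groupMeanDistance <- function(d, groupA, groupB) {
  m <- if (is(d, "DistanceMatrix")) as.matrix(d) else d
  groupA <- .resolveGroup(m, groupA); groupB <- .resolveGroup(m, groupB)
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  block <- m[groupA, groupB, drop = FALSE]
  if (anyNA(block)) {
    warning(sum(is.na(block)), " saturated pair(s) excluded from group mean")
    block <- block[!is.na(block)]
  }
  mean(block)
}

#' Mean within-group diversity
#'
#' Mean over all intra-group unordered pairs (e.g. the standing diversity of
#' the amphidromous source species).
#'
#' @param d a \code{DistanceMatrix} or plain symmetric matrix.
#' @param group label (or index/logical) vector with at least 2 members.
#' @return mean intra-group pairwise distance
#' @export
withinGroupDiversity <- function(d, group) {
  m <- if (is(d, "DistanceMatrix")) as.matrix(d) else d
  group <- .resolveGroup(m, group)
  if (length(group) < 2L) stop("group must have at least two members")
  sub <- m[group, group, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " saturated pair(s) excluded from diversity")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Pairwise mutational step counts (site mismatches)
#'
#' Integer site-mismatch counts after alignment-wide complete deletion;
#' the input to statistical parsimony network construction.
#'
#' @param x a \code{SequenceTable}, \code{HaplotypeSet} or sequence vector.
#' @return integer matrix of pairwise mismatch counts
#' @export
mismatchMatrix <- function(x) {
  sm <- .completeDeletion(.seqIntMatrix(x))
  n <- nrow(sm); L <- ncol(sm)
  same <- Reduce(`+`, lapply(1:4, function(b) tcrossprod((sm == b) * 1)))
  steps <- matrix(as.integer(round(L - same)), n, n,
                  dimnames = list(rownames(sm), rownames(sm)))
  diag(steps) <- 0L
  steps
}

#' Write a DistanceMatrix as square CSV
#' @param d a \code{DistanceMatrix}.
#' @param path output path.
#' @return invisibly, the matrix written
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- as.matrix(d)
  write.csv(data.frame(label = rownames(m), m, check.names = FALSE),
            path, row.names = FALSE)
  invisible(m)
}
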