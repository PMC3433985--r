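## morphology: character U-tests with Bonferroni correction, Ward
## clustering, morphology-vs-genetics regression, and body-size t tests
## from summary statistics. Records carry nine characters (a..i), each
## scored 0, 0.5 or 1, and the sexes are analysed strictly separately.

.MORPH_CHARS <- letters[1:9]

.checkMorphRecords <- function(records, chars = .MORPH_CHARS) {
  miss <- setdiff(c("individual_id", "population", "species", "sex", chars),
                  colnames(records))
  if (length(miss))
    stop("morphology records missing columns: ", paste(miss, collapse = ", "))
  scores <- as.matrix(records[, chars])
  if (!all(scores %in% c(0, 0.5, 1)))
    stop("character scores must be 0, 0.5 or 1")
  invisible(records)
}

## Mann-Whitney U statistic for group x against group y, with mid-ranks.
.uStatistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Exact or normal-approximation two-sided Mann-Whitney U test
#'
#' Exact enumeration of all group assignments when both groups have at
#' most \code{exactMax} observations (ties handled naturally through
#' mid-ranks); otherwise the normal approximation with tie correction (no
#' continuity correction). Two-sided p is the probability of a U at least
#' as far from its null mean as observed.
#'
#' @param x,y numeric score vectors for the two groups.
#' @param exactMax largest per-group size for the exact path (default 10).
#' @return list with \code{U}, \code{p} and \code{method}
#' @export
mannWhitneyU <- function(x, y, exactMax = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  U <- .uStatistic(x, y)
  mu <- n1 * n2 / 2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  if (n1 <= exactMax && n2 <= exactMax) {
    r <- rank(pooled)
    off <- n1 * (n1 + 1) / 2
    idx <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - off
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    nt <- table(pooled)
    N <- n1 + n2
    tieAdj <- sum(nt^3 - nt) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieAdj)
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Per-character, per-sex Mann-Whitney comparisons with Bonferroni control
#'
#' Compares each of the nine character scores between the two species
#' within each sex (18 tests in total); significance is declared at
#' p < 0.05 / 18 = 0.0028. A character with identical pooled scores in
#' both groups gets p = 1 and is flagged untestable.
#'
#' @param records morphology data.frame (individual_id, population,
#'   species, sex, a..i).
#' @param chars character columns to test (default a..i).
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return data.frame: character, sex, U, p, method, bonferroniThreshold,
#'   significant, untestable
#' @export
characterUTests <- function(records, chars = .MORPH_CHARS, alpha = 0.05) {
  .checkMorphRecords(records, chars)
  spp <- sort(unique(records$species))
  if (length(spp) != 2L) stop("records must contain exactly two species")
  sexes <- sort(unique(records$sex))
  nTests <- length(chars) * length(sexes)
  thr <- alpha / nTests
  out <- list()
  for (sx in sexes) {
    sub <- records[records$sex == sx, , drop = FALSE]
    g1 <- sub[sub$species == spp[1L], , drop = FALSE]
    g2 <- sub[sub$species == spp[2L], , drop = FALSE]
    if (!nrow(g1) || !nrow(g2))
      stop("both species must be present for sex ", sx)
    for (ch in chars) {
      res <- mannWhitneyU(g1[[ch]], g2[[ch]])
      out[[length(out) + 1L]] <- data.frame(
        character = ch, sex = sx, U = res$U, p = res$p,
        method = res$method, bonferroniThreshold = thr,
        significant = res$p < thr,
        untestable = res$method == "degenerate")
    }
  }
  do.call(rbind, out)
}

#' Ward clustering of morphological scores for one sex
#'
#' Agglomerative clustering on Euclidean distances over the nine character
#' scores, Ward criterion (default \code{"ward.D2"}, i.e. squared
#' distances inside the Lance-Williams update; \code{"ward.D"} is
#' switchable). Reports the two-cluster cut and its purity against the
#' species labels (proportion of individuals whose cluster's majority
#' species matches their own).
#'
#' @param records morphology data.frame.
#' @param sex which sex to cluster.
#' @param method \code{"ward.D2"} (default) or \code{"ward.D"}.
#' @param chars character columns (default a..i).
#' @return list: \code{hclust}, \code{assignment} (named 2-cluster cut),
#'   \code{purity}, \code{records}
#' @export
wardCluster <- function(records, sex, method = c("ward.D2", "ward.D"),
                        chars = .MORPH_CHARS) {
  .checkMorphRecords(records, chars)
  method <- match.arg(method)
  sub <- records[records$sex == sex, , drop = FALSE]
  if (nrow(sub) < 2L) stop("need at least two individuals of sex ", sex)
  scores <- as.matrix(sub[, chars])
  rownames(scores) <- sub$individual_id
  hc <- hclust(dist(scores), method = method)
  k <- min(2L, nrow(sub))
  cut <- cutree(hc, k = k)
  purity <- {
    tab <- table(cut, sub$species)
    sum(apply(tab, 1L, max)) / nrow(sub)
  }
  list(hclust = hc, assignment = cut, purity = purity, records = sub)
}

#' Mean morphological distance to a reference species, per population
#'
#' For each non-reference individual, the mean Euclidean distance (over the
#' nine scores) to every reference individual of the same sex; those values
#' are then averaged per population to give the site representative.
#'
#' @param records morphology data.frame.
#' @param referenceSpecies species label of the reference group.
#' @param sex which sex to use.
#' @param chars character columns (default a..i).
#' @return data.frame: population, meanDistance, n (focal individuals)
#' @export
morphDistanceToReference <- function(records, referenceSpecies, sex,
                                     chars = .MORPH_CHARS) {
  .checkMorphRecords(records, chars)
  sub <- records[records$sex == sex, , drop = FALSE]
  ref <- sub[sub$species == referenceSpecies, , drop = FALSE]
  foc <- sub[sub$species != referenceSpecies, , drop = FALSE]
  if (!nrow(ref)) stop("reference group empty for sex ", sex)
  refM <- as.matrix(ref[, chars])
  perInd <- vapply(seq_len(nrow(foc)), function(i) {
    v <- as.numeric(foc[i, chars])
    mean(sqrt(rowSums(sweep(refM, 2L, v, "-")^2)))
  }, numeric(1))
  agg <- aggregate(perInd, by = list(population = foc$population), FUN = mean)
  n <- as.vector(table(foc$population)[agg$population])
  data.frame(population = agg$population, meanDistance = agg$x, n = n)
}

#' Regress site morphological distance on site genetic distance
#'
#' Simple OLS of the per-site mean morphological Euclidean distance on the
#' per-site genetic distance, with the F test for the slope; significance
#' is declared at p < 0.05 / 2 = 0.025 (one test per sex).
#'
#' @param morphBySite data.frame (population, meanDistance) as from
#'   \code{\link{morphDistanceToReference}}.
#' @param geneticBySite named numeric of genetic distances per population,
#'   or data.frame (population, distance).
#' @param alpha family-wise rate before the two-sex Bonferroni correction.
#' @return list: slope, intercept, fStatistic, dfNum, dfDen, r2, p,
#'   significant, n
#' @export
regressMorphOnGenetic <- function(morphBySite, geneticBySite, alpha = 0.05) {
  if (is.data.frame(geneticBySite))
    geneticBySite <- setNames(geneticBySite$distance,
                              geneticBySite$population)
  g <- geneticBySite[as.character(morphBySite$population)]
  keep <- !is.na(g)
  y <- morphBySite$meanDistance[keep]; x <- as.numeric(g[keep])
  if (length(x) < 3L) stop("need at least three sites")
  if (var(x) == 0) stop("genetic distances are constant across sites")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  fv <- sm$fstatistic
  p <- pf(fv[1L], fv[2L], fv[3L], lower.tail = FALSE)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       fStatistic = unname(fv[1L]), dfNum = unname(fv[2L]),
       dfDen = unname(fv[3L]), r2 = sm$r.squared, p = unname(p),
       significant = unname(p) < alpha / 2, n = length(x))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t computed from group means, SDs and sizes (as printed in a
#' results table), with df = nA + nB - 2. Antisymmetric in group order.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @return list: t, df, p (two-sided)
#' @export
sizeTTest <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopifnot(nA >= 1, nB >= 1, sdA >= 0, sdB >= 0)
  df <- nA + nB - 2
  if (df < 1) stop("nA + nB must exceed 2")
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (meanA - meanB) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Export a dendrogram in Newick format with branch lengths
#'
#' @param hc an \code{hclust} object.
#' @param path output file (NULL returns the string only).
#' @return the Newick string, invisibly when written
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  build <- function(node, parentHeight) {
    if (node < 0) {
      lab <- hc$labels[-node]
      sprintf("%s:%g", gsub("[,():;]", "_", lab), parentHeight)
    } else {
      h <- hc$height[node]
      kids <- vapply(hc$merge[node, ], build, character(1), parentHeight = h)
      sprintf("(%s,%s):%g", kids[1L], kids[2L], parentHeight - h)
    }
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  kids <- vapply(hc$merge[top, ], build, character(1), parentHeight = h)
  nwk <- sprintf("(%s,%s);", kids[1L], kids[2L])
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}
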