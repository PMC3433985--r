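## clock: the waterfall clock. Waterfall height h grows by steady bedrock
## erosion at rate E (m/yr), so a population isolated when its waterfall
## formed has been diverging for t = h / E years. Regressing genetic
## distance D on h gives D = intercept + C h; with an independent
## divergence rate R (substitutions/site/year) the slope converts to the
## erosion rate E = R / C, and each waterfall of known height is dated as
## age = h / E.

#' Convert a percent-per-million-years divergence rate to per-year
#'
#' @param percentPerMyr divergence rate as percent per Myr (default 3.8).
#' @return rate in substitutions/site/year
#' @export
substitutionRate <- function(percentPerMyr = 3.8) {
  percentPerMyr / 100 / 1e6
}

#' Fit the height-distance regression
#'
#' Simple OLS of genetic distance on waterfall height, with the F test for
#' the slope. Populations flagged as downstream-drift descendants (e.g. a
#' site lying between two waterfalls, seeded from above) must be excluded
#' before fitting; the exclusion is an explicit input, not auto-detected.
#'
#' @param points data.frame with columns \code{name}, \code{height_m},
#'   \code{distance}.
#' @param exclude character vector of names to drop before fitting.
#' @return list: slope, intercept, fStatistic, dfNum, dfDen, r2, p,
#'   points, excluded
#' @export
fitHeightDistance <- function(points, exclude = character()) {
  stopifnot(all(c("name", "height_m", "distance") %in% colnames(points)))
  excluded <- intersect(exclude, points$name)
  pts <- points[!points$name %in% exclude, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("need at least three populations to fit the clock line")
  if (any(pts$height_m <= 0)) stop("heights must be positive")
  if (var(pts$height_m) == 0) stop("heights are constant")
  fit <- lm(distance ~ height_m, data = pts)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  fv <- sm$fstatistic
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       fStatistic = unname(fv[1L]), dfNum = unname(fv[2L]),
       dfDen = unname(fv[3L]), r2 = sm$r.squared,
       p = unname(pf(fv[1L], fv[2L], fv[3L], lower.tail = FALSE)),
       points = pts, excluded = excluded)
}

#' Erosion rate from the clock slope and the substitution rate
#'
#' E = R / C, where C is the regression slope (per metre) and R the
#' divergence rate (per year).
#'
#' @param slope regression slope C, substitutions/site per metre.
#' @param rate divergence rate R, substitutions/site per year.
#' @return list: \code{m_per_yr}, \code{mm_per_yr} (and \code{mm_per_yr_2sf}
#'   rounded to 2 significant figures for reporting)
#' @export
erosionRate <- function(slope, rate = substitutionRate(3.8)) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  E <- rate / slope
  list(m_per_yr = E, mm_per_yr = 1000 * E,
       mm_per_yr_2sf = signif(1000 * E, 2))
}

#' Date each waterfall from its height and the erosion rate
#'
#' age = height / E. Waterfalls with a missing height (e.g. one with no
#' dated landlocked population) are skipped.
#'
#' @param heights named numeric of waterfall heights in metres.
#' @param erosion erosion rate E in m/yr (a number or the list from
#'   \code{\link{erosionRate}}).
#' @return data.frame: name, height_m, age_yr
#' @export
waterfallAges <- function(heights, erosion) {
  E <- if (is.list(erosion)) erosion$m_per_yr else erosion
  if (!is.finite(E) || E <= 0) stop("erosion rate must be positive")
  keep <- is.finite(heights)
  h <- heights[keep]
  if (any(h < 0)) stop("heights must be non-negative")
  data.frame(name = if (is.null(names(h))) as.character(seq_along(h))
                    else names(h),
             height_m = as.numeric(h),
             age_yr = as.numeric(h) / E,
             row.names = NULL)
}

#' Check an erosion rate against the geomorphological plausibility band
#'
#' Independent regional erosion estimates place plausible rates between
#' 0.3 and 1.0 mm/yr for terrain of this ruggedness; values outside that
#' band are flagged.
#'
#' @param erosionMmPerYr erosion rate in mm/yr.
#' @param band plausibility band in mm/yr (default c(0.3, 1.0)).
#' @return list: value, band, status ("below", "within", "above"),
#'   plausible
#' @export
checkErosionRate <- function(erosionMmPerYr, band = c(0.3, 1.0)) {
  status <- if (erosionMmPerYr < band[1L]) "below"
            else if (erosionMmPerYr > band[2L]) "above"
            else "within"
  list(value = erosionMmPerYr, band = band, status = status,
       plausible = status == "within")
}

#' Full waterfall-clock analysis
#'
#' Fits the height-distance regression, converts the slope to an erosion
#' rate with the supplied divergence rate, and dates every waterfall of
#' known height.
#'
#' @param points data.frame (name, height_m, distance) of landlocked
#'   populations.
#' @param rate divergence rate per year (default 3.8 percent/Myr).
#' @param exclude population names to drop before fitting (downstream
#'   drift).
#' @param heights optional named heights of all waterfalls to date
#'   (defaults to the fitted points' heights).
#' @return a \code{\link{ClockFit-class}}
#' @export
clockAnalysis <- function(points, rate = substitutionRate(3.8),
                          exclude = character(), heights = NULL) {
  fit <- fitHeightDistance(points, exclude = exclude)
  ero <- erosionRate(fit$slope, rate)
  if (is.null(heights))
    heights <- setNames(fit$points$height_m, fit$points$name)
  ages <- waterfallAges(heights, ero)
  new("ClockFit", points = fit$points, excluded = fit$excluded,
      slope = fit$slope, intercept = fit$intercept,
      fStatistic = fit$fStatistic, dfNum = fit$dfNum, dfDen = fit$dfDen,
      r2 = fit$r2, pValue = fit$p, rate = rate,
      erosionRate = ero$m_per_yr, ages = ages)
}

#' The surveyed waterfall table
#'
#' The packaged waterfall survey (name, river system, number of steps,
#' total vertical height in metres, and the published age estimate where a
#' dated landlocked population exists; one waterfall has none and carries
#' NA).
#'
#' @return data.frame: name, river, steps, height_m, age_printed_yr
#' @export
waterfallTable <- function() {
  path <- system.file("extdata", "iriomote_waterfalls.csv",
                      package = "gobyclock", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
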