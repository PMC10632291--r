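#' Phenotype-only estimate of total three-way epistasis
#'
#' For homozygous line populations the total additive x additive x additive
#' (aaa) epistatic effect can be estimated from line means alone as half
#' the sum of the extreme line means minus the grand mean,
#' \deqn{\widehat{aaa}_p = \tfrac12 (L_{max} + L_{min}) - \bar L ,}
#' which is zero when the extremes are symmetric about the population mean.
#' Ties for the extreme lines do not affect the estimate.
#'
#' @param lineMeans numeric vector of per-line trait means (>= 2 lines)
#' @return an \linkS4class{AaaPhenotypic} (F statistic unset; see
#'   \code{\link{testAaaP}})
#' @examples
#' estimateAaaP(c(2.65, 98.26, rep(45.48, 10)))
#' @export
estimateAaaP <- function(lineMeans) {
  lineMeans <- as.numeric(lineMeans)
  if (length(lineMeans) < 2L || any(!is.finite(lineMeans)))
    stop("need >= 2 finite line means")
  lmin <- min(lineMeans); lmax <- max(lineMeans)
  gm <- mean(lineMeans)
  new("AaaPhenotypic", estimate = (lmax + lmin) / 2 - gm,
      Lmin = lmin, Lmax = lmax, grandMean = gm,
      Fstat = NA_real_, pValue = NA_real_, nLines = length(lineMeans))
}

#' Extreme-line contrast F test for the phenotypic aaa estimate
#'
#' Tests the phenotypic total-epistasis estimate against zero as a single
#' degree-of-freedom contrast over line means, with contrast coefficients
#' \eqn{1/2 - 1/n} on the lines attaining the minimum and maximum mean and
#' \eqn{-1/n} elsewhere (first line in input order taken on ties). The
#' contrast sum of squares is \eqn{est^2 / \sum_i c_i^2 / r_i} with
#' \eqn{r_i} the replicate count of line \eqn{i}; the denominator is the
#' pooled within-line replicate mean square, giving
#' \eqn{F = MS_{aaa_p} / MS_e} on \eqn{(1, \sum_i (r_i - 1))} degrees of
#' freedom. Because the extreme lines are located from the data, the test
#' is conservative rather than exactly calibrated; it remains a valid test
#' of no genetic signal.
#'
#' @param pheno a \linkS4class{PhenotypeSet} with at least one line
#'   replicated (otherwise the within-line error is not estimable and an
#'   error asks for an external error variance)
#' @param errorVariance optional externally supplied replicate error
#'   variance; when given it replaces the pooled MS_e with degrees of
#'   freedom \code{errorDf}
#' @param errorDf denominator degrees of freedom for an external variance
#'   (default Inf)
#' @return an \linkS4class{AaaPhenotypic} with F statistic and p value
#' @export
testAaaP <- function(pheno, errorVariance = NULL, errorDf = Inf) {
  stopifnot(is(pheno, "PhenotypeSet"))
  m <- lineMeans(pheno)
  r <- replicateCounts(pheno)
  n <- length(m)
  est <- estimateAaaP(m)
  cc <- rep(-1 / n, n)
  cc[which.min(m)] <- cc[which.min(m)] + 0.5
  cc[which.max(m)] <- cc[which.max(m)] + 0.5
  ss <- est@estimate^2 / sum(cc^2 / r)
  if (is.null(errorVariance)) {
    dfe <- sum(r - 1L)
    if (dfe < 1L)
      stop("no replicated lines: supply errorVariance (and errorDf) to test aaa_p")
    rec <- pheno@records
    mse <- sum((rec$value - m[rec$line_id])^2) / dfe
  } else {
    mse <- errorVariance
    dfe <- errorDf
  }
  Fstat <- if (mse > 0) ss / mse else if (ss == 0) 0 else Inf
  p <- stats::pf(Fstat, 1, dfe, lower.tail = FALSE)
  initialize(est, Fstat = Fstat, pValue = p)
}

#' Wright-type number of effective factors
#'
#' Estimates the number of segregating loci (effective factors) behind a
#' trait from the phenotypic range of line means and the genetic variance,
#' \deqn{\hat k = (L_{max} - L_{min})^2 / (4\, V_g),}
#' with \eqn{V_g} the variance of line means minus
#' \code{errorVariance / nReps}, floored at zero. The divisor 4 is the
#' calibration for fully homozygous line populations: k unlinked loci of
#' equal effect a give a genetic variance of \eqn{k a^2} among DH lines
#' and a range of \eqn{2 k a}, so \eqn{(2ka)^2/(4ka^2) = k} exactly
#' (the classical divisor 8 belongs to F2 metrics, where the per-locus
#' variance is halved). The ratio is invariant under shifting or rescaling
#' the trait. Returns 0 when the genetic variance estimate is 0. This is a
#' documented range-based variant; it is validated by simulation recovery,
#' not against any published gene count.
#'
#' @param lineMeans numeric per-line trait means
#' @param errorVariance nonnegative replicate error variance (0 = treat
#'   line means as noise-free)
#' @param nReps replicate count used to form the line means (default 1)
#' @return list with \code{kHat} (real), \code{k} (rounded integer) and
#'   \code{geneticVariance}
#' @export
effectiveFactors <- function(lineMeans, errorVariance = 0, nReps = 1) {
  lineMeans <- as.numeric(lineMeans)
  if (length(lineMeans) < 2L) stop("need >= 2 line means")
  if (errorVariance < 0 || nReps < 1) stop("negative inputs")
  vg <- max(stats::var(lineMeans) - errorVariance / nReps, 0)
  kHat <- if (vg > 0) (max(lineMeans) - min(lineMeans))^2 / (4 * vg) else 0
  list(kHat = kHat, k = as.integer(round(kHat)), geneticVariance = vg)
}
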