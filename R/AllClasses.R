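#' @import methods
NULL

#' GenotypeMatrix: marker genotypes of homozygous lines
#'
#' Lines x markers matrix of marker scores for a population of fully
#' homozygous (doubled-haploid or recombinant-inbred) lines. Raw scores are
#' coded -1/+1 by parental origin; missing scores are \code{NA}; imputed
#' scores are conditional expectations and may be any real value in
#' \eqn{[-1, +1]}. Row names are line identifiers, column names marker
#' identifiers, both unique.
#'
#' @slot values numeric matrix, rows = lines, columns = markers; non-missing
#'   entries in \eqn{[-1, +1]}.
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", representation(values = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry line (row) and marker (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate line ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate marker ids")
  }
  if (is.numeric(v)) {
    ok <- is.na(v) | (v >= -1 & v <= 1)
    if (!all(ok)) msg <- c(msg, "genotype entries must lie in [-1, +1] or be NA")
  }
  if (length(msg)) msg else TRUE
})

#' LinkageMap: marker positions on linkage groups
#'
#' Maps marker identifiers to a linkage group and a centimorgan (cM)
#' position within that group. Positions drive recombination-fraction
#' calculations for imputation and for genotype simulation.
#'
#' @slot map data.frame with columns \code{marker_id} (unique character),
#'   \code{group} (character), \code{position_cM} (nonnegative numeric).
#' @aliases LinkageMap
#' @exportClass LinkageMap
setClass("LinkageMap", representation(map = "data.frame"))

setValidity("LinkageMap", function(object) {
  m <- object@map
  need <- c("marker_id", "group", "position_cM")
  if (!all(need %in% names(m)))
    return(sprintf("map must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(m$marker_id)) msg <- c(msg, "duplicate marker_id in map")
  if (nrow(m) && (!is.numeric(m$position_cM) || any(!is.finite(m$position_cM)) ||
                  any(m$position_cM < 0)))
    msg <- c(msg, "position_cM must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' PhenotypeSet: replicated phenotype observations per line
#'
#' Long-format trait observations \code{(line_id, rep, value)}. Per-line
#' means feed the regression models as the response; per-line replicate
#' variances supply the diagonal weights of the weighted fit.
#'
#' @slot records data.frame with columns \code{line_id} (character),
#'   \code{rep} (integer replicate index), \code{value} (numeric).
#' @aliases PhenotypeSet
#' @exportClass PhenotypeSet
setClass("PhenotypeSet", representation(records = "data.frame"))

setValidity("PhenotypeSet", function(object) {
  r <- object@records
  need <- c("line_id", "rep", "value")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) && !is.numeric(r$value)) return("'value' must be numeric")
  if (nrow(r) && anyDuplicated(r[c("line_id", "rep")]))
    return("duplicate (line_id, rep) record")
  TRUE
})

#' ModelDesign: interaction design matrix [1 X Z W]
#'
#' Column-bound design of the three-way epistasis model: an intercept,
#' additive marker columns X, pairwise product columns Z and three-way
#' product columns W. The term table records the provenance of every
#' column; pairs and triples are stored with markers in additive order so
#' each unordered set appears exactly once.
#'
#' @slot G numeric matrix, n lines x (1 + p + pairs + triples).
#' @slot terms data.frame with columns \code{label}, \code{type}
#'   (intercept/additive/pair/triple), \code{m1}, \code{m2}, \code{m3}.
#' @aliases ModelDesign
#' @exportClass ModelDesign
setClass("ModelDesign", representation(G = "matrix", terms = "data.frame"))

setValidity("ModelDesign", function(object) {
  if (ncol(object@G) != nrow(object@terms))
    return("term table and design width disagree")
  if (!all(c("label", "type", "m1", "m2", "m3") %in% names(object@terms)))
    return("terms must have columns label, type, m1, m2, m3")
  TRUE
})

#' ModelFit: a fitted (un)weighted epistasis regression
#'
#' Least-squares fit of line means on a \linkS4class{ModelDesign}, either
#' ordinary or weighted by inverse per-line variances. Coefficient
#' covariance is the classical \eqn{\hat\sigma^2 (G'W^{-1}G)^{-1}} with
#' \eqn{\hat\sigma^2} the (weighted) residual mean square, so the supplied
#' variances act as relative, not absolute, weights.
#'
#' @slot coefficients named numeric vector over the design terms.
#' @slot vcov coefficient covariance matrix.
#' @slot residuals,fitted numeric vectors on the line-mean scale.
#' @slot sigma2 residual mean square (weighted when weighted).
#' @slot df.residual integer residual degrees of freedom.
#' @slot weights per-line regression weights actually used (unit when
#'   unweighted).
#' @slot weighted logical flag.
#' @slot r2 coefficient of determination (weighted centring when weighted).
#' @slot terms the design's term table, restricted to fitted columns.
#' @slot y the response used for the fit.
#' @aliases ModelFit
#' @exportClass ModelFit
setClass("ModelFit", representation(
  coefficients = "numeric", vcov = "matrix", residuals = "numeric",
  fitted = "numeric", sigma2 = "numeric", df.residual = "integer",
  weights = "numeric", weighted = "logical", r2 = "numeric",
  terms = "data.frame", y = "numeric"))

#' SelectedModel: outcome of the staged marker selection
#'
#' Markers and interaction terms surviving the three selection stages:
#' per-linkage-group stepwise AIC with a significance filter, the pooled
#' stepwise repeat, and the final stepwise pass over pairwise and triple
#' product terms with additive survivors protected. Every retained pair or
#' triple references retained additive markers only.
#'
#' @slot additive character vector of retained additive marker ids, in map
#'   order.
#' @slot pairs data.frame (m1, m2) of retained pairwise terms.
#' @slot triples data.frame (m1, m2, m3) of retained triple terms.
#' @slot log data.frame selection trace: stage, group, action, term, aic.
#' @slot config the \code{\link{selectionConfig}} list used.
#' @aliases SelectedModel
#' @exportClass SelectedModel
setClass("SelectedModel", representation(
  additive = "character", pairs = "data.frame", triples = "data.frame",
  log = "data.frame", config = "list"))

setValidity("SelectedModel", function(object) {
  ms <- c(unlist(object@pairs), unlist(object@triples))
  if (length(ms) && !all(ms %in% object@additive))
    return("interaction terms must reference retained additive markers only")
  TRUE
})

#' AaaPhenotypic: phenotype-only total three-way epistasis estimate
#'
#' @slot estimate the total aaa effect, half the sum of the extreme line
#'   means minus the grand mean, in trait units.
#' @slot Lmin,Lmax,grandMean extreme and overall line means.
#' @slot Fstat,pValue extreme-line contrast F statistic against pooled
#'   within-line error, and its p value (NA when untested).
#' @slot nLines number of lines.
#' @aliases AaaPhenotypic
#' @exportClass AaaPhenotypic
setClass("AaaPhenotypic", representation(
  estimate = "numeric", Lmin = "numeric", Lmax = "numeric",
  grandMean = "numeric", Fstat = "numeric", pValue = "numeric",
  nLines = "integer"))

setValidity("AaaPhenotypic", function(object) {
  if (length(object@estimate) != 1L) return("estimate must be scalar")
  if (object@Lmin > object@grandMean || object@grandMean > object@Lmax)
    return("grand mean must lie between the extreme line means")
  TRUE
})
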