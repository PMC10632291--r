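#' Construct a GenotypeMatrix
#'
#' @param values numeric matrix of genotype scores, non-missing entries in
#'   \eqn{[-1, +1]} (raw data: exactly -1 or +1).
#' @param lineIds,markerIds optional identifier vectors; default taken from
#'   the matrix dimnames.
#' @return a \linkS4class{GenotypeMatrix}
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, -1, -1, 1), 2, 2,
#'   dimnames = list(c("L1", "L2"), c("M1", "M2"))))
#' nLines(g)
#' @export
GenotypeMatrix <- function(values, lineIds = rownames(values),
                           markerIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- as.character(lineIds)
  colnames(values) <- as.character(markerIds)
  new("GenotypeMatrix", values = values)
}

#' Construct a LinkageMap
#'
#' @param marker_id character marker identifiers (unique)
#' @param group linkage-group labels
#' @param position_cM nonnegative positions in centimorgans
#' @return a \linkS4class{LinkageMap}
#' @export
LinkageMap <- function(marker_id, group, position_cM) {
  new("LinkageMap", map = data.frame(
    marker_id = as.character(marker_id),
    group = as.character(group),
    position_cM = as.numeric(position_cM),
    stringsAsFactors = FALSE))
}

#' Construct a PhenotypeSet
#'
#' @param line_id line identifiers (repeated across replicates)
#' @param rep replicate index within line
#' @param value numeric trait observation
#' @return a \linkS4class{PhenotypeSet}
#' @export
PhenotypeSet <- function(line_id, rep, value) {
  new("PhenotypeSet", records = data.frame(
    line_id = as.character(line_id),
    rep = as.integer(rep),
    value = as.numeric(value),
    stringsAsFactors = FALSE))
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@values))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@values))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genoValues", "GenotypeMatrix", function(x) x@values)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLines", "GenotypeMatrix", function(x) nrow(x@values))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@values))

#' @rdname LinkageMap-class
#' @param x a \linkS4class{LinkageMap}
#' @export
setMethod("markerIds", "LinkageMap", function(x) x@map$marker_id)

#' Map table of a LinkageMap, ordered by group then position
#'
#' @param x a \linkS4class{LinkageMap}
#' @return data.frame (marker_id, group, position_cM) sorted within group
#' @export
mapTable <- function(x) {
  stopifnot(is(x, "LinkageMap"))
  m <- x@map
  m[order(m$group, m$position_cM, m$marker_id), , drop = FALSE]
}

#' @rdname PhenotypeSet-class
#' @export
setMethod("lineIds", "PhenotypeSet", function(x) unique(x@records$line_id))

#' @describeIn PhenotypeSet-class per-line mean of replicate observations,
#'   in first-appearance line order.
#' @param ... unused
#' @export
setMethod("lineMeans", "PhenotypeSet", function(x, ...) {
  r <- x@records
  ids <- unique(r$line_id)
  m <- vapply(split(r$value, factor(r$line_id, levels = ids)), mean, 0)
  m[ids]
})

#' @describeIn PhenotypeSet-class per-line replicate sample variance, the
#'   w_ii of the weighted regression. Lines with a single replicate have no
#'   raw variance; with \code{fallback = "median"} (default) they receive
#'   the median of the available line variances, and when no line is
#'   replicated all variances fall back to 1 (unit weights) with a warning.
#'   \code{fallback = "none"} leaves them NA.
#' @param fallback "median" or "none"
#' @export
setMethod("lineVariances", "PhenotypeSet", function(x, fallback = c("median", "none"), ...) {
  fallback <- match.arg(fallback)
  r <- x@records
  ids <- unique(r$line_id)
  v <- vapply(split(r$value, factor(r$line_id, levels = ids)),
              function(z) if (length(z) >= 2L) stats::var(z) else NA_real_, 0)
  v <- v[ids]
  if (fallback == "median" && anyNA(v)) {
    if (all(is.na(v))) {
      warning("no line has >= 2 replicates; falling back to unit weights")
      v[] <- 1
    } else {
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    }
  }
  v
})

#' @describeIn PhenotypeSet-class number of replicates per line.
#' @export
setMethod("replicateCounts", "PhenotypeSet", function(x) {
  r <- x@records
  ids <- unique(r$line_id)
  n <- vapply(split(r$value, factor(r$line_id, levels = ids)), length, 0L)
  n[ids]
})

#' @rdname ModelDesign-class
#' @param x a \linkS4class{ModelDesign}
#' @export
setMethod("designMatrix", "ModelDesign", function(x) x@G)

#' @rdname ModelDesign-class
#' @export
setMethod("termInfo", "ModelDesign", function(x) x@terms)

#' @rdname ModelFit-class
#' @param object a \linkS4class{ModelFit}
#' @export
setMethod("coef", "ModelFit", function(object) object@coefficients)

#' @rdname ModelFit-class
#' @export
setMethod("residuals", "ModelFit", function(object) object@residuals)

#' @rdname ModelFit-class
#' @export
setMethod("fitted", "ModelFit", function(object) object@fitted)

#' @rdname ModelFit-class
#' @export
setMethod("vcov", "ModelFit", function(object) object@vcov)

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  nmiss <- sum(is.na(v))
  cat(sprintf("GenotypeMatrix: %d lines x %d markers (%.2f%% missing)\n",
              nrow(v), ncol(v), if (length(v)) 100 * nmiss / length(v) else 0))
})

setMethod("show", "LinkageMap", function(object) {
  m <- object@map
  cat(sprintf("LinkageMap: %d markers on %d linkage group(s), %.1f cM total\n",
              nrow(m), length(unique(m$group)),
              sum(vapply(split(m$position_cM, m$group),
                         function(p) if (length(p)) max(p) - min(p) else 0, 0))))
})

setMethod("show", "PhenotypeSet", function(object) {
  r <- object@records
  cat(sprintf("PhenotypeSet: %d observations on %d lines (reps %s)\n",
              nrow(r), length(unique(r$line_id)),
              paste(range(replicateCounts(object)), collapse = "-")))
})

setMethod("show", "ModelDesign", function(object) {
  tt <- table(factor(object@terms$type,
                     levels = c("intercept", "additive", "pair", "triple")))
  cat(sprintf("ModelDesign: %d lines x %d columns (%d additive, %d pair, %d triple)\n",
              nrow(object@G), ncol(object@G), tt["additive"], tt["pair"], tt["triple"]))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (%s): %d terms, df.residual = %d, R2 = %.3f\n",
              if (object@weighted) "weighted" else "unweighted",
              length(object@coefficients), object@df.residual, object@r2))
})

setMethod("show", "SelectedModel", function(object) {
  cat(sprintf("SelectedModel: %d additive marker(s), %d pair(s), %d triple(s)\n",
              length(object@additive), nrow(object@pairs), nrow(object@triples)))
})

setMethod("show", "AaaPhenotypic", function(object) {
  cat(sprintf("aaa_p = %.4f  (Lmin %.4g, Lmax %.4g, mean %.4g, n = %d)\n",
              object@estimate, object@Lmin, object@Lmax, object@grandMean,
              object@nLines))
  if (is.finite(object@Fstat))
    cat(sprintf("  F = %.4g, p = %.4g\n", object@Fstat, object@pValue))
})
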