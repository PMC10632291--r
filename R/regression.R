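.fitCore <- function(y, design, regWeights, weighted) {
  stopifnot(is(design, "ModelDesign"))
  y <- as.numeric(y)
  G <- designMatrix(design)
  n <- nrow(G)
  if (length(y) != n) stop("length(y) must match the design")
  if (n <= ncol(G))
    stop("need more lines than design columns (n = ", n, ", columns = ",
         ncol(G), ")")
  qrG <- qr(G)
  if (qrG$rank < ncol(G))
    stop("design is rank deficient; run checkFullRank()/dropAliased() first")
  fit <- stats::lm.wfit(G, y, regWeights)
  res <- y - G %*% fit$coefficients
  df <- n - ncol(G)
  s2 <- sum(regWeights * res^2) / df
  R <- fit$qr
  XtXinv <- chol2inv(R$qr[seq_len(ncol(G)), , drop = FALSE])
  # undo lm.wfit's pivoting
  piv <- R$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  vc <- s2 * XtXinv
  dimnames(vc) <- list(colnames(G), colnames(G))
  wmean <- sum(regWeights * y) / sum(regWeights)
  tss <- sum(regWeights * (y - wmean)^2)
  r2 <- if (tss > 0) 1 - sum(regWeights * res^2) / tss else NA_real_
  cf <- fit$coefficients
  names(cf) <- colnames(G)
  new("ModelFit", coefficients = cf, vcov = vc,
      residuals = as.numeric(res), fitted = as.numeric(G %*% cf),
      sigma2 = s2, df.residual = as.integer(df),
      weights = regWeights, weighted = weighted, r2 = r2,
      terms = termInfo(design), y = y)
}

#' Ordinary least-squares fit of the epistasis model
#'
#' Solves \eqn{\hat\alpha_u = (G'G)^{-1} G' y} for a full-rank design
#' \eqn{G = [1\; X\; Z\; W]}, with classical coefficient covariance
#' \eqn{\hat\sigma^2 (G'G)^{-1}}, \eqn{\hat\sigma^2} the residual mean
#' square.
#'
#' @param y numeric line means
#' @param design a full-rank \linkS4class{ModelDesign} (see
#'   \code{\link{dropAliased}})
#' @return a \linkS4class{ModelFit}
#' @export
fitUnweighted <- function(y, design) {
  .fitCore(y, design, rep(1, nrow(designMatrix(design))), weighted = FALSE)
}

#' Weighted least-squares fit with per-line variances
#'
#' Solves \eqn{\hat\alpha_w = (G' V^{-1} G)^{-1} G' V^{-1} y} with
#' \eqn{V = diag(w_{ii})}, the estimated replicate variance of each line,
#' i.e. regression weights \eqn{1/w_{ii}}. Coefficient covariance is
#' \eqn{\hat\sigma^2_w (G'V^{-1}G)^{-1}} with \eqn{\hat\sigma^2_w} the
#' weighted residual mean square, so the \eqn{w_{ii}} act as relative
#' weights: with all \eqn{w_{ii}} equal the fit coincides with
#' \code{\link{fitUnweighted}}.
#'
#' @param y numeric line means
#' @param design a full-rank \linkS4class{ModelDesign}
#' @param lineVariances strictly positive per-line variances \eqn{w_{ii}}
#'   (see \code{\link{lineVariances}} for the estimation fallbacks)
#' @return a \linkS4class{ModelFit}
#' @export
fitWeighted <- function(y, design, lineVariances) {
  lineVariances <- as.numeric(lineVariances)
  if (length(lineVariances) != nrow(designMatrix(design)))
    stop("one variance per line required")
  if (any(!is.finite(lineVariances)) || any(lineVariances <= 0))
    stop("line variances must be finite and > 0")
  .fitCore(y, design, 1 / lineVariances, weighted = TRUE)
}

#' Per-coefficient t tests
#'
#' @param fit a \linkS4class{ModelFit}
#' @return data.frame(term, type, estimate, se, t, p) over all fitted
#'   terms; two-sided p from the t distribution on the residual df
#' @export
coefficientTests <- function(fit) {
  stopifnot(is(fit, "ModelFit"))
  est <- fit@coefficients
  se <- sqrt(diag(fit@vcov))
  tt <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  p <- 2 * stats::pt(abs(tt), fit@df.residual, lower.tail = FALSE)
  data.frame(term = names(est), type = fit@terms$type, estimate = est,
             se = se, t = tt, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Total three-way epistasis from a fitted model
#'
#' Sums the fitted triple-interaction coefficients into the total aaa
#' effect (the genotypic analogue of the phenotypic estimate), along with
#' their range and count. By default only triples significant at
#' \code{alpha} (coefficient t test) enter the total, mirroring how
#' significant threes are counted and totalled per trait;
#' \code{which = "allRetained"} sums every triple in the fit.
#'
#' @param fit a \linkS4class{ModelFit}
#' @param which "significantOnly" (default) or "allRetained"
#' @param alpha significance level for "significantOnly" (default 0.001)
#' @return list(total, min, max, count, triples = data.frame with per-
#'   triple estimate, t and p). Zero triples give total 0 and NA range.
#' @export
totalAaa <- function(fit, which = c("significantOnly", "allRetained"),
                     alpha = 0.001) {
  which <- match.arg(which)
  ct <- coefficientTests(fit)
  tr <- ct[ct$type == "triple", , drop = FALSE]
  tr <- cbind(fit@terms[fit@terms$type == "triple", c("m1", "m2", "m3")], tr)
  if (which == "significantOnly")
    tr <- tr[is.finite(tr$p) & tr$p < alpha, , drop = FALSE]
  rownames(tr) <- NULL
  if (!nrow(tr))
    return(list(total = 0, min = NA_real_, max = NA_real_, count = 0L,
                triples = tr))
  list(total = sum(tr$estimate), min = min(tr$estimate),
       max = max(tr$estimate), count = nrow(tr), triples = tr)
}

#' Percent phenotypic variance explained by one triple
#'
#' The variance attributed to a single triple-interaction term: the drop
#' in residual sum of squares when the triple's column is added back to
#' the model containing every other fitted term, as a percentage of the
#' total (weighted) sum of squares of the response about its (weighted)
#' mean. Both refits use the weighting of the supplied fit.
#'
#' @param y the response used for the fit
#' @param design the \linkS4class{ModelDesign} the fit was computed on
#' @param fit a \linkS4class{ModelFit} containing the triple
#' @param triple the triple's column label ("m1:m2:m3") or a character
#'   vector of its three marker ids
#' @return percent in [0, 100]
#' @export
tripleVarianceExplained <- function(y, design, fit, triple) {
  stopifnot(is(design, "ModelDesign"), is(fit, "ModelFit"))
  if (length(triple) == 3L) {
    ti <- fit@terms
    hit <- ti$type == "triple" &
      apply(ti[c("m1", "m2", "m3")], 1L, function(m) setequal(m, triple))
    if (!any(hit)) stop("triple not present in fit")
    triple <- ti$label[hit][1L]
  }
  labs <- fit@terms$label
  if (!(triple %in% labs)) stop("triple not present in fit")
  y <- as.numeric(y)
  G <- designMatrix(design)[, labs, drop = FALSE]
  w <- fit@weights
  rssOf <- function(M) {
    f <- stats::lm.wfit(M, y, w)
    sum(w * (y - M %*% f$coefficients)^2)
  }
  rss1 <- rssOf(G)
  rss0 <- rssOf(G[, setdiff(labs, triple), drop = FALSE])
  wmean <- sum(w * y) / sum(w)
  tss <- sum(w * (y - wmean)^2)
  if (tss <= 0) return(0)
  max(0, 100 * (rss0 - rss1) / tss)
}

#' Per-triple report for a pair of fits
#'
#' Tabulates every triple retained in the design across the unweighted
#' and weighted fits: both estimates, t tests and percent variance
#' explained, plus the per-fit totals over significant triples.
#'
#' @param y line means
#' @param design the fitted \linkS4class{ModelDesign}
#' @param fitU,fitW unweighted and weighted \linkS4class{ModelFit}s on
#'   that design (either may be NULL)
#' @param alpha significance level used for the totals (default 0.001)
#' @return list(triples = data.frame, totals = data.frame)
#' @export
tripleReport <- function(y, design, fitU = NULL, fitW = NULL, alpha = 0.001) {
  ti <- termInfo(design)
  tr <- ti[ti$type == "triple", , drop = FALSE]
  out <- data.frame(QTL1 = tr$m1, QTL2 = tr$m2, QTL3 = tr$m3,
                    stringsAsFactors = FALSE)
  totals <- list()
  for (tag in c("gu", "gw")) {
    fit <- if (tag == "gu") fitU else fitW
    if (is.null(fit)) next
    ct <- coefficientTests(fit)
    ct <- ct[match(tr$label, ct$term), , drop = FALSE]
    out[[paste0("aaa_", tag)]] <- ct$estimate
    out[[paste0("p_", tag)]] <- ct$p
    out[[paste0("pctvar_", tag)]] <- vapply(tr$label, function(lb)
      tripleVarianceExplained(y, design, fit, lb), 0)
    tot <- totalAaa(fit, alpha = alpha)
    totals[[tag]] <- data.frame(model = tag, count = tot$count,
                                min = tot$min, max = tot$max,
                                total = tot$total, r2 = fit@r2,
                                stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  list(triples = out, totals = do.call(rbind, totals))
}
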