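#' Selection configuration
#'
#' Settings for the staged marker selection. \code{alphaStep} is the
#' critical significance level applied to additive coefficients after each
#' stepwise stage and to triple coefficients in the final model;
#' \code{bonferroni} divides it by the number of candidate terms tested in
#' the current stage. \code{hierarchical} restricts triples to markers
#' whose three constituent pairs were retained (sensitivity analysis;
#' default off, pairs and triples compete in one stepwise pool).
#'
#' @param alphaStep significance level in (0, 1], default 0.001
#' @param bonferroni divide alphaStep by the per-stage candidate count
#' @param maxAdditive optional cap on additive markers after the pooled
#'   stage (most significant kept)
#' @param hierarchical logical, see above
#' @param maxOrder highest interaction order built in the final stage
#' @return list of class "selectionConfig"
#' @export
selectionConfig <- function(alphaStep = 0.001, bonferroni = TRUE,
                            maxAdditive = NULL, hierarchical = FALSE,
                            maxOrder = 3) {
  stopifnot(alphaStep > 0, alphaStep <= 1)
  structure(list(alphaStep = alphaStep, bonferroni = bonferroni,
                 maxAdditive = maxAdditive, hierarchical = hierarchical,
                 maxOrder = maxOrder),
            class = "selectionConfig")
}

#' Greedy stepwise selection by AIC
#'
#' Bidirectional stepwise selection over the columns of a candidate
#' matrix, with an optional block of forced-in columns (always including
#' an intercept). At every step the single addition or removal giving the
#' lowest Gaussian AIC, \eqn{n \log(RSS/n) + 2k} (constants omitted, k =
#' fitted rank), is applied; the search stops when no move strictly
#' improves AIC. Ties are broken deterministically: additions are
#' considered before removals, candidates in column order, and the first
#' of the tied best moves wins. Additions stop when the model size would
#' leave fewer than 2 residual degrees of freedom. A zero-variance
#' response selects nothing.
#'
#' @param y numeric response (line means)
#' @param candidates numeric matrix of candidate columns (may have 0
#'   columns)
#' @param forced numeric matrix of columns kept in the model throughout
#'   (default: intercept only; an intercept is always prepended)
#' @return list(selected = integer column indices in selection order,
#'   log = data.frame(step, action, term, aic))
#' @export
stepwiseAIC <- function(y, candidates, forced = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  candidates <- as.matrix(candidates)
  if (nrow(candidates) && ncol(candidates) && nrow(candidates) != n)
    stop("candidate rows must match length(y)")
  F0 <- cbind(`(Intercept)` = rep(1, n), forced)
  log0 <- data.frame(step = integer(), action = character(),
                     term = character(), aic = numeric(),
                     stringsAsFactors = FALSE)
  if (ncol(candidates) == 0L || stats::var(y) == 0)
    return(list(selected = integer(), log = log0))
  cn <- colnames(candidates)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(candidates)))
  rssFloor <- 1e-12 * sum(y^2) + 1e-300  # saturated fits compare equal
  aicOf <- function(S) {
    f <- .lm.fit(cbind(F0, candidates[, S, drop = FALSE]), y)
    rss <- max(sum(f$residuals^2), rssFloor)
    n * log(rss / n) + 2 * f$rank
  }
  S <- integer()
  cur <- aicOf(S)
  logs <- list(data.frame(step = 0L, action = "start", term = "",
                          aic = cur, stringsAsFactors = FALSE))
  maxSize <- n - ncol(F0) - 2L
  step <- 0L
  repeat {
    step <- step + 1L
    bestAic <- cur; bestMove <- NULL
    if (length(S) < maxSize) {
      for (j in setdiff(seq_len(ncol(candidates)), S)) {
        a <- aicOf(c(S, j))
        if (a < bestAic - 1e-10) { bestAic <- a; bestMove <- c(1L, j) }
      }
    }
    for (j in S) {
      a <- aicOf(setdiff(S, j))
      if (a < bestAic - 1e-10) { bestAic <- a; bestMove <- c(-1L, j) }
    }
    if (is.null(bestMove)) break
    if (bestMove[1L] > 0) S <- c(S, bestMove[2L]) else S <- setdiff(S, bestMove[2L])
    cur <- bestAic
    logs[[length(logs) + 1L]] <- data.frame(
      step = step, action = if (bestMove[1L] > 0) "add" else "drop",
      term = cn[bestMove[2L]], aic = cur, stringsAsFactors = FALSE)
  }
  list(selected = S, log = do.call(rbind, logs))
}

# Backward-eliminate columns of X (given forced) until every survivor's
# coefficient is significant at thr: refit after each single drop, so a
# column is never discarded for collinearity with columns that are
# themselves on the way out. Returns the kept column indices of X.
.backwardFilter <- function(y, forced, X, thr) {
  keep <- seq_len(ncol(X))
  while (length(keep)) {
    p <- .blockPvalues(y, forced, X[, keep, drop = FALSE])
    p[is.na(p)] <- Inf   # aliased: drop first
    if (all(p < thr)) break
    keep <- keep[-which.max(p)]
  }
  keep
}

# t-test p-values for the candidate block of an OLS fit [forced | X_S]
.blockPvalues <- function(y, forced, X) {
  G <- cbind(forced, X)
  fit <- stats::lm.fit(G, y)
  df <- length(y) - fit$rank
  if (df < 1L) return(rep(NA_real_, ncol(X)))
  s2 <- sum(fit$residuals^2) / df
  R <- fit$qr
  cv <- s2 * chol2inv(R$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  se <- rep(NA_real_, ncol(G))
  se[R$pivot[seq_len(fit$rank)]] <- sqrt(diag(cv))
  tt <- fit$coefficients / se
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[seq.int(ncol(forced) + 1L, ncol(G))]
}

#' Staged marker and interaction selection
#'
#' The full selection protocol for one trait. Stage 1 runs stepwise AIC
#' (\code{\link{stepwiseAIC}}) separately within every linkage group over
#' that group's additive marker columns, then discards selected markers
#' whose additive coefficient fails a t test at \code{alphaStep}
#' (Bonferroni-corrected by the group's candidate count). The discard is
#' by backward elimination -- the single least significant marker is
#' dropped and the model refitted until every survivor passes -- so that
#' a true marker is not discarded merely because collinear neighbours,
#' themselves about to be dropped, inflate its standard error. Stage 2
#' pools the survivors of all groups and repeats stepwise AIC plus the
#' significance filter over the pooled candidates. Stage 3 builds all
#' pairwise and three-way product terms over the surviving additive
#' markers and runs stepwise AIC over the interaction terms with the
#' additive survivors protected in the model; retained triples must in
#' addition pass the same backward-eliminating filter at \code{alphaStep}
#' in the final unweighted fit. Fewer than three surviving additive
#' markers therefore yield zero triples. Selection is unweighted
#' throughout; weights enter only at the final estimation stage.
#'
#' @param y numeric line means, aligned with \code{geno} rows
#' @param geno complete \linkS4class{GenotypeMatrix}
#' @param map \linkS4class{LinkageMap}; markers absent from the map form
#'   their own "unplaced" stage-1 group
#' @param config a \code{\link{selectionConfig}}
#' @return a \linkS4class{SelectedModel}
#' @export
selectMarkers <- function(y, geno, map, config = selectionConfig()) {
  stopifnot(is(geno, "GenotypeMatrix"), is(map, "LinkageMap"),
            inherits(config, "selectionConfig"))
  v <- genoValues(geno)
  if (anyNA(v)) stop("selection requires complete genotypes; impute first")
  y <- as.numeric(y)
  if (length(y) != nrow(v)) stop("length(y) must equal the number of lines")
  mt <- mapTable(map)
  ord <- c(intersect(mt$marker_id, colnames(v)),
           setdiff(colnames(v), mt$marker_id))
  grp <- mt$group[match(ord, mt$marker_id)]
  grp[is.na(grp)] <- "<unplaced>"
  alpha <- function(ncand) {
    if (config$bonferroni && ncand > 0) config$alphaStep / ncand else config$alphaStep
  }
  logs <- list()
  addLog <- function(stage, group, df) {
    if (nrow(df)) logs[[length(logs) + 1L]] <<-
      cbind(stage = stage, group = group, df, stringsAsFactors = FALSE)
  }
  emptyModel <- function() new("SelectedModel",
    additive = character(), pairs = data.frame(m1 = character(), m2 = character()),
    triples = data.frame(m1 = character(), m2 = character(), m3 = character()),
    log = .bindLogs(logs), config = unclass(config))

  # stage 1: within linkage groups
  survivors <- character()
  for (g in unique(grp)) {
    mk <- ord[grp == g]
    X <- v[, mk, drop = FALSE]
    sw <- stepwiseAIC(y, X)
    addLog("group", g, sw$log)
    sel <- mk[sw$selected]
    if (length(sel)) {
      keepIdx <- .backwardFilter(y, matrix(1, length(y), 1),
                                 v[, sel, drop = FALSE], alpha(length(mk)))
      dropped <- sel[setdiff(seq_along(sel), keepIdx)]
      addLog("group", g, if (length(dropped)) data.frame(
        step = NA_integer_, action = "filter-drop", term = dropped,
        aic = NA_real_, stringsAsFactors = FALSE) else data.frame())
      survivors <- c(survivors, sel[keepIdx])
    }
  }
  survivors <- ord[ord %in% survivors]
  if (!length(survivors)) return(emptyModel())

  # stage 2: pooled
  Xp <- v[, survivors, drop = FALSE]
  sw2 <- stepwiseAIC(y, Xp)
  addLog("pooled", "", sw2$log)
  sel2 <- survivors[sw2$selected]
  if (length(sel2)) {
    keep2 <- .backwardFilter(y, matrix(1, length(y), 1),
                             v[, sel2, drop = FALSE], alpha(length(survivors)))
    dropped2 <- sel2[setdiff(seq_along(sel2), keep2)]
    addLog("pooled", "", if (length(dropped2)) data.frame(
      step = NA_integer_, action = "filter-drop", term = dropped2,
      aic = NA_real_, stringsAsFactors = FALSE) else data.frame())
    sel2 <- sel2[keep2]
  }
  additive <- ord[ord %in% sel2]
  if (!is.null(config$maxAdditive) && length(additive) > config$maxAdditive) {
    p3 <- .blockPvalues(y, matrix(1, length(y), 1), v[, additive, drop = FALSE])
    additive <- additive[order(p3)][seq_len(config$maxAdditive)]
    additive <- ord[ord %in% additive]
  }
  if (!length(additive)) return(emptyModel())

  # stage 3: interaction model, additive terms protected
  des <- buildDesign(geno, additive, maxOrder = config$maxOrder)
  ti <- termInfo(des)
  G <- designMatrix(des)
  inter <- ti$type %in% c("pair", "triple")
  pairs <- data.frame(m1 = character(), m2 = character(),
                      stringsAsFactors = FALSE)
  triples <- data.frame(m1 = character(), m2 = character(),
                        m3 = character(), stringsAsFactors = FALSE)
  if (any(inter)) {
    cand <- G[, inter, drop = FALSE]
    tiI <- ti[inter, , drop = FALSE]
    if (config$hierarchical) {
      isPair <- tiI$type == "pair"
      swP <- stepwiseAIC(y, cand[, isPair, drop = FALSE],
                         forced = G[, ti$type == "additive", drop = FALSE])
      addLog("interaction-pairs", "", swP$log)
      keptPairs <- tiI[isPair, ][swP$selected, , drop = FALSE]
      pairKey <- paste(keptPairs$m1, keptPairs$m2)
      okTriple <- vapply(which(tiI$type == "triple"), function(i) {
        m <- unlist(tiI[i, c("m1", "m2", "m3")])
        all(paste(utils::combn(m, 2)[1, ], utils::combn(m, 2)[2, ]) %in% pairKey)
      }, TRUE)
      allowed <- which(isPair)[swP$selected]
      allowed <- c(allowed, which(tiI$type == "triple")[okTriple])
      cand <- cand[, sort(allowed), drop = FALSE]
      tiI <- tiI[sort(allowed), , drop = FALSE]
    }
    sw3 <- stepwiseAIC(y, cand,
                       forced = G[, ti$type == "additive", drop = FALSE])
    addLog("interaction", "", sw3$log)
    kept <- tiI[sw3$selected, , drop = FALSE]
    kept <- kept[order(match(kept$label, ti$label)), , drop = FALSE]
    if (nrow(kept)) {
      # final-fit significance filter for triples (additive + retained
      # pairs held in the model)
      pairs <- kept[kept$type == "pair", c("m1", "m2"), drop = FALSE]
      kt <- kept[kept$type == "triple", , drop = FALSE]
      if (nrow(kt)) {
        forcedF <- cbind(matrix(1, length(y), 1),
                         G[, c(ti$label[ti$type == "additive"],
                               kept$label[kept$type == "pair"]), drop = FALSE])
        keepT <- .backwardFilter(y, forcedF, G[, kt$label, drop = FALSE],
                                 config$alphaStep)
        drp <- kt$label[setdiff(seq_len(nrow(kt)), keepT)]
        addLog("interaction", "", if (length(drp)) data.frame(
          step = NA_integer_, action = "filter-drop", term = drp,
          aic = NA_real_, stringsAsFactors = FALSE) else data.frame())
        kt <- kt[keepT, , drop = FALSE]
      }
      triples <- kt[, c("m1", "m2", "m3"), drop = FALSE]
    }
  }
  rownames(pairs) <- NULL; rownames(triples) <- NULL
  new("SelectedModel", additive = additive, pairs = pairs, triples = triples,
      log = .bindLogs(logs), config = unclass(config))
}

.bindLogs <- function(logs) {
  if (!length(logs))
    return(data.frame(stage = character(), group = character(),
                      step = integer(), action = character(),
                      term = character(), aic = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}
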