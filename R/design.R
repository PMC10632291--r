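#' Assemble the epistasis design matrix [1 X Z W]
#'
#' Builds the linear-model design for line means: an intercept column, one
#' additive column per marker in \code{additiveMarkers} (X), all pairwise
#' elementwise products (Z) and all three-way products (W) over
#' \code{interactionMarkers}, a subset of the additive markers. With
#' complete \eqn{\pm 1} genotypes every product column is again
#' \eqn{\pm 1}; product columns are indexed by the sorted marker set, so
#' each unordered pair/triple appears exactly once and the design is
#' invariant to permutation within a pair or triple. Pair and triple
#' labels join marker ids with \code{":"}.
#'
#' @param geno a complete (post-imputation) \linkS4class{GenotypeMatrix}
#' @param additiveMarkers ordered character vector of marker ids for X
#' @param interactionMarkers marker subset generating Z and W; defaults to
#'   all additive markers
#' @param maxOrder highest interaction order: 1 (X only), 2 (add pairs) or
#'   3 (add triples, default). Fewer than 2 (3) interaction markers simply
#'   yield an empty Z (W).
#' @return a \linkS4class{ModelDesign}
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, -1, 1, -1, -1, -1), 2, 3,
#'   dimnames = list(c("L1", "L2"), c("A", "B", "C"))))
#' termInfo(buildDesign(g, c("A", "B", "C")))
#' @export
buildDesign <- function(geno, additiveMarkers,
                        interactionMarkers = additiveMarkers,
                        maxOrder = 3) {
  stopifnot(is(geno, "GenotypeMatrix"), maxOrder %in% 1:3)
  v <- genoValues(geno)
  unknown <- setdiff(c(additiveMarkers, interactionMarkers), colnames(v))
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (!all(interactionMarkers %in% additiveMarkers))
    stop("interactionMarkers must be a subset of additiveMarkers")
  if (anyNA(v[, additiveMarkers, drop = FALSE]))
    stop("design requires complete genotypes; impute first")
  p <- length(additiveMarkers)
  n <- nrow(v)
  cols <- list(matrix(1, n, 1))
  terms <- data.frame(label = "(Intercept)", type = "intercept",
                      m1 = NA_character_, m2 = NA_character_,
                      m3 = NA_character_, stringsAsFactors = FALSE)
  if (p) {
    cols <- c(cols, list(v[, additiveMarkers, drop = FALSE]))
    terms <- rbind(terms, data.frame(
      label = additiveMarkers, type = "additive", m1 = additiveMarkers,
      m2 = NA_character_, m3 = NA_character_, stringsAsFactors = FALSE))
  }
  im <- additiveMarkers[additiveMarkers %in% interactionMarkers]
  k <- length(im)
  if (maxOrder >= 2 && k >= 2) {
    prs <- utils::combn(im, 2)
    Z <- v[, prs[1, ], drop = FALSE] * v[, prs[2, ], drop = FALSE]
    colnames(Z) <- paste(prs[1, ], prs[2, ], sep = ":")
    cols <- c(cols, list(Z))
    terms <- rbind(terms, data.frame(
      label = colnames(Z), type = "pair", m1 = prs[1, ], m2 = prs[2, ],
      m3 = NA_character_, stringsAsFactors = FALSE))
  }
  if (maxOrder >= 3 && k >= 3) {
    trs <- utils::combn(im, 3)
    W <- v[, trs[1, ], drop = FALSE] * v[, trs[2, ], drop = FALSE] *
         v[, trs[3, ], drop = FALSE]
    colnames(W) <- paste(trs[1, ], trs[2, ], trs[3, ], sep = ":")
    cols <- c(cols, list(W))
    terms <- rbind(terms, data.frame(
      label = colnames(W), type = "triple", m1 = trs[1, ], m2 = trs[2, ],
      m3 = trs[3, ], stringsAsFactors = FALSE))
  }
  G <- do.call(cbind, cols)
  colnames(G) <- terms$label
  rownames(G) <- rownames(v)
  new("ModelDesign", G = G, terms = terms)
}

#' Numerical rank check and aliased-column detection
#'
#' Reports whether the design has full column rank (rank from a
#' tolerance-thresholded QR) and, if not, which columns are aliased.
#' Aliased columns are found greedily in term order: a column linearly
#' dependent (within tolerance) on the columns before it is flagged, so
#' the earliest representative of each dependency survives. Dropping the
#' flagged columns yields a full-rank design.
#'
#' @param design a \linkS4class{ModelDesign}
#' @param tol relative tolerance on the QR decomposition (default 1e-8)
#' @return list(isFullRank, rank, aliased = character labels)
#' @export
checkFullRank <- function(design, tol = 1e-8) {
  stopifnot(is(design, "ModelDesign"))
  G <- designMatrix(design)
  qrG <- qr(G, tol = tol)
  rk <- qrG$rank
  if (rk == ncol(G))
    return(list(isFullRank = TRUE, rank = rk, aliased = character()))
  keep <- sort(qrG$pivot[seq_len(rk)])
  # greedy pass in term order so the earliest column of a dependency wins
  kept <- integer()
  aliased <- integer()
  for (j in seq_len(ncol(G))) {
    cand <- c(kept, j)
    if (qr(G[, cand, drop = FALSE], tol = tol)$rank == length(cand))
      kept <- cand
    else aliased <- c(aliased, j)
  }
  list(isFullRank = FALSE, rank = rk,
       aliased = colnames(G)[aliased])
}

#' Drop aliased columns from a design
#'
#' @param design a \linkS4class{ModelDesign}
#' @param tol tolerance passed to \code{\link{checkFullRank}}
#' @return full-rank \linkS4class{ModelDesign} (possibly the input)
#' @export
dropAliased <- function(design, tol = 1e-8) {
  chk <- checkFullRank(design, tol)
  if (chk$isFullRank) return(design)
  keep <- !(design@terms$label %in% chk$aliased)
  new("ModelDesign", G = design@G[, keep, drop = FALSE],
      terms = design@terms[keep, , drop = FALSE])
}
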