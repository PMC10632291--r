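#' Map distance to recombination fraction
#'
#' Converts a centimorgan distance to a recombination fraction under the
#' Haldane (no crossover interference) or Kosambi map function. Haldane:
#' \eqn{r = (1 - e^{-2d/100})/2}; Kosambi: \eqn{r = \tanh(2d/100)/2}.
#'
#' @param d_cM nonnegative map distance(s) in centimorgans
#' @param mapFunction "haldane" (default) or "kosambi"
#' @return recombination fraction(s) in [0, 0.5)
#' @examples
#' recombFraction(50)            # 0.3161 under Haldane
#' recombFraction(50, "kosambi")
#' @export
recombFraction <- function(d_cM, mapFunction = c("haldane", "kosambi")) {
  mapFunction <- match.arg(mapFunction)
  if (any(!is.finite(d_cM)) || any(d_cM < 0))
    stop("map distances must be finite and nonnegative")
  M <- d_cM / 100
  switch(mapFunction,
         haldane = (1 - exp(-2 * M)) / 2,
         kosambi = tanh(2 * M) / 2)
}

# Conditional expectation of a +/-1 DH genotype given flanking states.
# a, b: flank genotypes (may be NA); r1, r2: recombination fractions from
# left flank to target and target to right flank. Vectorised.
.flankExpectation <- function(a, r1, b, r2) {
  # single-flank conditionals: E[x | a] = a(1-2r1)
  out <- numeric(length(a))
  both <- !is.na(a) & !is.na(b)
  la <- !is.na(a) & is.na(b)
  rb <- is.na(a) & !is.na(b)
  if (any(both)) {
    # P(x = s | a, b) prop. to P(a -> s; r1) P(s -> b; r2)
    pp <- ifelse(a[both] == 1, 1 - r1[both], r1[both]) *
          ifelse(b[both] == 1, 1 - r2[both], r2[both])
    pm <- ifelse(a[both] == -1, 1 - r1[both], r1[both]) *
          ifelse(b[both] == -1, 1 - r2[both], r2[both])
    out[both] <- (pp - pm) / (pp + pm)
  }
  out[la] <- a[la] * (1 - 2 * r1[la])
  out[rb] <- b[rb] * (1 - 2 * r2[rb])
  out
}

#' Impute missing genotypes from flanking markers
#'
#' Replaces each missing score by the conditional expectation of the
#' \eqn{\pm 1} genotype given the nearest non-missing flanking markers of
#' the same line and linkage group, under a two-state Markov chain along
#' the chromosome appropriate for doubled-haploid gametes. With flanking
#' states \eqn{a} (left, recombination fraction \eqn{r_1} to the target)
#' and \eqn{b} (right, \eqn{r_2}),
#' \eqn{P(x = s) \propto P(a \to s; r_1)\,P(s \to b; r_2)} where a
#' transition occurs with probability \eqn{r} and the expectation is taken
#' over \eqn{s \in \{-1,+1\}}. Entries with a single informative flank use
#' the one-sided conditional \eqn{a(1-2r_1)}; entries with no informative
#' flank in their group, and markers absent from the map, are set to 0 (the
#' unconditional expectation) with a message.
#'
#' @param geno a \linkS4class{GenotypeMatrix} with raw -1/+1/NA scores
#' @param map a \linkS4class{LinkageMap} covering (ideally) all markers
#' @param mapFunction map function passed to \code{\link{recombFraction}}
#' @param round if TRUE, imputed dosages are rounded to hard -1/+1 calls by
#'   sign (ties to +1); default leaves them real-valued in [-1, +1]
#' @return a \linkS4class{GenotypeMatrix} with no missing entries;
#'   non-missing input entries are untouched
#' @export
imputeFlanking <- function(geno, map, mapFunction = c("haldane", "kosambi"),
                           round = FALSE) {
  stopifnot(is(geno, "GenotypeMatrix"), is(map, "LinkageMap"))
  mapFunction <- match.arg(mapFunction)
  v <- genoValues(geno)
  if (!anyNA(v)) return(geno)
  mt <- mapTable(map)
  unplaced <- setdiff(colnames(v), mt$marker_id)
  if (length(unplaced)) {
    nfill <- sum(is.na(v[, unplaced, drop = FALSE]))
    if (nfill) message(sprintf(
      "%d marker(s) absent from the map; %d missing value(s) set to 0",
      length(unplaced), nfill))
    v[, unplaced][is.na(v[, unplaced, drop = FALSE])] <- 0
  }
  for (grp in unique(mt$group)) {
    mk <- mt$marker_id[mt$group == grp]
    mk <- mk[mk %in% colnames(v)]
    if (!length(mk)) next
    pos <- mt$position_cM[match(mk, mt$marker_id)]
    sub <- v[, mk, drop = FALSE]
    if (!anyNA(sub)) next
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      nas <- which(is.na(row))
      if (!length(nas)) next
      obs <- which(!is.na(row) & row %in% c(-1, 1))
      for (j in nas) {
        left <- obs[obs < j]
        right <- obs[obs > j]
        a <- if (length(left)) row[max(left)] else NA_real_
        b <- if (length(right)) row[min(right)] else NA_real_
        r1 <- if (length(left)) recombFraction(pos[j] - pos[max(left)], mapFunction) else NA_real_
        r2 <- if (length(right)) recombFraction(pos[min(right)] - pos[j], mapFunction) else NA_real_
        sub[i, j] <- .flankExpectation(a, r1, b, r2)
      }
    }
    v[, mk] <- sub
  }
  if (round) v <- ifelse(v >= 0, 1, -1)
  GenotypeMatrix(v)
}
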