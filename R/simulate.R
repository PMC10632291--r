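#' Build an evenly spaced linkage map
#'
#' Convenience constructor for simulated maps: \code{nGroups} linkage
#' groups named LG1, LG2, ..., each with \code{markersPerGroup} markers
#' evenly spaced over \code{lengthCM} centimorgans. Marker ids are
#' "LG<g>_M<j>".
#'
#' @param nGroups number of linkage groups
#' @param markersPerGroup markers on each group
#' @param lengthCM group length in cM (default 100)
#' @return a \linkS4class{LinkageMap}
#' @export
simulateMap <- function(nGroups, markersPerGroup, lengthCM = 100) {
  stopifnot(nGroups >= 1, markersPerGroup >= 1)
  pos <- if (markersPerGroup == 1L) 0 else
    seq(0, lengthCM, length.out = markersPerGroup)
  g <- rep(paste0("LG", seq_len(nGroups)), each = markersPerGroup)
  LinkageMap(
    marker_id = paste0(g, "_M", rep(seq_len(markersPerGroup), nGroups)),
    group = g, position_cM = rep(pos, nGroups))
}

#' Simulate doubled-haploid line genotypes
#'
#' Draws \eqn{\pm 1} genotypes for fully homozygous lines along a linkage
#' map: within each group the first marker is +1 or -1 with probability
#' 1/2, and each subsequent marker flips sign relative to its predecessor
#' with the Haldane recombination fraction of the inter-marker distance (a
#' two-state Markov chain along the chromosome); linkage groups segregate
#' independently. Deterministic given \code{seed}.
#'
#' @param nLines number of lines (>= 2)
#' @param map a nonempty \linkS4class{LinkageMap}
#' @param seed optional integer seed
#' @return a complete \linkS4class{GenotypeMatrix} with lines
#'   "L001", "L002", ...
#' @export
simulateGenotypes <- function(nLines, map, seed = NULL) {
  stopifnot(is(map, "LinkageMap"))
  if (nLines < 2L) stop("need at least 2 lines")
  mt <- mapTable(map)
  if (!nrow(mt)) stop("empty linkage map")
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(NA_real_, nLines, nrow(mt))
  colnames(v) <- mt$marker_id
  rownames(v) <- sprintf("L%03d", seq_len(nLines))
  for (g in unique(mt$group)) {
    idx <- which(mt$group == g)
    r <- recombFraction(diff(mt$position_cM[idx]))
    col <- sample(c(-1, 1), nLines, replace = TRUE)
    v[, idx[1L]] <- col
    for (j in seq_along(r)) {
      flip <- stats::runif(nLines) < r[j]
      col <- ifelse(flip, -col, col)
      v[, idx[j + 1L]] <- col
    }
  }
  GenotypeMatrix(v)
}

#' Trait architecture for the phenotype simulator
#'
#' Defines the generative model for simulated traits: a grand mean plus
#' additive, pairwise-epistatic and triple-epistatic marker effects, and a
#' replicate-noise law. Per-line replicate standard deviations are either
#' constant (\code{noise = "constant"}, SD = \code{sigma}) or drawn
#' log-normally across lines (\code{noise = "lognormal"}, median
#' \code{sigma}, log-scale spread \code{sdlog}), the latter creating the
#' between-line variance heterogeneity that weighted regression exploits.
#'
#' @param mean grand mean
#' @param additive named numeric vector: marker id -> additive effect
#' @param pairs data.frame (m1, m2, effect); NULL for none
#' @param triples data.frame (m1, m2, m3, effect); NULL for none
#' @param noise "constant" or "lognormal"
#' @param sigma replicate SD (constant) or its across-line median
#'   (lognormal)
#' @param sdlog log-scale SD of per-line SDs for "lognormal" (default 1)
#' @param nReps replicates per line
#' @return list of class "architecture"
#' @export
architecture <- function(mean = 0, additive = numeric(), pairs = NULL,
                         triples = NULL, noise = c("constant", "lognormal"),
                         sigma = 1, sdlog = 1, nReps = 1) {
  noise <- match.arg(noise)
  stopifnot(sigma >= 0, sdlog >= 0, nReps >= 1)
  if (!is.null(pairs)) stopifnot(all(c("m1", "m2", "effect") %in% names(pairs)))
  if (!is.null(triples))
    stopifnot(all(c("m1", "m2", "m3", "effect") %in% names(triples)))
  structure(list(mean = mean, additive = additive, pairs = pairs,
                 triples = triples, noise = noise, sigma = sigma,
                 sdlog = sdlog, nReps = as.integer(nReps)),
            class = "architecture")
}

#' Genetic values of lines under an architecture
#'
#' @param geno complete \linkS4class{GenotypeMatrix}
#' @param arch an \code{\link{architecture}}
#' @return numeric vector of per-line genetic values
#' @export
geneticValues <- function(geno, arch) {
  stopifnot(is(geno, "GenotypeMatrix"), inherits(arch, "architecture"))
  v <- genoValues(geno)
  refd <- c(names(arch$additive), unlist(arch$pairs[c("m1", "m2")]),
            unlist(arch$triples[c("m1", "m2", "m3")]))
  missing <- setdiff(refd, colnames(v))
  if (length(missing))
    stop("architecture references absent marker(s): ",
         paste(missing, collapse = ", "))
  gv <- rep(arch$mean, nrow(v))
  for (m in names(arch$additive)) gv <- gv + arch$additive[[m]] * v[, m]
  if (!is.null(arch$pairs)) for (i in seq_len(nrow(arch$pairs)))
    gv <- gv + arch$pairs$effect[i] * v[, arch$pairs$m1[i]] * v[, arch$pairs$m2[i]]
  if (!is.null(arch$triples)) for (i in seq_len(nrow(arch$triples)))
    gv <- gv + arch$triples$effect[i] * v[, arch$triples$m1[i]] *
      v[, arch$triples$m2[i]] * v[, arch$triples$m3[i]]
  unname(gv)
}

#' Simulate replicated phenotypes
#'
#' Generates replicate observations per line as the line's genetic value
#' (see \code{\link{geneticValues}}) plus independent Gaussian noise with
#' the line's replicate SD drawn from the architecture's noise law.
#' Deterministic given \code{seed}.
#'
#' @param geno complete \linkS4class{GenotypeMatrix}
#' @param arch an \code{\link{architecture}}
#' @param seed optional integer seed
#' @return a \linkS4class{PhenotypeSet} with \code{arch$nReps} replicates
#'   per line, in genotype line order
#' @export
simulatePhenotypes <- function(geno, arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gv <- geneticValues(geno, arch)
  n <- length(gv)
  sds <- switch(arch$noise,
                constant = rep(arch$sigma, n),
                lognormal = arch$sigma * stats::rlnorm(n, 0, arch$sdlog))
  r <- arch$nReps
  obs <- rep(gv, each = r) + stats::rnorm(n * r, 0, rep(sds, each = r))
  PhenotypeSet(line_id = rep(lineIds(geno), each = r),
               rep = rep(seq_len(r), n), value = obs)
}

#' Canned desk-scale simulation scenarios
#'
#' The package's reference study conditions for validating the
#' estimators, at the size of a typical doubled-haploid mapping
#' experiment: 126 lines genotyped on 5 linkage groups of 40 markers
#' spanning 200 cM each, phenotyped in 3 replicates. The genetic
#' architecture of the non-null scenarios places three strong additive
#' QTLs (effect 8) on one linkage group at roughly 10, 97 and 190 cM --
#' mirroring how often real QTL triples fall within a single group -- and
#' one three-way interaction of effect 5 among them.
#'
#' \describe{
#'   \item{"recovery"}{low noise: constant replicate SD 0.5. Used for
#'     parameter-recovery checks.}
#'   \item{"heteroscedastic"}{log-normal per-line replicate SDs, median 3,
#'     log-scale spread 1.1 (upper/lower quartile ratio about 4.4), the
#'     regime where inverse-variance weighting should pay off.}
#'   \item{"null"}{no genetic effects at all, constant SD 2; for
#'     false-positive and test-calibration checks.}
#' }
#'
#' @param type scenario name
#' @return a scenario list for \code{\link{monteCarloCompare}}
#' @export
defaultScenario <- function(type = c("recovery", "heteroscedastic", "null")) {
  type <- match.arg(type)
  map <- simulateMap(5, 40, 200)
  qtl <- c("LG1_M3", "LG1_M20", "LG1_M38")
  triple <- data.frame(m1 = qtl[1], m2 = qtl[2], m3 = qtl[3], effect = 5,
                       stringsAsFactors = FALSE)
  arch <- switch(type,
    recovery = architecture(mean = 50,
      additive = stats::setNames(rep(8, 3), qtl), triples = triple,
      noise = "constant", sigma = 0.5, nReps = 3),
    heteroscedastic = architecture(mean = 50,
      additive = stats::setNames(rep(8, 3), qtl), triples = triple,
      noise = "lognormal", sigma = 3, sdlog = 1.1, nReps = 3),
    null = architecture(mean = 50, noise = "constant", sigma = 2, nReps = 3))
  list(map = map, nLines = 126, arch = arch, config = selectionConfig())
}

#' Monte-Carlo comparison of the epistasis estimators
#'
#' Runs the full analysis pipeline on freshly simulated populations:
#' simulate genotypes and phenotypes under a known architecture,
#' optionally mask genotypes at random and re-impute them, run the staged
#' marker selection, fit the interaction model unweighted and weighted,
#' and record per-replicate phenotypic and genotypic estimates of the
#' total aaa effect plus per-triple recovery. Summaries (bias, MSE,
#' recovery rate) are recomputable from the returned per-replicate table.
#'
#' @param scenario list with elements \code{map} (a
#'   \linkS4class{LinkageMap}), \code{nLines}, \code{arch} (an
#'   \code{\link{architecture}}), optional \code{maskRate} (MCAR genotype
#'   masking, default 0) and \code{config} (a
#'   \code{\link{selectionConfig}})
#' @param nReps number of Monte-Carlo replicates
#' @param seed integer seed; replicate r uses seed + r for every draw
#' @return list(reps = per-replicate data.frame, summary = one-row
#'   data.frame, trueAaa = total simulated triple effect)
#' @export
monteCarloCompare <- function(scenario, nReps, seed = 1) {
  stopifnot(is(scenario$map, "LinkageMap"),
            inherits(scenario$arch, "architecture"))
  cfg <- scenario$config
  if (is.null(cfg)) cfg <- selectionConfig()
  maskRate <- scenario$maskRate
  if (is.null(maskRate)) maskRate <- 0
  trueTr <- scenario$arch$triples
  trueAaa <- if (is.null(trueTr)) 0 else sum(trueTr$effect)
  trueKey <- if (is.null(trueTr)) character() else
    apply(trueTr[c("m1", "m2", "m3")], 1L, function(m) paste(sort(m), collapse = ":"))
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    g <- simulateGenotypes(scenario$nLines, scenario$map, seed = seed + r)
    ph <- simulatePhenotypes(g, scenario$arch)
    if (maskRate > 0) {
      v <- genoValues(g)
      v[stats::runif(length(v)) < maskRate] <- NA_real_
      g <- imputeFlanking(GenotypeMatrix(v), scenario$map)
    }
    ym <- lineMeans(ph)
    aaap <- estimateAaaP(ym)@estimate
    sel <- selectMarkers(unname(ym), g, scenario$map, cfg)
    nTriples <- nrow(sel@triples)
    guTot <- gwTot <- 0
    guTrue <- gwTrue <- NA_real_
    pctU <- pctW <- NA_real_
    recovered <- FALSE
    if (length(sel@additive)) {
      des <- dropAliased(buildDesign(g, sel@additive))
      ti <- termInfo(des)
      keep <- ti$type %in% c("intercept", "additive") |
        (ti$type == "pair" &
           ti$label %in% paste(sel@pairs$m1, sel@pairs$m2, sep = ":")) |
        (ti$type == "triple" &
           ti$label %in% paste(sel@triples$m1, sel@triples$m2, sel@triples$m3,
                               sep = ":"))
      des <- new("ModelDesign", G = designMatrix(des)[, keep, drop = FALSE],
                 terms = ti[keep, , drop = FALSE])
      wv <- lineVariances(ph)
      fu <- fitUnweighted(unname(ym), des)
      fw <- fitWeighted(unname(ym), des, unname(wv))
      guTot <- totalAaa(fu, "allRetained")$total
      gwTot <- totalAaa(fw, "allRetained")$total
      ti2 <- termInfo(des)
      tr <- ti2[ti2$type == "triple", , drop = FALSE]
      if (nrow(tr) && length(trueKey)) {
        key <- apply(tr[c("m1", "m2", "m3")], 1L,
                     function(m) paste(sort(m), collapse = ":"))
        hit <- match(trueKey[1L], key)
        if (!is.na(hit)) {
          recovered <- TRUE
          lab <- tr$label[hit]
          guTrue <- coef(fu)[[lab]]
          gwTrue <- coef(fw)[[lab]]
          pctU <- tripleVarianceExplained(unname(ym), des, fu, lab)
          pctW <- tripleVarianceExplained(unname(ym), des, fw, lab)
        }
      }
    }
    rows[[r]] <- data.frame(
      rep = r, aaa_p = aaap, n_additive = length(sel@additive),
      n_triples = nTriples, recovered = recovered,
      aaa_gu_total = guTot, aaa_gw_total = gwTot,
      aaa_gu_true = guTrue, aaa_gw_true = gwTrue,
      pctvar_gu = pctU, pctvar_gw = pctW,
      false_triples = nTriples - as.integer(recovered))
  }
  reps <- do.call(rbind, rows)
  hit <- reps$recovered
  summ <- data.frame(
    recovery_rate = mean(hit),
    mean_gw_true = mean(reps$aaa_gw_true[hit]),
    mean_gu_true = mean(reps$aaa_gu_true[hit]),
    se_gw_true = stats::sd(reps$aaa_gw_true[hit]) / sqrt(max(sum(hit), 1L)),
    bias_gw = mean(reps$aaa_gw_true[hit]) - trueAaa,
    bias_gu = mean(reps$aaa_gu_true[hit]) - trueAaa,
    mse_gw = mean((reps$aaa_gw_true[hit] - trueAaa)^2),
    mse_gu = mean((reps$aaa_gu_true[hit] - trueAaa)^2),
    mean_false_triples = mean(reps$false_triples))
  list(reps = reps, summary = summ, trueAaa = trueAaa)
}
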