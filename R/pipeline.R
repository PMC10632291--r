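#' Read a (possibly multi-trait) phenotype file
#'
#' Long CSV \code{line_id, rep, value} with an optional \code{trait}
#' column. Returns a named list of \linkS4class{PhenotypeSet}s, one per
#' trait ("trait1" when the column is absent).
#'
#' @param path CSV file path
#' @return named list of \linkS4class{PhenotypeSet}
#' @export
readPhenotypeTraits <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("line_id", "rep", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  if (nrow(df) && anyNA(val)) {
    i <- which(is.na(val))[1L]
    stop(sprintf("non-numeric phenotype value '%s' at row %d", df$value[i], i))
  }
  df$value <- val
  traits <- if ("trait" %in% names(df)) df$trait else rep("trait1", nrow(df))
  lapply(split(df, factor(traits, levels = unique(traits))), function(d)
    PhenotypeSet(d$line_id, as.integer(d$rep), d$value))
}

#' Phenotype-only summary for one or more traits
#'
#' Per-trait table of the extreme and overall line means, the phenotypic
#' total-epistasis estimate with its extreme-line contrast F test (when
#' replicates permit), and the Wright-type effective-factor count.
#'
#' @param phenos a \linkS4class{PhenotypeSet} or named list of them
#' @return data.frame(trait, n_lines, min, max, mean, aaa_p, F, p, k)
#' @export
aaaPhenoTable <- function(phenos) {
  if (is(phenos, "PhenotypeSet")) phenos <- list(trait1 = phenos)
  rows <- lapply(names(phenos), function(tn) {
    ph <- phenos[[tn]]
    m <- lineMeans(ph)
    r <- replicateCounts(ph)
    testable <- sum(r - 1L) >= 1L
    est <- if (testable) testAaaP(ph) else estimateAaaP(m)
    ev <- if (testable) {
      rec <- ph@records
      sum((rec$value - m[rec$line_id])^2) / sum(r - 1L)
    } else 0
    k <- effectiveFactors(m, errorVariance = ev, nReps = mean(r))
    data.frame(trait = tn, n_lines = length(m), min = est@Lmin,
               max = est@Lmax, mean = est@grandMean, aaa_p = est@estimate,
               F = est@Fstat, p = est@pValue, k = k$k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full estimation pipeline
#'
#' Chains the whole analysis for every trait: join phenotypes to
#' genotypes, impute missing genotypes from flanking markers, run the
#' staged marker selection on line means, fit the selected interaction
#' model by unweighted and weighted least squares, and write the result
#' tables: \code{triples.tsv} (per-triple estimates, p values, percent
#' variance), \code{totals.tsv} (per-trait counts, ranges, totals, R2),
#' \code{selection_log.tsv}, \code{pheno_summary.tsv} and
#' \code{run_metadata.yaml} (package version, seed, config echo). Partial
#' outputs are removed on error.
#'
#' @param genotypes \linkS4class{GenotypeMatrix} or path to a genotype CSV
#' @param map \linkS4class{LinkageMap} or path to a map CSV
#' @param phenotypes \linkS4class{PhenotypeSet}, named list of them, or
#'   path to a (possibly multi-trait) phenotype CSV
#' @param outDir output directory (created if needed)
#' @param config a \code{\link{selectionConfig}}
#' @param mapFunction map function for imputation
#' @param roundImputed round imputed dosages to hard calls
#' @param alpha significance level for counting/totalling triples
#' @param seed optional seed recorded in the metadata (the pipeline itself
#'   is deterministic; the seed matters when the inputs were simulated)
#' @return invisibly, a named list of per-trait results (selection, fits,
#'   report)
#' @export
runPipeline <- function(genotypes, map, phenotypes, outDir,
                        config = selectionConfig(),
                        mapFunction = "haldane", roundImputed = FALSE,
                        alpha = 0.001, seed = NULL) {
  if (is.character(genotypes)) genotypes <- readGenotypes(genotypes)
  if (is.character(map)) map <- readLinkageMap(map)
  if (is.character(phenotypes)) phenotypes <- readPhenotypeTraits(phenotypes)
  if (is(phenotypes, "PhenotypeSet")) phenotypes <- list(trait1 = phenotypes)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outFiles <- file.path(outDir, c("triples.tsv", "totals.tsv",
                                  "selection_log.tsv", "pheno_summary.tsv",
                                  "run_metadata.yaml"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outFiles), add = TRUE)

  genotypes <- imputeFlanking(genotypes, map, mapFunction = mapFunction,
                              round = roundImputed)
  allTriples <- list(); allTotals <- list(); allLogs <- list()
  results <- list()
  for (tn in names(phenotypes)) {
    j <- joinLines(phenotypes[[tn]], genotypes)
    ym <- lineMeans(j$pheno)
    sel <- selectMarkers(unname(ym), j$geno, map, config)
    res <- list(selection = sel)
    if (length(sel@additive)) {
      des <- dropAliased(buildDesign(j$geno, sel@additive))
      ti <- termInfo(des)
      keep <- ti$type %in% c("intercept", "additive") |
        ti$label %in% c(paste(sel@pairs$m1, sel@pairs$m2, sep = ":"),
                        paste(sel@triples$m1, sel@triples$m2, sel@triples$m3,
                              sep = ":"))
      des <- new("ModelDesign", G = designMatrix(des)[, keep, drop = FALSE],
                 terms = ti[keep, , drop = FALSE])
      wv <- lineVariances(j$pheno)
      fu <- fitUnweighted(unname(ym), des)
      fw <- fitWeighted(unname(ym), des, unname(wv))
      rep_ <- tripleReport(unname(ym), des, fu, fw, alpha = alpha)
      res$design <- des; res$fitU <- fu; res$fitW <- fw; res$report <- rep_
      if (nrow(rep_$triples))
        allTriples[[tn]] <- cbind(trait = tn, rep_$triples)
      if (!is.null(rep_$totals))
        allTotals[[tn]] <- cbind(trait = tn, n_qtl = length(sel@additive),
                                 rep_$totals)
    } else {
      allTotals[[tn]] <- data.frame(
        trait = tn, n_qtl = 0L, model = c("gu", "gw"), count = 0L,
        min = NA_real_, max = NA_real_, total = 0, r2 = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (nrow(sel@log)) allLogs[[tn]] <- cbind(trait = tn, sel@log)
    results[[tn]] <- res
  }
  emptyTriples <- data.frame(trait = character(), QTL1 = character(),
                             QTL2 = character(), QTL3 = character(),
                             aaa_gu = numeric(), p_gu = numeric(),
                             pctvar_gu = numeric(), aaa_gw = numeric(),
                             p_gw = numeric(), pctvar_gw = numeric(),
                             stringsAsFactors = FALSE)
  .writeTSV(if (length(allTriples)) do.call(rbind, allTriples) else
    emptyTriples, outFiles[1L])
  .writeTSV(do.call(rbind, allTotals), outFiles[2L])
  .writeTSV(if (length(allLogs)) do.call(rbind, allLogs) else
    data.frame(trait = character()), outFiles[3L])
  .writeTSV(aaaPhenoTable(phenotypes), outFiles[4L])
  meta <- list(
    package = "tripleQTL",
    version = as.character(utils::packageVersion("tripleQTL")),
    seed = if (is.null(seed)) NA else seed,
    mapFunction = mapFunction, roundImputed = roundImputed,
    alpha = alpha, config = unclass(config),
    traits = names(phenotypes))
  yaml::write_yaml(meta, outFiles[5L])
  ok <- TRUE
  invisible(results)
}
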