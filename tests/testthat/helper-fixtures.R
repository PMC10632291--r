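# Shared fixtures, built in code.

# tiny 2x2 genotype matrix
tinyGeno <- function() {
  GenotypeMatrix(matrix(c(1, -1, -1, 1), 2, 2,
                        dimnames = list(c("L1", "L2"), c("M1", "M2"))))
}

# write a genotype CSV from a character matrix (entries kept verbatim)
writeGenoCSV <- function(entries, lines, markers, path = tempfile(fileext = ".csv")) {
  df <- data.frame(line_id = lines, entries, check.names = FALSE)
  colnames(df) <- c("line_id", markers)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# three-marker one-group map with recombination fractions r1, r2 between
# consecutive markers (inverse Haldane positions)
threeMarkerMap <- function(r1, r2) {
  d1 <- if (r1 > 0) -50 * log(1 - 2 * r1) else 0
  d2 <- if (r2 > 0) -50 * log(1 - 2 * r2) else 0
  LinkageMap(c("A", "B", "C"), "LG1", c(0, d1, d1 + d2))
}

# published per-trait phenotypic summaries shipped with the package
traitSummary <- function() {
  read.csv(system.file("extdata", "mandub_begra_trait_summary.csv",
                       package = "tripleQTL"))
}

# a small complete genotype + map for design/selection tests
smallPopulation <- function(nLines = 60, nGroups = 3, perGroup = 8,
                            lenCM = 70, seed = 11) {
  map <- simulateMap(nGroups, perGroup, lenCM)
  list(map = map, geno = simulateGenotypes(nLines, map, seed = seed))
}
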