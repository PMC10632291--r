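#' Read a genotype matrix from CSV
#'
#' Expects a header row of marker ids with a leading \code{line_id} column;
#' entries are -1, 1 or the missing code. Any other entry is a format error
#' reported with its row and column.
#'
#' @param path CSV file path
#' @param missingCode string marking a missing score (default "NA")
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypes <- function(path, missingCode = "NA") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("genotype file needs a line_id column plus markers")
  lines <- df[[1L]]
  if (anyDuplicated(lines)) stop("duplicate line ids in ", path)
  markers <- colnames(df)[-1L]
  if (anyDuplicated(markers)) stop("duplicate marker ids in ", path)
  raw <- as.matrix(df[-1L])
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(lines, markers))
  miss <- raw == missingCode | is.na(raw)
  num <- suppressWarnings(as.numeric(raw[!miss]))
  bad <- is.na(num) | !(num %in% c(-1, 1))
  if (any(bad)) {
    idx <- which(!miss)[which(bad)[1L]]
    rc <- arrayInd(idx, dim(raw))
    stop(sprintf(
      "invalid genotype entry '%s' at line '%s', marker '%s' (row %d, column %d): must be -1, 1 or '%s'",
      raw[idx], lines[rc[1L]], markers[rc[2L]], rc[1L], rc[2L] + 1L, missingCode))
  }
  vals[!miss] <- num
  GenotypeMatrix(vals)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of \code{\link{readGenotypes}} for raw (un-imputed) matrices.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param path output file
#' @param missingCode string written for missing scores
#' @export
writeGenotypes <- function(x, path, missingCode = "NA") {
  stopifnot(is(x, "GenotypeMatrix"))
  v <- genoValues(x)
  out <- data.frame(line_id = rownames(v), check.names = FALSE)
  ch <- format(v, trim = TRUE, digits = 15)
  ch[is.na(v)] <- missingCode
  out <- cbind(out, as.data.frame(ch, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a linkage map from CSV
#'
#' Columns \code{marker_id, group, position_cM}. An empty file yields an
#' empty map with a warning.
#'
#' @param path CSV file path
#' @return a \linkS4class{LinkageMap}
#' @export
readLinkageMap <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character", "character", "numeric"))
  need <- c("marker_id", "group", "position_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) warning("empty linkage map: ", path)
  if (anyDuplicated(df$marker_id))
    stop("duplicate marker_id in map: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  if (nrow(df) && any(df$position_cM < 0))
    stop("negative position_cM in map: ", path)
  LinkageMap(df$marker_id, df$group, df$position_cM)
}

#' @rdname readLinkageMap
#' @param x a \linkS4class{LinkageMap}
#' @export
writeLinkageMap <- function(x, path) {
  stopifnot(is(x, "LinkageMap"))
  utils::write.csv(x@map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read replicated phenotypes from long-format CSV
#'
#' Columns \code{line_id, rep, value}; one row per replicate observation.
#'
#' @param path CSV file path
#' @return a \linkS4class{PhenotypeSet}
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character", "integer", "character"))
  need <- c("line_id", "rep", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  if (nrow(df) && anyNA(val)) {
    i <- which(is.na(val))[1L]
    stop(sprintf("non-numeric phenotype value '%s' at row %d (line '%s')",
                 df$value[i], i, df$line_id[i]))
  }
  PhenotypeSet(df$line_id, df$rep, val)
}

#' @rdname readPhenotypes
#' @param x a \linkS4class{PhenotypeSet}
#' @export
writePhenotypes <- function(x, path) {
  stopifnot(is(x, "PhenotypeSet"))
  r <- x@records
  r$value <- format(r$value, trim = TRUE, digits = 15)
  utils::write.csv(r, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join a PhenotypeSet to a GenotypeMatrix
#'
#' Restricts both objects to their common lines, in the genotype file's
#' line order, and errors on phenotyped lines absent from the genotypes.
#'
#' @param pheno a \linkS4class{PhenotypeSet}
#' @param geno a \linkS4class{GenotypeMatrix}
#' @return list(geno, pheno) restricted to shared lines, genotype order
#' @export
joinLines <- function(pheno, geno) {
  stopifnot(is(pheno, "PhenotypeSet"), is(geno, "GenotypeMatrix"))
  gl <- lineIds(geno)
  pl <- lineIds(pheno)
  orphan <- setdiff(pl, gl)
  if (length(orphan))
    stop("phenotyped lines absent from genotypes: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  keep <- gl[gl %in% pl]
  rec <- pheno@records
  rec <- rec[rec$line_id %in% keep, , drop = FALSE]
  rec <- rec[order(match(rec$line_id, keep), rec$rep), , drop = FALSE]
  list(geno = GenotypeMatrix(genoValues(geno)[keep, , drop = FALSE]),
       pheno = new("PhenotypeSet", records = rec))
}
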