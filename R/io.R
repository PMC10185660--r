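# Readers and writers for the external tabular formats: dosage TSV,
# minimal VCF, expression/centroid/candidate/LD/summary-stat/clinical TSV,
# with strict validation and effect-allele orientation checks.

.checkNoDupIds <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, " id(s): ", paste(head(dup, 5), collapse = ", "))
  }
}

#' Write a table as TSV
#'
#' Values are written at full double precision (15 significant digits) so a
#' write/read round trip is lossless.
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @param rowNamesAs when non-NULL, row names are written as a first column
#'   with this header.
#' @export
writeTSV <- function(x, path, rowNamesAs = NULL) {
  df <- as.data.frame(x)
  if (!is.null(rowNamesAs)) {
    df <- cbind(setNames(data.frame(rownames(df),
                                    stringsAsFactors = FALSE), rowNamesAs),
                df)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.15g", v)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV with required columns
#'
#' @param path input file.
#' @param required character vector of required column names (after
#'   lower-casing headers).
#' @param numeric character vector of columns coerced to numeric; rows that
#'   fail coercion raise an error naming the column.
#' @return data.frame with lower-cased column names; "NA" tokens become
#'   missing values and their count is recorded in \code{attr(, "nMissing")}.
#' @export
readTable <- function(path, required = character(),
                      numeric = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column role(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  nMissing <- 0L
  for (cn in intersect(numeric, names(df))) {
    v <- df[[cn]]
    nMissing <- nMissing + sum(is.na(v) | v == "NA")
    coerced <- suppressWarnings(as.numeric(v))
    badRow <- which(!is.na(v) & v != "NA" & is.na(coerced))
    if (length(badRow))
      stop("non-numeric value in column '", cn, "' at data row ",
           badRow[1], " of ", basename(path))
    df[[cn]] <- coerced
  }
  attr(df, "nMissing") <- nMissing
  df
}

#' Read a genotype dosage matrix from TSV or minimal VCF
#'
#' TSV: samples in rows (first column = sample id), SNPs in columns,
#' dosages 0/1/2 or NA. VCF: per-sample GT fields are converted to ALT
#' allele counts. When \code{effectTable} (columns \code{snp},
#' \code{effect_allele}, optionally \code{other_allele}) is supplied, each
#' SNP's dosage orientation is checked: if the effect allele equals the VCF
#' REF (or the TSV \code{other_allele}), dosages are flipped (2 - g) and
#' the flip count reported; SNPs whose alleles match neither orientation
#' are dropped with a reason; ambiguous-strand (A/T, C/G) SNPs are flagged.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @param effectTable optional orientation-governing table.
#' @return A \linkS4class{GenotypeMatrix} with attributes \code{flipped},
#'   \code{droppedAlleles} and \code{ambiguous}.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"),
                          effectTable = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    .checkNoDupIds(ids, "sample")
    d <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(d) <- "double"
    rownames(d) <- ids
    ref <- NULL; alt <- NULL
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    snpIds <- fix[, "ID"]
    .checkNoDupIds(snpIds, "SNP")
    count <- function(s) {
      ifelse(is.na(s), NA_real_,
             vapply(strsplit(gsub("\\|", "/", s), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    d <- t(apply(gt, 1, count))
    d <- matrix(as.numeric(d), nrow = nrow(gt),
                dimnames = list(snpIds, colnames(gt)))
    d <- t(d)
    ref <- setNames(fix[, "REF"], snpIds)
    alt <- setNames(fix[, "ALT"], snpIds)
  }
  .checkNoDupIds(colnames(d), "SNP")
  info <- data.frame(
    effect_allele = if (is.null(alt)) rep(NA_character_, ncol(d))
                    else unname(alt[colnames(d)]),
    other_allele = if (is.null(ref)) rep(NA_character_, ncol(d))
                   else unname(ref[colnames(d)]),
    row.names = colnames(d), stringsAsFactors = FALSE)
  flipped <- character(); droppedA <- character(); ambiguous <- character()
  if (!is.null(effectTable)) {
    et <- effectTable
    names(et) <- tolower(names(et))
    stopifnot(all(c("snp", "effect_allele") %in% names(et)))
    keep <- rep(TRUE, ncol(d))
    for (j in seq_len(ncol(d))) {
      s <- colnames(d)[j]
      row <- match(s, et$snp)
      if (is.na(row)) next
      want <- toupper(et$effect_allele[row])
      a1 <- toupper(info$effect_allele[j])  # counted allele (ALT)
      a2 <- toupper(info$other_allele[j])
      if (is.na(a1) && "other_allele" %in% names(et)) {
        a1 <- toupper(et$effect_allele[row])  # TSV assumed effect-coded
        a2 <- toupper(et$other_allele[row])
        info$effect_allele[j] <- a1
        info$other_allele[j] <- a2
      }
      pair <- sort(c(a1, a2))
      if (identical(pair, c("A", "T")) || identical(pair, c("C", "G")))
        ambiguous <- c(ambiguous, s)
      if (!is.na(a1) && want == a1) {
        # already effect-allele counts
      } else if (!is.na(a2) && want == a2) {
        d[, j] <- 2 - d[, j]
        info$effect_allele[j] <- a2
        info$other_allele[j] <- a1
        flipped <- c(flipped, s)
      } else if (!is.na(a1)) {
        keep[j] <- FALSE
        droppedA <- c(droppedA, s)
      }
    }
    d <- d[, keep, drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  info$effect_allele[is.na(info$effect_allele)] <- "A"
  info$other_allele[is.na(info$other_allele)] <- "G"
  out <- GenotypeMatrix(d, info)
  attr(out, "flipped") <- flipped
  attr(out, "droppedAlleles") <- droppedA
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Write a genotype dosage matrix as TSV
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file; samples in rows, first column \code{sample}.
#' @export
writeDosageTSV <- function(genotypes, path) {
  writeTSV(dosages(genotypes), path, rowNamesAs = "sample")
}

#' Write a minimal VCF 4.2 with per-sample GT
#'
#' Dosages 0/1/2 become GT 0/0, 0/1, 1/1 with the effect allele as ALT;
#' missing dosages become ./. . Placeholder positions are emitted
#' (chromosome 1, consecutive positions) unless \code{snpInfo} carries
#' \code{chrom}/\code{pos} columns.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @export
writeVCF <- function(genotypes, path) {
  d <- dosages(genotypes)
  info <- snpInfo(genotypes)
  chrom <- if ("chrom" %in% colnames(info)) info$chrom
           else rep("1", ncol(d))
  pos <- if ("pos" %in% colnames(info)) info$pos else seq_len(ncol(d))
  gtStr <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gtStr[g + 1L])
    paste(c(chrom[j], pos[j], colnames(d)[j], info$other_allele[j],
            info$effect_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' Rows are samples (first column = sample id), columns are genes or
#' probes; values numeric. Returned transposed as features x samples.
#'
#' @param path input file.
#' @param er optional column name holding ER status within the same file.
#' @return SummarizedExperiment (features x samples).
#' @export
readExpression <- function(path, er = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  .checkNoDupIds(ids, "sample")
  erCol <- NULL
  if (!is.null(er) && er %in% names(df)) {
    erCol <- as.character(df[[er]])
    df[[er]] <- NULL
  }
  E <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(E) <- "double"
  colnames(E) <- ids
  cd <- if (is.null(erCol)) DataFrame(row.names = ids)
        else DataFrame(er_status = erCol, row.names = ids)
  SummarizedExperiment(assays = list(exprs = E), colData = cd)
}

#' Read a centroid TSV (genes x subtype columns)
#'
#' @param path input file: first column gene id, then the five subtype
#'   columns; an optional logical/0-1 column \code{prolif} flags the
#'   proliferation subset.
#' @return A \linkS4class{CentroidMatrix}.
#' @export
readCentroids <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  .checkNoDupIds(genes, "gene")
  pg <- character()
  if ("prolif" %in% names(df)) {
    pg <- genes[as.logical(df$prolif)]
    df$prolif <- NULL
  }
  C <- as.matrix(df[, .subtypeLabels, drop = FALSE])
  rownames(C) <- genes
  CentroidMatrix(C, pg)
}

#' Write a centroid matrix as TSV
#' @param centroidMatrix a \linkS4class{CentroidMatrix}.
#' @param path output file.
#' @export
writeCentroids <- function(centroidMatrix, path) {
  C <- as.data.frame(centroids(centroidMatrix))
  C$prolif <- as.integer(rownames(C) %in% prolifGenes(centroidMatrix))
  writeTSV(C, path, rowNamesAs = "gene")
}

#' Read a candidate-SNP table (snp, risk allele, published p-value)
#' @param path TSV with columns snp, effect_allele, pub_p (and optionally
#'   source).
#' @return validated data.frame.
#' @export
readCandidateTable <- function(path) {
  df <- readTable(path, required = c("snp", "pub_p"),
                  numeric = "pub_p")
  .checkNoDupIds(df$snp, "SNP")
  if (any(df$pub_p <= 0 | df$pub_p > 1, na.rm = TRUE))
    stop("published p-values must lie in (0, 1]")
  df
}

#' Read a pairwise LD table (snp_a, snp_b, r2); PLINK --r2 headers accepted
#' @param path TSV file.
#' @return data.frame with columns snp_a, snp_b, r2.
#' @export
readLDTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (all(c("snp_a", "snp_b") %in% names(df))) {
  } else stop("LD table needs SNP_A/SNP_B (or snp_a/snp_b) columns")
  df$r2 <- as.numeric(df$r2)
  if (any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  df[, c("snp_a", "snp_b", "r2")]
}

#' Read a case-case summary-statistics table
#' @param path TSV with columns snp, effect_allele, beta_er_neg,
#'   beta_er_pos, freq, pub_p.
#' @return validated data.frame.
#' @export
readSummaryStats <- function(path) {
  df <- readTable(path,
                  required = c("snp", "beta_er_neg", "beta_er_pos",
                               "freq", "pub_p"),
                  numeric = c("beta_er_neg", "beta_er_pos", "freq",
                              "pub_p"))
  .checkNoDupIds(df$snp, "SNP")
  if (any(df$freq <= 0 | df$freq >= 1, na.rm = TRUE))
    stop("frequencies must lie strictly inside (0, 1)")
  df
}

#' Read a clinical/outcome table
#' @param path TSV with at least time and event columns; additional
#'   covariate columns pass through.
#' @return validated data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- readTable(path, required = c("time", "event"),
                  numeric = c("time", "event"))
  if ("sample" %in% names(df)) .checkNoDupIds(df$sample, "sample")
  if (any(df$time <= 0, na.rm = TRUE))
    stop("follow-up times must be > 0")
  if (!all(df$event %in% c(0, 1, NA)))
    stop("event indicator must be 0/1")
  df
}
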