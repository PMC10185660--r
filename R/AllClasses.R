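#' GenotypeMatrix: samples-by-SNPs risk-allele dosages
#'
#' Container for a dosage matrix (rows are samples, columns are SNPs) with
#' per-SNP metadata. Dosages count copies of the effect (risk) allele and are
#' 0, 1, 2 or \code{NA} (missing).
#'
#' @slot dosage numeric matrix, samples x SNPs, entries in \{0, 1, 2, NA\}.
#' @slot snpInfo data.frame with one row per SNP (rownames are SNP ids) and
#'   at least columns \code{effect_allele} and \code{other_allele}; a
#'   \code{freq} column, when present, records the generating or reference
#'   effect-allele frequency.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(dosage = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msgs <- character()
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    msgs <- c(msgs, "dosage entries must be 0, 1, 2 or NA")
  if (is.null(colnames(d)))
    msgs <- c(msgs, "dosage matrix must have SNP column names")
  if (is.null(rownames(d)))
    msgs <- c(msgs, "dosage matrix must have sample row names")
  if (nrow(object@snpInfo) != ncol(d))
    msgs <- c(msgs, "snpInfo must have one row per SNP column")
  if (!is.null(colnames(d)) && nrow(object@snpInfo) == ncol(d) &&
      !identical(rownames(object@snpInfo), colnames(d)))
    msgs <- c(msgs, "rownames(snpInfo) must match colnames(dosage)")
  if (!all(c("effect_allele", "other_allele") %in% colnames(object@snpInfo)))
    msgs <- c(msgs, "snpInfo needs effect_allele and other_allele columns")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of effect-allele dosages (samples x SNPs),
#'   entries in \{0, 1, 2, NA\}. Row and column names identify samples and
#'   SNPs; defaults are generated when absent.
#' @param snpInfo optional data.frame of per-SNP metadata (rownames must be
#'   the SNP ids in column order). When omitted, placeholder alleles A/G are
#'   recorded.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2,
#'                            dimnames = list(c("s1", "s2"), c("rs1", "rs2"))))
#' dosages(g)
#' @export
GenotypeMatrix <- function(dosage, snpInfo = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%05d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%04d", seq_len(ncol(dosage)))
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(effect_allele = rep("A", ncol(dosage)),
                          other_allele = rep("G", ncol(dosage)),
                          row.names = colnames(dosage),
                          stringsAsFactors = FALSE)
  }
  new("GenotypeMatrix", dosage = dosage, snpInfo = snpInfo)
}

#' @describeIn GenotypeMatrix dosage matrix accessor
#' @param x a GenotypeMatrix
#' @export
dosages <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  x@dosage
}

#' @describeIn GenotypeMatrix per-SNP metadata accessor
#' @export
snpInfo <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  x@snpInfo
}

#' @describeIn GenotypeMatrix observed effect-allele frequency among
#'   non-missing genotypes
#' @export
alleleFreq <- function(x) {
  colMeans(dosages(x), na.rm = TRUE) / 2
}

#' @describeIn GenotypeMatrix fraction of missing entries per SNP
#' @export
snpMissingness <- function(x) {
  colMeans(is.na(dosages(x)))
}

setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat("GenotypeMatrix:", nrow(d), "samples x", ncol(d), "SNPs\n")
  mis <- mean(is.na(d))
  cat(sprintf("  missing entries: %.2f%%\n", 100 * mis))
  cat("  snpInfo columns:", paste(colnames(object@snpInfo), collapse = ", "),
      "\n")
})

setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  d <- x@dosage[i, j, drop = FALSE]
  new("GenotypeMatrix", dosage = d,
      snpInfo = x@snpInfo[colnames(d), , drop = FALSE])
})

#' CentroidMatrix: PAM50-style subtype centroids
#'
#' Genes-by-subtypes centroid matrix with exactly the five intrinsic-subtype
#' columns (Basal, Her2, LumA, LumB, Normal) plus the identity of the
#' proliferation-gene subset used for the proliferation index.
#'
#' @slot centroids numeric matrix, genes x 5 subtypes.
#' @slot prolifGenes character vector of proliferation genes (a subset of the
#'   centroid gene ids; 11 genes in the canonical signature).
#'
#' @aliases CentroidMatrix-class
#' @exportClass CentroidMatrix
setClass("CentroidMatrix",
         representation(centroids = "matrix", prolifGenes = "character"))

setValidity("CentroidMatrix", function(object) {
  msgs <- character()
  if (!identical(colnames(object@centroids), .subtypeLabels))
    msgs <- c(msgs, paste("centroid columns must be exactly",
                          paste(.subtypeLabels, collapse = ", ")))
  if (anyDuplicated(rownames(object@centroids)))
    msgs <- c(msgs, "duplicate gene ids in centroid matrix")
  if (!all(object@prolifGenes %in% rownames(object@centroids)))
    msgs <- c(msgs, "prolifGenes must be a subset of centroid gene ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CentroidMatrix
#'
#' @param centroids numeric matrix (genes x subtypes) with columns Basal,
#'   Her2, LumA, LumB, Normal and gene ids as rownames.
#' @param prolifGenes character vector naming the proliferation-index genes.
#' @return A \linkS4class{CentroidMatrix}.
#' @export
CentroidMatrix <- function(centroids, prolifGenes = character()) {
  centroids <- as.matrix(centroids)
  new("CentroidMatrix", centroids = centroids,
      prolifGenes = as.character(prolifGenes))
}

#' @describeIn CentroidMatrix centroid matrix accessor
#' @param x a CentroidMatrix
#' @export
centroids <- function(x) {
  stopifnot(is(x, "CentroidMatrix"))
  x@centroids
}

#' @describeIn CentroidMatrix proliferation-gene accessor
#' @export
prolifGenes <- function(x) {
  stopifnot(is(x, "CentroidMatrix"))
  x@prolifGenes
}

setMethod("show", "CentroidMatrix", function(object) {
  cat("CentroidMatrix:", nrow(object@centroids), "genes x 5 subtypes;",
      length(object@prolifGenes), "proliferation genes\n")
})

#' RORPModel: coefficients and reporting options for the ROR-P score
#'
#' The ROR-P score is a fixed linear combination of the four prognostic
#' subtype-centroid correlations and the proliferation index:
#' \deqn{RORP = -0.001 Basal + 0.7 Her2 - 0.95 LumA + 0.49 LumB + 0.34 Prolif}
#' The Normal-like correlation participates in the subtype call but carries
#' no weight in the score. An optional affine rescale (slope, intercept) maps
#' the raw score onto a reporting scale (clinical reports use roughly 0-100),
#' and optional cutoffs split samples into Low/Medium/High groups.
#'
#' @slot coefficients named numeric: Basal, Her2, LumA, LumB, Prolif weights.
#' @slot rescale numeric of length 0 (raw score) or 2 (slope, intercept).
#' @slot cutoffs numeric of length 0 or 2 (low < high) for grouping.
#'
#' @aliases RORPModel-class
#' @exportClass RORPModel
setClass("RORPModel",
         representation(coefficients = "numeric", rescale = "numeric",
                        cutoffs = "numeric"))

setValidity("RORPModel", function(object) {
  msgs <- character()
  need <- c("Basal", "Her2", "LumA", "LumB", "Prolif")
  if (!all(need %in% names(object@coefficients)))
    msgs <- c(msgs, "coefficients must be named Basal, Her2, LumA, LumB, Prolif")
  if (!length(object@rescale) %in% c(0L, 2L))
    msgs <- c(msgs, "rescale must be empty or c(slope, intercept)")
  if (length(object@cutoffs) == 2L &&
      object@cutoffs[1] >= object@cutoffs[2])
    msgs <- c(msgs, "low cutoff must be below high cutoff")
  if (!length(object@cutoffs) %in% c(0L, 2L))
    msgs <- c(msgs, "cutoffs must be empty or c(low, high)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RORPModel
#'
#' @param coefficients named numeric weights for Basal, Her2, LumA, LumB and
#'   Prolif. Defaults to the canonical ROR-P coefficients.
#' @param rescale optional \code{c(slope, intercept)} applied after the
#'   linear combination; \code{NULL} reports the raw score.
#' @param cutoffs optional \code{c(low, high)} cutpoints for Low/Medium/High
#'   grouping (on the reported scale).
#' @return An \linkS4class{RORPModel}.
#' @examples
#' m <- rorpModel()
#' m
#' @export
rorpModel <- function(coefficients = .rorpCoefficients, rescale = NULL,
                      cutoffs = NULL) {
  new("RORPModel", coefficients = coefficients,
      rescale = if (is.null(rescale)) numeric() else as.numeric(rescale),
      cutoffs = if (is.null(cutoffs)) numeric() else as.numeric(cutoffs))
}

setMethod("show", "RORPModel", function(object) {
  co <- object@coefficients
  cat("RORPModel:",
      paste(sprintf("%+.3f*%s", co, names(co)), collapse = " "), "\n")
  if (length(object@rescale))
    cat(sprintf("  rescale: score * %.4g + %.4g\n",
                object@rescale[1], object@rescale[2]))
  if (length(object@cutoffs))
    cat(sprintf("  group cutoffs: low < %.4g <= medium < %.4g <= high\n",
                object@cutoffs[1], object@cutoffs[2]))
})

#' GroundTruth: recorded generating state of a synthetic cohort
#'
#' Per-sample latent quantities (latent ROR-P, its genetic component, true
#' intrinsic subtype, proliferation, receptor status, ancestry PCs, study)
#' and per-SNP true effects, as recorded by the cohort simulator. Used for
#' parameter-recovery tests; never consumed by the analysis path.
#'
#' @slot samples data.frame of per-sample ground truth.
#' @slot snpEffects data.frame of per-SNP true effects on the subtype and
#'   proliferation channels.
#' @slot params list of generator parameters actually used (including the
#'   calibrated proliferation noise SD).
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(samples = "data.frame", snpEffects = "data.frame",
                        params = "list"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@samples), "samples;",
      sum(object@snpEffects$subtype_effect != 0 |
            object@snpEffects$prolif_effect != 0), "causal SNPs\n")
  cat(sprintf("  latent ROR-P var: %.3f; genetic R2 (realized): %.3f\n",
              var(object@samples$latent_rorp),
              cor(object@samples$latent_rorp,
                  object@samples$genetic_value)^2))
})

#' @describeIn GroundTruth per-sample ground-truth accessor
#' @param x a GroundTruth
#' @export
truthSamples <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@samples
}

#' @describeIn GroundTruth per-SNP true-effect accessor
#' @export
truthSnpEffects <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@snpEffects
}
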