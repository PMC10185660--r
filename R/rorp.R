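# PAM50-style subtype calling and ROR-P scoring: probe collapse,
# ER-balanced median-of-medians normalization, Spearman centroid
# correlations, proliferation index, and the ROR-P linear combination.

.exprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) assay(expr) else as.matrix(expr)
}

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to the same gene are averaged (arithmetic mean). Gene-level
#' input (every probe its own gene) passes through unchanged. Unmapped probes
#' are dropped with a warning; a probe mapped to more than one gene is an
#' input error.
#'
#' @param expr SummarizedExperiment or matrix, features x samples.
#' @param probeMap data.frame with columns \code{probe} and \code{gene};
#'   when \code{NULL} and \code{expr} carries a \code{gene} column in
#'   \code{rowData}, that mapping is used.
#' @return SummarizedExperiment, genes x samples, with attribute-free clean
#'   mapping; the number of dropped probes is recorded in
#'   \code{metadata()$droppedProbes}.
#' @export
collapseProbes <- function(expr, probeMap = NULL) {
  E <- .exprMatrix(expr)
  if (is.null(probeMap)) {
    if (is(expr, "SummarizedExperiment") &&
        "gene" %in% colnames(rowData(expr))) {
      probeMap <- data.frame(probe = rownames(expr),
                             gene = rowData(expr)$gene,
                             stringsAsFactors = FALSE)
    } else {
      stop("probeMap is required when expr carries no gene mapping")
    }
  }
  if (anyDuplicated(probeMap$probe)) {
    dup <- unique(probeMap$probe[duplicated(probeMap$probe)])
    bad <- vapply(dup, function(p)
      length(unique(probeMap$gene[probeMap$probe == p])) > 1, logical(1))
    if (any(bad))
      stop("probe(s) mapped to multiple genes: ",
           paste(dup[bad], collapse = ", "))
    probeMap <- probeMap[!duplicated(probeMap$probe), ]
  }
  mapped <- rownames(E) %in% probeMap$probe[!is.na(probeMap$gene)]
  nDropped <- sum(!mapped)
  if (nDropped > 0)
    warning(nDropped, " unmapped probe(s) dropped")
  E <- E[mapped, , drop = FALSE]
  gene <- probeMap$gene[match(rownames(E), probeMap$probe)]
  G <- rowsum(E, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(G)])
  G <- G / counts
  out <- SummarizedExperiment(
    assays = list(exprs = G),
    rowData = DataFrame(gene = rownames(G), row.names = rownames(G)),
    colData = if (is(expr, "SummarizedExperiment")) colData(expr)
              else DataFrame(row.names = colnames(G)))
  metadata(out)$droppedProbes <- nDropped
  out
}

#' ER-balanced median-of-medians normalization
#'
#' Repeatedly subsamples all ER-negative cases plus an equal number of
#' randomly chosen ER-positive cases (without replacement), records the
#' per-gene median of each subsample, takes the per-gene median of the
#' \code{nReps} medians as the reference, and subtracts it from every sample.
#' This matches the target distribution of the original nearest-centroid
#' assay ("population assumption") when the input series is ER-imbalanced.
#' When fewer ER-positive than ER-negative samples are available, sampling
#' falls back to with-replacement with a warning. Deterministic given
#' \code{seed}.
#'
#' @param expr SummarizedExperiment (genes x samples) or matrix.
#' @param er optional character/factor of ER status ("positive"/"negative");
#'   taken from \code{colData(expr)$er_status} when omitted.
#' @param nReps number of subsampling repetitions (default 1000).
#' @param seed integer seed.
#' @return SummarizedExperiment of normalized expression; the per-gene
#'   reference medians are stored in \code{metadata()$referenceMedians}.
#' @export
erBalancedNormalize <- function(expr, er = NULL, nReps = 1000, seed = 1) {
  E <- .exprMatrix(expr)
  if (is.null(er)) {
    if (!is(expr, "SummarizedExperiment") ||
        !"er_status" %in% colnames(colData(expr)))
      stop("er status not supplied and not present in colData")
    er <- as.character(colData(expr)$er_status)
  }
  er <- as.character(er)
  if (length(er) != ncol(E))
    stop("er status length must equal the number of samples")
  neg <- which(er == "negative")
  pos <- which(er == "positive")
  if (length(neg) < 1)
    stop("at least one ER-negative sample is required")
  replacePos <- length(pos) < length(neg)
  if (replacePos)
    warning("fewer ER-positive than ER-negative samples; sampling ",
            "ER-positive cases with replacement")
  nG <- nrow(E)
  withr::with_seed(.deriveSeed(seed, 7L), {
    meds <- vapply(seq_len(nReps), function(r) {
      idx <- c(neg, sample(pos, length(neg), replace = replacePos))
      apply(E[, idx, drop = FALSE], 1, median)
    }, numeric(nG))
  })
  ref <- apply(matrix(meds, nrow = nG), 1, median)
  names(ref) <- rownames(E)
  out <- SummarizedExperiment(
    assays = list(exprs = E - ref),
    rowData = DataFrame(row.names = rownames(E)),
    colData = if (is(expr, "SummarizedExperiment")) colData(expr)
              else DataFrame(er_status = er, row.names = colnames(E)))
  metadata(out)$referenceMedians <- ref
  out
}

#' Spearman correlations with subtype centroids and subtype call
#'
#' For each sample, the Spearman rank correlation between its normalized
#' expression vector and each of the five subtype centroids is computed over
#' the genes shared between expression and centroid matrices (at least 3
#' required). The call is the argmax correlation, ties broken in the fixed
#' label order Basal, Her2, LumA, LumB, Normal. Samples with a constant
#' expression vector have undefined correlations and are flagged
#' (\code{flagged = TRUE}, call \code{NA}).
#'
#' @param exprNorm normalized SummarizedExperiment or matrix.
#' @param centroidMatrix a \linkS4class{CentroidMatrix}.
#' @return data.frame with one row per sample: the five correlations,
#'   \code{call}, and \code{flagged}; the shared-gene count is recorded in
#'   \code{attr(, "sharedGenes")}.
#' @export
subtypeCorrelations <- function(exprNorm, centroidMatrix) {
  E <- .exprMatrix(exprNorm)
  C <- centroids(centroidMatrix)
  shared <- intersect(rownames(E), rownames(C))
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between expression and centroids")
  E <- E[shared, , drop = FALSE]
  C <- C[shared, , drop = FALSE]
  constant <- apply(E, 2, function(v) sd(v) < 1e-12)
  cors <- suppressWarnings(cor(E, C, method = "spearman"))
  cors[constant, ] <- NA
  call <- rep(NA_character_, ncol(E))
  ok <- !constant
  if (any(ok))
    call[ok] <- .subtypeLabels[max.col(cors[ok, , drop = FALSE],
                                       ties.method = "first")]
  out <- data.frame(sample = colnames(E), cors, call = call,
                    flagged = constant, row.names = colnames(E),
                    stringsAsFactors = FALSE)
  attr(out, "sharedGenes") <- length(shared)
  out
}

#' Proliferation index
#'
#' Arithmetic mean of normalized expression over the flagged proliferation
#' genes. All proliferation genes must be present.
#'
#' @param exprNorm normalized SummarizedExperiment or matrix.
#' @param centroidMatrix a \linkS4class{CentroidMatrix} whose
#'   \code{prolifGenes} defines the subset.
#' @return named numeric, one value per sample.
#' @export
proliferationIndex <- function(exprNorm, centroidMatrix) {
  E <- .exprMatrix(exprNorm)
  pg <- prolifGenes(centroidMatrix)
  missing <- setdiff(pg, rownames(E))
  if (length(missing))
    stop("proliferation gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  colMeans(E[pg, , drop = FALSE])
}

#' Full subtype-correlation profile
#'
#' Combines \code{\link{subtypeCorrelations}} and
#' \code{\link{proliferationIndex}} into the per-sample profile consumed by
#' \code{\link{computeRORP}}.
#'
#' @inheritParams subtypeCorrelations
#' @return data.frame with the five correlations, \code{Prolif},
#'   \code{call} and \code{flagged}.
#' @export
subtypeProfile <- function(exprNorm, centroidMatrix) {
  prof <- subtypeCorrelations(exprNorm, centroidMatrix)
  prof$Prolif <- as.numeric(proliferationIndex(exprNorm, centroidMatrix))
  prof
}

#' Compute the ROR-P score
#'
#' Applies the ROR-P linear combination
#' \code{-0.001*Basal + 0.7*Her2 - 0.95*LumA + 0.49*LumB + 0.34*Prolif}
#' (or the model's override coefficients) to a subtype-correlation profile,
#' followed by the model's optional affine rescale. The Normal-like
#' correlation enters the subtype call but not the score.
#'
#' @param profile data.frame from \code{\link{subtypeProfile}} (columns
#'   Basal, Her2, LumA, LumB, Prolif required).
#' @param model an \linkS4class{RORPModel}.
#' @return named numeric vector of ROR-P scores.
#' @examples
#' prof <- data.frame(Basal = 0.2, Her2 = 0.1, LumA = -0.5, LumB = 0.4,
#'                    Prolif = 0.6)
#' computeRORP(prof)  # 0.9448
#' @export
computeRORP <- function(profile, model = rorpModel()) {
  validObject(model)
  comp <- c("Basal", "Her2", "LumA", "LumB", "Prolif")
  missing <- setdiff(comp, colnames(profile))
  if (length(missing))
    stop("profile is missing component(s): ",
         paste(missing, collapse = ", "))
  M <- as.matrix(profile[, comp])
  if (anyNA(M))
    stop("profile contains missing component values")
  score <- as.vector(M %*% model@coefficients[comp])
  if (length(model@rescale))
    score <- score * model@rescale[1] + model@rescale[2]
  names(score) <- rownames(profile)
  score
}

#' Group ROR-P scores into Low/Medium/High
#'
#' @param score numeric ROR-P scores.
#' @param cutoffs numeric \code{c(low, high)}: Low below \code{low}, High at
#'   or above \code{high}.
#' @return factor with levels Low, Medium, High.
#' @export
rorpGroups <- function(score, cutoffs) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  cut(score, breaks = c(-Inf, cutoffs, Inf),
      labels = c("Low", "Medium", "High"), right = FALSE)
}

#' Score ROR-P from raw expression in one call
#'
#' Convenience pipeline: probe collapse (when a mapping is available),
#' ER-balanced normalization, subtype profile and ROR-P computation.
#'
#' @param expr SummarizedExperiment or matrix (features x samples).
#' @param centroidMatrix a \linkS4class{CentroidMatrix}.
#' @param er optional ER status vector (else from colData).
#' @param nReps,seed normalization subsampling parameters.
#' @param model an \linkS4class{RORPModel}.
#' @param probeMap optional probe-to-gene map.
#' @return data.frame per sample: five centroid correlations, Prolif, call,
#'   flagged, and \code{rorp}.
#' @export
scoreRORP <- function(expr, centroidMatrix, er = NULL, nReps = 1000,
                      seed = 1, model = rorpModel(), probeMap = NULL) {
  hasMap <- !is.null(probeMap) ||
    (is(expr, "SummarizedExperiment") &&
       "gene" %in% colnames(rowData(expr)) &&
       !identical(rownames(expr), unname(rowData(expr)$gene)))
  if (hasMap) expr <- collapseProbes(expr, probeMap)
  norm <- erBalancedNormalize(expr, er = er, nReps = nReps, seed = seed)
  prof <- subtypeProfile(norm, centroidMatrix)
  ok <- !prof$flagged
  prof$rorp <- NA_real_
  if (any(ok))
    prof$rorp[ok] <- computeRORP(prof[ok, , drop = FALSE], model)
  prof
}
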