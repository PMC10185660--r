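# Comparator scores: case-case ER-/ER+ effect contrasts from paired
# case-control summary statistics, and population-calibrated
# likelihood-ratio PRSs built from per-allele odds ratios and risk-allele
# frequencies (also used for the overall-risk PRS).

#' Case-case effect contrast from paired case-control summary statistics
#'
#' When log-odds for ER-negative and ER-positive disease are estimated
#' against the same control group, their difference is the case-case
#' log-odds of ER-negative versus ER-positive disease:
#' \code{beta_contrast = beta_ER- - beta_ER+}. SNPs missing either estimate
#' are dropped with a warning.
#'
#' @param stats data.frame with columns \code{snp}, \code{beta_er_neg},
#'   \code{beta_er_pos}; other columns pass through.
#' @return \code{stats} augmented with \code{beta_contrast} and
#'   \code{or_contrast}.
#' @export
caseCaseBeta <- function(stats) {
  stopifnot(all(c("snp", "beta_er_neg", "beta_er_pos") %in%
                  colnames(stats)))
  bad <- is.na(stats$beta_er_neg) | is.na(stats$beta_er_pos)
  if (any(bad))
    warning(sum(bad), " SNP(s) dropped for missing beta: ",
            paste(head(stats$snp[bad], 5), collapse = ", "))
  out <- stats[!bad, , drop = FALSE]
  out$beta_contrast <- out$beta_er_neg - out$beta_er_pos
  out$or_contrast <- exp(out$beta_contrast)
  out
}

#' Per-genotype likelihood-ratio weights from an odds ratio and frequency
#'
#' Under a per-allele multiplicative model with risk-allele frequency
#' \code{p} (q = 1 - p) and Hardy-Weinberg genotype prior, the mean
#' multiplicative risk is \code{mu = (p*OR + q)^2}; the likelihood ratio for
#' genotype g (0, 1, 2 risk alleles) is \code{LR_g = OR^g / mu}, so that the
#' population-mean LR equals 1 by construction:
#' \code{q^2*LR0 + 2pq*LR1 + p^2*LR2 = 1}.
#'
#' @param snp SNP ids (recycled metadata; optional, default seq).
#' @param or per-allele odds ratio(s), > 0.
#' @param freq risk-allele frequency(ies), strictly inside (0, 1).
#' @param effectAllele optional effect-allele labels.
#' @return \code{LikelihoodRatioWeights} data.frame: snp, effect_allele,
#'   or, freq, lr0, lr1, lr2.
#' @examples
#' buildLRWeights(or = 2, freq = 0.5)  # mu = 2.25; LR = 4/9, 8/9, 16/9
#' @export
buildLRWeights <- function(or, freq, snp = NULL, effectAllele = NULL) {
  if (any(or <= 0)) stop("odds ratios must be > 0")
  if (any(freq <= 0 | freq >= 1))
    stop("risk-allele frequencies must lie strictly inside (0, 1)")
  n <- max(length(or), length(freq))
  or <- rep_len(or, n)
  freq <- rep_len(freq, n)
  if (is.null(snp)) snp <- sprintf("snp%04d", seq_len(n))
  if (is.null(effectAllele)) effectAllele <- rep("A", n)
  mu <- (freq * or + (1 - freq))^2
  data.frame(snp = as.character(snp),
             effect_allele = as.character(effectAllele),
             or = or, freq = freq,
             lr0 = 1 / mu, lr1 = or / mu, lr2 = or^2 / mu,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a likelihood-ratio (multiplicative) PRS
#'
#' \code{PRS = prod_k LR_(g_k)} over the weight SNPs available in the
#' genotype matrix, computed as the exponentiated sum of log-LRs for
#' numerical stability. SNPs absent from the genotypes, and missing
#' dosages, contribute a factor of 1; the coverage fraction is reported.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param weights data.frame from \code{\link{buildLRWeights}}.
#' @param onMissing only \code{"skip"} is implemented.
#' @return numeric product score per sample with attributes
#'   \code{coverage} and \code{nUsed}.
#' @export
scoreLRPRS <- function(genotypes, weights, onMissing = "skip") {
  onMissing <- match.arg(onMissing, "skip")
  X <- dosages(genotypes)
  avail <- intersect(as.character(weights$snp), colnames(X))
  if (!length(avail))
    stop("no weight SNP present in the genotype matrix")
  w <- weights[match(avail, weights$snp), , drop = FALSE]
  logLR <- log(cbind(w$lr0, w$lr1, w$lr2))
  G <- X[, avail, drop = FALSE]
  acc <- numeric(nrow(G))
  for (k in seq_along(avail)) {
    g <- G[, k]
    contrib <- logLR[k, ][g + 1L]
    contrib[is.na(g)] <- 0
    acc <- acc + contrib
  }
  out <- exp(acc)
  names(out) <- rownames(X)
  attr(out, "coverage") <- length(avail) / nrow(weights)
  attr(out, "nUsed") <- length(avail)
  out
}

#' Build the case-case ER-/ER+ likelihood-ratio PRS weights
#'
#' Applies LD pruning (r2 threshold 0.2, keeping the SNP with the lower
#' published p-value) to the summary-statistic SNPs, forms the case-case
#' contrast, and converts the contrast odds ratio and risk-allele frequency
#' into population-calibrated likelihood-ratio weights.
#'
#' @param stats data.frame with columns snp, effect_allele, beta_er_neg,
#'   beta_er_pos, freq, pub_p.
#' @param ld LD table (snp_a, snp_b, r2); pairs not listed are assumed
#'   independent.
#' @param r2Threshold LD pruning threshold (default 0.2).
#' @return \code{LikelihoodRatioWeights} data.frame (one row per retained
#'   SNP).
#' @export
buildERPRS <- function(stats, ld, r2Threshold = 0.2) {
  stopifnot(all(c("snp", "freq", "pub_p") %in% colnames(stats)))
  pruned <- ldPrune(stats, ld, r2Threshold = r2Threshold)
  cc <- caseCaseBeta(pruned)
  buildLRWeights(or = cc$or_contrast, freq = cc$freq, snp = cc$snp,
                 effectAllele = if ("effect_allele" %in% colnames(cc))
                   cc$effect_allele else NULL)
}
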