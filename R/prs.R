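# PRS construction for ROR-P: LD pruning, Hardy-Weinberg fill of missing
# genotypes, ancestry/study residualization, per-SNP scans, repeated
# cross-validated p-value threshold selection, final weights and scoring.

#' Greedy LD pruning of a candidate SNP table
#'
#' Candidates are visited in order of ascending published p-value (ties by
#' SNP id); a SNP is kept iff its r-squared with every already-kept SNP is
#' below the threshold. Pairs absent from the LD table are assumed
#' independent (r2 = 0). Within a correlated pair this keeps the SNP with
#' the lower published p-value.
#'
#' @param candidates data.frame with columns \code{snp} and \code{pub_p}
#'   (published p-value); other columns pass through.
#' @param ld data.frame with columns \code{snp_a}, \code{snp_b}, \code{r2}
#'   (PLINK-style \code{SNP_A}/\code{SNP_B}/\code{R2} headers accepted).
#' @param r2Threshold pairs at or above this r-squared are mutually
#'   exclusive (default 0.2).
#' @return the retained subset of \code{candidates}, in input order, with
#'   attribute \code{"dropped"} listing removed SNP ids.
#' @examples
#' cand <- data.frame(snp = c("A", "B", "C"), pub_p = c(1e-9, 1e-8, 1e-7))
#' ld <- data.frame(snp_a = c("A", "B"), snp_b = c("B", "C"),
#'                  r2 = c(0.25, 0.25))
#' ldPrune(cand, ld)$snp  # "A" "C"
#' @export
ldPrune <- function(candidates, ld, r2Threshold = 0.2) {
  stopifnot(all(c("snp", "pub_p") %in% colnames(candidates)))
  names(ld) <- tolower(names(ld))
  if ("snp_a" %in% names(ld)) {
    a <- as.character(ld$snp_a); b <- as.character(ld$snp_b)
  } else stop("ld table needs snp_a / snp_b columns")
  r2 <- ld$r2
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  hot <- r2 >= r2Threshold
  adj <- split(c(b[hot], a[hot]), c(a[hot], b[hot]))
  ord <- order(candidates$pub_p, candidates$snp)
  kept <- character()
  keptSet <- new.env(hash = TRUE, parent = emptyenv())
  for (i in ord) {
    s <- as.character(candidates$snp[i])
    partners <- adj[[s]]
    if (is.null(partners) ||
        !any(vapply(partners, exists, logical(1), envir = keptSet))) {
      assign(s, TRUE, envir = keptSet)
      kept <- c(kept, s)
    }
  }
  out <- candidates[candidates$snp %in% kept, , drop = FALSE]
  attr(out, "dropped") <- setdiff(as.character(candidates$snp), kept)
  out
}

#' Exclude high-missingness SNPs and fill the rest from Hardy-Weinberg
#'
#' SNPs with missingness above \code{maxMissing} (default 5\%) are removed.
#' For the remaining SNPs, each missing entry is drawn from the
#' Hardy-Weinberg genotype distribution (q^2, 2pq, p^2) implied by the
#' effect-allele frequency observed among that SNP's non-missing samples.
#' Deterministic given \code{seed}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} with \code{NA} entries.
#' @param maxMissing missingness threshold above which a SNP is excluded.
#' @param seed integer seed.
#' @return A complete \linkS4class{GenotypeMatrix}; excluded SNP ids are in
#'   \code{attr(, "excluded")}.
#' @export
fillMissingGenotypes <- function(genotypes, maxMissing = 0.05, seed = 1) {
  d <- dosages(genotypes)
  miss <- colMeans(is.na(d))
  allMiss <- miss == 1
  if (any(allMiss))
    warning(sum(allMiss), " SNP(s) with all entries missing removed")
  drop <- miss > maxMissing
  excluded <- colnames(d)[drop]
  d <- d[, !drop, drop = FALSE]
  if (anyNA(d)) {
    withr::with_seed(.deriveSeed(seed, 8L), {
      for (j in which(colSums(is.na(d)) > 0)) {
        x <- d[, j]
        p <- mean(x, na.rm = TRUE) / 2
        probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
        nNA <- sum(is.na(x))
        d[is.na(x), j] <- sample(0:2, nNA, replace = TRUE, prob = probs)
      }
    })
  }
  out <- GenotypeMatrix(d, snpInfo(genotypes)[colnames(d), , drop = FALSE])
  attr(out, "excluded") <- excluded
  out
}

# Covariate model matrix: PC1-PC10 plus study dummies, with an explicit
# rank-deficiency check that names the offending columns.
.covarMatrix <- function(covars, n = NULL) {
  pcs <- paste0("PC", 1:10)
  if (!all(pcs %in% colnames(covars)))
    stop("covariates must contain columns PC1..PC10")
  df <- covars[, pcs, drop = FALSE]
  if ("study" %in% colnames(covars)) {
    st <- factor(covars$study)
    if (nlevels(st) > 1) df$study <- st
  }
  M <- model.matrix(~ ., data = df)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[seq.int(qrM$rank + 1, ncol(M))]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  M
}

#' Residualize ROR-P on ancestry and study
#'
#' Ordinary least squares of the ROR-P score on PC1-PC10 plus study
#' indicator dummies; returns the residuals (mean zero).
#'
#' @param rorp numeric ROR-P per sample.
#' @param covars data.frame with PC1..PC10 and optionally \code{study}.
#' @return numeric residual vector.
#' @export
residualizeRORP <- function(rorp, covars) {
  if (anyNA(rorp) || anyNA(covars[, paste0("PC", 1:10)]))
    stop("complete ROR-P and covariates required")
  M <- .covarMatrix(covars)
  if (length(rorp) <= ncol(M))
    stop("need more samples than covariate columns")
  qr.resid(qr(M), rorp)
}

#' Per-SNP association scan of a residualized phenotype
#'
#' One simple linear regression of the residual on dosage per SNP;
#' two-sided p-values from the t statistic. Zero-variance (monomorphic)
#' SNPs are flagged and excluded from scoring.
#'
#' @param residuals numeric phenotype residuals.
#' @param genotypes complete \linkS4class{GenotypeMatrix}.
#' @return data.frame: snp, beta, se, p, excluded.
#' @export
snpScan <- function(residuals, genotypes) {
  X <- dosages(genotypes)
  if (anyNA(X)) stop("genotypes must be complete (fill missingness first)")
  stopifnot(length(residuals) == nrow(X))
  n <- length(residuals)
  yc <- residuals - mean(residuals)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  mono <- sxx < 1e-10
  sxy <- as.vector(crossprod(Xc, yc))
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  syy <- sum(yc^2)
  rss <- pmax(syy - beta * sxy, 0)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(snp = colnames(X), beta = beta, se = se, p = p,
             excluded = mono, row.names = NULL, stringsAsFactors = FALSE)
}

# Covariate-adjusted per-SNP weights via Frisch-Waugh-Lovell: the dosage
# coefficient of lm(y ~ dosage + covars), vectorized over SNPs.
.adjustedWeights <- function(y, X, M) {
  qrM <- qr(M)
  yR <- qr.resid(qrM, y)
  XR <- qr.resid(qrM, X)
  sxx <- colSums(XR^2)
  mono <- sxx < 1e-10
  sxy <- as.vector(crossprod(XR, yR))
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  dfres <- length(y) - ncol(M) - 1
  rss <- pmax(sum(yR^2) - beta * sxy, 0)
  se <- sqrt(rss / dfres / sxx)
  p <- 2 * pt(abs(beta / se), dfres, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, mono = mono)
}

#' Select the PRS p-value threshold by repeated k-fold cross-validation
#'
#' For each repeat, samples are partitioned into \code{k} folds. Within each
#' training set the phenotype is residualized on ancestry and study, every
#' SNP is scanned against the residual, and for each grid threshold the SNPs
#' with scan p below the threshold are given covariate-adjusted weights and
#' used to score the held-out fold. The fold r-squared is the squared
#' Pearson correlation between held-out PRS and held-out residuals
#' (residualized with the training-fold covariate model). The cross-validated
#' r-squared per threshold is the mean over all folds and repeats; the
#' selected threshold is the argmax, ties resolved toward the smaller
#' threshold. The final SNP set is a full-data scan at the selected
#' threshold.
#'
#' @param rorp numeric ROR-P per sample.
#' @param covars covariate data.frame (PC1..PC10, study).
#' @param genotypes complete \linkS4class{GenotypeMatrix}.
#' @param candidates optional data.frame with a \code{snp} column
#'   restricting the scan to a candidate panel.
#' @param grid numeric vector of p-value thresholds (default 0.1 to 0.6 in
#'   steps of 0.025).
#' @param k folds (default 5), \code{repeats} repetitions (default 10).
#' @param repeats number of times the k-fold partition is redrawn.
#' @param seed integer seed.
#' @return list of class \code{"cvResult"}: \code{grid}, \code{cvR2} (mean
#'   per threshold), \code{perRepeat} (repeats x thresholds),
#'   \code{selectedThreshold}, \code{selectedSNPs}, \code{nSelected},
#'   \code{scan} (full-data scan).
#' @export
cvThresholdSelection <- function(rorp, covars, genotypes,
                                 candidates = NULL,
                                 grid = seq(0.1, 0.6, by = 0.025),
                                 k = 5, repeats = 10, seed = 1) {
  if (!length(grid)) stop("threshold grid must be nonempty")
  if (k < 2) stop("k must be >= 2")
  if (!is.null(candidates))
    genotypes <- genotypes[, colnames(dosages(genotypes)) %in%
                               as.character(candidates$snp)]
  X <- dosages(genotypes)
  if (anyNA(X)) stop("genotypes must be complete (fill missingness first)")
  n <- nrow(X)
  M <- .covarMatrix(covars)
  grid <- sort(grid)
  perFold <- array(NA_real_, dim = c(repeats, k, length(grid)))
  emptyCells <- 0L
  withr::with_seed(.deriveSeed(seed, 9L), {
    for (r in seq_len(repeats)) {
      fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        tr <- fold != f
        Mtr <- M[tr, , drop = FALSE]
        qrTr <- qr(Mtr)
        resTr <- qr.resid(qrTr, rorp[tr])
        # held-out residuals from the training-fold covariate model
        gam <- qr.coef(qrTr, rorp[tr])
        gam[is.na(gam)] <- 0
        resTe <- rorp[!tr] - as.vector(M[!tr, , drop = FALSE] %*% gam)
        scanP <- snpScan(resTr, GenotypeMatrix(X[tr, , drop = FALSE],
                                               snpInfo(genotypes)))
        w <- .adjustedWeights(rorp[tr], X[tr, , drop = FALSE], Mtr)
        usable <- !scanP$excluded & !w$mono
        for (g in seq_along(grid)) {
          sel <- usable & scanP$p < grid[g]
          if (!any(sel)) {
            perFold[r, f, g] <- 0
            emptyCells <- emptyCells + 1L
            next
          }
          prsTe <- as.vector(X[!tr, sel, drop = FALSE] %*% w$beta[sel])
          perFold[r, f, g] <-
            if (sd(prsTe) < 1e-12 || sd(resTe) < 1e-12) 0
            else cor(prsTe, resTe)^2
        }
      }
    }
  })
  if (emptyCells > 0)
    warning(emptyCells,
            " fold/threshold cell(s) had no SNP below threshold; ",
            "their r2 was recorded as 0")
  cvR2 <- apply(perFold, 3, mean)
  names(cvR2) <- as.character(grid)
  perRepeat <- apply(perFold, c(1, 3), mean)
  colnames(perRepeat) <- as.character(grid)
  best <- grid[which.max(cvR2)]  # which.max takes the first (smallest) tie
  resFull <- residualizeRORP(rorp, covars)
  scanFull <- snpScan(resFull, genotypes)
  selected <- scanFull$snp[!scanFull$excluded & scanFull$p < best]
  structure(list(grid = grid, cvR2 = cvR2, perRepeat = perRepeat,
                 selectedThreshold = best, selectedSNPs = selected,
                 nSelected = length(selected), scan = scanFull),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat("Cross-validated p-value threshold selection\n")
  cat(sprintf("  grid: %g .. %g (%d thresholds)\n", min(x$grid),
              max(x$grid), length(x$grid)))
  cat(sprintf("  selected threshold: %g (CV r2 = %.4f), %d SNPs\n",
              x$selectedThreshold,
              x$cvR2[as.character(x$selectedThreshold)], x$nSelected))
  invisible(x)
}

#' Fit final per-SNP PRS weights
#'
#' For each selected SNP, the weight is the dosage coefficient of the
#' single-SNP linear model \code{rorp ~ dosage + PC1..PC10 + study}, fitted
#' on the full data.
#'
#' @param rorp numeric ROR-P per sample.
#' @param covars covariate data.frame.
#' @param genotypes complete \linkS4class{GenotypeMatrix}.
#' @param snps character vector of selected SNP ids.
#' @param scan optional full-data scan (from
#'   \code{\link{cvThresholdSelection}}) whose p-values are carried into the
#'   weight table as \code{scan_p}.
#' @return \code{PRSWeightTable} data.frame: snp, effect_allele, beta, se,
#'   p, and scan_p when available.
#' @export
fitFinalWeights <- function(rorp, covars, genotypes, snps, scan = NULL) {
  if (!length(snps)) stop("selected SNP set is empty")
  X <- dosages(genotypes)
  missing <- setdiff(snps, colnames(X))
  if (length(missing))
    stop("SNP(s) not in genotypes: ", paste(missing, collapse = ", "))
  X <- X[, snps, drop = FALSE]
  if (anyNA(X)) stop("genotypes must be complete")
  M <- .covarMatrix(covars)
  w <- .adjustedWeights(rorp, X, M)
  info <- snpInfo(genotypes)[snps, , drop = FALSE]
  out <- data.frame(snp = snps, effect_allele = info$effect_allele,
                    beta = w$beta, se = w$se, p = w$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(scan))
    out$scan_p <- scan$p[match(snps, scan$snp)]
  out[!w$mono, , drop = FALSE]
}

#' Score a weighted-sum PRS
#'
#' \code{PRS = sum_k beta_k x_k} over the weight SNPs available in the
#' genotype matrix; unavailable SNPs are dropped without reweighting, and
#' the coverage fraction (available / total weights) is reported.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}; \code{NA} dosages
#'   contribute 0 to the sum.
#' @param weights weight table with columns \code{snp} and \code{beta}.
#' @param onMissing only \code{"drop"} is implemented (matching the use of
#'   partial SNP panels without rescaling).
#' @return numeric PRS per sample with attributes \code{coverage} and
#'   \code{nUsed}.
#' @export
scorePRS <- function(genotypes, weights, onMissing = "drop") {
  onMissing <- match.arg(onMissing, "drop")
  X <- dosages(genotypes)
  avail <- intersect(as.character(weights$snp), colnames(X))
  if (!length(avail))
    stop("no weight SNP present in the genotype matrix")
  b <- weights$beta[match(avail, weights$snp)]
  G <- X[, avail, drop = FALSE]
  G[is.na(G)] <- 0
  prs <- as.vector(G %*% b)
  names(prs) <- rownames(X)
  attr(prs, "coverage") <- length(avail) / nrow(weights)
  attr(prs, "nUsed") <- length(avail)
  prs
}

#' Standardize a PRS
#'
#' \code{"zscore"}: (x - mean) / SD over the case set. \code{"log-zscore"}:
#' natural log first (for multiplicative likelihood-ratio scores), then
#' z-score.
#'
#' @param prs numeric scores.
#' @param mode "zscore" or "log-zscore".
#' @return standardized numeric vector (mean 0, SD 1).
#' @export
standardizePRS <- function(prs, mode = c("zscore", "log-zscore")) {
  mode <- match.arg(mode)
  x <- as.numeric(prs)
  if (length(x) < 2) stop("need at least 2 samples")
  if (mode == "log-zscore") {
    if (any(x <= 0)) stop("log-zscore requires strictly positive scores")
    x <- log(x)
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero standard deviation")
  out <- (x - mean(x)) / s
  names(out) <- names(prs)
  out
}
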