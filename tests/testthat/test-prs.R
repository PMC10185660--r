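# PRS construction: LD pruning, HWE fill, residualization, scans,
# cross-validated threshold selection, weights and scoring.

test_that("ldPrune keeps the lower-p member and honors the greedy order", {
  ld <- data.frame(snp_a = "S1", snp_b = "S2", r2 = 0.3)
  cand <- data.frame(snp = c("S1", "S2"), pub_p = c(1e-9, 1e-8))
  expect_identical(ldPrune(cand, ld)$snp, "S1")
  # below threshold: both kept
  ld2 <- data.frame(snp_a = "S1", snp_b = "S2", r2 = 0.1)
  expect_identical(ldPrune(cand, ld2)$snp, c("S1", "S2"))
  # chain A-B, B-C correlated, A-C not: greedy keeps {A, C}
  cand3 <- data.frame(snp = c("A", "B", "C"),
                      pub_p = c(1e-9, 1e-8, 1e-7))
  ld3 <- data.frame(snp_a = c("A", "B"), snp_b = c("B", "C"),
                    r2 = c(0.25, 0.25))
  expect_identical(ldPrune(cand3, ld3)$snp, c("A", "C"))
  expect_error(ldPrune(cand3, transform(ld3, r2 = c(0.5, 1.2))),
               "\\[0, 1\\]")
})

test_that("ldPrune output is maximal: every dropped SNP conflicts with a kept one", {
  set.seed(41)
  snps <- sprintf("rs%03d", 1:40)
  cand <- data.frame(snp = snps, pub_p = runif(40, 1e-10, 1e-5))
  pairs <- t(combn(40, 2))
  pick <- sample(nrow(pairs), 120)
  ld <- data.frame(snp_a = snps[pairs[pick, 1]],
                   snp_b = snps[pairs[pick, 2]],
                   r2 = runif(120))
  kept <- ldPrune(cand, ld)
  r2of <- function(a, b) {
    hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
    if (any(hit)) max(ld$r2[hit]) else 0
  }
  keptIds <- kept$snp
  # no retained pair in LD
  for (i in seq_along(keptIds)) for (j in seq_len(i - 1))
    expect_lt(r2of(keptIds[i], keptIds[j]), 0.2)
  # every dropped SNP is blocked by some kept SNP
  for (d in attr(kept, "dropped"))
    expect_true(any(vapply(keptIds, function(k) r2of(d, k) >= 0.2,
                           logical(1))))
})

test_that("fillMissingGenotypes excludes >5% missingness and fills from HWE", {
  g <- hweGenotypes(400, c(0.3, 0.4, 0.2), seed = 2)
  d <- dosages(g)
  d[1:30, 1] <- NA     # 7.5% missing -> excluded
  d[1:10, 2] <- NA     # 2.5% missing -> filled
  gm <- GenotypeMatrix(d, snpInfo(g))
  filled <- fillMissingGenotypes(gm, seed = 3)
  expect_identical(attr(filled, "excluded"), "snp0001")
  expect_false(anyNA(dosages(filled)))
  expect_identical(dim(dosages(filled)), c(400L, 2L))
  # untouched SNP passes through unchanged
  expect_identical(dosages(filled)[, "snp0003"], d[, 3])
  # no missingness: identity
  g2 <- hweGenotypes(50, c(0.25), seed = 5)
  expect_identical(dosages(fillMissingGenotypes(g2)), dosages(g2))
  # all-missing SNP removed with warning
  d3 <- dosages(hweGenotypes(50, c(0.3, 0.3), seed = 6))
  d3[, 2] <- NA
  expect_warning(f3 <- fillMissingGenotypes(GenotypeMatrix(d3)),
                 "all entries missing")
  expect_identical(colnames(dosages(f3)), "snp0001")
})

test_that("residualizeRORP matches OLS and reports collinearity", {
  co <- nullCovars(500, seed = 8)
  withr::with_seed(1, {
    y <- 2 * co$PC1 + rnorm(500)
  })
  r <- residualizeRORP(y, co)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  expect_equal(var(r), 1, tolerance = 0.15)
  # phenotype exactly linear in PC1: residuals vanish
  expect_lt(max(abs(residualizeRORP(3 * co$PC1 - 1, co))), 1e-8)
  # orthogonal covariates: residual equals centered phenotype
  yInd <- withr::with_seed(2, rnorm(500))
  ortho <- residuals(lm(yInd ~ ., data = co))
  expect_lt(max(abs(residualizeRORP(ortho + 5, co) - ortho)), 1e-8)
  # rank deficiency names the collinear column
  bad <- co; bad$PC10 <- bad$PC1
  expect_error(residualizeRORP(y, bad), "PC10")
})

test_that("snpScan recovers simulated effects and flags monomorphic SNPs", {
  g <- hweGenotypes(2000, c(0.3, 0.4), seed = 9)
  d <- cbind(dosages(g), snp0003 = rep(1, 2000))
  g <- GenotypeMatrix(d)
  withr::with_seed(3, {
    y <- 0.5 * d[, 1] + rnorm(2000)
  })
  scan <- snpScan(y - mean(y), g)
  expect_true(scan$excluded[3])
  expect_true(is.na(scan$beta[3]))
  ci <- scan$beta[1] + c(-1.96, 1.96) * scan$se[1]
  expect_gt(0.5, ci[1]); expect_lt(0.5, ci[2])
  # agrees with lm to numerical precision
  ref <- summary(lm(y ~ d[, 1]))$coefficients[2, ]
  expect_equal(scan$beta[1], unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(scan$se[1], unname(ref["Std. Error"]), tolerance = 1e-8)
})

test_that("cross-validation is seeded, warns on empty thresholds, and is honest on null data", {
  n <- 600
  g <- hweGenotypes(n, runif(40, 0.1, 0.5), seed = 12)
  co <- nullCovars(n, seed = 13)
  y <- withr::with_seed(14, rnorm(n))
  cv1 <- cvThresholdSelection(y, co, g, grid = c(0.2, 0.4), k = 3,
                              repeats = 2, seed = 15)
  cv2 <- cvThresholdSelection(y, co, g, grid = c(0.2, 0.4), k = 3,
                              repeats = 2, seed = 15)
  expect_identical(cv1$cvR2, cv2$cvR2)
  expect_identical(cv1$selectedSNPs, cv2$selectedSNPs)
  # null data: CV r2 below the in-sample r2 of the same selected model
  res <- residualizeRORP(y, co)
  w <- fitFinalWeights(y, co, g, cv1$selectedSNPs, scan = cv1$scan)
  insample <- cor(scorePRS(g, w), res)^2
  expect_lt(mean(cv1$cvR2), insample)
  # absurdly small threshold: no SNP passes -> r2 zero with warning
  expect_warning(cv0 <- cvThresholdSelection(y, co, g, grid = 1e-12,
                                             k = 3, repeats = 1,
                                             seed = 16),
                 "no SNP below threshold")
  expect_equal(unname(cv0$cvR2), 0)
})

test_that("final weights equal the covariate-adjusted single-SNP model", {
  n <- 800
  g <- hweGenotypes(n, c(0.3, 0.4, 0.25), seed = 20)
  co <- nullCovars(n, seed = 21)
  d <- dosages(g)
  y <- withr::with_seed(22, 0.4 * d[, 1] + 0.3 * co$PC1 + rnorm(n))
  w <- fitFinalWeights(y, co, g, colnames(d))
  fit1 <- lm(reformulate(c("dose", paste0("PC", 1:10), "study"), "y"),
             data = cbind(co, dose = d[, 1], y = y))
  expect_equal(w$beta[1], unname(coef(fit1)["dose"]), tolerance = 1e-10)
  expect_equal(w$se[1],
               unname(sqrt(diag(vcov(fit1))["dose"])), tolerance = 1e-8)
  # null SNP: CI covers zero
  ci3 <- w$beta[3] + c(-1.96, 1.96) * w$se[3]
  expect_true(ci3[1] < 0 && ci3[2] > 0)
})

test_that("ancestry adjustment reduces confounding bias in the weights", {
  n <- 3000
  withr::with_seed(31, {
    pc1 <- rnorm(n)
    # dosage correlated with PC1 (ancestry-structured frequency)
    dose <- rbinom(n, 2, plogis(-0.4 + 0.8 * pc1) * 0.5 + 0.1)
    y <- 0.2 * dose + 1.0 * pc1 + rnorm(n)
    co <- nullCovars(n, seed = 32)
    co$PC1 <- pc1
  })
  g <- GenotypeMatrix(matrix(dose, ncol = 1,
                             dimnames = list(NULL, "snpC")))
  unadjusted <- unname(coef(lm(y ~ dose))[2])
  adjusted <- fitFinalWeights(y, co, g, "snpC")$beta
  expect_lt(abs(adjusted - 0.2), abs(unadjusted - 0.2))
})

test_that("scorePRS is an additive dosage sum with coverage accounting", {
  d <- rbind(s1 = c(2, 1, 0), s2 = c(0, 2, 1))
  colnames(d) <- c("a", "b", "c")
  g <- GenotypeMatrix(d)
  w <- data.frame(snp = c("a", "b", "c"), beta = c(0.1, -0.2, 0.05))
  prs <- scorePRS(g, w)
  expect_equal(unname(prs["s1"]), 0.1 * 2 - 0.2 * 1 + 0)  # hand sum 0.0
  expect_equal(unname(prs["s2"]), -0.2 * 2 + 0.05)
  expect_equal(attr(prs, "coverage"), 1)
  # single-SNP example and missing-SNP drop
  w1 <- data.frame(snp = c("a", "zzz"), beta = c(0.2, 9))
  p1 <- scorePRS(g, w1)
  expect_equal(unname(p1["s1"]), 0.4)
  expect_equal(attr(p1, "coverage"), 0.5)
  expect_error(scorePRS(g, data.frame(snp = "q", beta = 1)), "no weight")
  # additivity over disjoint SNP sets
  pa <- scorePRS(g, w[1, ]); pb <- scorePRS(g, w[2:3, ])
  expect_equal(as.numeric(prs), as.numeric(pa) + as.numeric(pb))
  # all-zero weights
  expect_true(all(scorePRS(g, transform(w, beta = 0)) == 0))
})

test_that("standardizePRS yields exact z-scores and is affine invariant", {
  x <- withr::with_seed(7, rlnorm(500))
  z <- standardizePRS(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardizePRS(3 * x + 10), standardizePRS(x))
  # log-zscore of a lognormal sample is (shapiro-)normal
  lz <- standardizePRS(x, mode = "log-zscore")
  expect_gt(shapiro.test(lz)$p.value, 0.01)
  expect_error(standardizePRS(rep(1, 5)), "zero standard deviation")
  expect_error(standardizePRS(c(-1, 2), mode = "log-zscore"), "positive")
})

test_that("built PRS recovers a substantial share of the oracle genetic signal", {
  cfg <- simulationConfig(nSamples = 2500, seed = 47)
  co <- simulateCohort(cfg)
  s <- truthSamples(co$truth)
  rorp <- scoreRORP(co$expression, co$centroids, nReps = 100, seed = 48)
  geno <- fillMissingGenotypes(co$genotypes, seed = 49)
  covars <- truthCovars(co$truth)
  cv <- cvThresholdSelection(rorp$rorp, covars, geno,
                             grid = seq(0.1, 0.6, 0.1), repeats = 2,
                             seed = 50)
  w <- fitFinalWeights(rorp$rorp, covars, geno, cv$selectedSNPs,
                       scan = cv$scan)
  prs <- scorePRS(geno, w)
  # oracle: best linear genetic predictor from the true causal dosages
  eff <- truthSnpEffects(co$truth)
  causal <- eff$snp[eff$subtype_effect != 0 | eff$prolif_effect != 0]
  Xc <- dosages(co$genotypesComplete)[, causal, drop = FALSE]
  oracle <- fitted(lm(s$latent_rorp ~ Xc))
  r2Built <- cor(prs, s$genetic_value)^2
  r2Oracle <- cor(oracle, s$genetic_value)^2
  expect_gt(r2Built, 0.5 * r2Oracle)
})
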