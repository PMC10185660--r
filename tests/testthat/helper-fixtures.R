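# Shared fixtures, all generated in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

smallCohort <- function(n = 300, m = 30, seed = 7, ...) {
  nc <- max(1L, min(3L, m %/% 2L))
  simulateCohort(simulationConfig(nSamples = n, nSnps = m,
                                  nCausalSubtype = nc, nCausalProlif = nc,
                                  seed = seed, ...))
}

# Covariate frame (PC1..PC10 + study) from a GroundTruth.
truthCovars <- function(truth) {
  s <- truthSamples(truth)
  data.frame(s[, paste0("PC", 1:10)], study = s$study)
}

# Independent-null covariates for tests that need no structure.
nullCovars <- function(n, nStudies = 2, seed = 1) {
  withr::with_seed(seed, {
    out <- as.data.frame(matrix(rnorm(n * 10), n,
                                dimnames = list(NULL, paste0("PC", 1:10))))
    out$study <- sample(paste0("study", seq_len(nStudies)), n,
                        replace = TRUE)
  })
  out
}

# Hardy-Weinberg genotype matrix with given frequencies.
hweGenotypes <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    d <- sapply(freqs, function(p) rbinom(n, 2, p))
  })
  rownames(d) <- sprintf("s%05d", seq_len(n))
  colnames(d) <- sprintf("snp%04d", seq_along(freqs))
  GenotypeMatrix(d)
}

# Exponential survival records with log-linear hazard in `z`.
survRecords <- function(z, hr, baseline = 0.05, censor = 10, seed = 1,
                        covars = NULL) {
  n <- length(z)
  withr::with_seed(seed, {
    t0 <- rexp(n, baseline * exp(log(hr) * z))
  })
  rec <- data.frame(time = pmin(t0, censor),
                    event = as.integer(t0 <= censor), z = z)
  if (!is.null(covars)) rec <- cbind(rec, covars)
  rec
}

expect_chisq_hwe <- function(dosage, p, alpha = 0.001) {
  obs <- tabulate(dosage + 1L, 3L)
  expprob <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  gof <- suppressWarnings(chisq.test(obs, p = expprob))
  expect_gt(gof$p.value, alpha)
}
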