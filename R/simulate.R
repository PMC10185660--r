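# Synthetic cohort generator: HWE genotypes, SNP-driven tumor state,
# PAM50-like expression, and survival outcomes with recorded ground truth.

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Validated parameter object consumed by all \code{simulate*} functions.
#' Defaults describe the study conditions the package is exercised under:
#' a development-scale case series (2500 cases, 226 candidate SNPs, 20
#' causal), latent ROR-P heritability 0.17 (mid-range of published estimates
#' of 13-21\%), and a follow-up regime (baseline breast cancer-specific
#' hazard 0.02/year, administrative censoring at 10 years) giving roughly
#' 18\% events, as in cohorts enriched for higher-risk disease.
#'
#' @slot nSamples,nSnps cohort and candidate-panel sizes.
#' @slot mafRange interval within [0, 0.5] from which per-SNP effect-allele
#'   frequencies are drawn uniformly.
#' @slot nCausalSubtype,nCausalProlif numbers of SNPs with true effects on
#'   the subtype-propensity and proliferation channels.
#' @slot geneticVarianceFraction target fraction in [0, 1) of latent ROR-P
#'   variance explained by genotype (heritability of the latent score).
#' @slot nGenes,nProlifGenes expression panel size and proliferation subset.
#' @slot nStudies number of contributing studies (location shifts, Eq.-2
#'   style study indicator).
#' @slot erPositiveFraction target marginal ER-positive fraction.
#' @slot hrPerSd true hazard ratio per SD of latent ROR-P (> 0).
#' @slot baselineHazard baseline event hazard per year.
#' @slot adminCensorTime administrative censoring time in years.
#' @slot missingRate i.i.d. genotype missingness rate in [0, 1).
#' @slot probeMultiplicity maximum probes per gene in simulated expression.
#' @slot expressionNoiseSd per-gene Gaussian noise SD around the centroid.
#' @slot studyShiftSd SD of per-study, per-gene expression location shifts.
#' @slot pcRorpEffect optional confounding toggle: effect of PC1 on the
#'   proliferation channel (0 = no ancestry confounding).
#' @slot seed root seed; every generator derives its stream from it.
#' @slot architectureSeed seed governing the *population* genetic
#'   architecture (per-SNP allele frequencies, causal SNP identities and
#'   effect sizes). Defaults to \code{seed}. Two configs sharing an
#'   architectureSeed but differing in \code{seed} draw independent cohorts
#'   from the same population, as when a PRS is developed in one cohort and
#'   validated in another.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nSamples = "numeric", nSnps = "numeric",
                        mafRange = "numeric", nCausalSubtype = "numeric",
                        nCausalProlif = "numeric",
                        geneticVarianceFraction = "numeric",
                        nGenes = "numeric", nProlifGenes = "numeric",
                        nStudies = "numeric", erPositiveFraction = "numeric",
                        hrPerSd = "numeric", baselineHazard = "numeric",
                        adminCensorTime = "numeric", missingRate = "numeric",
                        probeMultiplicity = "numeric",
                        expressionNoiseSd = "numeric",
                        studyShiftSd = "numeric", pcRorpEffect = "numeric",
                        seed = "numeric", architectureSeed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 1 || object@nSnps < 1)
    msgs <- c(msgs, "nSamples and nSnps must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] < 0 || mr[2] > 0.5)
    msgs <- c(msgs, "mafRange must be c(lo, hi) with 0 <= lo <= hi <= 0.5")
  h2 <- object@geneticVarianceFraction
  if (h2 < 0 || h2 >= 1)
    msgs <- c(msgs, "geneticVarianceFraction must be in [0, 1)")
  if (object@nCausalSubtype + object@nCausalProlif > object@nSnps)
    msgs <- c(msgs, "causal SNP counts exceed nSnps")
  if (h2 > 0 && object@nCausalSubtype + object@nCausalProlif == 0)
    msgs <- c(msgs,
              "nonzero geneticVarianceFraction requires causal SNPs")
  if (object@nProlifGenes > object@nGenes)
    msgs <- c(msgs, "nProlifGenes must not exceed nGenes")
  if (object@erPositiveFraction <= 0 || object@erPositiveFraction >= 1)
    msgs <- c(msgs, "erPositiveFraction must be in (0, 1)")
  if (object@hrPerSd <= 0) msgs <- c(msgs, "hrPerSd must be > 0")
  if (object@baselineHazard <= 0)
    msgs <- c(msgs, "baselineHazard must be > 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msgs <- c(msgs, "missingRate must be in [0, 1)")
  if (object@probeMultiplicity < 1)
    msgs <- c(msgs, "probeMultiplicity must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSamples,nSnps,mafRange,nCausalSubtype,nCausalProlif,geneticVarianceFraction,nGenes,nProlifGenes,nStudies,erPositiveFraction,hrPerSd,baselineHazard,adminCensorTime,missingRate,probeMultiplicity,expressionNoiseSd,studyShiftSd,pcRorpEffect,seed
#'   see \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nSamples = 200, nSnps = 30, seed = 7)
#' @export
simulationConfig <- function(nSamples = 2500, nSnps = 226,
                             mafRange = c(0.05, 0.5),
                             nCausalSubtype = 10, nCausalProlif = 10,
                             geneticVarianceFraction = 0.17,
                             nGenes = 50, nProlifGenes = 11, nStudies = 3,
                             erPositiveFraction = 0.75,
                             hrPerSd = 1.3, baselineHazard = 0.02,
                             adminCensorTime = 10, missingRate = 0.02,
                             probeMultiplicity = 1,
                             expressionNoiseSd = 0.8, studyShiftSd = 0.25,
                             pcRorpEffect = 0, seed = 1,
                             architectureSeed = seed) {
  new("SimulationConfig", nSamples = nSamples, nSnps = nSnps,
      mafRange = as.numeric(mafRange), nCausalSubtype = nCausalSubtype,
      nCausalProlif = nCausalProlif,
      geneticVarianceFraction = geneticVarianceFraction, nGenes = nGenes,
      nProlifGenes = nProlifGenes, nStudies = nStudies,
      erPositiveFraction = erPositiveFraction, hrPerSd = hrPerSd,
      baselineHazard = baselineHazard, adminCensorTime = adminCensorTime,
      missingRate = missingRate, probeMultiplicity = probeMultiplicity,
      expressionNoiseSd = expressionNoiseSd, studyShiftSd = studyShiftSd,
      pcRorpEffect = pcRorpEffect, seed = seed,
      architectureSeed = architectureSeed)
}

# Baseline subtype prevalences (development-set-like mixture) and the
# per-subtype slopes on the standardized causal-subtype SNP score: higher
# genetic score tilts toward the more proliferative subtypes.
.subtypePrev <- c(Basal = 0.18, Her2 = 0.11, LumA = 0.40, LumB = 0.22,
                  Normal = 0.09)
.subtypeSlope <- c(Basal = 0.5, Her2 = 0.2, LumA = -0.5, LumB = 0.3,
                   Normal = -0.2)
# Latent-score contribution of the *true* subtype (indicator pattern of the
# ROR-P coefficients; Normal-like carries no weight).
.subtypeValue <- c(Basal = -0.001, Her2 = 0.7, LumA = -0.95, LumB = 0.49,
                   Normal = 0)
# Conditional receptor-status probabilities given true subtype.
.erPosGivenSubtype <- c(Basal = 0.10, Her2 = 0.50, LumA = 0.95, LumB = 0.85,
                        Normal = 0.80)
.her2PosGivenSubtype <- c(Basal = 0.05, Her2 = 0.80, LumA = 0.07,
                          LumB = 0.25, Normal = 0.10)
.gradeGivenSubtype <- rbind(Basal = c(0.02, 0.18, 0.80),
                            Her2 = c(0.05, 0.35, 0.60),
                            LumA = c(0.45, 0.45, 0.10),
                            LumB = c(0.10, 0.45, 0.45),
                            Normal = c(0.40, 0.45, 0.15))

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each SNP's effect-allele frequency is drawn uniformly from
#' \code{mafRange}; dosages are then i.i.d. Binomial(2, p) per sample, i.e.
#' Hardy-Weinberg genotype proportions (q^2, 2pq, p^2). Deterministic given
#' the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GenotypeMatrix} whose \code{snpInfo} records the
#'   generating frequency in \code{freq}.
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  n <- as.integer(config@nSamples)
  m <- as.integer(config@nSnps)
  # Population properties (frequencies, allele labels) come from the
  # architecture seed; the cohort's dosage draws from the cohort seed.
  withr::with_seed(.deriveSeed(config@architectureSeed, 1L), {
    maf <- runif(m, config@mafRange[1], config@mafRange[2])
    pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "T"), c("C", "T"))
    pick <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
  })
  withr::with_seed(.deriveSeed(config@seed, 11L), {
    d <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  })
  rownames(d) <- sprintf("s%05d", seq_len(n))
  colnames(d) <- sprintf("snp%04d", seq_len(m))
  info <- data.frame(effect_allele = pick[, 1], other_allele = pick[, 2],
                     freq = maf, row.names = colnames(d),
                     stringsAsFactors = FALSE)
  GenotypeMatrix(d, info)
}

#' Simulate tumor state (subtype, proliferation, latent ROR-P) from genotypes
#'
#' A subset of SNPs drives a multinomial-logit subtype propensity; a disjoint
#' subset drives proliferation additively. The latent ROR-P is the ROR-P
#' coefficient pattern applied to true-subtype indicators plus 0.34 times
#' proliferation. The proliferation noise SD is calibrated on the realized
#' cohort so that the variance fraction of latent ROR-P explained by its
#' genetic expectation matches \code{geneticVarianceFraction}. ER/HER2/grade
#' are sampled conditionally on subtype (luminal subtypes mostly ER-positive,
#' basal mostly ER-negative).
#'
#' @param genotypes complete (pre-missingness) \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GroundTruth}.
#' @export
simulateTumorState <- function(genotypes, config) {
  validObject(config)
  X <- dosages(genotypes)
  if (anyNA(X))
    stop("genotypes must be complete (simulate tumor state before ",
         "injecting missingness)")
  n <- nrow(X)
  m <- ncol(X)
  h2 <- config@geneticVarianceFraction
  ns <- as.integer(config@nCausalSubtype)
  np <- as.integer(config@nCausalProlif)
  if (h2 > 0 && ns + np == 0)
    stop("nonzero geneticVarianceFraction requires causal SNPs")

  # Causal SNP identities and effect sizes are population properties.
  withr::with_seed(.deriveSeed(config@architectureSeed, 2L), {
    causal <- sample.int(m, ns + np)
    subIdx <- causal[seq_len(ns)]
    proIdx <- causal[ns + seq_len(np)]
    gammaS <- if (ns) rnorm(ns) else numeric()
    deltaP <- if (np) rnorm(np) else numeric()
  })
  if (h2 == 0) {
    gammaS[] <- 0
    deltaP[] <- 0
  }
  withr::with_seed(.deriveSeed(config@seed, 12L), {
    unitScale <- function(v) {
      v <- as.numeric(v)
      s <- sd(v)
      if (is.na(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
    }
    gS <- if (ns && any(gammaS != 0))
      unitScale(X[, subIdx, drop = FALSE] %*% gammaS) else rep(0, n)
    gP <- if (np && any(deltaP != 0))
      unitScale(X[, proIdx, drop = FALSE] %*% deltaP) else rep(0, n)

    # Multinomial-logit subtype with baseline prevalences as intercepts.
    eta <- outer(gS, .subtypeSlope) +
      rep(log(.subtypePrev), each = n)
    P <- exp(eta)
    P <- P / rowSums(P)
    u <- runif(n)
    cum <- t(apply(P, 1, cumsum))
    subtype <- .subtypeLabels[max.col(u < cum, ties.method = "first")]

    # Genetic value: expectation of the latent score given genotypes.
    gSub <- as.vector(P %*% .subtypeValue)
    g <- gSub + 0.34 * gP

    # Calibrate proliferation noise so Var(g)/Var(latent) hits the target.
    cS <- .subtypeValue[subtype]
    vrs <- var(cS - gSub)
    vg <- var(g)
    if (h2 == 0) {
      sigma <- 1
    } else {
      s2 <- (vg * (1 - h2) / h2 - vrs) / 0.34^2
      if (s2 < 0)
        stop("geneticVarianceFraction ", h2, " is not attainable: the ",
             "subtype channel alone contributes more non-genetic variance ",
             "than the target allows; lower the fraction")
      sigma <- sqrt(s2)
    }
    pcs <- matrix(rnorm(n * 10), n, dimnames = list(rownames(X),
                                                    paste0("PC", 1:10)))
    prolif <- gP + rnorm(n, 0, sigma) + config@pcRorpEffect * pcs[, 1]
    latent <- cS + 0.34 * prolif

    # Receptor status, shifted on the logit scale so the expected marginal
    # ER-positive fraction matches the configured target.
    base <- .erPosGivenSubtype
    shift <- tryCatch(uniroot(function(d) {
      sum(.subtypePrev * plogis(qlogis(base) + d)) -
        config@erPositiveFraction
    }, c(-8, 8))$root, error = function(e) 0)
    pER <- plogis(qlogis(base) + shift)[subtype]
    er <- ifelse(runif(n) < pER, "positive", "negative")
    her2 <- ifelse(runif(n) < .her2PosGivenSubtype[subtype],
                   "positive", "negative")
    gu <- runif(n)
    gcum <- t(apply(.gradeGivenSubtype[subtype, , drop = FALSE], 1, cumsum))
    grade <- max.col(gu < gcum, ties.method = "first")
    study <- sample.int(as.integer(config@nStudies), n, replace = TRUE)
  })

  eff <- data.frame(snp = colnames(X),
                    subtype_effect = 0, prolif_effect = 0,
                    row.names = colnames(X), stringsAsFactors = FALSE)
  if (ns) eff$subtype_effect[subIdx] <- gammaS
  if (np) eff$prolif_effect[proIdx] <- deltaP

  samples <- data.frame(sample = rownames(X), subtype = subtype,
                        prolif = prolif, latent_rorp = latent,
                        genetic_value = g, er_status = er,
                        her2_status = her2, grade = grade,
                        study = paste0("study", study),
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, pcs)
  new("GroundTruth", samples = samples, snpEffects = eff,
      params = list(sigmaProlif = if (h2 == 0) 1 else sigma,
                    config = config))
}

#' Simulate subtype-structured expression from ground truth
#'
#' Expression for each sample is its true subtype's centroid column plus
#' Gaussian noise; proliferation genes are additionally shifted by the
#' sample's proliferation value. Optional per-study location shifts and
#' probe-level expansion (1..\code{probeMultiplicity} probes per gene with
#' probe noise) emulate multi-study, multi-platform input.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param centroidMatrix a \linkS4class{CentroidMatrix} covering
#'   \code{nGenes} genes.
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} (features x
#'   samples) with \code{er_status} and \code{study} in \code{colData} and a
#'   \code{gene} column in \code{rowData} mapping probes to genes.
#' @export
simulateExpression <- function(truth, centroidMatrix, config) {
  validObject(config)
  C <- centroids(centroidMatrix)
  s <- truthSamples(truth)
  n <- nrow(s)
  genes <- rownames(C)
  if (length(genes) < config@nGenes)
    stop("centroid matrix covers fewer genes than nGenes")
  withr::with_seed(.deriveSeed(config@seed, 3L), {
    E <- C[, s$subtype, drop = FALSE] +
      matrix(rnorm(length(genes) * n, 0, config@expressionNoiseSd),
             nrow = length(genes))
    pg <- intersect(prolifGenes(centroidMatrix), genes)
    E[pg, ] <- E[pg, , drop = FALSE] +
      rep(s$prolif, each = length(pg))
    if (config@studyShiftSd > 0 && config@nStudies > 1) {
      shifts <- matrix(rnorm(length(genes) * config@nStudies, 0,
                             config@studyShiftSd), nrow = length(genes))
      colnames(shifts) <- paste0("study", seq_len(config@nStudies))
      E <- E + shifts[, s$study, drop = FALSE]
    }
    if (config@probeMultiplicity > 1) {
      nProbes <- sample.int(as.integer(config@probeMultiplicity),
                            length(genes), replace = TRUE)
      probeGene <- rep(genes, nProbes)
      E <- E[probeGene, , drop = FALSE] +
        matrix(rnorm(length(probeGene) * n, 0, 0.25),
               nrow = length(probeGene))
      probeId <- unlist(lapply(seq_along(genes), function(i)
        sprintf("%s_p%d", genes[i], seq_len(nProbes[i]))))
      rownames(E) <- probeId
    } else {
      probeGene <- genes
    }
  })
  colnames(E) <- s$sample
  SummarizedExperiment(
    assays = list(exprs = E),
    rowData = DataFrame(gene = probeGene, row.names = rownames(E)),
    colData = DataFrame(er_status = s$er_status, study = s$study,
                        row.names = s$sample))
}

#' Simulate survival outcomes and clinical covariates
#'
#' Event times are exponential with hazard
#' \code{baselineHazard * exp(log(hrPerSd) * z)} where \code{z} is the
#' standardized latent ROR-P, administratively censored at
#' \code{adminCensorTime}. Emits ancestry PCs, age, BMI, stage (mildly
#' increasing in latent ROR-P), treatment flags with simple dependencies on
#' receptor status and stage, ER/HER2/grade, and the intrinsic-like subtype
#' surrogate derived from them (LumA = ER+/HER2-/grade 1-2; LumB = ER+ and
#' (HER2+ or grade 3); HER2-enriched = ER-/HER2+; Basal = ER-/HER2-).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame of one \code{SurvivalRecord} per sample.
#' @export
simulateOutcomes <- function(truth, config) {
  validObject(config)
  if (config@hrPerSd <= 0) stop("hrPerSd must be > 0")
  s <- truthSamples(truth)
  n <- nrow(s)
  z <- as.numeric(scale(s$latent_rorp))
  if (anyNA(z)) z <- rep(0, n)
  withr::with_seed(.deriveSeed(config@seed, 4L), {
    rate <- config@baselineHazard * exp(log(config@hrPerSd) * z)
    tEvent <- rexp(n, rate)
    event <- as.integer(tEvent <= config@adminCensorTime)
    time <- pmin(tEvent, config@adminCensorTime)
    age <- pmin(pmax(round(rnorm(n, 58, 10)), 25), 90)
    bmi <- round(pmin(pmax(rnorm(n, 27, 5), 16), 55), 1)
    stageBase <- c(0.45, 0.35, 0.15, 0.05)
    tilt <- exp(outer(0.3 * z, 0:3))
    probs <- sweep(tilt, 2, stageBase, `*`)
    probs <- probs / rowSums(probs)
    su <- runif(n)
    stage <- max.col(su < t(apply(probs, 1, cumsum)),
                     ties.method = "first")
    erPos <- s$er_status == "positive"
    her2Pos <- s$her2_status == "positive"
    chemo <- as.integer(runif(n) <
                          plogis(-0.5 + 0.5 * z + 0.8 * (stage >= 2)))
    radiation <- as.integer(runif(n) < 0.6)
    trastuzumab <- as.integer(runif(n) < ifelse(her2Pos, 0.7, 0.02))
    hormone <- as.integer(runif(n) < ifelse(erPos, 0.8, 0.05))
  })
  intrinsic <- intrinsicLikeSubtype(s$er_status, s$her2_status, s$grade)
  rec <- data.frame(sample = s$sample, time = time, event = event,
                    age = age, bmi = bmi, stage = stage,
                    radiation = radiation, chemo = chemo,
                    trastuzumab = trastuzumab, hormone_therapy = hormone,
                    er_status = s$er_status, her2_status = s$her2_status,
                    grade = s$grade, intrinsic_subtype = intrinsic,
                    study = s$study, stringsAsFactors = FALSE)
  cbind(rec, s[, paste0("PC", 1:10)])
}

#' Intrinsic-like subtype surrogate from receptor status and grade
#'
#' LumA = ER+/HER2-/grade 1-2; LumB = ER+ and (HER2+ or grade 3);
#' HER2-enriched = ER-/HER2+; Basal = ER-/HER2-.
#'
#' @param er,her2 character vectors, "positive"/"negative".
#' @param grade integer vector, 1-3.
#' @return character vector of intrinsic-like labels.
#' @export
intrinsicLikeSubtype <- function(er, her2, grade) {
  erPos <- er == "positive"
  her2Pos <- her2 == "positive"
  out <- ifelse(erPos,
                ifelse(her2Pos | grade == 3, "LumB", "LumA"),
                ifelse(her2Pos, "Her2", "Basal"))
  out
}

#' Mask genotype entries at random
#'
#' Entries are set to missing i.i.d. with probability \code{missingRate};
#' deterministic given the seed. Produces input for
#' \code{\link{fillMissingGenotypes}}.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param missingRate fraction in [0, 1).
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeMatrix} with \code{NA} entries.
#' @export
injectMissingness <- function(genotypes, missingRate, seed = 1) {
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  d <- dosages(genotypes)
  if (missingRate == 0) return(genotypes)
  withr::with_seed(.deriveSeed(seed, 5L), {
    mask <- runif(length(d)) < missingRate
  })
  d[mask] <- NA
  GenotypeMatrix(d, snpInfo(genotypes))
}

#' Generate a seeded synthetic centroid matrix
#'
#' Centroid columns share a common gene profile plus subtype-specific
#' deviations, giving moderate between-centroid correlation as in published
#' subtype centroids; the last \code{nProlifGenes} genes are flagged as the
#' proliferation subset.
#'
#' @param nGenes,nProlifGenes panel sizes (defaults 50 and 11).
#' @param seed integer seed.
#' @return A \linkS4class{CentroidMatrix}.
#' @export
syntheticCentroids <- function(nGenes = 50, nProlifGenes = 11, seed = 42) {
  stopifnot(nProlifGenes <= nGenes)
  withr::with_seed(.deriveSeed(seed, 6L), {
    shared <- rnorm(nGenes)
    C <- sapply(.subtypeLabels, function(s) 0.6 * shared + rnorm(nGenes))
  })
  rownames(C) <- sprintf("g%03d", seq_len(nGenes))
  CentroidMatrix(C, rownames(C)[seq.int(nGenes - nProlifGenes + 1, nGenes)])
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running genotype, tumor-state, expression and outcome
#' generation plus missingness injection under one config.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param centroidMatrix optional \linkS4class{CentroidMatrix}; generated
#'   from the config seed when omitted.
#' @return list with elements \code{genotypes} (missingness injected),
#'   \code{genotypesComplete}, \code{expression}, \code{clinical},
#'   \code{truth}, \code{centroids}, of class \code{"rorpCohort"}.
#' @examples
#' co <- simulateCohort(simulationConfig(nSamples = 150, nSnps = 20,
#'                                       nCausalSubtype = 2,
#'                                       nCausalProlif = 2, seed = 3))
#' names(co)
#' @export
simulateCohort <- function(config, centroidMatrix = NULL) {
  validObject(config)
  if (is.null(centroidMatrix))
    centroidMatrix <- syntheticCentroids(config@nGenes,
                                         config@nProlifGenes,
                                         seed = config@seed)
  geno <- simulateGenotypes(config)
  truth <- simulateTumorState(geno, config)
  expr <- simulateExpression(truth, centroidMatrix, config)
  clin <- simulateOutcomes(truth, config)
  genoMiss <- injectMissingness(geno, config@missingRate,
                                seed = config@seed)
  structure(list(genotypes = genoMiss, genotypesComplete = geno,
                 expression = expr, clinical = clin, truth = truth,
                 centroids = centroidMatrix),
            class = "rorpCohort")
}

#' @export
print.rorpCohort <- function(x, ...) {
  d <- dim(x$genotypes)
  cat("Synthetic cohort:", d[1], "samples,", d[2], "SNPs,",
      nrow(assay(x$expression)), "expression features,",
      sum(x$clinical$event), "events\n")
  invisible(x)
}
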