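# ROR-P scoring: probe collapse, ER-balanced normalization, centroid
# correlations, proliferation index, and the score itself.

toyExpr <- function(E, er = NULL) {
  cd <- if (is.null(er)) S4Vectors::DataFrame(row.names = colnames(E))
        else S4Vectors::DataFrame(er_status = er, row.names = colnames(E))
  SummarizedExperiment(assays = list(exprs = E), colData = cd)
}

test_that("collapseProbes averages probes and enforces the mapping contract", {
  E <- rbind(p1 = c(1, 5), p2 = c(3, 7), p3 = c(10, 20), px = c(0, 0))
  colnames(E) <- c("s1", "s2")
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("gA", "gA", "gB"))
  expect_warning(out <- collapseProbes(toyExpr(E), map), "unmapped")
  G <- assay(out)
  expect_equal(unname(G["gA", ]), c(2, 6))       # mean of two probes
  expect_equal(unname(G["gB", ]), c(10, 20))     # single probe: identity
  expect_equal(metadata(out)$droppedProbes, 1L)

  badMap <- rbind(map, data.frame(probe = "p1", gene = "gB"))
  expect_error(collapseProbes(toyExpr(E), badMap), "multiple genes")
})

test_that("ER-balanced normalization zeroes constant genes and is seeded", {
  set.seed(4)
  n <- 60
  E <- rbind(gConst = rep(3.5, n),
             gVar = rnorm(n))
  colnames(E) <- sprintf("s%02d", 1:n)
  er <- rep(c("negative", "positive"), c(20, 40))
  a <- erBalancedNormalize(toyExpr(E), er, nReps = 50, seed = 9)
  b <- erBalancedNormalize(toyExpr(E), er, nReps = 50, seed = 9)
  expect_true(all(assay(a)["gConst", ] == 0))
  expect_identical(assay(a), assay(b))
  # adding a per-gene constant is absorbed by the reference median
  shifted <- erBalancedNormalize(toyExpr(E + 2.5), er, nReps = 50,
                                 seed = 9)
  expect_equal(assay(shifted), assay(a))
})

test_that("reference approaches the overall median under ER exchangeability", {
  set.seed(11)
  n <- 400
  E <- matrix(rnorm(20 * n), 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%03d", 1:n)))
  er <- sample(rep(c("negative", "positive"), each = n / 2))
  out <- erBalancedNormalize(toyExpr(E), er, nReps = 300, seed = 2)
  ref <- metadata(out)$referenceMedians
  expect_lt(max(abs(ref - apply(E, 1, median))), 0.15)
})

test_that("fewer ER-positive than ER-negative falls back to replacement", {
  set.seed(5)
  E <- matrix(rnorm(5 * 30), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  er <- rep(c("negative", "positive"), c(25, 5))
  expect_warning(erBalancedNormalize(toyExpr(E), er, nReps = 10, seed = 1),
                 "replacement")
})

test_that("subtype correlations recover self, anti and null structure", {
  cm <- syntheticCentroids(nGenes = 50, seed = 8)
  C <- centroids(cm)
  E <- cbind(selfLumA = C[, "LumA"],
             antiBasal = -C[, "Basal"])
  prof <- subtypeCorrelations(E, cm)
  expect_equal(prof["selfLumA", "LumA"], 1)
  expect_identical(prof["selfLumA", "call"], "LumA")
  expect_equal(prof["antiBasal", "Basal"], -1)

  # random vectors: correlations centered at zero
  set.seed(3)
  R <- matrix(rnorm(50 * 1000), 50,
              dimnames = list(rownames(C), sprintf("r%04d", 1:1000)))
  pr <- subtypeCorrelations(R, cm)
  expect_lt(abs(mean(as.matrix(pr[, rorpPRS:::.subtypeLabels]))), 0.05)

  # constant vector: flagged, excluded from calls
  E2 <- cbind(flat = rep(1, 50), ok = C[, "Her2"])
  rownames(E2) <- rownames(C)
  p2 <- subtypeCorrelations(E2, cm)
  expect_true(p2["flat", "flagged"])
  expect_true(is.na(p2["flat", "call"]))
  expect_identical(p2["ok", "call"], "Her2")
})

test_that("proliferation index is the mean over the flagged genes", {
  cm <- syntheticCentroids(nGenes = 15, nProlifGenes = 11, seed = 1)
  pg <- prolifGenes(cm)
  E <- matrix(0, 15, 2, dimnames = list(rownames(centroids(cm)),
                                        c("a", "b")))
  E[pg, "b"] <- 0:10   # values 0..10 over 11 genes
  pi <- proliferationIndex(E, cm)
  expect_equal(unname(pi), c(0, 5))
  expect_error(proliferationIndex(E[-match(pg[1], rownames(E)), ], cm),
               pg[1])
})

test_that("computeRORP applies the exact linear combination", {
  base <- data.frame(Basal = 0, Her2 = 0, LumA = 0, LumB = 0, Prolif = 0)
  expect_equal(unname(computeRORP(base)), 0)
  expect_equal(unname(computeRORP(transform(base, Basal = 1))), -0.001)
  prof <- data.frame(Basal = 0.2, Her2 = 0.1, LumA = -0.5, LumB = 0.4,
                     Prolif = 0.6)
  expect_equal(unname(computeRORP(prof)), 0.9448)
  # exact linearity: finite difference equals the coefficient
  for (comp in c("Basal", "Her2", "LumA", "LumB", "Prolif")) {
    bumped <- prof; bumped[[comp]] <- bumped[[comp]] + 1
    expect_equal(unname(computeRORP(bumped) - computeRORP(prof)),
                 unname(rorpPRS:::.rorpCoefficients[comp]))
  }
  expect_error(computeRORP(prof[, -1]), "Basal")
  # affine rescale and grouping
  m <- rorpModel(rescale = c(10, 50))
  expect_equal(unname(computeRORP(prof, m)), 0.9448 * 10 + 50)
  expect_identical(as.character(rorpGroups(c(-1, 0.5, 2), c(0, 1))),
                   c("Low", "Medium", "High"))
})

test_that("computed ROR-P tracks the latent score; noiseless calls are exact", {
  co <- smallCohort(n = 2000, m = 10, seed = 19)
  rorp <- scoreRORP(co$expression, co$centroids, nReps = 100, seed = 5)
  s <- truthSamples(co$truth)
  expect_gt(mean(rorp$call == s$subtype, na.rm = TRUE), 0.8)
  expect_gt(cor(rorp$rorp, s$latent_rorp, use = "complete",
                method = "spearman"), 0.5)

  # noise -> 0 limit: recomputed call equals the true subtype everywhere
  cfg0 <- simulationConfig(nSamples = 300, nSnps = 10, nCausalSubtype = 2,
                           nCausalProlif = 2, expressionNoiseSd = 1e-4,
                           studyShiftSd = 0, seed = 23)
  co0 <- simulateCohort(cfg0)
  r0 <- scoreRORP(co0$expression, co0$centroids, nReps = 50, seed = 2)
  expect_identical(r0$call, truthSamples(co0$truth)$subtype)
})

test_that("probe expansion then collapse reproduces the single-probe run", {
  cfgM <- simulationConfig(nSamples = 200, nSnps = 10, nCausalSubtype = 2,
                           nCausalProlif = 2, probeMultiplicity = 3,
                           seed = 29)
  coM <- simulateCohort(cfgM)
  expect_gt(nrow(assay(coM$expression)), 50)
  collapsed <- collapseProbes(coM$expression)
  cfg1 <- simulationConfig(nSamples = 200, nSnps = 10, nCausalSubtype = 2,
                           nCausalProlif = 2, probeMultiplicity = 1,
                           seed = 29)
  co1 <- simulateCohort(cfg1)
  g <- intersect(rownames(assay(collapsed)), rownames(assay(co1$expression)))
  delta <- assay(collapsed)[g, ] - assay(co1$expression)[g, ]
  # probe-level noise (sd 0.25) averages toward the gene value
  expect_lt(mean(abs(delta)), 0.3)
})
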