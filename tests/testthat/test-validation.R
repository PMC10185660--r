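# Outcome validation: Cox fits, KM tertiles, meta-analysis,
# Gronnesby-Borgan, bootstrap calibration, feature associations.

test_that("coxFit recovers a true hazard ratio and matches a brute-force toy fit", {
  z <- withr::with_seed(71, rnorm(5000))
  rec <- survRecords(z, hr = 1.5, seed = 72)
  out <- coxFit(rec, "z", covariates = "none")
  expect_gt(1.5, out$ci_lower); expect_lt(1.5, out$ci_upper)
  expect_equal(out$events, sum(rec$event))

  # toy data: partial likelihood maximized by grid search
  toy <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                    z = c(1, 0, 1, 0))
  fitB <- coxFit(toy, "z", covariates = "none")
  pl <- function(b) {
    # distinct event times: risk sets {1,2,3,4} then {2,3,4}
    x <- toy$z
    (b * x[1] - log(sum(exp(b * x)))) +
      (b * x[2] - log(sum(exp(b * x[2:4]))))
  }
  grid <- seq(-3, 3, by = 1e-4)
  bHat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_lt(abs(log(fitB$hr) - bHat), 1e-3)

  expect_error(coxFit(data.frame(time = 1:3, event = 0, z = rnorm(3)),
                      "z", covariates = "none"), "2 events")
})

test_that("joint model attenuates two correlated exposures toward the null", {
  withr::with_seed(73, {
    shared <- rnorm(4000)
    a <- scale(0.55 * shared + rnorm(4000))[, 1]
    b <- scale(0.55 * shared + rnorm(4000))[, 1]
  })
  rec <- survRecords(shared, hr = 1.6, seed = 74)
  rec$a <- a; rec$b <- b
  margA <- coxFit(rec, "a", covariates = "none")$hr
  margB <- coxFit(rec, "b", covariates = "none")$hr
  joint <- coxFit(rec, c("a", "b"), covariates = "none")
  expect_identical(nrow(joint), 2L)
  for (i in 1:2) {
    marg <- c(margA, margB)[i]
    expect_gt(joint$hr[i], 1)
    expect_lt(joint$hr[i], marg)
  }
})

test_that("kmTertiles partitions near-equally and the log-rank test behaves", {
  # identical groups (cloned data): statistic ~ 0
  base <- data.frame(time = rep(c(1, 2, 3, 4, 6), 30),
                     event = rep(c(1, 0, 1, 0, 1), 30))
  base$x <- rep(1:3, each = 50) + rep(seq(0, 0.9, length.out = 50), 3)
  km0 <- kmTertiles(base[order(base$time), ], "x")
  # tertile sizes differ by at most one
  expect_lte(diff(range(table(km0$tertile))), 1)

  cloned <- base
  cloned$x <- rep(1:3, 50)  # same survival pattern in every tertile
  kmC <- kmTertiles(cloned, "x")
  expect_lt(kmC$chisq, 0.2)
  expect_gt(kmC$p, 0.9)
  expect_identical(kmC$df, 2L)
})

test_that("two-group log-rank matches the hand-computed O-E statistic", {
  rec <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 1, 1, 1, 0, 1),
                    g = c(0, 1, 0, 1, 0, 1))
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ g, data = rec)
  # hypergeometric O-E and variance accumulated by hand over event times
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(rec$time[rec$event == 1]))) {
    at <- rec$time >= t
    d <- sum(rec$event == 1 & rec$time == t)
    n <- sum(at); n1 <- sum(at & rec$g == 1)
    d1 <- sum(rec$event == 1 & rec$time == t & rec$g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  hand <- (O - E)^2 / V
  expect_equal(as.numeric(sd2$chisq), hand, tolerance = 1e-6)
  # two groups: statistic equals the squared standardized O-E
  expect_equal(as.numeric(sd2$chisq),
               (O - E)^2 / V, tolerance = 1e-10)
})

test_that("random-effects meta-analysis has the expected closed-form limits", {
  # two identical studies: summary equals them, no heterogeneity
  same <- data.frame(hr = c(1.2, 1.2), ci_lower = c(1.05, 1.05),
                     ci_upper = c(1.37, 1.37))
  m0 <- randomEffectsMeta(same)
  expect_equal(m0$hr, 1.2, tolerance = 1e-6)
  expect_equal(m0$Q, 0, tolerance = 1e-10)
  expect_equal(m0$I2, 0)
  # single study passes through
  m1 <- randomEffectsMeta(same[1, ])
  expect_equal(m1$hr, 1.2, tolerance = 1e-6)
  expect_equal(m1$ci_lower, 1.05, tolerance = 1e-3)
  # tau2 fixed at 0 equals the fixed-effect inverse-variance estimate
  st <- data.frame(hr = c(1.3, 1.05, 1.18),
                   ci_lower = c(1.1, 0.9, 1.02),
                   ci_upper = c(1.54, 1.22, 1.37))
  yi <- log(st$hr)
  sei <- (log(st$ci_upper) - log(st$ci_lower)) / (2 * qnorm(0.975))
  wFE <- 1 / sei^2
  fe <- sum(wFE * yi) / sum(wFE)
  mFix <- randomEffectsMeta(st, tau2 = 0)
  expect_lt(abs(log(mFix$hr) - fe), 1e-10)
  # equal SEs at tau2 = 0: summary is the arithmetic mean of log effects
  eq <- data.frame(logeff = c(0.1, 0.2, 0.3), se = rep(0.05, 3))
  mEq <- randomEffectsMeta(eq, tau2 = 0)
  expect_equal(log(mEq$hr), 0.2, tolerance = 1e-10)
  expect_error(randomEffectsMeta(data.frame(hr = 1.1, ci_lower = -1,
                                            ci_upper = 1.3)), "positive")
})

test_that("Gronnesby-Borgan is zero for perfectly matched groups and has df = groups - 1", {
  z <- withr::with_seed(81, rnorm(800))
  rec <- survRecords(z, hr = 1.5, baseline = 0.08, seed = 82)
  fit <- attr(coxFit(rec, "z", covariates = "none"), "fit")
  gb <- gronnesbyBorgan(fit, nGroups = 10)
  expect_identical(gb$df, 9L)
  expect_gte(gb$chisq, 0)
  # null exposure in a null model: statistic small, p not extreme
  gb5 <- gronnesbyBorgan(fit, nGroups = 5)
  expect_identical(gb5$df, 4L)
})

test_that("bootstrap calibration is seeded and close for a well-specified model", {
  z <- withr::with_seed(83, rnorm(2500))
  rec <- survRecords(z, hr = 1.5, baseline = 0.06, seed = 84)
  cal <- bootstrapCalibration(rec, "z", covariates = "none", horizon = 5,
                              nBoot = 25, nStrata = 10, seed = 85)
  expect_identical(nrow(cal), 10L)
  # per-stratum KM noise at ~250 samples/stratum: mean gap small, max bounded
  expect_lt(mean(abs(cal$predicted - cal$observed_corrected)), 0.03)
  expect_lt(max(abs(cal$predicted - cal$observed_corrected)), 0.08)
  cal2 <- bootstrapCalibration(rec, "z", covariates = "none", horizon = 5,
                               nBoot = 25, nStrata = 10, seed = 85)
  expect_identical(cal, cal2)
  expect_warning(
    app <- bootstrapCalibration(rec, "z", covariates = "none",
                                horizon = 5, nBoot = 0, seed = 1),
    "apparent")
  expect_equal(app$observed, app$observed_corrected)
  expect_error(bootstrapCalibration(rec, "z", covariates = "none",
                                    horizon = 99), "horizon")
})

test_that("featureAssociation recovers logistic and multinomial effects", {
  n <- 3000
  withr::with_seed(91, {
    z <- rnorm(n)
    pcs <- nullCovars(n, seed = 92)[, 1:10]
    erNeg <- runif(n) < plogis(-1 + 0.3 * z)
  })
  fe <- featureAssociation(z, factor(ifelse(erNeg, "neg", "pos"),
                                     levels = c("pos", "neg")),
                           covars = pcs)
  ciLog <- log(c(fe$ci_lower, fe$ci_upper))
  expect_gt(0.3, ciLog[1]); expect_lt(0.3, ciLog[2])
  expect_lt(attr(fe, "companion_p"), 0.05)
  # null feature: CI covers OR 1
  withr::with_seed(93, fNull <- sample(c("a", "b"), n, replace = TRUE))
  fn <- featureAssociation(z, fNull)
  expect_true(fn$ci_lower < 1 && fn$ci_upper > 1)
  # multinomial: one contrast per non-reference level
  withr::with_seed(94, {
    lin <- 0.4 * z
    p3 <- cbind(1, exp(0.2 + lin), exp(-0.5 + 0.8 * z))
    p3 <- p3 / rowSums(p3)
    cls <- apply(p3, 1, function(pr) sample(c("lumA", "lumB", "basal"),
                                            1, prob = pr))
  })
  fm <- featureAssociation(z, factor(cls, levels = c("lumA", "lumB",
                                                     "basal")))
  expect_identical(nrow(fm), 2L)
  expect_true(all(c("lumB", "basal") %in% fm$level))
  expect_lt(attr(fm, "companion_p"), 0.05)
  expect_error(featureAssociation(z, rep("one", n)), "2 levels")
})

test_that("prsRorpCorrelation reports Pearson r and its null behavior", {
  expect_equal(prsRorpCorrelation(1:10, 1:10)$r, 1)
  reps <- vapply(1:40, function(i) {
    withr::with_seed(1000 + i, {
      abs(prsRorpCorrelation(rnorm(484), rnorm(484))$r)
    })
  }, numeric(1))
  expect_gte(mean(reps < 0.1), 0.9)
  expect_error(prsRorpCorrelation(rep(1, 10), rnorm(10)), "variance")
  expect_error(prsRorpCorrelation(1:2, 2:3), "3 paired")
})
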