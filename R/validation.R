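# Outcome validation: Cox models with ancestry adjustment and nested
# covariate sets, Kaplan-Meier tertiles with log-rank tests, REML
# random-effects meta-analysis, Gronnesby-Borgan goodness of fit,
# bootstrap calibration, and tumor-feature associations.

.covariateSets <- list(
  none = character(),
  ancestry = paste0("PC", 1:10),
  age_bmi = c("age", "bmi"),
  stage = "stage",
  treatments = c("radiation", "chemo", "trastuzumab", "hormone_therapy"),
  measured_rorp = "measured_rorp",
  er = "er_status")

.resolveCovariates <- function(covariates) {
  unknown <- setdiff(covariates, names(.covariateSets))
  if (length(unknown))
    stop("unknown covariate set(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(.covariateSets), collapse = ", "))
  unique(unlist(.covariateSets[covariates]))
}

#' Cox proportional-hazards fit for one or two standardized exposures
#'
#' Partial-likelihood fit (Efron tie handling) of breast cancer-specific
#' survival on the exposure(s), adjusted for the named covariate sets.
#' Reports the hazard ratio per SD (the exposure is assumed standardized),
#' Wald confidence interval and p-value for each exposure term.
#'
#' @param records data.frame with \code{time}, \code{event}, the exposure
#'   column(s), and the covariates requested.
#' @param exposure character vector of one or two exposure column names
#'   (two = joint model).
#' @param covariates character vector of covariate-set names from
#'   \code{"none"}, \code{"ancestry"} (PC1-PC10), \code{"age_bmi"},
#'   \code{"stage"}, \code{"treatments"}, \code{"measured_rorp"},
#'   \code{"er"}; sets are combined.
#' @param subset optional logical vector for stratified fits (e.g. by ER
#'   status).
#' @return \code{AssociationResult} data.frame, one row per exposure:
#'   exposure, hr, ci_lower, ci_upper, p, n, events. The fitted
#'   \code{coxph} object is attached as \code{attr(, "fit")}.
#' @export
coxFit <- function(records, exposure, covariates = "ancestry",
                   subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  covs <- .resolveCovariates(covariates)
  need <- c("time", "event", exposure, covs)
  missing <- setdiff(need, colnames(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  records <- records[complete.cases(records[, need, drop = FALSE]), ,
                     drop = FALSE]
  if (sum(records$event) < 2) stop("need at least 2 events")
  rhs <- paste(c(exposure, covs), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         model = TRUE)
  if (!is.null(fit$info) || any(is.na(coef(fit)[exposure])))
    stop("Cox model did not produce estimates for the exposure(s)")
  est <- coef(fit)[exposure]
  se <- sqrt(diag(vcov(fit))[exposure])
  z <- qnorm(0.975)
  out <- data.frame(exposure = exposure, hr = exp(est),
                    ci_lower = exp(est - z * se),
                    ci_upper = exp(est + z * se),
                    p = 2 * pnorm(-abs(est / se)),
                    n = fit$n, events = fit$nevent,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Nested Cox models over the standard covariate ladder
#'
#' Fits the ancestry-adjusted base model plus the nested adjustment sets:
#' ancestry + age/BMI; + stage; + treatments; ancestry + measured ROR-P;
#' ancestry + ER status.
#'
#' @inheritParams coxFit
#' @return data.frame of \code{AssociationResult} rows with a \code{model}
#'   label column.
#' @export
nestedCoxModels <- function(records, exposure) {
  ladder <- list(
    model1_ancestry = "ancestry",
    model2_age_bmi = c("ancestry", "age_bmi"),
    model3_stage = c("ancestry", "age_bmi", "stage"),
    model4_treatments = c("ancestry", "age_bmi", "stage", "treatments"),
    model5_measured_rorp = c("ancestry", "measured_rorp"),
    model6_er = c("ancestry", "er"))
  out <- lapply(names(ladder), function(nm) {
    covs <- ladder[[nm]]
    have <- all(.resolveCovariates(covs) %in% colnames(records))
    if (!have) return(NULL)
    res <- coxFit(records, exposure, covariates = covs)
    cbind(model = nm, res)
  })
  do.call(rbind, out)
}

#' Kaplan-Meier analysis of exposure tertiles
#'
#' Splits the analyzed cases into three equal-size groups by exposure rank
#' (sizes differ by at most one), estimates Kaplan-Meier curves per group,
#' and tests for differences with the log-rank test (2 df).
#'
#' @param records data.frame with \code{time}, \code{event} and the
#'   exposure column.
#' @param exposure exposure column name.
#' @return list of class \code{"kmTertiles"}: \code{fit} (survfit by
#'   tertile), \code{chisq}, \code{df}, \code{p}, \code{tertile} (group
#'   assignment).
#' @export
kmTertiles <- function(records, exposure) {
  x <- records[[exposure]]
  ok <- complete.cases(records[, c("time", "event")]) & !is.na(x)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) < 3) stop("need at least 3 samples")
  tert <- factor(.ntile(records[[exposure]], 3), levels = 1:3,
                 labels = c("T1", "T2", "T3"))
  records$.tertile <- tert
  fit <- survival::survfit(survival::Surv(time, event) ~ .tertile,
                           data = records)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ .tertile,
                            data = records)
  df <- length(sd0$n) - 1L
  structure(list(fit = fit, chisq = as.numeric(sd0$chisq), df = df,
                 p = pchisq(as.numeric(sd0$chisq), df,
                            lower.tail = FALSE),
                 tertile = tert),
            class = "kmTertiles")
}

#' @export
print.kmTertiles <- function(x, ...) {
  cat(sprintf("Log-rank test over tertiles: chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' REML random-effects meta-analysis of ratio-scale study results
#'
#' Combines study-level hazard (or odds) ratios on the log scale using a
#' restricted-maximum-likelihood estimate of the between-study variance
#' tau^2, with standard errors recovered from the Wald confidence intervals
#' as \code{SE = (ln U - ln L) / (2 * 1.96)}. Heterogeneity is summarized by
#' Cochran's Q and \code{I2 = max(0, (Q - df) / Q) * 100}. With a single
#' study the summary equals that study.
#'
#' @param results data.frame with columns \code{hr}, \code{ci_lower},
#'   \code{ci_upper} (or \code{logeff} and \code{se}); optional
#'   \code{label}.
#' @param tau2 optional fixed value for the between-study variance (0 gives
#'   the fixed-effect inverse-variance estimate); \code{NULL} estimates it
#'   by REML.
#' @return list of class \code{"metaResult"}: \code{hr}, \code{ci_lower},
#'   \code{ci_upper}, \code{p}, \code{tau2}, \code{Q}, \code{Qp},
#'   \code{I2}, \code{perStudy}.
#' @examples
#' studies <- data.frame(hr = c(1.13, 1.14), ci_lower = c(1.04, 1.01),
#'                       ci_upper = c(1.23, 1.29))
#' randomEffectsMeta(studies)
#' @export
randomEffectsMeta <- function(results, tau2 = NULL) {
  if (all(c("logeff", "se") %in% colnames(results))) {
    yi <- results$logeff
    sei <- results$se
  } else {
    stopifnot(all(c("hr", "ci_lower", "ci_upper") %in% colnames(results)))
    if (any(results$ci_lower <= 0 | results$hr <= 0))
      stop("ratio-scale inputs must be positive")
    yi <- log(results$hr)
    sei <- (log(results$ci_upper) - log(results$ci_lower)) / (2 * qnorm(0.975))
  }
  k <- length(yi)
  if (k < 1) stop("need at least one study")
  if (k == 1) {
    out <- list(hr = exp(yi), ci_lower = exp(yi - qnorm(0.975) * sei),
                ci_upper = exp(yi + qnorm(0.975) * sei),
                p = 2 * pnorm(-abs(yi / sei)), tau2 = 0, Q = 0, Qp = 1,
                I2 = 0,
                perStudy = data.frame(logeff = yi, se = sei))
    return(structure(out, class = "metaResult"))
  }
  fit <- if (is.null(tau2))
    metafor::rma.uni(yi = yi, sei = sei, method = "REML")
  else
    metafor::rma.uni(yi = yi, sei = sei, tau2 = tau2)
  Q <- as.numeric(fit$QE)
  dfQ <- k - 1
  structure(list(hr = as.numeric(exp(fit$beta)),
                 ci_lower = as.numeric(exp(fit$ci.lb)),
                 ci_upper = as.numeric(exp(fit$ci.ub)),
                 p = as.numeric(fit$pval),
                 tau2 = as.numeric(fit$tau2), Q = Q,
                 Qp = as.numeric(fit$QEp),
                 I2 = max(0, (Q - dfQ) / Q) * 100,
                 perStudy = data.frame(
                   label = if ("label" %in% colnames(results))
                     results$label else paste0("study", seq_len(k)),
                   logeff = yi, se = sei)),
            class = "metaResult")
}

#' @export
print.metaResult <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (%d studies): HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    nrow(x$perStudy), x$hr, x$ci_lower, x$ci_upper, x$p))
  cat(sprintf("  tau2 = %.4g; Q = %.3f (p = %.3g); I2 = %.1f%%\n",
              x$tau2, x$Q, x$Qp, x$I2))
  invisible(x)
}

#' Gronnesby-Borgan goodness-of-fit test for a Cox model
#'
#' Samples are grouped into \code{nGroups} equal-size strata of the fitted
#' linear predictor; the statistic is the score test for adding the
#' (nGroups - 1) group indicators to the model, evaluated at the fitted
#' coefficients (equivalently, a test that grouped martingale residuals
#' vanish), chi-squared with nGroups - 1 degrees of freedom under a
#' well-calibrated model. The information matrix is adjusted for the
#' estimation of the model coefficients. Groups without events are merged
#' into the neighboring group with a warning.
#'
#' @param fit a fitted \code{coxph} model retaining its model frame
#'   (\code{model = TRUE}; \code{\link{coxFit}} fits do).
#' @param nGroups number of risk strata (default 10).
#' @return list: \code{chisq}, \code{df}, \code{p}, \code{groups}.
#' @export
gronnesbyBorgan <- function(fit, nGroups = 10) {
  if (nGroups < 2) stop("nGroups must be >= 2")
  lp <- fit$linear.predictors
  y <- fit$y
  if (is.null(y)) stop("coxph fit must retain the response (y = TRUE)")
  X <- tryCatch(stats::model.matrix(fit), error = function(e)
    stop("coxph fit must retain its model frame (model = TRUE)"))
  grp <- .ntile(lp, nGroups)
  ev <- if (ncol(y) == 2) y[, 2] else y[, 3]
  tab <- tapply(ev, grp, sum)
  while (any(tab == 0) && length(tab) > 2) {
    bad <- which(tab == 0)[1]
    neighbor <- if (bad == 1) 2 else bad - 1
    grp[grp == as.integer(names(tab)[bad])] <-
      as.integer(names(tab)[neighbor])
    grp <- match(grp, sort(unique(grp)))
    tab <- tapply(ev, grp, sum)
    warning("merged a risk stratum without events into its neighbor")
  }
  G <- factor(grp)
  df <- nlevels(G) - 1L
  # global score test at (beta-hat, 0): its only nonzero components are the
  # group-indicator scores, with the information adjusted for beta-hat
  sc <- suppressWarnings(
    survival::coxph(y ~ X + G, ties = "efron",
                    init = c(coef(fit), rep(0, df)),
                    control = survival::coxph.control(iter.max = 0)))
  chisq <- as.numeric(sc$score)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE), groups = grp)
}

# Model-predicted survival at a horizon from a coxph fit, for arbitrary
# linear predictors (on the fit's centered scale).
.predSurvAt <- function(fit, lp, horizon) {
  bh <- survival::basehaz(fit, centered = TRUE)
  idx <- findInterval(horizon, bh$time)
  H0 <- if (idx == 0) 0 else bh$hazard[idx]
  exp(-H0 * exp(lp))
}

#' Bootstrap-bias-corrected calibration of a Cox model at a fixed horizon
#'
#' Compares model-predicted survival at \code{horizon} years with the
#' Kaplan-Meier observed survival across \code{nStrata} equal-size strata of
#' predicted risk, with an optimism correction estimated from
#' \code{nBoot} bootstrap refits (the apparent-minus-test difference of each
#' bootstrap model, averaged, is subtracted from the apparent observed
#' values). Deterministic given \code{seed}.
#'
#' @param records data.frame with \code{time}, \code{event}, exposure and
#'   covariates.
#' @param exposure,covariates model specification as in \code{\link{coxFit}}.
#' @param horizon prediction horizon in years (default 5).
#' @param nBoot bootstrap repeats (default 200); 0 returns the apparent
#'   (uncorrected) calibration with a warning.
#' @param nStrata number of risk strata (default 10).
#' @param seed integer seed.
#' @return data.frame per stratum: \code{stratum}, \code{predicted},
#'   \code{observed}, \code{observed_corrected}, \code{n}.
#' @export
bootstrapCalibration <- function(records, exposure,
                                 covariates = "ancestry", horizon = 5,
                                 nBoot = 200, nStrata = 10, seed = 1) {
  covs <- .resolveCovariates(covariates)
  need <- c("time", "event", exposure, covs)
  records <- records[complete.cases(records[, need, drop = FALSE]), ,
                     drop = FALSE]
  if (max(records$time) < horizon)
    stop("no follow-up reaches the requested horizon")
  rhs <- paste(c(exposure, covs), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time, event) ~", rhs))

  calib <- function(dat, newdat = NULL) {
    f <- survival::coxph(fml, data = dat, ties = "efron", model = TRUE)
    evalDat <- if (is.null(newdat)) dat else newdat
    lp <- predict(f, newdata = evalDat, type = "lp")
    pred <- .predSurvAt(f, lp, horizon)
    grp <- .ntile(pred, nStrata)
    predM <- tapply(pred, grp, mean)
    obs <- vapply(sort(unique(grp)), function(g)
      .kmAt(evalDat$time[grp == g], evalDat$event[grp == g], horizon),
      numeric(1))
    list(predicted = as.numeric(predM), observed = as.numeric(obs),
         n = as.numeric(table(grp)))
  }

  app <- calib(records)
  if (nBoot == 0) {
    warning("nBoot = 0: returning apparent (uncorrected) calibration")
    optimism <- rep(0, nStrata)
  } else {
    n <- nrow(records)
    withr::with_seed(.deriveSeed(seed, 10L), {
      opt <- matrix(NA_real_, nBoot, nStrata)
      for (b in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bootDat <- records[idx, , drop = FALSE]
        opt[b, ] <- tryCatch({
          bootApp <- calib(bootDat)
          bootOrig <- calib(bootDat, newdat = records)
          (bootApp$observed - bootApp$predicted) -
            (bootOrig$observed - bootOrig$predicted)
        }, error = function(e) rep(NA_real_, nStrata))
      }
    })
    optimism <- colMeans(opt, na.rm = TRUE)
  }
  data.frame(stratum = seq_len(nStrata),
             predicted = app$predicted,
             observed = app$observed,
             observed_corrected = app$observed - optimism,
             n = app$n, row.names = NULL)
}

#' Association between a standardized PRS and a tumor feature
#'
#' Binary features (ER, HER2): logistic regression of the feature on the
#' standardized PRS, adjusted for ancestry PCs, plus a companion t-test of
#' the PRS across feature levels. Features with three or more levels
#' (grade, intrinsic-like subtype): multinomial logistic regression with one
#' contrast per non-reference level, plus a companion ANOVA.
#'
#' @param prs numeric PRS (standardized internally to per-SD units).
#' @param feature factor or vector with >= 2 levels.
#' @param covars optional data.frame of PC1..PC10 adjustment covariates.
#' @param reference optional reference level (default: first level).
#' @return \code{AssociationResult} data.frame, one row per contrast:
#'   level, or_per_sd, ci_lower, ci_upper, p, n; the companion test
#'   p-value is in \code{attr(, "companion_p")}.
#' @export
featureAssociation <- function(prs, feature, covars = NULL,
                               reference = NULL) {
  feature <- droplevels(as.factor(feature))
  if (nlevels(feature) < 2)
    stop("feature must have at least 2 levels")
  if (!is.null(reference)) feature <- relevel(feature, ref = reference)
  z <- standardizePRS(prs)
  dat <- data.frame(.f = feature, .z = z)
  if (!is.null(covars)) {
    pcs <- intersect(paste0("PC", 1:10), colnames(covars))
    dat <- cbind(dat, covars[, pcs, drop = FALSE])
  }
  rhs <- paste(setdiff(colnames(dat), ".f"), collapse = " + ")
  zcrit <- qnorm(0.975)
  if (nlevels(feature) == 2) {
    fit <- glm(as.formula(paste(".f ~", rhs)), data = dat,
               family = binomial())
    if (!fit$converged || abs(coef(fit)[".z"]) > 15)
      stop("apparent perfect separation; penalized regression is out of ",
           "scope here")
    est <- coef(fit)[".z"]
    se <- sqrt(diag(vcov(fit))[".z"])
    out <- data.frame(level = levels(feature)[2],
                      or_per_sd = exp(est),
                      ci_lower = exp(est - zcrit * se),
                      ci_upper = exp(est + zcrit * se),
                      p = 2 * pnorm(-abs(est / se)),
                      n = nrow(dat), row.names = NULL)
    attr(out, "companion_p") <-
      t.test(z ~ feature)$p.value
  } else {
    fit <- nnet::multinom(as.formula(paste(".f ~", rhs)), data = dat,
                          trace = FALSE, maxit = 500)
    co <- coef(fit)
    V <- vcov(fit)
    lv <- rownames(co)
    est <- co[, ".z"]
    se <- sqrt(diag(V)[paste0(lv, ":.z")])
    if (any(abs(est) > 15))
      stop("apparent perfect separation; penalized regression is out of ",
           "scope here")
    out <- data.frame(level = lv, or_per_sd = exp(est),
                      ci_lower = exp(est - zcrit * se),
                      ci_upper = exp(est + zcrit * se),
                      p = 2 * pnorm(-abs(est / se)),
                      n = nrow(dat), row.names = NULL)
    attr(out, "companion_p") <-
      summary(aov(z ~ feature))[[1]][["Pr(>F)"]][1]
  }
  out
}

#' Pearson correlation between a PRS and measured ROR-P
#'
#' @param prs,measuredRorp paired numeric vectors (>= 3 complete pairs).
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
prsRorpCorrelation <- function(prs, measuredRorp) {
  ok <- !is.na(prs) & !is.na(measuredRorp)
  x <- prs[ok]; y <- measuredRorp[ok]
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
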