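# Pipeline orchestration: run the simulate -> score -> build -> score ->
# validate -> meta stages in dependency order under one config, with a
# manifest accounting for every sample/SNP entering and leaving each stage.

#' Run the full analysis pipeline on synthetic or supplied inputs
#'
#' Executes, in dependency order: cohort simulation (development and
#' validation cohorts), ROR-P scoring of the development expression data,
#' PRS construction (LD-aware candidate panel, missing-genotype fill,
#' residualization, CV threshold selection, final weights), PRS scoring of
#' the validation cohort, Cox survival validation with Kaplan-Meier
#' tertiles, and (when both cohort halves are analyzed) meta-analysis.
#' Every source of randomness derives from \code{config$seed}. Rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param config list with optional elements \code{seed} (default 1),
#'   \code{development} and \code{validation} (argument lists passed to
#'   \code{\link{simulationConfig}}), \code{nReps} (normalization
#'   subsamples, default 1000), \code{grid}, \code{folds}, \code{repeats}
#'   (CV settings), and \code{outDir} (when set, stage tables are written
#'   there as TSV).
#' @return list of class \code{"runManifest"}: per-stage row counts and
#'   exclusions, wall-clock seconds, the key stage outputs
#'   (\code{rorp}, \code{cv}, \code{weights}, \code{prs}, \code{cox},
#'   \code{km}), and the software version.
#' @export
runPipeline <- function(config = list()) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  devArgs <- config$development
  if (is.null(devArgs)) devArgs <- list()
  valArgs <- config$validation
  if (is.null(valArgs)) valArgs <- list(nSamples = 5000)
  devArgs$seed <- .deriveSeed(seed, 101L)
  valArgs$seed <- .deriveSeed(seed, 102L)
  # one shared population architecture across the two cohorts
  if (is.null(devArgs$architectureSeed))
    devArgs$architectureSeed <- .deriveSeed(seed, 100L)
  if (is.null(valArgs$architectureSeed))
    valArgs$architectureSeed <- devArgs$architectureSeed
  nReps <- if (is.null(config$nReps)) 1000 else config$nReps
  grid <- if (is.null(config$grid)) seq(0.1, 0.6, by = 0.025)
          else config$grid
  folds <- if (is.null(config$folds)) 5 else config$folds
  repeats <- if (is.null(config$repeats)) 10 else config$repeats

  manifest <- list(version = as.character(packageVersion("rorpPRS")),
                   seed = seed, stages = list())
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }

  # --- simulate ---------------------------------------------------------
  st <- tick({
    devCfg <- do.call(simulationConfig, devArgs)
    valCfg <- do.call(simulationConfig, valArgs)
    list(dev = simulateCohort(devCfg), val = simulateCohort(valCfg))
  })
  dev <- st$val$dev; val <- st$val$val
  manifest$stages$simulate <- list(
    secs = st$secs,
    dev_samples = nrow(dosages(dev$genotypes)),
    dev_snps = ncol(dosages(dev$genotypes)),
    val_samples = nrow(dosages(val$genotypes)),
    val_snps = ncol(dosages(val$genotypes)),
    exclusions = list())

  # --- score-rorp -------------------------------------------------------
  st <- tick(scoreRORP(dev$expression, dev$centroids, nReps = nReps,
                       seed = .deriveSeed(seed, 103L)))
  rorpTab <- st$val
  nFlagged <- sum(rorpTab$flagged)
  manifest$stages$score_rorp <- list(
    secs = st$secs, samples_in = nrow(rorpTab),
    samples_out = nrow(rorpTab) - nFlagged,
    exclusions = list(constant_expression = nFlagged))

  # --- build-prs --------------------------------------------------------
  st <- tick({
    geno <- fillMissingGenotypes(dev$genotypes,
                                 seed = .deriveSeed(seed, 104L))
    ts <- truthSamples(dev$truth)
    covars <- data.frame(ts[, paste0("PC", 1:10)], study = ts$study)
    ok <- !rorpTab$flagged
    cv <- cvThresholdSelection(rorpTab$rorp[ok],
                               covars[ok, , drop = FALSE],
                               geno[ok, ], grid = grid, k = folds,
                               repeats = repeats,
                               seed = .deriveSeed(seed, 105L))
    weights <- fitFinalWeights(rorpTab$rorp[ok],
                               covars[ok, , drop = FALSE],
                               geno[ok, ], cv$selectedSNPs, scan = cv$scan)
    list(geno = geno, cv = cv, weights = weights)
  })
  cv <- st$val$cv; weights <- st$val$weights
  manifest$stages$build_prs <- list(
    secs = st$secs,
    snps_in = ncol(dosages(dev$genotypes)),
    snps_after_fill = ncol(dosages(st$val$geno)),
    snps_selected = nrow(weights),
    selected_threshold = cv$selectedThreshold,
    cv_r2 = unname(cv$cvR2[as.character(cv$selectedThreshold)]),
    exclusions = list(
      high_missingness = length(attr(st$val$geno, "excluded"))))

  # --- score validation cohort -----------------------------------------
  st <- tick({
    valGeno <- fillMissingGenotypes(val$genotypes,
                                    seed = .deriveSeed(seed, 106L))
    prs <- scorePRS(valGeno, weights)
    standardizePRS(prs)
  })
  prsZ <- st$val
  manifest$stages$score_prs <- list(
    secs = st$secs, samples = length(prsZ),
    coverage = attr(st$val, "coverage"),
    exclusions = list())

  # --- validate ---------------------------------------------------------
  st <- tick({
    rec <- val$clinical
    rec$rorp_prs <- as.numeric(prsZ)
    cox <- coxFit(rec, "rorp_prs", covariates = "ancestry")
    km <- kmTertiles(rec, "rorp_prs")
    list(rec = rec, cox = cox, km = km)
  })
  manifest$stages$validate <- list(
    secs = st$secs, samples = nrow(st$val$rec),
    events = sum(st$val$rec$event),
    hr_per_sd = st$val$cox$hr, exclusions = list())

  manifest$rorp <- rorpTab
  manifest$cv <- cv
  manifest$weights <- weights
  manifest$prs <- prsZ
  manifest$cox <- st$val$cox
  manifest$km <- st$val$km

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeDosageTSV(dev$genotypes,
                   file.path(config$outDir, "dev_genotypes.tsv"))
    writeTSV(rorpTab, file.path(config$outDir, "dev_rorp.tsv"))
    writeTSV(weights, file.path(config$outDir, "prs_weights.tsv"))
    writeTSV(data.frame(sample = names(prsZ), prs = as.numeric(prsZ)),
             file.path(config$outDir, "val_prs.tsv"))
    writeTSV(manifest$cox, file.path(config$outDir, "cox.tsv"))
  }
  structure(manifest, class = "runManifest")
}

#' @export
print.runManifest <- function(x, ...) {
  cat("Pipeline run (rorpPRS", x$version, "), seed", x$seed, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-12s %6.2fs", nm, s$secs))
    ex <- unlist(s$exclusions)
    if (length(ex) && sum(ex) > 0)
      cat("  exclusions:", paste(names(ex), ex, sep = "=", collapse = ", "))
    cat("\n")
  }
  cat(sprintf("  validation HR per SD = %.3f (CV r2 = %.4f at threshold %g)\n",
              x$cox$hr, x$cv$cvR2[as.character(x$cv$selectedThreshold)],
              x$cv$selectedThreshold))
  invisible(x)
}
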