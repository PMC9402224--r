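#' Pipeline run configuration
#'
#' @param cohortDir directory of an existing cohort bundle
#'   (\code{\link{writeCohort}} layout); if NULL, a cohort is simulated from
#'   \code{simulate}.
#' @param simulate list of simulation settings used when \code{cohortDir} is
#'   NULL: nHc, nOcd, nCycles, masterSeed, noiseSd (NA = automatic).
#' @param subspace integer vector of model ids to fit (NULL = full space).
#' @param inversion settings from \code{\link{inversionSettings}}.
#' @param alpha0 Dirichlet prior concentration for RFX BMS.
#' @param windowRatio Occam's-window odds cutoff (default 1/20).
#' @param bmaSamples BMA Monte-Carlo draws (default 20000).
#' @param statsAlpha significance level for the stats table.
#' @param seed seed for BMS exceedance and BMA sampling.
#' @param outDir output directory (NULL = nothing written).
#' @param cacheDir inversion cache directory (NULL = no cache).
#' @return Named configuration list.
#' @export
runConfig <- function(cohortDir = NULL,
                      simulate = list(nHc = 32L, nOcd = 30L, nCycles = 2L,
                                      masterSeed = 1L, noiseSd = NA_real_),
                      subspace = NULL, inversion = inversionSettings(),
                      alpha0 = 1, windowRatio = 1 / 20, bmaSamples = 20000L,
                      statsAlpha = 0.05, seed = 1L, outDir = NULL,
                      cacheDir = NULL) {
  list(cohortDir = cohortDir, simulate = simulate, subspace = subspace,
       inversion = inversion, alpha0 = alpha0, windowRatio = windowRatio,
       bmaSamples = bmaSamples, statsAlpha = statsAlpha,
       seed = as.integer(seed), outDir = outDir, cacheDir = cacheDir)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file (extension .yaml/.yml or .json).
#' @return Configuration list (missing fields filled with
#'   \code{\link{runConfig}} defaults).
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- runConfig()
  for (nm in names(raw)) base[[nm]] <- raw[[nm]]
  if (!is.null(base$subspace)) base$subspace <- as.integer(base$subspace)
  base
}

#' Pipeline job plan
#'
#' Reports the number of (subject, model) inversions the configuration implies
#' before any fitting starts.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @return List: nSubjects, nModels, nJobs.
#' @export
planPipeline <- function(config, template = defaultTemplate()) {
  nModels <- if (!is.null(config$subspace)) length(config$subspace)
             else length(enumerateModels(template))
  nSubjects <- if (!is.null(config$cohortDir)) {
    length(jsonlite::read_json(
      file.path(config$cohortDir, "manifest.json"))$subjects)
  } else {
    as.integer(config$simulate$nHc) + as.integer(config$simulate$nOcd)
  }
  list(nSubjects = nSubjects, nModels = nModels,
       nJobs = nSubjects * nModels)
}

# invert one (subject, model) pair through the cache
.cachedInvert <- function(bold, design, mask, template, priors, settings,
                          cacheDir) {
  if (is.null(cacheDir))
    return(list(est = invertModel(bold, design, mask, template, priors,
                                  settings),
                cached = FALSE))
  key <- .contentKey(bold@y, bold@tr, mask@aMask, mask@bMaskLow, mask@cMask,
                     priors@mean, priors@variance, priors@lambdaMean,
                     priors@lambdaVar, settings)
  f <- file.path(cacheDir, paste0(key, ".rds"))
  if (file.exists(f)) return(list(est = readRDS(f), cached = TRUE))
  est <- invertModel(bold, design, mask, template, priors, settings)
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(est, f)
  list(est = est, cached = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the cohort; enumerate the model space
#' (or the configured subspace); invert every (subject, model) pair; per-group
#' random-effects BMS; Occam's window and BMA per group; group statistics
#' table; write artifacts. Inversions are cached by content hash when
#' \code{cacheDir} is set, so interrupted runs resume. Deterministic given
#' (inputs, config, seeds).
#'
#' @param config list from \code{\link{runConfig}}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @param verbose log one line per (subject, model) fit.
#' @return List: plan, evidence (per group), bms, window, bma, stats,
#'   newInversions (count of fits not served from cache).
#' @export
runPipeline <- function(config = runConfig(), template = defaultTemplate(),
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  plan <- planPipeline(config, template)
  say("plan: ", plan$nSubjects, " subjects x ", plan$nModels, " models = ",
      plan$nJobs, " inversions")

  if (!is.null(config$cohortDir)) {
    say("stage cohort: loading ", config$cohortDir)
    raw <- readCohort(config$cohortDir)
    subjects <- raw$subjects
    design <- raw$design
  } else {
    sim <- config$simulate
    say("stage cohort: simulating ", sim$nHc, " HC + ", sim$nOcd, " OCD")
    noiseSd <- if (is.null(sim$noiseSd)) NA_real_ else sim$noiseSd
    cohort <- generateCohort(
      hcSpec = hcTruthSpec(as.integer(sim$nHc), noiseSd),
      ocdSpec = ocdTruthSpec(as.integer(sim$nOcd), noiseSd),
      design = designSpec(nCycles = as.integer(sim$nCycles)),
      template = template, masterSeed = as.integer(sim$masterSeed))
    subjects <- cohort@subjects
    design <- cohort@design
  }

  models <- enumerateModels(template)
  if (!is.null(config$subspace)) {
    if (!all(config$subspace %in% seq_along(models)))
      stop("stage model-space: subspace ids outside the enumerated space")
    models <- models[config$subspace]
  }
  masksList <- lapply(models, modelMasks, template = template)
  priorsList <- lapply(masksList, defaultPriors, template = template)
  ids <- vapply(models, modelId, 1L)

  say("stage inversion: ", length(subjects) * length(models), " fits")
  newInv <- 0L
  posteriors <- lapply(subjects, function(s) {
    fits <- lapply(seq_along(models), function(k) {
      r <- .cachedInvert(s$bold, design, masksList[[k]], template,
                         priorsList[[k]], config$inversion, config$cacheDir)
      say(sprintf("  %s model %d: F = %.3f (%d iter%s)", s$id, ids[k],
                  r$est@freeEnergy, r$est@nIter,
                  if (r$cached) ", cached" else ""))
      r
    })
    newInv <<- newInv + sum(!vapply(fits, function(r) r$cached, TRUE))
    setNames(lapply(fits, function(r) r$est), as.character(ids))
  })

  groups <- vapply(subjects, function(s) s$group, "")
  evidence <- lapply(split(names(subjects), groups), function(sub) {
    f <- t(vapply(sub, function(s)
      vapply(posteriors[[s]], freeEnergy, 0), numeric(length(models))))
    dimnames(f) <- list(sub, as.character(ids))
    f
  })

  say("stage bms: per-group random-effects model selection")
  bms <- lapply(evidence, rfxBms, alpha0 = config$alpha0,
                seed = config$seed)
  window <- lapply(bms, function(b)
    occamsWindow(b@expectedProb, ratio = config$windowRatio, modelIds = ids))

  say("stage bma: averaging over Occam's window")
  bma <- lapply(names(bms), function(g) {
    bmaAverage(posteriors[groups[names(posteriors)] == g], window[[g]],
               template, nSamples = config$bmaSamples, seed = config$seed)
  })
  names(bma) <- names(bms)

  say("stage stats: group parameter tests")
  if (!all(c("HC", "OCD") %in% names(bma)))
    stop("stage stats: expected groups 'HC' and 'OCD', got ",
         paste(names(bma), collapse = ", "))
  stats <- buildStatsTable(bma$HC, bma$OCD, alpha = config$statsAlpha)

  result <- list(plan = plan, evidence = evidence, bms = bms,
                 window = window, bma = bma, stats = stats,
                 newInversions = newInv)
  if (!is.null(config$outDir)) {
    say("stage write: ", config$outDir)
    objects <- list(stats = stats)
    for (g in names(evidence)) {
      objects[[paste0("evidence_", g)]] <- evidence[[g]]
      objects[[paste0("bma_", g)]] <- data.frame(
        subject = rownames(bma[[g]]@estimates), bma[[g]]@estimates,
        check.names = FALSE)
      objects[[paste0("bms_", g)]] <- list(
        alpha = bms[[g]]@alpha, expected_prob = bms[[g]]@expectedProb,
        exceedance_prob = bms[[g]]@exceedanceProb,
        window = window[[g]]$ids,
        weights = as.numeric(window[[g]]$weights))
    }
    writeResults(objects, config$outDir, config = config)
  }
  result
}
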