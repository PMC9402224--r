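# Group-level connectivity summaries (means and between-subject SDs) used as
# generative defaults for the two cohorts: intrinsic coupling over the 13
# pathways and demand-specific modulation over the 5 permutable pathways.
.HC_INTRINSIC <- data.frame(
  pathway = .PATHWAYS,
  mean = c(0.09, 0.12, 0.02, 0.00, 0.02, 0.10, 0.09, 0.00, 0.04, 0.04,
           -0.01, 0.00, 0.02),
  sd = c(0.12, 0.12, 0.14, 0.02, 0.14, 0.14, 0.14, 0.14, 0.15, 0.13,
         0.14, 0.13, 0.13))
.OCD_INTRINSIC <- data.frame(
  pathway = .PATHWAYS,
  mean = c(-0.06, 0.08, 0.01, 0.00, 0.03, 0.12, 0.08, -0.04, 0.07, 0.07,
           0.03, -0.03, 0.03),
  sd = c(0.12, 0.12, 0.14, 0.02, 0.14, 0.14, 0.14, 0.14, 0.14, 0.13,
         0.14, 0.13, 0.14))
.MOD_PATHWAYS <- c("dACC->Thal", "dPFC->Thal", "Thal->dACC", "Thal->dPFC",
                   "dPFC->BG")
.HC_MOD_LOW <- data.frame(pathway = .MOD_PATHWAYS,
                          mean = c(0.05, 0.04, 0.08, 0.23, 0.03),
                          sd = c(0.28, 0.22, 0.28, 0.27, 0.25))
.OCD_MOD_LOW <- data.frame(pathway = .MOD_PATHWAYS,
                           mean = c(0.03, -0.03, 0.20, -0.06, -0.06),
                           sd = c(0.25, 0.27, 0.28, 0.27, 0.30))
.HC_MOD_HIGH <- data.frame(pathway = .MOD_PATHWAYS,
                           mean = c(0.10, -0.02, 0.17, 0.28, 0.07),
                           sd = c(0.26, 0.24, 0.29, 0.29, 0.26))
.OCD_MOD_HIGH <- data.frame(pathway = .MOD_PATHWAYS,
                            mean = c(0.04, 0.03, 0.21, 0.09, -0.04),
                            sd = c(0.27, 0.26, 0.31, 0.30, 0.30))
# Driving efficacy is not reported at the group level. 0.25 Hz keeps peak
# neural excursions within the regime where the balloon model is physically
# valid (sustained activity below -gamma collapses blood inflow) and yields
# V1 BOLD amplitudes of ~3-4% signal change, typical of long block designs.
.DRIVING_DEFAULT <- data.frame(region = "V1", mean = 0.25, sd = 0.05)

#' Design specification for the blocked attention task
#'
#' Defaults emulate the CPT-IP block design: 120 s task epochs at 250 ms SOA
#' (50 ms presentations), 20 s rests, TR 2.6 s. One cycle is
#' low / rest / high / rest.
#'
#' @param taskEpochS task epoch length (s).
#' @param restEpochS rest epoch length (s).
#' @param soaMs stimulus onset asynchrony (ms).
#' @param stimMs stimulus presentation time (ms).
#' @param trS repetition time (s).
#' @param nCycles number of low/rest/high/rest cycles (default 2).
#' @param microtimeBins microtime bins per TR (default 16).
#' @return Named list (validated).
#' @export
designSpec <- function(taskEpochS = 120, restEpochS = 20, soaMs = 250,
                       stimMs = 50, trS = 2.6, nCycles = 2L,
                       microtimeBins = 16L) {
  stopifnot(taskEpochS > 0, restEpochS > 0, soaMs > 0, stimMs > 0, trS > 0,
            soaMs >= stimMs, microtimeBins >= 1L)
  list(taskEpochS = taskEpochS, restEpochS = restEpochS, soaMs = soaMs,
       stimMs = stimMs, trS = trS, nCycles = as.integer(nCycles),
       microtimeBins = as.integer(microtimeBins))
}

#' Build the task design
#'
#' Epochs alternate low / rest / high / rest for \code{nCycles}; the condition
#' boxcars are laid out on the microtime grid (dt = TR / microtimeBins) and the
#' number of scans is the number of complete TRs in the total duration.
#'
#' @param spec list from \code{\link{designSpec}}.
#' @return A \linkS4class{TaskDesign}.
#' @export
makeDesign <- function(spec = designSpec()) {
  if (spec$nCycles < 1L) stop("design must contain at least one cycle")
  cyc <- data.frame(
    condition = c("low", "rest", "high", "rest"),
    duration = c(spec$taskEpochS, spec$restEpochS, spec$taskEpochS,
                 spec$restEpochS))
  epochs <- do.call(rbind, replicate(spec$nCycles, cyc, simplify = FALSE))
  epochs$onset <- cumsum(c(0, epochs$duration[-nrow(epochs)]))
  epochs <- epochs[, c("condition", "onset", "duration")]
  designFromEpochs(epochs, tr = spec$trS, microtimeBins = spec$microtimeBins)
}

#' Build a TaskDesign from an epoch table
#'
#' @param epochs data.frame with columns condition ("low"/"high"/"rest"),
#'   onset (s), duration (s). Rest epochs may be omitted (gaps are rest).
#' @param tr repetition time (s).
#' @param microtimeBins microtime bins per TR.
#' @param totalS total run duration (s); defaults to the end of the last epoch.
#' @return A \linkS4class{TaskDesign}.
#' @export
designFromEpochs <- function(epochs, tr, microtimeBins = 16L, totalS = NULL) {
  stopifnot(all(c("condition", "onset", "duration") %in% names(epochs)))
  task <- epochs[epochs$condition %in% c("low", "high"), , drop = FALSE]
  if (nrow(task) > 1L) {
    o <- order(task$onset)
    so <- task[o, ]
    if (any(so$onset[-1] < (so$onset + so$duration)[-nrow(so)] - 1e-9))
      stop("task epochs overlap")
  }
  if (is.null(totalS)) totalS <- max(epochs$onset + epochs$duration)
  nScans <- as.integer(floor(totalS / tr + 1e-9))
  if (nScans < 1L) stop("design shorter than one TR")
  bins <- as.integer(microtimeBins)
  T <- nScans * bins
  tbin <- (seq_len(T) - 1L) * (tr / bins)
  u <- matrix(0, 2L, T)
  for (i in seq_len(nrow(task))) {
    on <- task$onset[i]; off <- on + task$duration[i]
    row <- if (task$condition[i] == "low") 1L else 2L
    u[row, tbin >= on - 1e-9 & tbin < off - 1e-9] <- 1
  }
  new("TaskDesign", u = u, tr = tr, microtimeBins = bins,
      epochs = epochs[, c("condition", "onset", "duration")],
      nScans = nScans)
}

#' Stimulus arithmetic for one task epoch
#'
#' @param epochS epoch length (s).
#' @param soaMs stimulus onset asynchrony (ms).
#' @return Number of stimulus events in the epoch
#'   (\code{floor(epochS * 1000 / soaMs)}).
#' @examples
#' stimulusCount(120, 250) # 480
#' @export
stimulusCount <- function(epochS, soaMs) {
  stopifnot(soaMs > 0)
  as.integer(floor(epochS * 1000 / soaMs))
}

#' @rdname stimulusCount
#' @param count stimulus count.
#' @param targetFraction fraction of targets (default 0.25).
#' @return \code{targetCount}: \code{round(count * targetFraction)}.
#' @export
targetCount <- function(count, targetFraction = 0.25) {
  as.integer(round(count * targetFraction))
}

.truthSpec <- function(label, n, intrinsic, modLow, modHigh,
                       driving, noiseSd) {
  new("GroupTruthSpec", label = label, nSubjects = as.integer(n),
      intrinsic = intrinsic, modLow = modLow, modHigh = modHigh,
      driving = driving, noiseSd = noiseSd)
}

#' Default group truth specifications
#'
#' Generative parameter distributions for the two cohorts: per-pathway
#' intrinsic means/SDs, per-pathway per-condition modulation means/SDs, and
#' driving efficacy. Cohort sizes default to 32 (HC) and 30 (OCD).
#' \code{noiseSd = NA} requests automatic calibration to SNR 1 at generation
#' time.
#'
#' @param n number of subjects.
#' @param noiseSd scan-noise SD (percent signal) or NA for automatic.
#' @return A \linkS4class{GroupTruthSpec}.
#' @export
hcTruthSpec <- function(n = 32L, noiseSd = NA_real_) {
  .truthSpec("HC", n, .HC_INTRINSIC, .HC_MOD_LOW, .HC_MOD_HIGH,
             .DRIVING_DEFAULT, noiseSd)
}

#' @rdname hcTruthSpec
#' @export
ocdTruthSpec <- function(n = 30L, noiseSd = NA_real_) {
  .truthSpec("OCD", n, .OCD_INTRINSIC, .OCD_MOD_LOW, .OCD_MOD_HIGH,
             .DRIVING_DEFAULT, noiseSd)
}

# DcmParameters at the spec's group means (no sampling), masked.
.meanParameters <- function(spec, template, mask, selfDecay = 0.5) {
  n <- length(template@regions)
  a <- matrix(0, n, n); bl <- a; bh <- a
  a[.connectionIndex(spec@intrinsic$pathway, template@regions)] <-
    spec@intrinsic$mean
  bl[.connectionIndex(spec@modLow$pathway, template@regions)] <-
    spec@modLow$mean
  bh[.connectionIndex(spec@modHigh$pathway, template@regions)] <-
    spec@modHigh$mean
  cm <- matrix(0, n, 2L)
  cm[match(spec@driving$region, template@regions), ] <- spec@driving$mean
  maskParameters(dcmParameters(a, bl, bh, cm, selfDecay), mask)
}

#' Sample per-subject ground-truth parameters
#'
#' Each subject's A / B / C entries are drawn independently from
#' N(pathway mean, pathway SD^2) per the group specification, then masked by
#' the generating model (all permuted connections present and modulated, by
#' default).
#'
#' @param spec a \linkS4class{GroupTruthSpec}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @param seed RNG seed.
#' @param generatingMask \linkS4class{MaskSet} of the generating model
#'   (default: the all-PRESENT_MODULATED architecture).
#' @param selfDecay fixed self-decay (Hz).
#' @return List of \linkS4class{DcmParameters}, one per subject.
#' @export
sampleGroupTruth <- function(spec, template, seed,
                             generatingMask = NULL, selfDecay = 0.5) {
  ok <- all(c(spec@intrinsic$pathway, spec@modLow$pathway,
              spec@modHigh$pathway) %in% templatePathways(template))
  if (!ok) stop("truth specification names a pathway outside the template")
  if (is.null(generatingMask)) {
    conns <- c(template@permuted3, template@permuted2)
    full <- new("ModelSpec", modelId = 0L,
                states = setNames(rep("PRESENT_MODULATED", length(conns)),
                                  conns))
    generatingMask <- modelMasks(full, template)
  }
  n <- length(template@regions)
  iA <- .connectionIndex(spec@intrinsic$pathway, template@regions)
  iL <- .connectionIndex(spec@modLow$pathway, template@regions)
  iH <- .connectionIndex(spec@modHigh$pathway, template@regions)
  iD <- match(spec@driving$region, template@regions)
  set.seed(seed)
  lapply(seq_len(spec@nSubjects), function(s) {
    a <- matrix(0, n, n); bl <- a; bh <- a
    a[iA] <- rnorm(nrow(iA), spec@intrinsic$mean, spec@intrinsic$sd)
    bl[iL] <- rnorm(nrow(iL), spec@modLow$mean, spec@modLow$sd)
    bh[iH] <- rnorm(nrow(iH), spec@modHigh$mean, spec@modHigh$sd)
    cm <- matrix(0, n, 2L)
    cm[iD, 1L] <- rnorm(length(iD), spec@driving$mean, spec@driving$sd)
    cm[iD, 2L] <- rnorm(length(iD), spec@driving$mean, spec@driving$sd)
    maskParameters(dcmParameters(a, bl, bh, cm, selfDecay), generatingMask)
  })
}

# flatten a DcmParameters to the full named parameter vector
.flattenParameters <- function(params, template) {
  regions <- template@regions
  perm <- permutedPathways(template)
  vals <- c(params@a[.connectionIndex(templatePathways(template), regions)],
            params@bLow[.connectionIndex(perm, regions)],
            params@bHigh[.connectionIndex(perm, regions)],
            as.vector(t(params@c[match(template@drivingTargets, regions), ,
                                 drop = FALSE])))
  setNames(vals, fullParameterNames(template))
}

#' Automatic noise calibration (SNR 1)
#'
#' The scan-noise SD that makes the global signal-to-noise ratio of a subject
#' at the HC group-mean parameters approximately 1: the pooled SD over regions
#' and scans of that subject's noiseless BOLD.
#'
#' @param spec a \linkS4class{GroupTruthSpec} (its means are used).
#' @param design the \linkS4class{TaskDesign}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @param generatingMask \linkS4class{MaskSet} of the generating model.
#' @param hemo hemodynamic constants.
#' @return Scalar noise SD (percent signal).
#' @export
calibrateNoiseSd <- function(spec, design, template, generatingMask = NULL,
                             hemo = defaultHemoParams()) {
  if (is.null(generatingMask)) {
    conns <- c(template@permuted3, template@permuted2)
    full <- new("ModelSpec", modelId = 0L,
                states = setNames(rep("PRESENT_MODULATED", length(conns)),
                                  conns))
    generatingMask <- modelMasks(full, template)
  }
  pm <- .meanParameters(spec, template, generatingMask)
  y <- simulateBold(pm, design, hemo = hemo, noiseSd = 0)
  sd(as.vector(y@y))
}

#' Generate a two-group synthetic cohort
#'
#' Per subject: draw ground-truth parameters from the group specification,
#' integrate the forward model under the shared design, add scan noise, and
#' package the series with its stored truth. Subject seeds are derived
#' deterministically from the master seed, so the cohort is regenerable
#' bit-exactly. A subject whose sampled parameters destabilize the integrator
#' is resampled once with halved couplings, then the generator fails.
#'
#' @param hcSpec,ocdSpec \linkS4class{GroupTruthSpec} for the two groups.
#' @param design a \linkS4class{TaskDesign} (or a \code{\link{designSpec}}
#'   list).
#' @param template the \linkS4class{NetworkTemplate}.
#' @param masterSeed integer master seed.
#' @param generatingMask optional \linkS4class{MaskSet} of the generating
#'   model (default all-PRESENT_MODULATED).
#' @param hemo hemodynamic constants.
#' @param outDir optional directory for a TSV/JSON bundle
#'   (see \code{\link{writeCohort}}).
#' @return A \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(hcSpec = hcTruthSpec(), ocdSpec = ocdTruthSpec(),
                           design = designSpec(), template = defaultTemplate(),
                           masterSeed = 1L, generatingMask = NULL,
                           hemo = defaultHemoParams(), outDir = NULL) {
  if (!is(design, "TaskDesign")) design <- makeDesign(design)
  if (is.null(generatingMask)) {
    conns <- c(template@permuted3, template@permuted2)
    full <- new("ModelSpec", modelId = 0L,
                states = setNames(rep("PRESENT_MODULATED", length(conns)),
                                  conns))
    generatingMask <- modelMasks(full, template)
  }
  noiseSd <- hcSpec@noiseSd
  if (is.na(noiseSd))
    noiseSd <- calibrateNoiseSd(hcSpec, design, template, generatingMask,
                                hemo)
  masterSeed <- as.integer(masterSeed)
  groupSeed <- function(k) (masterSeed * 1009L + k * 7919L) %% 2147483647L
  truthHc <- sampleGroupTruth(hcSpec, template, seed = groupSeed(1L),
                              generatingMask = generatingMask)
  truthOcd <- sampleGroupTruth(ocdSpec, template, seed = groupSeed(2L),
                               generatingMask = generatingMask)
  subjects <- list()
  rows <- list()
  specs <- list(list(spec = hcSpec, truth = truthHc),
                list(spec = ocdSpec, truth = truthOcd))
  sidx <- 0L
  for (g in specs) {
    gn <- if (!is.na(g$spec@noiseSd)) g$spec@noiseSd else noiseSd
    for (i in seq_len(g$spec@nSubjects)) {
      sidx <- sidx + 1L
      id <- sprintf("sub-%02d", sidx)
      truth <- g$truth[[i]]
      seedI <- groupSeed(100L + sidx)
      bold <- tryCatch(
        simulateBold(truth, design, hemo = hemo, noiseSd = gn, seed = seedI),
        error = function(e) NULL)
      if (is.null(bold)) {
        # damp the couplings once; persistent instability is an error
        truth@a <- truth@a * 0.5
        truth@bLow <- truth@bLow * 0.5
        truth@bHigh <- truth@bHigh * 0.5
        truth@c <- truth@c * 0.5
        bold <- simulateBold(truth, design, hemo = hemo, noiseSd = gn,
                             seed = seedI)
      }
      subjects[[id]] <- list(id = id, group = g$spec@label, bold = bold,
                             truth = truth)
      rows[[id]] <- data.frame(subject = id, group = g$spec@label,
                               t(.flattenParameters(truth, template)),
                               check.names = FALSE)
    }
  }
  cohort <- new("SyntheticCohort", subjects = subjects,
                truth = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                design = design, masterSeed = masterSeed, noiseSd = noiseSd)
  if (!is.null(outDir)) writeCohort(cohort, outDir)
  cohort
}
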