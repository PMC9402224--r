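# Canonical region order. Fixes the row/column semantics of every matrix in
# the package: coupling matrices are indexed [target, source].
.REGIONS <- c("V1", "SPC", "Thal", "BG", "dACC", "dPFC")

# The 13 inter-regional pathways, in the order group tables report them.
.PATHWAYS <- c("V1->SPC", "V1->Thal", "SPC->Thal", "SPC->BG", "Thal->BG",
               "Thal->dACC", "Thal->dPFC", "BG->Thal", "BG->dPFC",
               "dACC->Thal", "dACC->BG", "dPFC->Thal", "dPFC->BG")

.STATES3 <- c("ABSENT", "PRESENT", "PRESENT_MODULATED")
.STATES2 <- c("ABSENT", "PRESENT_MODULATED")

#' Canonical region names
#'
#' The six network regions in canonical order: primary visual cortex (V1),
#' superior parietal cortex (SPC), thalamus (Thal), basal ganglia (BG),
#' dorsal anterior cingulate cortex (dACC) and dorsal prefrontal cortex
#' (dPFC). All 6x6 matrices in the package index \code{[target, source]} in
#' this order.
#'
#' @return Character vector of length 6.
#' @export
regionNames <- function() .REGIONS

# split "SRC->DST" into c(source, target); vectorized
.parseConnection <- function(x) {
  parts <- strsplit(x, "->", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed connection string: ", x[bad][1])
  do.call(rbind, parts)
}

.connectionIndex <- function(x, regions = .REGIONS) {
  p <- .parseConnection(x)
  src <- match(p[, 1], regions)
  dst <- match(p[, 2], regions)
  if (anyNA(src) || anyNA(dst))
    stop("unknown region in connection: ", x[is.na(src) | is.na(dst)][1])
  cbind(target = dst, source = src)
}

#' NetworkTemplate: the hypothesis-space skeleton
#'
#' Defines the six regions, the eight intrinsic connections fixed across the
#' model space, the four fronto-thalamic connections permuted over
#' \{ABSENT, PRESENT, PRESENT_MODULATED\}, the dPFC->BG connection permuted
#' over \{ABSENT, PRESENT_MODULATED\}, and the regions receiving driving
#' input.
#'
#' @slot regions character, the canonical region order.
#' @slot fixed character, 8 connections "SRC->DST" present in every model.
#' @slot permuted3 character, 4 three-state permuted connections.
#' @slot permuted2 character, 1 two-state permuted connection.
#' @slot drivingTargets character, regions whose rows of C are free.
#' @export
setClass("NetworkTemplate",
  representation(regions = "character", fixed = "character",
                 permuted3 = "character", permuted2 = "character",
                 drivingTargets = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@regions) != 6L || anyDuplicated(object@regions))
      msg <- c(msg, "exactly 6 unique regions required")
    all3 <- c(object@fixed, object@permuted3, object@permuted2)
    idx <- tryCatch(.connectionIndex(all3, object@regions),
                    error = function(e) conditionMessage(e))
    if (is.character(idx)) return(idx)
    if (any(idx[, 1] == idx[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(all3))
      msg <- c(msg, "fixed and permuted connection lists must be disjoint")
    if (length(object@fixed) != 8L)
      msg <- c(msg, "exactly 8 fixed connections required")
    if (!all(object@drivingTargets %in% object@regions))
      msg <- c(msg, "driving targets must be regions")
    if (length(msg)) msg else TRUE
  })

#' ModelSpec: one architecture in the hypothesis space
#'
#' @slot modelId integer position (1-based) in the enumeration order.
#' @slot states named character vector mapping each permuted connection to its
#'   state (ABSENT, PRESENT or PRESENT_MODULATED).
#' @export
setClass("ModelSpec",
  representation(modelId = "integer", states = "character"),
  validity = function(object) {
    ok <- object@states %in% .STATES3
    if (!all(ok)) return("invalid connection state")
    if (is.null(names(object@states))) return("states must be named")
    TRUE
  })

#' MaskSet: binary masks over A, B and C for one model
#'
#' @slot aMask 6x6 binary, free off-diagonal intrinsic couplings.
#' @slot bMaskLow,bMaskHigh 6x6 binary, couplings modulated by the low/high
#'   demand condition. Modulation applies to both conditions jointly, so the
#'   two masks are always equal.
#' @slot cMask 6x2 binary, free driving-input entries.
#' @export
setClass("MaskSet",
  representation(aMask = "matrix", bMaskLow = "matrix",
                 bMaskHigh = "matrix", cMask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (any(diag(object@aMask) != 0)) msg <- c(msg, "aMask diagonal must be 0")
    if (!all(object@bMaskLow == object@bMaskHigh))
      msg <- c(msg, "bMaskLow and bMaskHigh must be equal")
    if (!all(object@bMaskLow <= object@aMask))
      msg <- c(msg, "b masks must be nested in aMask")
    vals <- c(object@aMask, object@bMaskLow, object@bMaskHigh, object@cMask)
    if (!all(vals %in% c(0, 1))) msg <- c(msg, "masks must be binary")
    if (length(msg)) msg else TRUE
  })

#' DcmParameters: numeric coupling parameters (Hz)
#'
#' @slot a 6x6 intrinsic coupling, off-diagonal only; the diagonal is fixed at
#'   \code{-selfDecay} inside the integrator.
#' @slot bLow,bHigh 6x6 condition-specific modulation of coupling.
#' @slot c 6x2 driving-input efficacy (columns: low, high demand input).
#' @slot selfDecay positive scalar, magnitude of the fixed self-decay (Hz).
#' @export
setClass("DcmParameters",
  representation(a = "matrix", bLow = "matrix", bHigh = "matrix",
                 c = "matrix", selfDecay = "numeric"),
  validity = function(object) {
    if (length(object@selfDecay) != 1L || object@selfDecay <= 0)
      return("selfDecay must be a positive scalar")
    if (any(diag(object@a) != 0))
      return("diagonal of a must be zero (self-decay is fixed separately)")
    TRUE
  })

#' TaskDesign: condition inputs on the microtime grid
#'
#' @slot u 2 x T binary matrix (row 1: low demand; row 2: high demand) on the
#'   microtime grid; rows are never simultaneously 1.
#' @slot tr repetition time (s).
#' @slot microtimeBins microtime bins per TR.
#' @slot epochs data.frame with columns condition ("low"/"high"/"rest"),
#'   onset (s), duration (s).
#' @slot nScans number of acquired volumes; T = nScans * microtimeBins.
#' @export
setClass("TaskDesign",
  representation(u = "matrix", tr = "numeric", microtimeBins = "integer",
                 epochs = "data.frame", nScans = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(object@u %in% c(0, 1))) msg <- c(msg, "u entries must be 0/1")
    if (nrow(object@u) != 2L) msg <- c(msg, "u must have 2 rows")
    if (any(colSums(object@u) > 1))
      msg <- c(msg, "low and high inputs must not be simultaneously active")
    if (ncol(object@u) != object@nScans * object@microtimeBins)
      msg <- c(msg, "u length must equal nScans * microtimeBins")
    if (length(msg)) msg else TRUE
  })

#' BoldTimeSeries: region x scan BOLD matrix
#'
#' @slot y 6 x nScans matrix of BOLD responses (percent signal change).
#' @slot tr repetition time (s).
#' @slot regions region names, canonical order.
#' @export
setClass("BoldTimeSeries",
  representation(y = "matrix", tr = "numeric", regions = "character"),
  validity = function(object) {
    if (nrow(object@y) != length(object@regions))
      return("y must have one row per region")
    if (!all(is.finite(object@y))) return("y must be finite")
    TRUE
  })

#' DcmPriors: Gaussian shrinkage priors over free parameters
#'
#' @slot mean,variance numeric vectors over the free parameters, in canonical
#'   flattening order (A block, then B low, B high, C).
#' @slot paramNames names of the free parameters ("A:SRC->DST", ...).
#' @slot lambdaMean,lambdaVar prior mean/variance of the log noise precision
#'   (shared across regions).
#' @export
setClass("DcmPriors",
  representation(mean = "numeric", variance = "numeric",
                 paramNames = "character", lambdaMean = "numeric",
                 lambdaVar = "numeric"),
  validity = function(object) {
    if (any(object@variance <= 0)) return("prior variances must be positive")
    if (length(object@mean) != length(object@variance) ||
        length(object@mean) != length(object@paramNames))
      return("mean, variance and paramNames must have equal length")
    TRUE
  })

#' PosteriorEstimate: variational-Laplace posterior for one subject and model
#'
#' @slot mu posterior mean over free parameters.
#' @slot sigma posterior covariance (symmetric positive semi-definite).
#' @slot freeEnergy the variational bound F on log model evidence (nats).
#' @slot lambda estimated log noise precision per region.
#' @slot fHistory F at each accepted iteration (non-decreasing).
#' @slot nIter accepted Gauss-Newton iterations.
#' @slot converged TRUE if the F increment fell below tolerance.
#' @slot paramNames names of the free parameters.
#' @export
setClass("PosteriorEstimate",
  representation(mu = "numeric", sigma = "matrix", freeEnergy = "numeric",
                 lambda = "numeric", fHistory = "numeric", nIter = "integer",
                 converged = "logical", paramNames = "character"),
  validity = function(object) {
    if (max(abs(object@sigma - t(object@sigma))) > 1e-10)
      return("sigma must be symmetric")
    if (!is.finite(object@freeEnergy)) return("free energy must be finite")
    TRUE
  })

#' BmsResult: random-effects Bayesian model selection summary
#'
#' @slot alpha Dirichlet concentration parameters over models.
#' @slot expectedProb expected model frequencies (alpha / sum(alpha)).
#' @slot exceedanceProb Monte-Carlo exceedance probabilities.
#' @slot nIter,converged fixed-point iteration diagnostics.
#' @export
setClass("BmsResult",
  representation(alpha = "numeric", expectedProb = "numeric",
                 exceedanceProb = "numeric", nIter = "integer",
                 converged = "logical"),
  validity = function(object) {
    if (abs(sum(object@expectedProb) - 1) > 1e-9)
      return("expected probabilities must sum to 1")
    TRUE
  })

#' BmaResult: Bayesian model averages over Occam's window
#'
#' @slot estimates subjects x parameters matrix on the full parameterization
#'   (13 intrinsic + 2x5 modulation + driving entries); parameters absent from
#'   a sampled model contribute 0.
#' @slot mcse Monte-Carlo standard errors, same shape.
#' @slot windowIds model ids inside Occam's window.
#' @slot weights renormalized window weights.
#' @slot nSamples,seed sampling settings.
#' @export
setClass("BmaResult",
  representation(estimates = "matrix", mcse = "matrix",
                 windowIds = "integer", weights = "numeric",
                 nSamples = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@windowIds) == 0L) return("Occam's window is empty")
    if (abs(sum(object@weights) - 1) > 1e-12)
      return("window weights must sum to 1")
    TRUE
  })

#' GroupTruthSpec: generative distribution of one cohort's parameters
#'
#' Pathway-level means and between-subject SDs used to draw each subject's
#' ground-truth coupling parameters.
#'
#' @slot label group label ("HC"/"OCD").
#' @slot nSubjects number of subjects (>= 2).
#' @slot intrinsic data.frame pathway/mean/sd over the 13 pathways.
#' @slot modLow,modHigh data.frame pathway/mean/sd over the 5 modulable
#'   pathways, per demand condition.
#' @slot driving data.frame region/mean/sd for driving efficacy.
#' @slot noiseSd scan-noise SD (percent signal); NA requests the automatic
#'   SNR-1 calibration at cohort generation time.
#' @export
setClass("GroupTruthSpec",
  representation(label = "character", nSubjects = "integer",
                 intrinsic = "data.frame", modLow = "data.frame",
                 modHigh = "data.frame", driving = "data.frame",
                 noiseSd = "numeric"),
  validity = function(object) {
    if (object@nSubjects < 2L) return("nSubjects must be >= 2")
    for (s in c("intrinsic", "modLow", "modHigh"))
      if (any(slot(object, s)$sd < 0)) return("SDs must be non-negative")
    TRUE
  })

#' SyntheticCohort: simulated subjects with stored ground truth
#'
#' @slot subjects list; each element has fields id, group, bold
#'   (\linkS4class{BoldTimeSeries}) and truth (\linkS4class{DcmParameters}).
#' @slot truth data.frame of each subject's true parameter values on the full
#'   parameterization.
#' @slot design the shared \linkS4class{TaskDesign}.
#' @slot masterSeed seed the cohort is regenerable from.
#' @slot noiseSd the scan-noise SD actually used.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", truth = "data.frame",
                 design = "TaskDesign", masterSeed = "integer",
                 noiseSd = "numeric"))
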