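#' @name accessors
#' @title Accessors for tcdcm S4 classes
#' @description Slot accessors for the central data objects. Prefer these over
#'   direct slot access.
#' @param object an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("boldMatrix", function(object) standardGeneric("boldMatrix"))
#' @rdname accessors
#' @export
setMethod("boldMatrix", "BoldTimeSeries", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("repetitionTime",
           function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setMethod("repetitionTime", "BoldTimeSeries", function(object) object@tr)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "TaskDesign", function(object) object@tr)

#' @rdname accessors
#' @export
setGeneric("inputMatrix", function(object) standardGeneric("inputMatrix"))
#' @rdname accessors
#' @export
setMethod("inputMatrix", "TaskDesign", function(object) object@u)

#' @rdname accessors
#' @export
setGeneric("epochTable", function(object) standardGeneric("epochTable"))
#' @rdname accessors
#' @export
setMethod("epochTable", "TaskDesign", function(object) object@epochs)

#' @rdname accessors
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))
#' @rdname accessors
#' @export
setMethod("nScans", "TaskDesign", function(object) object@nScans)
#' @rdname accessors
#' @export
setMethod("nScans", "BoldTimeSeries", function(object) ncol(object@y))

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setMethod("modelId", "ModelSpec", function(object) object@modelId)

#' @rdname accessors
#' @export
setGeneric("connectionStates",
           function(object) standardGeneric("connectionStates"))
#' @rdname accessors
#' @export
setMethod("connectionStates", "ModelSpec", function(object) object@states)

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(object) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "PosteriorEstimate", function(object) {
  setNames(object@mu, object@paramNames)
})

#' @rdname accessors
#' @export
setGeneric("posteriorCov", function(object) standardGeneric("posteriorCov"))
#' @rdname accessors
#' @export
setMethod("posteriorCov", "PosteriorEstimate", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "PosteriorEstimate",
          function(object) object@freeEnergy)

#' @rdname accessors
#' @export
setGeneric("expectedProb", function(object) standardGeneric("expectedProb"))
#' @rdname accessors
#' @export
setMethod("expectedProb", "BmsResult", function(object) object@expectedProb)

#' @rdname accessors
#' @export
setGeneric("exceedanceProb",
           function(object) standardGeneric("exceedanceProb"))
#' @rdname accessors
#' @export
setMethod("exceedanceProb", "BmsResult",
          function(object) object@exceedanceProb)

#' @rdname accessors
#' @export
setGeneric("bmaEstimates", function(object) standardGeneric("bmaEstimates"))
#' @rdname accessors
#' @export
setMethod("bmaEstimates", "BmaResult", function(object) object@estimates)

#' @rdname accessors
#' @export
setGeneric("cohortSubjects",
           function(object) standardGeneric("cohortSubjects"))
#' @rdname accessors
#' @export
setMethod("cohortSubjects", "SyntheticCohort",
          function(object) object@subjects)

setMethod("show", "NetworkTemplate", function(object) {
  cat("NetworkTemplate:", length(object@regions), "regions;",
      length(object@fixed), "fixed,",
      length(object@permuted3) + length(object@permuted2),
      "permuted connections; driving ->",
      paste(object@drivingTargets, collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec", object@modelId, "\n")
  st <- object@states
  cat(paste0("  ", names(st), ": ", st, collapse = "\n"), "\n")
})

setMethod("show", "BoldTimeSeries", function(object) {
  cat("BoldTimeSeries:", nrow(object@y), "regions x", ncol(object@y),
      "scans, TR", object@tr, "s\n")
})

setMethod("show", "TaskDesign", function(object) {
  cat("TaskDesign:", object@nScans, "scans, TR", object@tr, "s,",
      object@microtimeBins, "microtime bins/TR;",
      nrow(object@epochs), "epochs\n")
})

setMethod("show", "PosteriorEstimate", function(object) {
  cat("PosteriorEstimate:", length(object@mu), "parameters, F =",
      format(object@freeEnergy, digits = 8), "nats,", object@nIter,
      "iterations,", if (object@converged) "converged" else "not converged",
      "\n")
})

setMethod("show", "BmsResult", function(object) {
  k <- which.max(object@exceedanceProb)
  cat("BmsResult over", length(object@alpha), "models; top exceedance model",
      k, sprintf("(xp = %.3f)", object@exceedanceProb[k]), "\n")
})

setMethod("show", "BmaResult", function(object) {
  cat("BmaResult:", nrow(object@estimates), "subjects x",
      ncol(object@estimates), "parameters;", length(object@windowIds),
      "models in Occam's window;", object@nSamples, "samples\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  gr <- table(vapply(object@subjects, function(s) s$group, ""))
  cat("SyntheticCohort:", length(object@subjects), "subjects (",
      paste(names(gr), gr, sep = "=", collapse = ", "), "), noise SD",
      format(object@noiseSd, digits = 4), "\n")
})
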