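#' Occam's window over model probabilities
#'
#' Retains the models whose expected probability is within a fixed odds ratio
#' of the best model's, and renormalizes the weights over the retained set.
#'
#' @param expectedProb probability vector over models (sums to 1).
#' @param ratio odds cutoff (default 1/20): model k stays if
#'   \code{expectedProb[k] / max(expectedProb) > ratio}.
#' @param modelIds optional ids to label the result (default positions).
#' @return List with \code{ids} (retained model ids) and \code{weights}
#'   (renormalized, named by id).
#' @export
occamsWindow <- function(expectedProb, ratio = 1 / 20,
                         modelIds = seq_along(expectedProb)) {
  stopifnot(abs(sum(expectedProb) - 1) < 1e-6, ratio >= 0)
  keep <- which(expectedProb / max(expectedProb) > ratio)
  w <- expectedProb[keep] / sum(expectedProb[keep])
  list(ids = as.integer(modelIds[keep]), weights = setNames(w, modelIds[keep]))
}

#' Bayesian model averaging over Occam's window
#'
#' For each of \code{nSamples} draws, a model is sampled from the window
#' weights and, for every subject, a parameter vector is drawn from that
#' subject's posterior under the sampled model, embedded into the full
#' parameterization with zeros for parameters the model omits. The subject's
#' BMA estimate is the mean over draws; Monte-Carlo standard errors are
#' returned alongside.
#'
#' @param posteriors list over subjects (named by subject id); each element a
#'   list of \linkS4class{PosteriorEstimate} named by model id.
#' @param window list from \code{\link{occamsWindow}} (\code{ids},
#'   \code{weights}).
#' @param template the \linkS4class{NetworkTemplate} (defines the full
#'   parameterization).
#' @param nSamples Monte-Carlo draws (default 20000).
#' @param seed RNG seed.
#' @return A \linkS4class{BmaResult}.
#' @export
bmaAverage <- function(posteriors, window, template, nSamples = 20000L,
                       seed = 1L) {
  fullNames <- fullParameterNames(template)
  ids <- as.character(window$ids)
  missing <- unlist(lapply(names(posteriors), function(s) {
    miss <- setdiff(ids, names(posteriors[[s]]))
    if (length(miss)) paste0("(subject ", s, ", model ", miss, ")")
  }))
  if (length(missing))
    stop("missing posteriors for window models: ",
         paste(missing, collapse = ", "))
  nSub <- length(posteriors)
  nSamples <- as.integer(nSamples)
  set.seed(seed)
  counts <- as.vector(rmultinom(1L, nSamples, window$weights))
  est <- matrix(0, nSub, length(fullNames),
                dimnames = list(names(posteriors), fullNames))
  ssq <- est
  for (s in seq_len(nSub)) {
    for (k in seq_along(ids)) {
      m <- counts[k]
      if (m == 0L) next
      po <- posteriors[[s]][[ids[k]]]
      idx <- match(po@paramNames, fullNames)
      if (anyNA(idx)) stop("posterior parameter names outside the template")
      p <- length(po@mu)
      L <- tryCatch(chol(po@sigma), error = function(e)
        chol(po@sigma + diag(1e-10, p)))
      z <- matrix(rnorm(m * p), m, p) %*% L
      draws <- sweep(z, 2L, po@mu, "+")
      est[s, idx] <- est[s, idx] + colSums(draws)
      ssq[s, idx] <- ssq[s, idx] + colSums(draws^2)
    }
  }
  mean <- est / nSamples
  mcse <- sqrt(pmax(ssq / nSamples - mean^2, 0) / nSamples)
  new("BmaResult", estimates = mean, mcse = mcse,
      windowIds = as.integer(window$ids), weights = as.numeric(window$weights),
      nSamples = nSamples, seed = as.integer(seed))
}

#' Write a BMA result: TSV of estimates plus JSON metadata
#'
#' @param res a \linkS4class{BmaResult}.
#' @param path TSV output (one row per subject, named parameter columns);
#'   metadata (window, weights, seed, n_samples) goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeBmaResult <- function(res, path) {
  df <- data.frame(subject = rownames(res@estimates), res@estimates,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(window = res@windowIds, weights = res@weights,
         n_samples = res@nSamples, seed = res@seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
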