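#' Random-effects Bayesian model selection
#'
#' Variational fixed-point estimation of the Dirichlet posterior over model
#' frequencies in the population. With subject-by-model log evidences F, the
#' updates iterate responsibilities u_nk proportional to
#' exp(F_nk + psi(alpha_k) - psi(sum alpha)) (rows normalized; each subject's
#' row of F is recentred first, which leaves the result unchanged but avoids
#' overflow) and alpha_k = alpha0 + sum_n u_nk, until the largest change in
#' alpha falls below \code{tol}.
#'
#' @param f N x K matrix of free energies (subjects x models, nats).
#' @param alpha0 Dirichlet prior concentration (default 1, uniform).
#' @param tol fixed-point tolerance on max |delta alpha| (default 1e-6).
#' @param maxIter maximum iterations (default 200).
#' @param exceedanceSamples Monte-Carlo draws for the exceedance computation.
#' @param seed RNG seed for the exceedance draws.
#' @return A \linkS4class{BmsResult}.
#' @export
rfxBms <- function(f, alpha0 = 1, tol = 1e-6, maxIter = 200L,
                   exceedanceSamples = 1e5, seed = 1L) {
  f <- as.matrix(f)
  if (!all(is.finite(f))) stop("free energies must be finite")
  N <- nrow(f); K <- ncol(f)
  stopifnot(N >= 1L, K >= 2L)
  fr <- f - apply(f, 1L, max)
  alpha <- rep(alpha0, K)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxIter)) {
    lg <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(fr, 2L, lg, "+")
    lu <- lu - apply(lu, 1L, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alphaNew <- alpha0 + colSums(u)
    d <- max(abs(alphaNew - alpha))
    alpha <- alphaNew
    iter <- it
    if (d < tol) { converged <- TRUE; break }
  }
  xp <- exceedanceProbability(alpha, nSamples = exceedanceSamples, seed = seed)
  new("BmsResult", alpha = alpha, expectedProb = alpha / sum(alpha),
      exceedanceProb = xp, nIter = iter, converged = converged)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo estimate of the probability that each model is the most
#' frequent in the population: draws \code{nSamples} vectors from
#' Dirichlet(alpha) and returns the frequency with which each component is the
#' maximum (ties broken by first index, a probability-zero event for
#' continuous draws). The output sums to 1 exactly.
#'
#' @param alpha positive Dirichlet concentration vector.
#' @param nSamples Monte-Carlo draws (default 1e5).
#' @param seed RNG seed (default 1).
#' @return Numeric vector of exceedance probabilities.
#' @export
exceedanceProbability <- function(alpha, nSamples = 1e5, seed = 1L) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  set.seed(seed)
  # a Dirichlet argmax equals the argmax of independent Gamma(alpha_k) draws
  g <- matrix(rgamma(nSamples * K, shape = rep(alpha, each = nSamples)),
              nrow = nSamples, ncol = K)
  win <- max.col(g, ties.method = "first")
  tabulate(win, nbins = K) / nSamples
}

#' Write / read an evidence matrix as TSV
#'
#' Rows are subjects, columns are model ids.
#'
#' @param f N x K evidence matrix with rownames (subject ids) and colnames
#'   (model ids).
#' @param path TSV file.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeEvidence <- function(f, path) {
  df <- data.frame(subject = rownames(f), f, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject
  m
}

#' Serialize a BMS result to JSON
#' @param res a \linkS4class{BmsResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBmsResult <- function(res, path) {
  jsonlite::write_json(
    list(alpha = res@alpha, expected_prob = res@expectedProb,
         exceedance_prob = res@exceedanceProb, n_iter = res@nIter,
         converged = res@converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
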