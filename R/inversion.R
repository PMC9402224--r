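#' Default shrinkage priors for a model
#'
#' Zero-mean Gaussian priors over the free parameters: variance 1/16 for
#' intrinsic (A) and modulation (B) couplings, 1/4 for driving (C) entries.
#' The log noise precision per region has a Gaussian prior with mean log(1) = 0
#' and variance 1.
#'
#' @param mask a \linkS4class{MaskSet}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @return A \linkS4class{DcmPriors}.
#' @export
defaultPriors <- function(mask, template) {
  ix <- .maskIndex(mask, template)
  v <- c(rep(1 / 16, ix$nA + 2L * ix$nB), rep(1 / 4, ix$nC))
  new("DcmPriors", mean = numeric(length(v)), variance = v,
      paramNames = ix$paramNames, lambdaMean = 0, lambdaVar = 1)
}

#' Inversion settings
#'
#' @param maxIter maximum Gauss-Newton iterations (default 64).
#' @param tol convergence tolerance on the free-energy increment (nats,
#'   default 0.01).
#' @param h finite-difference step for the Jacobian (default 1e-4).
#' @param maxHalvings Levenberg-style step halvings before giving up an
#'   iteration (default 8).
#' @return Named list of settings.
#' @export
inversionSettings <- function(maxIter = 64L, tol = 0.01, h = 1e-4,
                              maxHalvings = 8L) {
  list(maxIter = as.integer(maxIter), tol = tol, h = h,
       maxHalvings = as.integer(maxHalvings))
}

# KL( N(mu, Sigma) || N(m0, diag(v0)) ), diagonal prior.
.klGauss <- function(mu, sigma, m0, v0) {
  p <- length(mu)
  ld <- tryCatch(2 * sum(log(diag(chol(sigma)))), error = function(e) {
    # near-singular but PSD covariances (noiseless data) need a jitter
    jit <- max(diag(sigma), 0) * 1e-10 + 1e-300
    tryCatch(2 * sum(log(diag(chol(sigma + diag(jit, p))))),
             error = function(e2)
               stop("posterior covariance is not positive definite"))
  })
  0.5 * (sum(diag(sigma) / v0) + sum((mu - m0)^2 / v0) - p +
           sum(log(v0)) - ld)
}

#' Variational free energy
#'
#' The variational lower bound on log model evidence for Gaussian observation
#' noise with per-region log precision \code{lambda}:
#' F = sum_r ( n/2 (lambda_r - log 2 pi) - exp(lambda_r)/2 (||e_r||^2 +
#' tr(J_r Sigma J_r')) ) - KL( N(mu, Sigma) || prior ). The curvature term
#' tr(J Sigma J') (the expectation of the log likelihood under the posterior)
#' is included when a Jacobian is supplied and omitted otherwise.
#'
#' @param data,prediction 6 x n matrices (or \linkS4class{BoldTimeSeries}).
#' @param mu,sigma posterior mean and covariance of the free parameters.
#' @param priors a \linkS4class{DcmPriors}.
#' @param lambda log noise precision per region.
#' @param jacobian optional (n_regions * n_scans) x p Jacobian of the
#'   prediction (rows ordered region-fastest, as columns of the prediction
#'   stacked).
#' @return Scalar F (nats).
#' @export
computeFreeEnergy <- function(data, prediction, mu, sigma, priors, lambda,
                              jacobian = NULL) {
  y <- if (is(data, "BoldTimeSeries")) data@y else data
  g <- if (is(prediction, "BoldTimeSeries")) prediction@y else prediction
  stopifnot(identical(dim(y), dim(g)))
  if (max(abs(sigma - t(sigma))) > 1e-10) stop("sigma must be symmetric")
  nr <- nrow(y); n <- ncol(y)
  lambda <- rep_len(lambda, nr)
  e <- y - g
  sse <- rowSums(e^2)
  trj <- numeric(nr)
  if (!is.null(jacobian)) {
    js <- jacobian %*% sigma
    rq <- rowSums(jacobian * js)        # diag(J Sigma J')
    reg <- rep_len(seq_len(nr), length(rq))
    trj <- vapply(seq_len(nr), function(r) sum(rq[reg == r]), 0)
  }
  acc <- sum(n / 2 * (lambda - log(2 * pi)) - exp(lambda) / 2 * (sse + trj))
  acc - .klGauss(mu, sigma, priors@mean, priors@variance)
}

# A candidate parameter vector is admissible only if every condition-specific
# effective coupling matrix is strictly stable (spectral abscissa below
# -margin): the bilinear model is only defined on the stable region, and
# finite-difference Jacobians need an interior point.
.stableTheta <- function(theta, ix, selfDecay, n, margin = 1e-3) {
  aEff <- matrix(0, n, n)
  diag(aEff) <- -selfDecay
  k <- nrow(ix$iA)
  if (k) aEff[ix$iA + 1L] <- theta[seq_len(k)]
  bl <- matrix(0, n, n); bh <- bl
  kb <- nrow(ix$iB)
  if (kb) {
    bl[ix$iB + 1L] <- theta[k + seq_len(kb)]
    bh[ix$iB + 1L] <- theta[k + kb + seq_len(kb)]
  }
  sa <- function(m) max(Re(eigen(m, only.values = TRUE)$values))
  sa(aEff) < -margin && sa(aEff + bl) < -margin && sa(aEff + bh) < -margin
}

# MAP-flavored EM update of the per-region log noise precision, combining the
# ML estimate (residual power plus posterior-uncertainty correction) with the
# Gaussian prior on lambda, weighted by the Fisher information n/2.
.lambdaUpdate <- function(sse, trj, n, priors) {
  mse <- pmax((sse + trj) / n, 1e-12)
  lamMl <- -log(mse)
  (n / 2 * lamMl + priors@lambdaMean / priors@lambdaVar) /
    (n / 2 + 1 / priors@lambdaVar)
}

#' Invert one model for one subject (variational Laplace)
#'
#' Gauss-Newton ascent on the variational free energy with central
#' finite-difference Jacobians, coordinate updates of the posterior
#' covariance, an EM update of the per-region log noise precision, and
#' Levenberg-style step-length control: a mean step is accepted only if the
#' bound, re-evaluated under a fresh linearization at the new point, does not
#' fall below the best value seen, otherwise it is reverted and retried at
#' half the step length. The recorded F sequence is therefore non-decreasing
#' over accepted iterations. Candidate means are restricted to dynamically
#' stable parameters (negative spectral abscissa of the effective coupling
#' matrices). Initialization is at the prior mean. Deterministic given
#' (data, settings).
#'
#' @param data a \linkS4class{BoldTimeSeries}.
#' @param design the \linkS4class{TaskDesign} the data were acquired under.
#' @param mask the model's \linkS4class{MaskSet}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @param priors \linkS4class{DcmPriors}; defaults to
#'   \code{\link{defaultPriors}}.
#' @param settings list from \code{\link{inversionSettings}}.
#' @param hemo fixed hemodynamic constants.
#' @param selfDecay fixed self-decay magnitude (Hz).
#' @return A \linkS4class{PosteriorEstimate}.
#' @export
invertModel <- function(data, design, mask, template,
                        priors = defaultPriors(mask, template),
                        settings = inversionSettings(),
                        hemo = defaultHemoParams(), selfDecay = 0.5) {
  y <- data@y
  stopifnot(all(is.finite(y)), ncol(y) == design@nScans)
  nr <- nrow(y); n <- ncol(y)
  ix <- .maskIndex(mask, template)
  if (!identical(ix$paramNames, priors@paramNames))
    stop("priors do not match the mask's free parameters")
  hv <- .hemoVectors(hemo, nr)
  p <- length(priors@mean)
  m0 <- priors@mean; v0 <- priors@variance
  yv <- as.vector(y)
  reg <- rep_len(seq_len(nr), length(yv))
  regIdx <- lapply(seq_len(nr), function(r) which(reg == r))

  fe <- function(gv, mu, sigma, lambda, J) {
    e <- yv - gv
    sse <- vapply(regIdx, function(i) sum(e[i]^2), 0)
    js <- J %*% sigma
    rq <- rowSums(J * js)
    trj <- vapply(regIdx, function(i) sum(rq[i]), 0)
    list(f = sum(n / 2 * (lambda - log(2 * pi)) -
                   exp(lambda) / 2 * (sse + trj)) -
           .klGauss(mu, sigma, m0, v0),
         sse = sse, trj = trj)
  }

  # (sigma, lambda) coordinate updates at a fixed linearization; each is kept
  # only if it does not lower the bound
  refresh <- function(st) {
    w <- exp(st$lambda)[reg]
    H <- crossprod(st$J * sqrt(w)) + diag(1 / v0, p)
    sigmaNew <- tryCatch(chol2inv(chol(H)), error = function(err)
      chol2inv(chol(H + diag(1e-8, p))))
    sigmaNew <- (sigmaNew + t(sigmaNew)) / 2
    fSig <- fe(st$g, st$mu, sigmaNew, st$lambda, st$J)$f
    if (is.finite(fSig) && fSig >= st$f) {
      st$sigma <- sigmaNew
      st$f <- fSig
    }
    cur <- fe(st$g, st$mu, st$sigma, st$lambda, st$J)
    lambdaC <- .lambdaUpdate(cur$sse, cur$trj, n, priors)
    fLam <- fe(st$g, st$mu, st$sigma, lambdaC, st$J)$f
    if (is.finite(fLam) && fLam >= st$f) {
      st$lambda <- lambdaC
      st$f <- fLam
    }
    st
  }

  gj <- .predictJac(priors@mean, ix, selfDecay, design, hv, settings$h)
  if (!isTRUE(gj$ok))
    stop("forward model unstable at the prior mean")
  st <- list(mu = m0, sigma = diag(v0, p), lambda = rep(priors@lambdaMean, nr),
             g = gj$g, J = gj$J)
  st$f <- fe(st$g, st$mu, st$sigma, st$lambda, st$J)$f
  st <- refresh(st)

  best <- st
  fHist <- st$f
  converged <- FALSE
  iter <- 0L
  damp <- 1            # Levenberg-style step-length state across iterations
  nAccept <- 0L
  dampFloor <- 2^(-settings$maxHalvings)

  # SPM-style expansion-point scheme: a Gauss-Newton step is accepted
  # provisionally on a cheap screen under the current linearization; the
  # next iteration re-linearizes at the new point and judges it honestly.
  # A step whose refreshed bound falls below the best state is reverted
  # (reusing the stored linearization, no recomputation) and retried with a
  # halved step length, so the recorded F sequence is non-decreasing.
  for (it in seq_len(settings$maxIter)) {
    if (st$f < best$f) {
      if (best$f - st$f < settings$tol) {
        # the refreshed bound sits within tolerance of the best state: no
        # tolerance-sized improvement is available from this direction
        converged <- TRUE
        break
      }
      st <- best                       # revert the provisional step
      damp <- damp / 2
      if (damp < dampFloor) break
    } else if (it > 1L || st$f > best$f) {
      gain <- st$f - best$f
      best <- st
      fHist <- c(fHist, st$f)
      iter <- iter + 1L
      if (it > 1L && gain < settings$tol) {
        converged <- TRUE
        break
      }
      # step-length memory is sticky: re-expanding it after every accepted
      # step just re-triggers expensive revert ladders
      nAccept <- nAccept + 1L
      if (nAccept %% 3L == 0L) damp <- min(1, damp * 2)
    }

    # damped Gauss-Newton proposal from the current expansion point,
    # screened under its linearization with sigma and lambda held fixed
    w <- exp(st$lambda)[reg]
    H <- crossprod(st$J * sqrt(w)) + diag(1 / v0, p)
    curv <- tryCatch(chol2inv(chol(H)), error = function(err)
      chol2inv(chol(H + diag(1e-8, p))))
    grad <- crossprod(st$J, w * (yv - st$g)) - (st$mu - m0) / v0
    delta <- as.vector(curv %*% grad)
    accepted <- FALSE
    tstep <- damp
    while (tstep >= dampFloor) {
      muC <- st$mu + tstep * delta
      if (.stableTheta(muC, ix, selfDecay, nr)) {
        gC <- tryCatch(as.vector(.predict(muC, ix, selfDecay, design, hv)),
                       error = function(err) NULL)
        if (!is.null(gC) && all(is.finite(gC)) &&
            fe(gC, muC, st$sigma, st$lambda, st$J)$f >= st$f) {
          gjC <- .predictJac(muC, ix, selfDecay, design, hv, settings$h)
          if (isTRUE(gjC$ok)) {
            stC <- list(mu = muC, sigma = st$sigma, lambda = st$lambda,
                        g = gjC$g, J = gjC$J)
            stC$f <- fe(stC$g, stC$mu, stC$sigma, stC$lambda, stC$J)$f
            stC <- refresh(stC)
            st <- stC                  # provisional: judged next iteration
            accepted <- TRUE
          }
          break
        }
      }
      tstep <- tstep / 2
    }
    if (!accepted) break               # no admissible proposal from here
  }

  # final provisional step, if any, is kept only when it improved the bound
  if (st$f > best$f) {
    best <- st
    fHist <- c(fHist, st$f)
    iter <- iter + 1L
  }
  new("PosteriorEstimate", mu = best$mu, sigma = best$sigma,
      freeEnergy = best$f, lambda = best$lambda, fHistory = fHist,
      nIter = iter, converged = converged, paramNames = ix$paramNames)
}

#' Serialize a posterior estimate to JSON
#'
#' @param est a \linkS4class{PosteriorEstimate}.
#' @param modelId the model id the estimate belongs to.
#' @param path output file.
#' @param sigmaPath optional TSV sidecar receiving the full covariance.
#' @return \code{path}, invisibly.
#' @export
writePosterior <- function(est, modelId, path, sigmaPath = NULL) {
  obj <- list(model_id = modelId, F = est@freeEnergy,
              mu = setNames(as.list(est@mu), est@paramNames),
              diag_sigma = setNames(as.list(diag(est@sigma)), est@paramNames),
              lambda = est@lambda, n_iter = est@nIter,
              converged = est@converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(sigmaPath))
    write.table(est@sigma, sigmaPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = est@paramNames)
  invisible(path)
}
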