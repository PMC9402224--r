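# Shared fixtures: the default template and model space, a small task design,
# and a designated ground-truth subject used by the recovery checks.

tpl <- defaultTemplate()
modelSpace <- enumerateModels(tpl)

findModelByStates <- function(states) {
  key <- paste(states, collapse = ",")
  for (m in modelSpace)
    if (paste(connectionStates(m), collapse = ",") == key) return(m)
  stop("no model with the requested states")
}

# scaled-down designs used by cohort-level checks
smallDesign <- function(nCycles = 1L, bins = 8L) {
  makeDesign(designSpec(nCycles = nCycles, microtimeBins = bins))
}

setEntry <- function(m, src, dst, v) {
  m[dst, src] <- v
  m
}

# Ground-truth subject for parameter recovery: the architecture with all four
# fronto-thalamic connections present and the two ascending relays modulated
# (18 free parameters), with couplings strong enough to engage every region.
recoveryModel <- function() {
  findModelByStates(c("PRESENT_MODULATED", "PRESENT", "PRESENT_MODULATED",
                      "PRESENT", "ABSENT"))
}

recoveryTruth <- function() {
  r <- regionNames()
  a <- matrix(0, 6, 6, dimnames = list(r, r))
  a <- setEntry(a, "V1", "SPC", 0.25); a <- setEntry(a, "V1", "Thal", 0.30)
  a <- setEntry(a, "SPC", "Thal", 0.15); a <- setEntry(a, "SPC", "BG", 0.10)
  a <- setEntry(a, "Thal", "BG", 0.20); a <- setEntry(a, "Thal", "dACC", 0.30)
  a <- setEntry(a, "Thal", "dPFC", 0.25); a <- setEntry(a, "BG", "Thal", -0.15)
  a <- setEntry(a, "BG", "dPFC", 0.20); a <- setEntry(a, "dACC", "Thal", -0.10)
  a <- setEntry(a, "dACC", "BG", 0.15); a <- setEntry(a, "dPFC", "Thal", 0.10)
  bl <- matrix(0, 6, 6, dimnames = list(r, r)); bh <- bl
  bl <- setEntry(bl, "Thal", "dPFC", 0.30)
  bl <- setEntry(bl, "Thal", "dACC", 0.25)
  bh <- setEntry(bh, "Thal", "dPFC", 0.40)
  bh <- setEntry(bh, "Thal", "dACC", -0.20)
  cm <- matrix(0, 6, 2); cm[1, ] <- 0.25
  maskParameters(dcmParameters(a, bl, bh, cm),
                 modelMasks(recoveryModel(), tpl))
}

# embed a posterior mean into the full parameterization (zeros elsewhere)
embedMu <- function(est) {
  full <- setNames(numeric(length(fullParameterNames(tpl))),
                   fullParameterNames(tpl))
  full[est@paramNames] <- est@mu
  full
}

# group truth spec with only the Thal->dPFC modulation free (same mean for
# both demand conditions), used by the planted-difference checks
plantThalDpfc <- function(base, mean, sd = 0.27) {
  base@modLow$mean <- ifelse(base@modLow$pathway == "Thal->dPFC", mean, 0)
  base@modLow$sd <- ifelse(base@modLow$pathway == "Thal->dPFC", sd, 0)
  base@modHigh$mean <- base@modLow$mean
  base@modHigh$sd <- base@modLow$sd
  base
}

# analytic evidence and posterior for the conjugate linear-Gaussian model
# y = X theta + e, e ~ N(0, 1/s I), theta ~ N(0, diag(v0))
linearGaussOracle <- function(X, y, v0, s) {
  n <- length(y)
  sigma <- solve(s * crossprod(X) + diag(1 / v0, length(v0)))
  mu <- as.vector(sigma %*% (s * crossprod(X, y)))
  C <- X %*% diag(v0, length(v0)) %*% t(X) + diag(1 / s, n)
  logEv <- as.numeric(-0.5 * (n * log(2 * pi) +
                              determinant(C)$modulus + t(y) %*% solve(C, y)))
  list(mu = mu, sigma = sigma, logEv = logEv)
}
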