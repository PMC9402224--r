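---
title: "Modeling demand-dependent thalamo-cortical effective connectivity"
author: "tcdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling demand-dependent thalamo-cortical effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcdcm)
```

## The scientific problem

Sustained attention engages a distributed thalamo-cortical network: primary
visual cortex (V1), superior parietal cortex (SPC), thalamus, basal ganglia
(BG), dorsal anterior cingulate cortex (dACC) and dorsal prefrontal cortex
(dPFC). Dynamic causal modeling (DCM) asks which *directed* couplings between
these regions are present, and which of them change strength when the
attentional demand of a blocked continuous-performance task switches between a
low (2-digit) and a high (3-digit) condition. The quantities of interest are
the entries of three coupling matrices in the bilinear neural state equation

$$\dot{x} = \Bigl(A + \sum_{j=1}^{2} u_j B^{(j)}\Bigr)x + Cu,$$

where $x$ is a six-vector of regional neuronal states, $u_1, u_2$ are the
low- and high-demand condition boxcars, $A$ (Hz) is demand-independent
(intrinsic) coupling, $B^{(j)}$ (Hz) is the demand-specific *contextual
modulation* of those couplings, and $C$ (Hz) is the driving efficacy of the
stimulus stream on the network's sensory entry point. Group questions — does a
clinical group (OCD) differ from controls (HC) in the intrinsic coupling of the
dorsal visual pathway, or in the demand-dependent modulation of the ascending
thalamus-to-prefrontal relay? — are answered by t-tests on subject-level
parameter estimates after Bayesian model averaging.

## The hypothesis space

The model space is generated by a `NetworkTemplate`. Eight intrinsic
connections are fixed in every model (V1→SPC, V1→Thal, SPC→Thal, SPC→BG,
Thal→BG, BG→Thal, BG→dPFC, dACC→BG). Four fronto-thalamic connections
(Thal→dPFC, dPFC→Thal, Thal→dACC, dACC→Thal) are permuted over three states —
absent, present, or present *and* contextually modulated by both demand
conditions — and dPFC→BG is permuted over two states (absent, or present and
modulated). The Cartesian product gives $3^4 \times 2 = 162$ architectures;
`enumerateModels()` orders them lexicographically (first permuted connection
most significant, ABSENT < PRESENT < PRESENT_MODULATED), so model ids are
stable across runs. A three-state reading of the permuted connections is the
only one consistent with the advertised count, and modulation is always joint
over both conditions: the low- and high-demand B masks are identical by
construction (`bMaskLow == bMaskHigh`), although their *values* are estimated
separately.

Driving input enters V1 only, on both condition inputs. The sensory entry
point of a visual stream is V1; the template accepts other driving targets
(`defaultTemplate(drivingTargets = ...)`) for sensitivity analyses.

## Forward model

Neural dynamics use the bilinear equation above with the diagonal of $A$ fixed
at $-0.5$ Hz (`selfDecay`). The group tables this package mirrors report only
inter-regional pathways, so self-connections are not estimated; a fixed decay
also bounds the system away from instability in most of the parameter range.
The observation stage is the balloon–Windkessel model per region: a
vasodilatory signal $s$, inflow $f$, venous volume $v$ and deoxyhemoglobin
$q$, with canonical constants $\kappa = 0.64$ Hz, $\gamma = 0.32$ Hz,
$\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$, $\epsilon = 1$,
held fixed during estimation. BOLD output is percent signal change,
$y = 100\,V_0\,(k_1(1-q) + k_2(1 - q/v) + k_3(1-v))$ with $k_1 = 7E_0$,
$k_2 = 2$, $k_3 = 2E_0 - 0.2$.

Three numerical choices matter:

* **Log-space hemodynamic states.** $f$, $v$ and $q$ are integrated as
  logarithms. The plain parameterization has no positive flow fixed point once
  sustained neural activity falls below $-\gamma$ (steady-state
  $f = 1 + x/\gamma$), and a fixed-step integrator then fails on a material
  fraction of plausible parameter draws. The log form solves the identical
  ODE while keeping the states positive by construction.
* **Joint integration.** `simulateBold()` and the inverter's prediction
  function advance the neural and hemodynamic states in one classical RK4
  pass over the joint 30-dimensional state. Integrating the hemodynamics
  against a stored, linearly interpolated neural trajectory would silently
  reduce the scheme to second order; the joint pass keeps fourth-order
  accuracy (halving the microtime step changes noiseless BOLD by well under
  $10^{-4}$ of its amplitude). The separate `integrateNeural()` and
  `hemodynamics()` stages remain available for analysis and testing (the
  neural stage is verified against a matrix-exponential stepper).
* **Sampling at volume onsets.** Scan $s$ samples the model at time
  $(s-1)\,\mathrm{TR}$, a time present on every microtime grid, so predictions
  do not depend on the microtime resolution. The microtime grid defaults to 16
  bins per TR ($dt = 0.1625$ s); inputs are piecewise constant over bins.

## Subject-level inversion

`invertModel()` implements variational Laplace under Gaussian priors:
zero-mean with variance $1/16$ for A and B entries and $1/4$ for C entries,
and a Gaussian prior (mean 0, variance 1) on the per-region log noise
precision. The free energy

$$F = \sum_r \Bigl[\tfrac{n}{2}(\lambda_r - \log 2\pi)
      - \tfrac{e^{\lambda_r}}{2}\bigl(\lVert e_r\rVert^2
      + \mathrm{tr}(J_r \Sigma J_r^\top)\bigr)\Bigr]
      - \mathrm{KL}\bigl(\mathcal{N}(\mu, \Sigma) \,\Vert\,
        \mathcal{N}(m_0, V_0)\bigr)$$

is the standard lower bound on log model evidence; the trace term is the
posterior-expectation correction to the log likelihood, and with it $F$ equals
the closed-form log marginal likelihood exactly in the conjugate
linear-Gaussian case (a property the tests exercise). Optimization alternates
a Gauss–Newton step on the posterior mean (Jacobian by central finite
differences, fixed $h = 10^{-4}$, computed in compiled code), the matched
covariance update, and an EM update of the noise precision. Two safeguards
keep the search honest:

* every accepted iteration is evaluated under its *own* fresh linearization —
  a step that looks good under a stale Jacobian but lowers the refreshed
  bound is rejected and retried at half the step length (Levenberg-style),
  so the recorded `fHistory` is non-decreasing by construction;
* candidate means are restricted to the dynamically stable region (spectral
  abscissa of $A_\mathrm{eff}$ and $A_\mathrm{eff} + B^{(j)}$ below
  $-10^{-3}$), where the model — and its finite-difference Jacobian — is
  defined.

Convergence is declared when an accepted iteration gains less than 0.01 nats
(default; `inversionSettings()`), with a 64-iteration cap. Initialization is
at the prior mean; the procedure is deterministic given the data and settings.

## Group level: model selection, averaging, statistics

`rfxBms()` is random-effects Bayesian model selection: the variational
Dirichlet fixed point over per-subject model frequencies (prior concentration
$\alpha_0 = 1$), with per-subject evidence recentring for overflow safety
(mathematically neutral). Exceedance probabilities are Monte-Carlo (default
$10^5$ seeded Dirichlet draws via independent Gamma variates).

`occamsWindow()` retains models whose expected probability is within odds
$1/20$ of the best model and renormalizes; `bmaAverage()` draws a model from
the window weights and, per subject, a parameter vector from that subject's
posterior under the drawn model, embedding it in the full parameterization
(13 intrinsic + 2×5 modulation + driving entries) with zeros for absent
parameters — 20,000 samples by default, with Monte-Carlo standard errors
reported. Window weights are computed per group and shared by that group's
subjects. The sampling mean is validated against the analytic mixture mean
$\sum_k w_k \mu_{nk}$ in the tests.

`buildStatsTable()` reports, per pathway and parameter class, group means and
SDs, one-sample t-tests per group, and the pooled-variance independent-samples
t-test between groups (all through `stats::t.test`). Two conventions are
explicit because the reported tables differ: intrinsic rows are signed HC−OCD,
modulation rows OCD−HC. Recomputing the published modulation comparisons from
their printed summaries under pooling reproduces the printed t-scores to
within the rounding of the inputs (e.g., −2.54 for the high-demand Thal→dPFC
row), which is what fixes the pooled (rather than Welch) form. Tests are
two-sided and flags use uncorrected p < 0.05, matching the reporting
convention of the tables; a Benjamini–Hochberg column is emitted alongside.

## The synthetic cohort generator

`generateCohort()` emulates the study conditions so the pipeline is testable
without imaging data: a blocked design of 120 s low- and high-demand epochs
with 20 s rests at TR 2.6 s (two cycles, 560 s, 215 complete volumes by
default; the 480-stimulus/25%-target arithmetic of each block is bookkeeping
only — epochs, not individual stimuli, drive the model); two groups (32 HC, 30
OCD) whose intrinsic and modulation parameters are drawn per pathway from the
published group means and between-subject SDs; driving efficacy
$\mathcal{N}(0.25, 0.05^2)$ Hz on V1 — the driving strength is not reported at
the group level, and 0.25 Hz both keeps typical draws inside the
hemodynamically valid regime (sustained $x > -\gamma$) and yields realistic
3–4% V1 block amplitudes. Scan noise is white Gaussian; by default its SD is
calibrated at generation time to the pooled SD of the noiseless BOLD of a
subject at the HC group means (global SNR ≈ 1) and recorded in the bundle
manifest. A subject whose sampled parameters destabilize the integrator is
re-simulated once with all couplings and drives halved; the few such subjects
are a consequence of drawing independent Gaussian pathway values at the
published SDs, which occasionally lands outside the stable region.

What the generator does *not* emulate: serially correlated or physiological
noise (scan noise is white, so tests say nothing about AR-noise robustness),
hemodynamic variability across regions or subjects (constants are canonical
and shared), scanner drift and motion (preprocessing concerns out of scope),
and any dependence between pathways in the truth (draws are independent).
Passing tests therefore demonstrate internal consistency of the estimation
machinery under the stated generative model, not performance on real fMRI.

## Problem sizes used in tests and the acceptance script

Full-scale inversion (10,044 subject-model fits) is a cluster job, not a test.
The test suite and `scripts/acceptance.R` run the complete pipeline at sizes
chosen to finish on one CPU while preserving every qualitative property:

* parameter recovery: one subject, 2 cycles (215 scans), default microtime,
  noiseless and SNR ≈ 1; recovery correlation over free A/B entries ≥ 0.8;
* model identification: a 4-model subspace, 8 + 8 subjects, 1 cycle, 8
  microtime bins, 10 seeded replicates; the generating model must take the
  top exceedance probability in ≥ 9/10;
* planted group difference: the Thal→dPFC modulation deficit at the published
  effect size (HC mean 0.25, OCD 0.00, SD 0.27), full group sizes (32/30), a
  2-model subspace, the full 2-cycle design at 4 microtime bins, 10 seeded
  replicates;
  detection (a significantly lower OCD modulation in at least one demand
  condition) is required in ≥ 8/10, and in ≤ 2/10 when no difference is
  planted;
* demonstration pipeline: 4-model subspace, 4 + 4 subjects, 1 cycle,
  end-to-end through the stats table.

The coarser microtime grids used in the cohort-level replicates (8 or 4 bins
per TR) change noiseless BOLD by far less than the scan noise — the joint
integrator is fourth order, so even 4 bins/TR (dt = 0.65 s) is within
0.003% signal of the converged solution — while cutting runtime
proportionally. Detection power at the published effect size needs the full
2-cycle run length; the low- and high-demand modulations are each informed by
their own epochs, and one epoch per condition is not enough.

## Known limitations

* The inverter estimates only A/B/C; hemodynamic parameters are fixed, so
  hemodynamic variability in real data would be absorbed into coupling
  estimates.
* Free energies are comparable across models for a fixed subject and design,
  but the bound is a Laplace-family approximation; no claim is made of
  numerical equality with other DCM implementations.
* BMA draws treat subjects as independent given the group-level window; no
  hierarchical (empirical-Bayes) shrinkage across subjects is performed.
* At SNR ≈ 1 the saturated 25-parameter architecture is only partially
  identifiable; posterior shrinkage toward zero is expected and intended
  behavior of the priors, and the recovery guarantees are stated for the
  sparser generating architectures described above.
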