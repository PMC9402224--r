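# tcdcm

Dynamic causal modeling (DCM) of a six-region thalamo-cortical attention
network: simulation, subject-level Bayesian inversion, random-effects model
selection, Occam's-window model averaging, and group statistics — with a
synthetic-cohort generator so the entire pipeline runs and is tested without
imaging data.

## The problem and who this is for

Blocked sustained-attention tasks (a continuous performance task with 2- vs
3-digit streams) engage V1, superior parietal cortex, thalamus, basal ganglia,
dorsal ACC and dorsal PFC. The scientific questions are *directed*: which
couplings between these regions exist, and which are modulated when attention
demand changes — in particular the ascending thalamus → prefrontal relay, and
whether a clinical group (OCD) differs from healthy controls. This package is
for researchers who want a self-contained, testable implementation of that
analysis chain: the bilinear neural model

    dx/dt = (A + u1·B1 + u2·B2) x + C u

observed through a balloon–Windkessel hemodynamic stage, a 162-model
hypothesis space over permuted fronto-thalamic connections (3⁴ × 2
architectures), variational-Laplace estimation of each model's parameters and
free energy per subject, random-effects Bayesian model selection (expected and
exceedance probabilities over a Dirichlet posterior on model frequencies),
Bayesian model averaging inside Occam's window, and one-sample /
independent-samples pooled t-tests on the averaged parameters.

## Worked example

A scaled-down end-to-end run: simulate a 4 + 4 subject cohort under the
blocked design (one 120 s low / 20 s rest / 120 s high / 20 s rest cycle),
fit a 4-model subspace, select models per group, average parameters in
Occam's window and produce the group statistics table.

```r
library(tcdcm)
tpl <- defaultTemplate()
length(enumerateModels(tpl))
#> [1] 162

cfg <- runConfig(
  simulate  = list(nHc = 4L, nOcd = 4L, nCycles = 1L, masterSeed = 42L),
  subspace  = c(1L, 81L, 141L, 162L),
  inversion = inversionSettings(maxIter = 32L),
  bmaSamples = 5000L, seed = 1L, outDir = "demo_out")
res <- runPipeline(cfg, tpl, verbose = FALSE)

res$plan$nJobs                      # (subject, model) inversions performed
#> [1] 32
round(exceedanceProb(res$bms$HC), 3)
#> [1] 0.061 0.129 0.253 0.557
res$window$HC$ids                   # models inside Occam's window (HC group)
#> [1]   1  81 141 162

stats <- res$stats
stats[stats$pathway == "Thal->dPFC",
      c("class", "hc_mean", "ocd_mean", "inter_t", "inter_p")]
#>              class hc_mean ocd_mean inter_t inter_p
#> 7        intrinsic   0.116   0.0183   0.912   0.397
#> 14  modulation-low   0.110   0.0935  -0.227   0.828
#> 19 modulation-high   0.013   0.0608   1.244   0.260
```

Reading the output: the exceedance probabilities are the posterior chance that
each fitted architecture is the most frequent in the (HC) population — here
the saturated model 162 leads at 0.56, unsurprising since this toy cohort is
generated from the saturated architecture with all four subspace models inside
Occam's window. The stats rows give, for the Thal→dPFC pathway, each group's
mean averaged parameter (Hz), the pooled two-sample t and its two-sided p —
intrinsic rows signed HC−OCD, modulation rows OCD−HC. At n = 4 + 4 nothing is
significant, as it should be; the planted-effect tests in the suite run the
full 32 + 30 group sizes.

`writeCohort()` / `readCohort()` serialize cohorts as TSV/JSON bundles,
`writeModelSpace()` the hypothesis space, and `writeResults()` the pipeline
artifacts; `inst/scripts/tcdcm.R` is a thin command-line driver
(`enumerate | simulate | plan | run`) over the same functions.

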