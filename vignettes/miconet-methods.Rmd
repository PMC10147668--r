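---
title: "Methods: community-level analysis of 16S compositions with miconet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-level analysis of 16S compositions with miconet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miconet)
```

## The problem and the model

16S rRNA gene surveys deliver sparse, overdispersed counts whose row sums
(sequencing depths) are arbitrary: only relative abundances carry
information. `miconet` treats the data accordingly — all analysis happens in
centered log-ratio (CLR) space — and asks a community-level question: which
*groups* of taxa co-occur across participants, and do those groups track
continuous clinical traits?

The working model is a weighted correlation network over taxa. Pearson
correlations of CLR abundances are soft-thresholded,
`a_ij = |r_ij|^beta`, which preserves the continuum of evidence instead of
imposing a hard cutoff, and pairwise similarity is measured by topological
overlap,

    t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
    l_ij = sum_u a_iu a_uj,   k_i = sum_{u != i} a_iu,

which scores two taxa as similar when they share network neighbours, not
merely when they are directly correlated. Modules are branches of the
average-linkage tree of `1 - t`; each module is summarized by its
*eigentaxon* (first principal component of the standardized member taxa), and
module-trait relationships are plain Pearson correlations between eigentaxa
and traits. The assumptions are those of the correlation network tradition:
approximately monotone taxon-taxon relationships on the CLR scale, samples
exchangeable (no longitudinal structure), and linear nuisance effects of the
covariates that are removed beforehand.

## Pipeline stages and the parameters that matter

**Sample QC.** A sample is removed when it concurrently fails the depth and
alpha-diversity thresholds (`depth_min = 10000` reads,
`shannon_min = 2.5` nats, rule `"and"`). Stool samples failing both are
sequencing failures rather than biology; either threshold alone (rule
`"or"`) is exposed but not the default, because moderate-depth samples still
carry usable compositional information. The Shannon index uses natural
logarithms; the base is configurable.

**Retain-resolve agglomeration.** ASVs are retained at full resolution when
prevalence > 50% *or* (mean relative abundance > 0.1% *and* prevalence >
10%); the remaining ASVs are summed to genus and the genus groups re-filtered
with the laxer 0.01% MRA branch. All inequalities are strict, following the
thresholds' wording; boundary taxa (exactly 50% prevalence) fail. The
two-branch rule is read as `A OR (B AND C)`: a taxon present in most samples
is kept regardless of abundance, which is the point of "retaining common"
ASVs. Grouping keys are full lineage prefixes, so homonymous genera in
different families are not merged; ASVs lacking a genus are grouped at their
deepest annotated rank and displayed with an `_NA` suffix
(e.g. `Lachnospiraceae_NA`). The `Other taxa` column carries
`depth - sum(final taxa)` per sample so that the final columns partition each
sample's depth exactly — integer conservation is asserted, and a negative
remainder is a hard failure. Prevalence and MRA are computed after sample QC,
and the per-taxon filter report records both values, the decision and the
branch that fired.

**CLR and covariate correction.** Counts get a pseudocount of 0.5 (the usual
Dirichlet-prior convention) before closure; the `Other taxa` column
participates in the geometric mean — that is its purpose — but is excluded
from the analysis matrix. Age and BMI effects are removed per taxon by
linear regression on the standardized covariates with empirical-Bayes slope
shrinkage: the shrinkage weight is `se^2 / (se^2 + tau^2)` where `tau^2` is
the across-taxa variance of the raw slopes in excess of their average
sampling variance. Shrinkage stabilizes slopes for noisy taxa while leaving
well-estimated slopes essentially untouched; `shrink = FALSE` reproduces
plain OLS residualization exactly and is tested against the normal-equations
oracle. Samples missing a covariate are mean-imputed for the design matrix
only, with a warning, and keep their trait values downstream.

**Network construction.** The soft-threshold power defaults to selection by
scale-free topology fit (smallest candidate with R-squared at least 0.8 and
negative slope; otherwise the best-fitting candidate, logged); a fixed
`beta = 3` reproduces the conventional choice for taxon networks of this
size. The network is unsigned by default — strong negative co-occurrence is
still co-structure — with the signed variant (`((1 + r)/2)^beta`) exposed.
Module detection is a deterministic static cut of the average-linkage tree
at `cut_height = 0.97` on the `1 - TOM` scale followed by the minimum module
size rule (10, 15 or 25 taxa; branches below it stay "unassigned"). This is
the deterministic core of the dynamic tree-cut family without its recursive
branch re-analysis: on the compressed TOM dissimilarity scale, genuine
modules complete well below 0.97 while noise merges concentrate just under
1.0, and determinism makes bootstrap results exactly reproducible. Modules
are named by size rank in the conventional colour order (turquoise, blue,
brown, ...). Merging joins modules whose eigentaxon correlation
dissimilarity falls below 0.25, iterating to stability; with well-separated
modules it is a no-op and labels are returned unchanged.

**Module statistics.** Eigentaxa are unit-variance and sign-oriented so the
average correlation with member taxa is non-negative: a participant rich in
the module's taxa has a high eigentaxon value. Hub taxa are those at or
above their module's 95th percentile of own-module membership
(linear-interpolation percentile, inclusive threshold, ties all kept, at
least one hub per module); the percentile is computed within each module
because hubs are module-level regulator candidates, with the across-all-taxa
variant exposed. Trait correlations use pairwise-complete observations with
the per-cell n recorded, Student-t p-values, and Benjamini-Hochberg
correction across taxa within each trait.

**Stability.** Bootstrap resampling is over participants — the observations
— never taxa. Each replicate rebuilds the network with the *same* beta and
minimum module size (re-selection per replicate is available via a flag but
conflates parameter uncertainty with cluster stability). Original modules
are matched to bootstrap modules by maximum Jaccard similarity (ties:
larger bootstrap module, then lexicographic label); a replicate without
modules contributes similarity zero, which penalizes — correctly — networks
whose modules vanish under resampling. Validity requires mean Jaccard
strictly above 0.5, the minimal requirement for a cluster to be
recognizably itself. The suite runs 100–200 replicates; a full analysis uses
1000 via `n_boot`.

**Associations and consensus.** The Dirichlet Monte-Carlo GLM draws
per-sample proportions from Dirichlet(counts + 0.5), CLR-transforms each
instance over the full closure, regresses each taxon on the standardized
trait, and averages slopes and p-values across instances (128 by default);
averaging p-values over posterior instances is deliberately conservative for
low-count taxa, whose evidence genuinely is weaker. The trait is
standardized so effect sizes read as CLR change per trait standard
deviation. Random-forest importance is out-of-bag permutation importance
(less biased than impurity for correlated compositional features), with a
25% holdout reporting predictive R-squared — which may be negative, and
typically is when taxa carry little marginal signal for the trait. The
consensus criterion is conjunctive on the network side (valid module,
module-trait p < 0.05, taxon significance p < 0.05 — each sub-criterion
switchable) and disjunctive across the secondary methods (GLM p < 0.05 or
importance rank <= 20).

## The synthetic-data generator

`simulate_dataset()` emulates the structure the pipeline is built for:
per-taxon baseline log abundances (background N(0, 1.5), half of them
shifted down 4 log units to mimic the rare tail; planted-module taxa at
N(2, 0.5), since a co-occurrence signal carried by taxa the filters would
drop could not have been observed); module latent factors N(0, 1) per sample
with loadings `module_factor_sd * U(0.85, 1.15)`; linear age/BMI effects on
a random 20% of taxa; per-taxon noise SDs `U(0.8, 1.6)` (real taxa differ in
dispersion); softmax closure; log-normal depths (median 30,000 reads); and
Dirichlet-multinomial counts with concentration 150. The GAD-7-like trait is
built from the first module's factor to hit a target correlation (default
-0.4, matching a moderate clinical effect); PHQ-9 tracks GAD-7 (comorbid),
DARS runs opposite (it is reverse-scored); two ages and eight DARS scores
are missing by default, mirroring realistic questionnaire missingness.
`module_factor_sd = 2` was calibrated once so the median within-module CLR
correlation exceeds 0.4, and high-SNR test fixtures use 2.5 with
`rare_fraction = 0`.

What the generator does *not* emulate: phylogenetic correlation between
related taxa, realistic taxonomy strings, batch effects, nonlinear covariate
action, or longitudinal sampling. Passing tests therefore demonstrate that
the machinery recovers planted structure of the stated kind at the stated
strength — not that any particular clinical dataset contains such structure.

One compositional subtlety is worth naming: because relative abundances must
sum to one, planting a strong positive co-occurrence module mechanically
induces weak negative correlations between its members and everything else
(and weak positive correlations among the background). This is real
compositional geometry, not a generator artifact; it is why the network is
built on filter-passing taxa with the full closure retained through the
`Other taxa` column, and why pseudocount-dominated rare taxa — whose CLR
values reflect the geometric mean rather than the taxon — must be filtered
before networking.

## Numerical choices

* Pseudocount 0.5 everywhere a log or a Dirichlet prior needs one.
* Correlation p-values use the Student transform
  `t = r sqrt((n-2)/(1-r^2))`, floored at the smallest positive double.
* Eigentaxon computation is a thin SVD of the standardized module block;
  sign fixed by the mean-member-correlation rule; a module needs >= 2
  non-constant taxa.
* The scale-free fit bins connectivity into 10 equal-width bins and
  regresses log10 frequency on log10 mean connectivity over occupied bins;
  fewer than two occupied bins or all-equal connectivities are errors.
* Static cut height 0.97, minimum module sizes 10/15/25, merge height 0.25.
* Taxa that become constant inside a bootstrap replicate are dropped from
  that replicate only.
* Hard edge-export thresholds are strict (`r > 0.35`, `r > 0.2`).
* All stochastic stages take explicit seeds, restore the caller's RNG state,
  and the pipeline manifest records every parameter, so a run can be
  replayed byte-for-byte from the manifest alone.

## Problem sizes used by the test suite

The suite exercises the study-shaped scale without its full cost: planted
fixtures use 200 samples x 300 ASVs (three modules of 25), trait-recovery
checks 400 samples over ten seeds, stability 200 bootstrap replicates
(scaled from the 1000 a full analysis would use), the GLM null calibration
1000 taxa x 178 samples at depth 100,000 with 64 Monte-Carlo instances, and
the end-to-end determinism check a 60-sample pipeline replayed from its
manifest. These sizes are the package's own choice of a thorough but
routine-to-run suite.

## Known limitations

* Module detection is a static-height cut: on dissimilarity scales where
  genuine modules complete above the cut height (very weak signal, very few
  samples), modules will be missed rather than mis-split; lower
  `cut_height` or smaller `min_module_size` are then the right levers.
* The empirical-Bayes correction assumes linear covariate effects and a
  unimodal slope distribution across taxa.
* Averaged Monte-Carlo p-values are conservative for rare taxa; this is
  inherited deliberately from the Dirichlet Monte-Carlo tradition.
* Consensus membership inherits every upstream threshold; it is a screening
  device for candidate taxa, not an error-controlled discovery set.
* No block-wise approximation is implemented: the design point is the
  few-hundred-taxon scale that retain-resolve agglomeration produces.
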