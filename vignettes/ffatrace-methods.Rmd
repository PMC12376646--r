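---
title: "Models and methods in ffatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ffatrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffatrace)
```

This vignette is the package's account of its science: the measurement and
mixture models, the estimation machinery, the choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
establish about real data.

## The measurement model

An FFA with C carbons is observed as C+1 isotopologue intensities
`I_M0..I_MC`. Two processes put ¹³C into a molecule: deliberate tracer
incorporation during synthesis, and natural abundance (~1.07 % of all
carbon). The package treats these sequentially.

**Natural-abundance correction** inverts the binomial convolution
`M[j, i] = choose(C - i, j - i) p¹³^(j-i) (1 - p¹³)^(C-j)`, the probability
that a molecule with i tracer carbons is observed at shift j. The system is
lower-triangular, so noiseless data are solved exactly by forward
substitution; when measurement noise drives the direct solution negative the
solver falls back to non-negative least squares, and a relative residual
above 5 % raises a correction failure. The correction is carbon-only: at the
resolving power typical of Orbitrap FFA panels, ¹³C isotopologues are
separated from ²H/¹⁷O/¹⁸O fine structure, so only carbon needs
deconvolution. `p13` defaults to 0.0107 and is exposed everywhere. The
labeled intensity `Σ i·I_Mi` is only defined on corrected vectors — on raw
data it would double-count natural ¹³C — and the package refuses to compute
it otherwise.

**Detection.** An FFA counts as isotopically labeled when some M+i (i ≥ 1)
has a labeled fraction strictly above 0.005 in strictly more than half of
the samples. Both inequalities are strict because the rule is phrased as
exceedances; the thresholds are arguments (`detection_threshold`,
`detection_min_fraction`) with those defaults.

## The synthesis model

Fatty-acid synthesis appends 2-carbon acetyl-CoA units. With unit labeling
simplex x = (x₀, x₁, x₂), a chain of n units has mass-shift distribution
equal to the n-fold convolution of x — the multinomial sum over all (m, n₁)
with 2m + n₁ = i of `multinomial(n; m, n₁) x₂^m x₁^{n₁} x₀^{n-m-n₁}`. The
convolution form is used because it is exact, O(n²), and makes mass balance
(ΣD = 1) structural rather than incidental. Routes compose this primitive:

* de novo: C/2 units (myristate 7, palmitate 8);
* elongation: the de novo C16 distribution convolved with one unit per step
  (`E_i = D_i x₀ + D_{i-1} x₁ + D_{i-2} x₂`); one widely circulated printed
  form of this recursion ends in `D_{i-2} x₀`, which violates mass balance —
  the package deliberately uses x₂;
* desaturation: the precursor's pattern unchanged (a double bond shifts no
  carbon mass), so FFA(16:1) shares palmitate's model;
* essential elongation: PUFAs elongate an unlabeled dietary precursor, so
  only appended units carry label.

The default route table assigns the 13-species panel accordingly and is
config-overridable.

**Fitting g(t).** The observed MID is modeled as
`(1 - g) δ₀ + g D_route(x)`: a pre-existing fully unlabeled pool plus newly
synthesized molecules. This two-pool simplification deliberately collapses a
full synthesis/elongation/desaturation flux network onto the single
parameter per species that downstream analyses use; the acetyl simplex is
fitted freely per (tissue, species) since sharing it across species is an
assumption the data need not satisfy. Estimation is bounded least squares
(L-BFGS-B) over g and a stick-breaking parameterization of the simplex
(x₁ = u₁, x₂ = (1 − u₁)u₂ with u ∈ [0,1]²; smooth and exactly covering the
simplex), from 8 deterministic lattice starts. Ties break to the lowest SSE,
then the lowest g, so results are reproducible without a stochastic global
optimizer. A fit is converged when a start reaches the shared minimum with a
clean optimizer status or the SSE is below the 1e-10 tolerance floor (the
line search legitimately aborts on exactly flat objectives at perfect fits).
Observations whose labeling extent falls below `detection_floor` (default
0.005) pin g to 0 with a flag rather than fitting noise.

**Pseudo rates.** g is a fraction of a tissue-specific pool, so comparing g
across tissues ignores pool size. Mean total intensities per species are
min–max rescaled to [0, 1] across tissues and multiply g. Two consequences
are intentional and documented rather than corrected: the tissue at the
per-species minimum gets factor 0 (its rate is reported as 0, not missing),
and when all tissues tie the factor is 1 with a warning. The rates remain
relative; absolute flux would need absolute pool quantification.

**Known bias.** The two-pool model attributes all labeled molecules to
in-situ synthesis. In tissues that also take up labeled FFAs from serum, the
fitted g is inflated by that uptake — which is why the output is called a
*pseudo* rate. The package's tests assert this direction of bias explicitly
on synthetic data (fitted g exceeds the generator's g exactly in tissues
given nonzero uptake).

## Crosstalk analytics

**Similarity.** `1 / (1 + Σ_{i=1..C} |L_a,i − L_serum,i|)` over labeled
channels only; M0 is excluded by the summation bounds so that two tissues
differing only in overall labeling extent are still distinguished from
tissues differing in pattern. The score is symmetric and in (0, 1], equal to
1 exactly on identical labeled fractions. Replicates are summarized by the
median (robust to one aberrant animal); donor screening combines a
labeling-extent criterion (tissue mean ≥ serum mean within 5 % relative
tolerance — at exchange equilibrium the extents converge) with a similarity
threshold (default 0.8). Both thresholds are configuration, not constants,
because the underlying principles are qualitative.

**Deconvolution.** For palmitate, the tissue's labeled fractions
(normalized to sum 1 over i = 1..C) are fitted as
`α D_i/ΣD + β U_i`, where D is the de novo multinomial at a fitted acetyl
simplex and U is the serum's normalized labeled pattern (mean across serum
replicates). α + β is not constrained to 1: both component patterns are
normalized, so a well-specified fit lands near α + β = 1 on its own, and the
reported composition is the renormalized pair — leaving the constraint off
keeps lack-of-fit visible in the raw coefficients rather than hidden by the
constraint. Observed MIDs are normalized before fitting so that the SSE
compares shapes, not labeling magnitudes. For stearate, the synthesis
pattern is the tissue's palmitate distribution convolved with one acetyl
unit taken from the same tissue's palmitate fit, and only α, β are free.

**Identifiability.** The split is meaningless when serum uptake and in-situ
synthesis produce the same labeled pattern. The flag is computed by profile
SSE: the fit is marked non-identifiable when a pure-uptake model and a
pure-synthesis model each fit essentially as well as the joint model (within
`identifiability_tol² / C`, default tol 0.02 on the Manhattan scale). A
check based only on the distance between U and D at the jointly fitted x
fails precisely in the degenerate case it should catch, because on the ridge
the optimizer may return α ≈ 0 with an arbitrary simplex. Note one structural
consequence: for the donor tissue itself (serum is its export), the two
patterns coincide up to noise and the flag fires by design; per-replicate
noise can leave it marginally unset, so donor-tissue compositions should
never be interpreted regardless of the flag.

**Permutation test.** The statistic is the Manhattan distance between group
mean labeled fractions, matching the similarity score's geometry; the exact
test statistic behind published MID comparisons is typically unstated, and
this choice keeps one distance underlying both analyses. The p-value uses
the add-one estimator `(1 + #{perm ≥ obs}) / (1 + n_perm)`, so p is never 0
and the test is valid (if minutely conservative). Label permutations are
drawn under a caller-supplied seed with the global RNG state preserved.

## The synthetic-data generator

`simulation_config()` encodes the emulated study: 15 tissues + serum, 13
labeled FFA species (C14–C24, 0–5 double bonds), timepoints 0/6/24 h with
n = 4 at baseline and n = 6 after refeeding. Noiseless tissue MIDs are
three-way mixtures of an unlabeled pool, the route MID at tissue-specific
acetyl labeling, and the serum pool weighted by an uptake fraction β; serum
is the liver's synthesis-only MID (configurable donor), matching a
liver-dominated circulating pool. g at 6 h is 0.6× its 24 h value except in
adipose tissues, which plateau early. Intensities are scaled per
(tissue, species), forward-convolved with natural abundance, and perturbed
by independent multiplicative log-normal noise (CV 0.02 by default —
log-normal because LC–MS technical variance is dominantly multiplicative;
no replicate-level variance estimates exist to fit, so the level is a stated
default, not an inference). Default parameter magnitudes follow the
emulated biology: g ≈ 0.2–0.4 for the actively synthesized SFA/MUFA species
in lipogenic tissues, < 0.1 for PUFAs, brain favoring palmitate and C20
PUFAs, and the lung the largest serum uptake.

What passing tests therefore show: the estimators recover the parameters of
this generative family — including under its noise, natural abundance, and
serum coupling — and the pipeline's algebra is correct. What they do not
show: robustness to chromatographic artifacts, peak-detection errors,
ion-suppression structure, inter-animal biological variance beyond
log-normal intensity noise, or route misspecification (e.g. an FFA labeled
through a pathway not in the route table). Those belong to the upstream
peak-extraction tools and to study design.

The aging scenario multiplies g per tissue (default: peripheral ×0.6, brain
×1.0). One subtlety the tests document: for a brain species with tiny
synthesis and nonzero uptake (FFA(16:1), g ≈ 0.02, β = 0.02), a third of the
fitted g is uptake-carried serum signal, which declines with the liver
donor; its fitted old/young ratio is therefore genuinely ≈ 0.9, between the
configured decline and full sparing. Brain sparing is recovered within
±0.05 where synthesis dominates the signal (palmitate).

## Problem sizes and determinism

The test suite and the acceptance script use: 100 random simplex draws
against the exhaustive 3⁸ enumeration oracle; the full 13-species panel for
natural-abundance round trips; 200 simulations per condition (n = 6
replicates, CV 2 %) for synthesis-fraction and deconvolution recovery,
fitting the mean corrected MID per simulation; 1000 null simulations at
n_perm = 999 for permutation calibration; and a 6-tissue, 2-species panel
through the full pipeline for the aging contrast. These sizes give stable
RMSE and rate estimates while keeping a complete run in minutes on one CPU.
All randomness flows from explicit seeds; identical configs and seeds give
byte-identical simulated data.

## Interfaces

The package is an R-level pipeline: `read_isotopologue_table()` validates
the long-format dialect with row-level diagnostics, `run_pipeline()` chains
every stage and writes CSV tables, a YAML config echo and a JSON-lines log,
and every tunable above is a `pipeline_config()` field. A thin Rscript
wrapper (`inst/scripts/run_pipeline.R`) exposes the same run to the shell;
there is deliberately no heavier CLI layer, since the intended users work in
R and every subcommand-sized step is an exported function.

## Limitations

Beyond the pseudo-rate and donor-degeneracy caveats above: the correction
ignores isotopic fine structure (adequate only at high resolving power);
double-bond positions are not resolved, so desaturation routes are assigned
by species identity; esterified lipid transport is out of scope — the model
sees only free fatty acids; and compositions for non-identifiable fits are
reported but must be treated as undetermined.
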