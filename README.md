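# ffatrace

Analysis of in vivo ¹³C stable-isotope tracing of free fatty acid (FFA)
metabolism. Given long-format LC–MS isotopologue intensity tables — one row
per (sample, tissue, timepoint, FFA species, isotopologue M+i, intensity) —
`ffatrace` quantifies where fatty acids are made, how fast, and how they move
between tissues through the circulating serum pool. It is written for
metabolomics researchers running [U-¹³C]-glucose (or similar) tracer studies
across multiple tissues, and ships a ground-truth synthetic-data generator
that emulates a 15-tissue + serum mouse refeeding study, so every stage of
the pipeline is testable against known parameters.

## The model

For an FFA with C carbons, the measured intensities `I_M0..I_MC` are first
corrected for natural ¹³C abundance (carbon-only binomial matrix
deconvolution, p₁₃ = 0.0107 by default) and normalized to a mass
isotopologue distribution (MID) `L_M0..L_MC`. Elementary quantities:

* labeled intensity `I_13C = Σᵢ i·I_Mi` (labeled-carbon-weighted),
* labeling extent `LE = 1 − L_M0` (molecule-level),
* ¹³C enrichment `Σᵢ i·L_Mi / C` (atom-level),
* an FFA counts as labeled when some M+i (i ≥ 1) exceeds 0.005 in more than
  50 % of samples.

**Synthesis fitting.** A chain built de novo from n acetyl-CoA units whose
labeling simplex is x = (x₀, x₁, x₂) has the multinomial mass-shift
distribution `D = (x₀, x₁, x₂)^{*n}` (n-fold convolution); elongation adds
one unit per step, desaturation leaves the pattern unchanged, and PUFAs
elongate an unlabeled essential precursor. The observed MID is modeled as a
two-pool mixture `(1 − g)·δ₀ + g·D_route(x)` and the newly synthesized
fraction g(t) plus x are estimated by bounded multi-start least squares.
Multiplying g by a per-species min–max pool-size factor across tissues gives
the pseudo relative biosynthesis rate.

**Crosstalk.** Tissue–serum MID similarity is scored as
`1 / (1 + Σ_{i≥1} |L_tissue,i − L_serum,i|)`; donor tissues must match serum
in labeling extent and MID shape. For palmitate, the labeled pattern is
deconvolved into de novo synthesis vs serum uptake,
`M_i = α·D_i/ΣD + β·U_i`, and for stearate into elongation of the tissue's
palmitate vs uptake, with the reported composition `(α, β)/(α + β)`. Group
MID differences are tested by Monte Carlo permutation on the Manhattan
statistic.

## Worked example

```r
library(ffatrace)

fix <- worked_fixture()   # liver, lung, cortex + serum; 3 species; n = 4; 24 h
cfg <- pipeline_config(input = fix$data, n_perm = 999, seed = 1,
                       route_table = fix$config$route_table,
                       tissues = c(fix$config$tissues, "serum"))
res <- run_pipeline(cfg)
res$pseudo_rates
#>   tissue species   g_mean     g_sd pinned factor pseudo_rate
#> 1 cortex FFA(16:0) 0.132  0.00468  FALSE   0          0
#> 4 liver  FFA(16:0) 0.316  0.00187  FALSE   1          0.316
#> 7 lung   FFA(16:0) 0.339  0.00555  FALSE   0.576      0.195
res$donor_screen[, c("tissue", "species", "le_tissue", "le_serum",
                     "median_similarity", "verdict")]
#>   tissue species   le_tissue le_serum median_similarity verdict
#> 1 cortex FFA(16:0)    0.109     0.292             0.834 not-donor-consistent
#> 4 liver  FFA(16:0)    0.298     0.292             0.984 donor-consistent
```

Reading the output: ~32 % of liver palmitate is newly synthesized over the
24 h labeling window (the generator's ground truth is g = 0.315); the lung's
higher apparent g (0.339) includes serum uptake — the documented inflation of
a *pseudo* rate. The liver matches serum in both labeling extent
(0.298 vs 0.292) and MID shape (similarity 0.984, the maximum across
tissues), identifying it as the serum donor, while the cortex, with a far
lower labeling extent, is not donor-consistent. `res$deconvolution` then
splits each tissue's labeled palmitate into synthesis vs uptake fractions.

Real data are read with `read_isotopologue_table()`; a shell entry point for
full runs is `inst/scripts/run_pipeline.R`.

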