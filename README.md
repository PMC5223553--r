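# mdinet

Molecular-formula annotation and mass difference network analysis for
direct-infusion ultrahigh-resolution (FT-ICR) mass-spectrometry
metabolomics, plus the companion assay statistics of a viral-latency
reactivation study: a Poisson limiting-dilution frequency estimator and
2^−ΔCt expression-ratio helpers.

## Who this is for

Direct-infusion FT-ICR-MS produces one spectrum per sample with sub-ppm
mass accuracy and no chromatographic separation: every downstream
conclusion rests on exact-mass arithmetic. `mdinet` is for analysts who
have per-sample peak lists (m/z, intensity, optional S/N) and want a
reproducible, tested path from those lists to annotated molecular
formulas, regulated-metabolite sets, and chemical interpretation — without
vendor black boxes. The package also ships a ground-truthed metabolome
simulator, so the entire pipeline is testable end to end.

## The core methods

**Formula assignment.** A deprotonated ion at measured m/z implies a
neutral monoisotopic mass m. All formulas on the grid
C₁₋₁₀₀H₀₋₂₀₀O₀₋₇₀N₀₋₂₀S₀₋₃P₀₋₃ with |Δm/m| ≤ 0.5 ppm are enumerated and
filtered by the Senior rules (integer, non-negative double-bond
equivalents DBE = 1 + Σcᵢ(vᵢ−2)/2; even valence sum) and elemental-ratio
plausibility (H/C, O/C, N/C, S/C, P/C ranges plus O ≥ 4·P and N > 6 ⇒
O ≥ N). Candidates are validated against the ¹³C isotopologue: expected
M+1 intensity n_C·(1.07/98.93) at +1.00335 Da. Features without isotope
evidence receive formulas by breadth-first propagation through the mass
difference network from validated seeds; features the network never
reaches fall back to the best mass-only candidate.

**Mass difference networks (MDiN) and enrichment (MDEA).** Nodes are
assigned formulas; an edge of type r connects two nodes whose element-wise
difference equals a reaction-equivalent mass difference (REMD, e.g. CH₂,
H₂O, HPO₃ — a curated library of ~57 ships in-package, a 490-entry user
library drops in). For each REMD, with N edges total, n hit edges (both —
or optionally any — endpoints regulated), K edges of that REMD and a hits
among them, MDEA reports the one-sided Fisher/hypergeometric p,

    Z = (a − Kn/N) / sqrt( Kn/N · (N−K)/N · (N−n)/(N−1) ),

and Benjamini–Hochberg q-values.

**Limiting-dilution reactivation frequency.** Wells with c cells at
producer frequency f are CPE-positive with probability 1 − e^(−fc); at
f·c = 1 that is 1 − 1/e = 63.2%. The crossing estimator interpolates the
complementary-log-log-transformed positive fractions against log c and
inverts f = 1/c*; the maximum-likelihood estimator fits all dilutions
jointly with a profile-likelihood CI. Frequencies normalize to viral
genomic load with the untreated control anchored at 1.

## Worked example

Simulate the emulated study design (4 groups × 3 mice: control, acute
infection, latent infection + carbon-nanoparticle second hit, particles
only; 300 metabolites, 100 ppb mass error, planted phospholipid
up-regulation and glycolysis down-regulation in the infected groups) and
run the full pipeline:

```r
library(mdinet)
res <- run_pipeline(run_config(simulate = sim_config(seed = 1),
                               out_dir = "run1"))
res$assignments
#> <formula_assignments> 418 features: 167 isotope-validated,
#>   106 network-propagated, 0 unassigned
head(res$classes, 3)
#>              class up down unchanged total        p
#> 1 sugar_glycolysis  0   11         9    20 1.97e-05
#> 2       fatty_acid  1    7        96   104 5.59e-03
#> 3       amino_acid  0    1        31    32 3.82e-02
subset(res$score_tests, component == "PC1")
#>   component      group1      group2     t        p  dataset
#> 1       PC1     control virus_acute 28.78 8.67e-06 virus_np
#> 2       PC1     control    virus_np 25.19 1.48e-05 virus_np
#> 3       PC1 virus_acute    virus_np  2.34 7.93e-02 virus_np
```

Of 418 aligned, replicate-filtered features, 167 are isotope-confirmed and
106 network-propagated (the rest are recognized ¹³C peaks); the planted
glycolysis down-regulation is the top class signal (Fisher p ≈ 2e-5), and
PC1 separates both infected groups from control (Student t, p < 2e-5)
while acute infection and the second-hit group are not separable from each
other — the "restored acute signature" pattern the design plants.

The reactivation assay, at a true frequency of 1 producing cell in 200:

```r
set.seed(1)
s <- simulate_dilution_series(1/200)   # threefold from 1000 cells, 24 wells
ld_frequency_mle(s)
#> <frequency_estimate> f = 0.005926 (1 in 168.8 cells), mle [ok],
#>   95% CI 0.004249-0.008126
ld_frequency_crossing(s)
#> <frequency_estimate> f = 0.005452 (1 in 183.4 cells), crossing [ok],
#>   95% CI 0.004249-0.008126
```

Both estimators recover the planted frequency within the CI.

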