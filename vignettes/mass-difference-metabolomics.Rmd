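---
title: "Formula annotation and mass difference networks for direct-infusion FT-ICR-MS metabolomics"
author: "mdinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula annotation and mass difference networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Direct-infusion Fourier-transform ion cyclotron resonance mass spectrometry
(FT-ICR-MS) resolves thousands of metabolite ions by exact mass alone — no
chromatography, one spectrum per sample. At a resolution around 430,000 and
sub-ppm mass accuracy, the measured mass of a singly deprotonated ion
[M−H]⁻ carries enough information to propose a molecular formula, and the
analysis pipeline becomes a chain of mass-arithmetic problems:

1. filter picked peaks by signal-to-noise and the recorded mass window,
2. recalibrate each spectrum linearly against a reference list of masses
   that occur in essentially every biological sample,
3. align peaks across samples into consensus features at a 1 ppm window,
4. discard features never observed in a complete replicate group,
5. assign molecular formulas combinatorially at ±0.5 ppm, validated by the
   Senior rules, elemental-ratio plausibility and the ¹³C isotopologue
   pattern, then propagate formulas through a mass-difference network to
   the low-abundance peaks that lack isotope evidence,
6. normalize, scale, and compare groups by PCA and per-feature tests,
7. interpret regulated metabolites chemically through mass difference
   enrichment analysis (MDEA) and compound-class summaries.

`mdinet` implements this chain as composable functions plus a
`run_pipeline()` orchestrator, together with a Poisson limiting-dilution
estimator for viral reactivation assays and 2^−ΔCt expression helpers used
in the same experimental context (murine gammaherpesvirus latency and its
reactivation by nanoparticle exposure), and a ground-truthed simulator that
makes every stage testable without instrument data.

# Formula algebra and validity

A formula is a bag of atom counts over C, H, O, N, S, P with IUPAC
monoisotopic masses fixed to ≥9 significant digits in `element_table()`.
Ion arithmetic assumes [M−H]⁻ exclusively (negative electrospray), with the
proton mass 1.007276466 Da; other adducts and charge states are out of
scope.

**Senior rules** (`senior_check()`): a formula can describe a connected
closed-shell molecule only if the double-bond equivalents
DBE = 1 + Σ cᵢ(vᵢ − 2)/2 are a non-negative integer and the total valence
sum is even. Valences are the lowest common organic ones (C=4, H=1, O=2,
N=3, S=2, P=3) and are configurable; with trivalent P, phosphate esters
such as C₆H₁₃O₉P come out at integer DBE, which is the convention that
keeps the whole biological search space Senior-valid.

**Elemental-ratio screen** (`ratio_check()`): candidate formulas must fall
inside heuristic biomolecule ranges, by default 0.2 ≤ H/C ≤ 3.1, O/C ≤ 1.2,
N/C ≤ 1.3, S/C ≤ 0.8, P/C ≤ 0.3. Two heteroatom relationships are enforced
on top, both standard practice in exact-mass formula filtering and both
config-exposed: phosphorus occurs in metabolites in phosphate-like moieties
(O ≥ 4·P), and nitrogen counts beyond purine/peptide chemistry come with
oxygen (N > 6 requires O ≥ N). These two rules are load-bearing: the
CHNOSP grid contains near-exact mass doublets — e.g. replacing C₂H₁₂O₁₀ by
N₁₄ changes the mass by ~0.02 ppm — that no realistic mass accuracy can
separate. Mass alone ties C₃₃H₆₅O₁₀P to C₃₁H₅₃N₁₄P; chemistry does not.

**Isotopologues**: the M+1 intensity is modeled first-order as n_C·r(¹³C)
with r = 1.07/98.93, at an exact mass shift of 1.0033548 Da ("infinite
resolution": the isotopologue is a point mass, no peak-shape convolution).
³⁴S on the M+2 channel is available but unused by default.

# Spectra processing

* `sn_filter()`: retains S/N ≥ 4 (boundary inclusive) inside 129–1000 m/z.
  Peaks without an S/N value pass — the cutoff belongs to vendor peak
  picking, which is the package's input boundary.
* `calibrate()`: pairs each reference mass with its nearest peak within
  2 ppm (wider than the aligned 1 ppm window because pre-calibration errors
  exceed it), fits reference ~ observed by least squares, applies
  `slope·mz + offset`, reports the residual sd in ppb and accepts the fit
  below 100 ppb. Fewer than 4 matched references is an error, mirroring
  calibration on at least 4 reference clusters.
* `align()`: greedy single-linkage over the pooled m/z-sorted peaks. A peak
  joins the open cluster while within 1 ppm of the running
  intensity-weighted mean; a same-sample collision keeps the peak nearer
  the mean (ties to the higher intensity) and the loser spawns its own
  feature. Whether the original alignment tool used running means or fixed
  anchors is not recorded anywhere we could consult; the greedy centroid
  rule is this package's documented choice, and the suite validates it
  against an exhaustive pairwise-clustering oracle and permutation
  invariance, not against the original tool.
* `triplicate_filter()`: a feature survives only if non-zero in every
  member of at least one replicate group. This is the main noise gate: in
  simulations it removes essentially every uniform-random noise peak,
  because random m/z do not reproduce within 1 ppm across three spectra.
* `iqr_euclidean_normalize()`: per sample, the Euclidean norm of the
  non-zero intensities lying inside the closed interval [Q1, Q3] of that
  sample's non-zero intensity distribution becomes the size factor.
  Quantiles use the linear-interpolation convention (R type 7), fixed so
  that the worked example — column (3, 4, 5, 100, 0), in-IQR set {4, 5},
  divisor √41 — is reproducible. The normalization is exactly invariant to
  positive per-sample rescaling (bit-exact for power-of-two factors).

# Formula assignment

`enumerate_candidates()` searches the grid C₁₋₁₀₀H₀₋₂₀₀O₀₋₇₀N₀₋₂₀S₀₋₃P₀₋₃
at ±0.5 ppm. The loops run over S, P, N with cumulative-mass pruning; for
each branch the O×C plane is evaluated as a matrix and H is solved from the
mass residual — the tolerance is four orders of magnitude below one
hydrogen mass, so at most one H count fits per grid point. The test suite
holds this search to exact set equality with a naive full-grid oracle. The
H range 0–200 is wide enough to cover anything the other bounds admit
below 1000 Da.

`assign_formulas()` runs a three-stage cascade:

1. **Isotope-confirmed.** For features with a measured M+1 partner (a
   feature within 1 ppm of the expected isotopologue position, detected in
   at least one sample where the parent is), candidates compatible with the
   observed ratio (within ±50% by default) are scored by
   (ppm/0.1)² + n·(mean log ratio/0.05)², combining the mass deviation with
   the isotopologue evidence over the n samples where it was measured. The
   scales are the typical mass accuracy (100 ppb) and isotopologue-ratio
   repeatability (5%) of this instrument class. The isotope term is what
   separates near-isobaric candidates two carbons apart (a 6% ratio
   difference) that are indistinguishable by mass.
2. **Network propagation.** Confirmed formulas seed a breadth-first
   expansion over the REMD library: an unassigned feature within ±0.5 ppm
   of seed ± REMD acquires the corresponding formula if it stays on the
   grid and passes Senior and ratio checks. Conflicts resolve by smallest
   |ppm|, then shortest depth, then lexicographic formula; depth is capped
   at 10 to bound error accumulation. Propagation runs at the assignment
   tolerance, not the 1 ppm alignment window — it asserts chemistry, not
   peak identity. This stage is what gives the low-abundance majority of
   features (whose isotopologue patterns are unobservable) biochemically
   consistent formulas instead of mass-only guesses.
3. **Default validation.** Features the network never reaches fall back to
   their best mass-only candidate when the expected M+1 intensity is below
   the dataset noise level (`noise_level()` = the minimum over samples of
   the per-sample maximum intensity); an observable-but-absent pattern
   leaves the feature unassigned.

A feature recognized as the M+1 partner of a confirmed formula is marked
`isotopologue` and excluded from assignment and from the network — it is a
measurement of its parent, not a metabolite.

# Mass difference networks and enrichment

`build_mdin()` connects two formulas by an undirected edge whenever their
element-wise difference equals a reaction-equivalent mass difference
(REMD) exactly. The in-repo library holds ~57 curated building blocks
(CH₂, H₂, O, H₂O, CO₂, NH₃, acetyl, monosaccharide and amino-acid
residues, HPO₃, SO₃, fatty-acyl units, ...); a user file replaces it, and
every report records which library was used. The edge search hashes
node+delta against the node set and is held to equality with an all-pairs
oracle in the tests.

`select_nodes_of_interest()` labels features by log2 fold change of group
means (zeros imputed with half the feature's minimum positive intensity)
and a Welch t-test: up if log2FC ≥ log2(1.5) and p < 0.05, symmetric for
down. The equal-variance Student test is used for the PC-score group
comparisons (matching the original analysis); Welch is deliberately the
default for per-feature work where variances differ.

`mdea()` tests each REMD for association with the nodes of interest. With
N edges, n hits, K edges of one REMD and a hit edges among them, the
one-sided enrichment p is the hypergeometric upper tail (Fisher's exact
test) and Z = (a − Kn/N)/√(Kn/N·(N−K)/N·(N−n)/(N−1)). A hit edge has both
endpoints of interest by default (`mode = "both"`, the stricter reading:
an edge built *between* regulated metabolites); `mode = "any"` counts
edges built *from* a regulated metabolite and is the more powerful choice
when the labeled set is small relative to the class it samples, e.g. at
n = 3 replicates. Benjamini–Hochberg q-values are reported alongside the
raw p and Z. Up and down sets can be tested separately or jointly.

# Multivariate comparison

Feature-wise Z-transformation (mean 0, sd 1, n−1 denominator) precedes PCA
by singular value decomposition of the centered samples×features matrix —
deterministic, with the sign of each component fixed by making its
largest-magnitude loading positive. The study design splits the data into
one dataset per second-hit exposure, each containing {second-hit group,
time-matched controls, acute infection group}; scaling and PCA run per
dataset, after splitting. Student t-tests compare the first three PC
scores between groups. `loading_correlation()` compares metabotypes across
datasets by Pearson correlation over shared features, reporting the
orientation maximizing |r| (PCA signs are arbitrary) with the flip
flagged; its p-values are uniform under independent loadings, which the
suite verifies by KS test.

# Limiting dilution and expression ratios

Under the single-hit Poisson model a well containing c cells at producer
frequency f is positive with probability 1 − e^(−fc); at fc = 1 this is
1 − 1/e = 63.2%, the crossing the assay reads out. `ld_frequency_crossing()`
locates the 63.2% crossing by linear interpolation of the
complementary-log-log-transformed positive fractions against log c — the
scale on which the model is exactly linear with slope 1 — and inverts
f = 1/c*. Saturated (all-positive) and empty (all-negative) series return
flagged boundary estimates. `ld_frequency_mle()` maximizes the full
binomial likelihood over f with a 95% profile-likelihood CI (χ²₁ cutoff
3.84); at the assay's plate design (threefold dilutions from 1000
cells/well, 24 wells per dilution) its median bias is under 1% in 1000
simulations at f = 1/200. Both estimators are exposed because the original
readout rule (interpolation vs joint fit) is not recorded; the crossing CI
is taken from the same likelihood and widened to contain the point
estimate when the two disagree. A freeze–thaw background series is handled
as a second `dilution_series` compared at reporting time, never inside the
likelihood. `normalize_reactivation()` rescales frequencies by viral
genomic load with the untreated control anchored at 1.

`relative_expression_ddct()` implements 2^−ΔCt against a reference gene;
`expression_ratio()` forms per-sample lytic/latency gene ratios (the
reference cancels) anchored to a control-group mean of 1; and
`overlap_filter()` applies the "at least 1.5-fold against every control
group" rule as a generic table operation with an inclusive boundary.

# The simulator: what it emulates and what it does not

`simulate_metabolome()` draws a metabolome of 300 formulas (default) from
a built-in table of ~314 curated entries in five classes
(glycerophospholipid, fatty-acid, sugar/glycolysis, amino-acid,
nucleotide/cofactor homologous series), all Senior- and ratio-valid, on
the assignment grid, inside the 129–1000 m/z window, and ≥3 ppm apart so
features are uniquely resolvable at the 1 ppm alignment window. Study
conditions mirror the emulated design: 4 groups × 3 replicates (control,
acute infection, latent infection + particle second hit, particle only),
Gaussian mass error of 100 ppb, per-sample linear calibration drift,
¹³C isotopologue peaks with 5% lognormal ratio noise, 150 uniform-random
noise peaks per sample drawn from the lower quartile of true intensities,
10% independent missingness, and planted multiplicative effects:
glycerophospholipids +1.5 log2 and glycolysis-type metabolites −1 log2 in
the acute and second-hit groups. Intensities are lognormal (base sd 1 log
unit between metabolites, 0.3 between replicates) because no intensity
model is published for this design; both are parameters, not claims.

What passing tests show: the pipeline recovers ≥99% of detected true
formulas, assigns essentially no noise peaks, flags planted class effects,
and detects a planted REMD. What they do not show: robustness to
correlated missingness, electrospray matrix effects, isotopic fine
structure, multiply charged ions, or adducts other than [M−H]⁻ — none of
which the simulator emulates.

# Numerical choices and known limitations

* Quantile convention type 7, closed IQR interval; alignment ties resolved
  toward higher intensity; PCA sign convention as above; BH across REMDs.
* Per-sample norm-based normalization is compositional: planting +1.5 log2
  on a third of all features drags every sample norm up, so unaffected
  features acquire apparent negative fold changes (~−0.7 log2 at the
  default composition) and some cross the −1.5-fold threshold. The down
  label set therefore mixes truly down-regulated metabolites with
  compositional artifacts; the up set is clean in simulations. This is a
  property of the normalization, not a bug, and it is why the planted
  up-class is verified against the up label set.
* The validate-by-default rule for unobservable isotope patterns means an
  isolated featureless peak with any grid-valid candidate gets a formula:
  on unfiltered random m/z about half acquire one. The replicate filter is
  what makes this safe in practice; datasets without replicate structure
  should treat stage-3 assignments with suspicion.
* The N > 6 ⇒ O ≥ N heteroatom rule would reject exotic polyamine-like
  formulas (e.g. large N-rich, O-free molecules); relax
  `ratio_bounds(n_needs_o_above = Inf)` when such chemistry is expected.
* Problem sizes used throughout the suite: 300-formula metabolomes,
  12 samples, ~1100 aligned features, 50-mass enumeration oracles, 1000
  simulation replicates for the estimator calibrations — sizes at which
  every stage's behavior is measurable in minutes on one CPU.

# Reproducing a full run

```{r}
library(mdinet)
cfg <- run_config(simulate = sim_config(seed = 1), out_dir = "run1")
res <- run_pipeline(cfg)
res$assignments$summary
head(res$enrichment)
res$score_tests
```

Every run writes its stage outputs, a JSON manifest with parameters,
seeds, per-stage record counts and file checksums into `out_dir`; the same
config and seed reproduce the run byte-identically.
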