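---
title: "Models and methods behind xlinkquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xlinkquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkquant)
```

`xlinkquant` covers three quantitative analyses that together make up the
in-silico tail of a photo-cross-linking interactome study: label-free
enrichment classification from MaxQuant-style protein-group tables, one-site
ITC binding analysis, and peak-level colocalization summaries. This vignette
explains the underlying models, the parameters that matter, the numerical
choices, and what the accompanying synthetic-data generators do and do not
emulate.

## 1. Enrichment classification

### The model

The experiment compares paired +UV and −UV pulldowns, two biological
replicates each. Input is a proteinGroups-style table of per-sample iBAQ
intensities. After contaminant/decoy removal and shared-peptide grouping,
quantification proceeds on **riBAQ**, the compositional form of iBAQ: a
group's iBAQ divided by the summed iBAQ of the groups retained for that
sample. riBAQ removes between-run loading differences — multiplying every
intensity of one run by a constant leaves all downstream quantities
unchanged (this invariance is tested).

Two rules shape the analysis:

* **Presence rule.** A group counts as present in a condition only when its
  iBAQ is strictly positive in *every* replicate of that condition. The
  riBAQ denominator for a sample runs over the groups present in that
  sample's condition, so every riBAQ column sums to exactly 1 and no
  pseudocounts are ever needed where logarithms are taken.
* **Exclusivity rule.** A group is an exclusive +UV candidate when it is
  present (both replicates) in +UV *and* has zero intensity in every −UV
  replicate; symmetrically for −UV. Requiring all-zero on the opposite side
  is deliberately stricter than merely failing the presence rule: a protein
  seen once in −UV is weak evidence of absence, not of exclusivity.

These two rules leave a small third class: groups present in one condition
with partial (one-of-two) detection in the other. They are neither exclusive
nor testable (a t-test needs positive values on both sides), so they are
reported as `common_ns` with `NA` fold and p-value. The category partition
is therefore exhaustive, and the Venn identity
`n_exclusive_plus + n_exclusive_minus + n_common = n_analyzed` always holds.

Common groups get a linear fold enrichment, the ratio of arithmetic
condition means of riBAQ, and a two-sided two-sample t-test on log2 riBAQ.
The default thresholds — p ≤ 0.05 on the raw p-value and fold ≥ 2 — mirror
standard practice for this assay type; both are exposed
(`p_threshold`, `fc_threshold`), as is an off-by-default Benjamini–Hochberg
option (`p_adjust = "BH"`). "Fold about 2" is implemented as a hard cutoff
at 2.0 because a soft threshold is not operational.

### Why Student's t, not Welch

With only two replicates per condition the choice of t-test matters more
than usual. Welch's unequal-variance test estimates its degrees of freedom
from the data; with n = 2 per group the Satterthwaite estimate collapses
toward 1 whenever the two sample variances differ by chance, and the
resulting heavy-tailed null reference costs roughly a third of the power at
a fixed true effect (in the spike-in benchmark below, mean sensitivity drops
from ≈ 0.87 to ≈ 0.56). The pooled-variance Student test is exact under the
log-normal noise model (log2 riBAQ is Gaussian) and is the default; Welch
remains available via `test = "welch"` for designs with more replicates or
genuinely heteroscedastic conditions. The log2 transform itself
(`log_transform = TRUE`) stabilizes the multiplicative replicate noise;
testing raw riBAQ is possible but not recommended.

### Shared-peptide grouping

Two entries are linked when they share a fraction of peptides strictly
greater than `share_threshold` (default 0.30, so exactly 30 % does not
merge), and groups are the connected components of that graph — single
linkage, i.e. transitive closure. "Fraction of their peptides" is ambiguous
for sets of unequal size; the default denominator is the smaller set
(`rule = "min_set"`), which merges fragment/isoform entries whose peptides
are a subset of a larger entry — the usual intent of parsimony-style
grouping — with Jaccard as the conservative alternative. Merged groups pool
the union of peptides and, by default, the per-sample sum of member
intensities (`combine = "sum"`; `"representative"` keeps the top member's
values instead). The representative is the member with the largest total
iBAQ, ties broken lexicographically, and group output is sorted by pooled
total iBAQ, making results independent of input row order. The
implementation is verified against a brute-force oracle (all-pairs fraction
matrix, repeated merging to a fixpoint) on randomized instances.

## 2. One-site ITC model

### Forward model

The titration protocol defaults to the common bromodomain setup: a 200 µl
perfusion cell at 15 °C, one initial 0.4 µl injection followed by 18
injections of 2 µl, syringe peptide at 1.6 mM (the studied experiments used
1.5–1.8 mM) titrated into protein at 90 µM (80–100 µM); all are
configurable in `itc_protocol()`. In a perfusion cell each injection expels
cell volume, and the standard correction

$$M_t = M_0\,\frac{1 - dV/2V_0}{1 + dV/2V_0},\qquad
  X_t = X_0\,\frac{dV/V_0}{1 + dV/2V_0}$$

(with cumulative injected volume $dV$) is used rather than the exponential
dilution alternative, for fidelity to the perfusion-cell instrument family.
The bound fraction solves one-site mass action:

$$\Theta = \tfrac12\Bigl[\,b - \sqrt{b^2 - 4r}\,\Bigr],\quad
  b = 1 + r + \frac{K_D}{N M_t},\quad r = \frac{X_t}{N M_t}$$

whose discriminant is provably non-negative for $K_D > 0$ (asserted, and
cross-checked against a bisection solver in the tests). Cell heat content is
$Q_i = N\,\Theta_i\,M_{t,i}\,\Delta H\,V_0$; the measured injection heat
adds the displaced-volume term
$\Delta Q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i+Q_{i-1})/2$ and a constant
dilution offset per mole of injectant. Units are µM, µl, µcal and kcal/mol
throughout (kcal, not kJ, following bromodomain ITC convention). Measurement
noise is Gaussian on the raw heats with user-set σ (µcal); 0.5 µcal is a
realistic per-injection figure for a modern low-volume calorimeter.

### Fitting

`fit_one_site()` minimizes the sum of squared molar-heat residuals over
(N, K_D, ΔH, offset) with bounded Levenberg–Marquardt (minpack.lm), bounds
N ∈ [0.1, 10] and K_D ∈ [10⁻³, 10⁵] µM. The first injection is excluded
from the residuals, so the fit is provably invariant to its recorded value
(tested by perturbation). Without an initial guess the fit self-initializes
from the isotherm shape — ΔH from the early-minus-late plateau difference,
offset from the final plateau, N from the molar ratio at half amplitude,
K_D from the transition steepness via the Wiseman c-parameter — and falls
back to a three-point multi-start over c if the first attempt does not
converge; the weak-binding regime (K_D well above the cell concentration)
is shallow and genuinely ill-conditioned, which is why the bounds and
multi-start exist. Convergence uses relative-SSE and parameter-step
tolerances (1e-14 / 1e-12); isotherms whose amplitude is below 3× the
estimated noise are refused as "flat" rather than fitted to nothing.
Standard errors come from the local quadratic approximation
$\sigma^2 (J^\top J)^{-1}$ with a central-difference Jacobian evaluated at
the solution. Derived quantities are $\Delta G = RT\ln K_D$ (reference
state 1 M, R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹) and $-T\Delta S = \Delta G -
\Delta H$.

Noise-free simulate-then-fit round trips recover parameters to better than
0.1 % relative across K_D from 5 to 300 µM even from ±30 %-perturbed
starting values; at 0.5 µcal noise a single 18-injection titration
determines a 25 µM K_D with a sampling SD of roughly 6 µM (median across
realizations unbiased) — a useful reminder that single-titration K_D values
carry real uncertainty.

## 3. Peak colocalization

Coordinates are 0-based half-open (BED convention) at every interface;
1-based GRanges objects exist only inside the interval machinery. The
overlap predicate is ≥ 1 bp intersection with no reciprocal-fraction
requirement, the anchor/other distinction is explicit (overlap fractions
are asymmetric), and the other set is merged internally so pre-merging it
cannot change results. Peak-level three-set Venn counts are inherently
anchor-dependent — one anchor peak can overlap several peaks of another
set — so `venn3()` reports all three anchor perspectives instead of
pretending a unique 7-region diagram exists.

TSS-anchored matrices use a ±5 kb window at 50 bp bins by default (±3 kb is
the same operation with `flank = 3000`). Window bins take the bp-weighted
mean of the underlying track bins, windows running off a chromosome end are
zero-padded and flagged, minus-strand rows are column-reversed so column 1
is always 5′-most, and rows are sorted by descending row mean with a stable
sort (ties keep input order). Track correlations are computed on the
concatenated genome-wide bin vectors; zero-variance tracks yield `NA` with
a warning rather than a silent 0/0.

## 4. What the generators emulate — and what they do not

`simulate_proteomics()` draws baseline abundances from a log-normal
(meanlog 16, sdlog 1.5 — a realistic 3-decade dynamic range for a pulldown),
multiplies true interactors by the enrichment factor (default 8×, a typical
covalent-capture enrichment) in +UV samples only, applies log-normal
replicate noise at CV 25 % (default; typical for label-free iBAQ across
biological replicates), and then zeroes observations with logistic
probability in log abundance (midpoint three baseline SDs below the mean,
slope 1 — a few percent overall missingness concentrated in the low tail,
applied after the condition effect so exclusivity can arise both by
construction and stochastically). Exclusive binders are forced to zero in
−UV; contaminants and decoys carry flags; a 5 % fraction of background
proteins is paired into shared-peptide families exceeding the 30 %
threshold. Two replicates per condition is the default, matching the ±UV
design the pipeline targets. All generators are pure functions of
(configuration, seed) and restore the caller's RNG state.

What this deliberately does **not** model: correlated contaminant profiles,
intensity-dependent variance beyond the log-normal, peptide-level
missingness, ratio compression, or chromatographic batch effects. Passing
the spike-in benchmark therefore demonstrates that the statistical machinery
is correct and well calibrated under its stated assumptions — not that real
cross-linking data will behave this nicely. One real effect the generator
*does* reproduce is compositional closure: spiking 50 of 850 proteins at 8×
inflates the +UV riBAQ denominator by ~40 %, so unenriched background
appears mildly depleted. This is a property of any relative quantification
and the reason the depleted class should be interpreted cautiously when a
large enriched fraction is expected.

`simulate_peaks()` draws a latent site list and includes each site in each
peak set with a per-set inclusion probability, so the expected overlap
fraction of set A against set B equals B's inclusion probability when no
private peaks are added; tracks are rectangular bumps plus Gaussian bin
noise. It does not model read-level sampling, fragment-size effects or peak
callers.

## 5. Benchmark conditions and numerical conventions

The test suite and `scripts/acceptance.R` exercise the pipeline at fixed,
package-chosen sizes: 100 random generator configurations for riBAQ
compositionality (tolerance 1e-9 on column sums); 100 random ≤ 15-protein
instances against the grouping oracle; 1000 background proteins for null
calibration (enriched-call rate compared to 0.05 plus three binomial
standard errors); 20 seeds of 800 background + 50 true interactors at
8×/CV 25 % for spike-in recovery (mean sensitivity ≥ 0.8, mean FDP ≤ 0.1
for the exclusive ∪ enriched call set); K_D ∈ {5, 25, 100, 300} µM
noise-free round trips at 0.1 % relative tolerance plus 50 noisy titrations
(median K_D within 15 %); 50 random peak-set triples and 20 random tracks
against quadratic/per-bp oracles; and byte-identical re-runs of every CLI
subcommand. The whole suite runs in under two minutes on one core.

Other conventions: peptide identifiers compare as exact case-sensitive
strings; entries flagged both contaminant and reverse are removed once,
counted under "reverse"; iBAQ values are written at full double precision
(`%.17g`) so write/read round trips are exact; all output tables are
timestamp-free and the run manifest echoes the full configuration, making
pipeline outputs byte-reproducible.

## 6. Known limitations

* Two replicates per condition is the floor the design allows; with n = 2
  the per-group variance estimate is noisy and power at p ≤ 0.05 is
  limited. Moderated-variance approaches (limma-style shrinkage) would help
  and are natural future work, but are deliberately out of scope for a
  faithful implementation of the raw per-group t-test procedure.
* Raw p-values are used by default (no multiplicity correction), matching
  the procedure this package implements; the BH option changes the
  operating characteristics substantially on large tables.
* The ITC module fits integrated injection heats; thermogram baseline
  integration, competitive and multi-site models are out of scope.
* Peak-level Venn counts depend on the anchor; there is no single "number
  of shared peaks" without fixing a perspective, which the interfaces make
  explicit rather than hiding.
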