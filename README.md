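# xlinkquant

Quantitative post-processing for photo-cross-linking (±UV) interactome
experiments, with companion tools for one-site ITC binding analysis and
genomic peak colocalization.

## The problem

Genetically encoded photo-cross-linkers (e.g. 4-azido-L-phenylalanine placed
in a bromodomain binding pocket) covalently trap transient binding partners
under 365 nm UV. A pulldown of the bait followed by label-free LC-MS/MS then
yields a `proteinGroups.txt`-style table of iBAQ intensities for paired
UV-irradiated (+UV) and untreated (−UV) samples. True partners should be
present, or enriched, only in +UV. `xlinkquant` implements the analysis
chain downstream of MaxQuant:

1. **Read & filter** — parse the tab-separated proteinGroups dialect,
   replace default protein names/symbols from a user map, remove entries
   flagged "Potential contaminant" or "Reverse" (entries flagged only
   "identified by site" are retained).
2. **Group** — merge proteins that share more than 30 % of their peptides
   (fraction of the smaller set by default; Jaccard optional), transitively.
3. **Normalize** — riBAQ: each group's iBAQ divided by the summed iBAQ of
   all groups retained for that sample, under the rule that a group counts
   as present in a condition only when detected in *every* replicate of
   that condition. Each sample's riBAQ column sums to 1.
4. **Classify** — groups detected in both +UV replicates and absent from
   every −UV replicate are *exclusive* candidates (and vice versa); groups
   present in both conditions get a fold enrichment (ratio of condition
   means) and a two-sided t-test on log2 riBAQ. Common groups with
   p ≤ 0.05 and fold ≥ 2 are called *enriched*.

The companion modules cover the two orthogonal quantitative analyses of such
a study. The **ITC module** simulates and fits the one-site (Wiseman)
binding isotherm in a perfusion cell: after injection *i* with cumulative
volume *dV*,

    Mt = M0 (1 − dV/2V0) / (1 + dV/2V0),   Xt = X0 (dV/V0) / (1 + dV/2V0)

the bound fraction Θ is the physical root of the mass-action quadratic

    Θ = ½ [ 1 + r + Kd/(N·Mt) − sqrt( (1 + r + Kd/(N·Mt))² − 4r ) ],
    r = Xt/(N·Mt)

and the cell heat content is Q = N·Θ·Mt·ΔH·V0. Injection heats include the
displaced-volume correction; the initial small injection is discarded at fit
time. A bounded Levenberg–Marquardt fit recovers N, K_D, ΔH and a constant
dilution offset; ΔG = RT·ln(K_D) and −TΔS = ΔG − ΔH follow. The
**colocalization module** computes peak-level overlap fractions, anchored
three-set Venn classifications, TSS-anchored tornado/metagene matrices
(±5 kb by default) and binned-signal correlations from BED/bedGraph input.

Seeded generators (`simulate_proteomics()`, `simulate_isotherm()`,
`simulate_peaks()`) emulate the statistical structure of each input —
log-normal abundances, spiked interactors, abundance-dependent dropout,
shared-peptide families, Gaussian injection-heat noise, latent colocalized
peak sites — with ground-truth labels, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(xlinkquant)

sim <- simulate_proteomics(n_background = 300, n_true_interactors = 25,
                           n_exclusive_plus = 10, n_contaminants = 5,
                           n_decoys = 5, seed = 7)
kept    <- filter_entries(sim$entries)$kept
groups  <- group_proteins(kept)                      # >30% shared peptides
ribaq   <- compute_ribaq(groups, sim$design)         # per-sample riBAQ
records <- classify_enrichment(ribaq, sim$design)    # p <= 0.05, fold >= 2
venn_counts(records)
#> # A tibble: 1 × 4
#>   n_exclusive_plus n_exclusive_minus n_common n_common_enriched
#>              <int>             <int>    <int>             <int>
#> 1               10                 0      318                20
```

All 10 simulated exclusive binders are recovered exactly, and 20 of the 25
spiked 8×-enriched interactors pass the common-enriched call at these noise
settings (the remainder fall below the p ≤ 0.05 threshold for this seed).
`plot_volcano(records)` draws the corresponding volcano plot.

Fitting a simulated bromodomain-affinity titration (K_D 24.6 µM, ΔH
−8 kcal/mol, 0.5 µcal heat noise, 0.4 µl + 18 × 2 µl protocol at 15 °C):

```r
iso <- simulate_isotherm(one_site_params(N = 1, kd = 24.6, dH = -8),
                         itc_protocol(), noise_sd = 0.5, seed = 7)
fit <- fit_one_site(iso)
fit
#> One-site ITC fit
#>   N      = 0.999
#>   Kd     = 16.3 uM
#>   dH     = -7.401 kcal/mol
#>   offset = -0.0307 kcal/mol
#>   dG     = -6.313 kcal/mol, -TdS = 1.088 kcal/mol
#>   SSE    = 0.3399, converged: TRUE
```

At this noise level a single titration determines K_D only to within a few
µM (the reported standard error for this fit is ±3.5 µM; across noise
realizations the median fitted K_D is unbiased). `tidy(fit)` and
`glance(fit)` return the parameters broom-style; `autoplot(fit)` overlays
the fitted isotherm on the data.

## Command line

A thin CLI over the same functions ships in `inst/cli/xlinkquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "xlinkquant.R", package = "xlinkquant"))')" \
  enrich --protein-groups proteinGroups.txt --design design.tsv \
  --out-dir out --p 0.05 --fc 2.0 --share 0.30
```

Subcommands: `simulate`, `enrich`, `itc`, `coloc`. Outputs are
deterministic given `--seed` and the configuration.
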