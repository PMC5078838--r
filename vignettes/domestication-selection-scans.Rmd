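---
title: "Domestication selection scans: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domestication selection scans: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan scans a candidate gene set for signatures of selection across a
domestication contrast: an ancestral (wild) population and a descendant
(landrace) population resequenced over the same loci. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the design decisions taken where the methodology was genuinely
open.

## The scan in one paragraph

For every gene we estimate within-population diversity (θπ, Watterson's θω,
Tajima's D) and between-population differentiation (Hudson's F~ST~), rank each
gene's descendant-population statistics against an empirical background
distribution, and call **purifying** selection where diversity sits in the
lower 5% tail, F~ST~ above the 95th percentile and Tajima's D is negative, or
**balancing** selection where diversity sits in the upper 25%, Tajima's D in
the upper 5% and F~ST~ in the 10–90% mid-band. Sites are classified
analogously at base-pair resolution and annotated by codon effect. Coding
genes get pairwise K~a~:K~s~ by NG86 and an approximate MYN-style estimator.
Called genes are validated with HKA-family polymorphism/divergence tests
against a neutral panel, and summarised as minimum-spanning haplotype
networks stratified by sample metadata.

## Diversity statistics and missing data

θπ is the mean over sample pairs of per-pair differences divided by per-pair
comparable sites (**pairwise deletion**): a site enters a pair's comparison
only when both sequences have a called base, and each pair is normalised by
its own comparable length. This preserves information in modest panels
(tens of haplotypes) where complete deletion would discard many columns.
θω = S/(a₁L) with a₁ = Σ₁ⁿ⁻¹ 1/i, S the count of sites with at least two
distinct called bases and L the count of sites with at least two called
bases. Tajima's D uses the standard constants (a₁, a₂, b₁, b₂, c₁, c₂, e₁,
e₂); the mean pairwise difference count Π is the pairwise-deletion per-site
diversity scaled by L, keeping D consistent with θπ under missing data. A
monomorphic alignment (S = 0) has an undefined D, rendered `NA`.

F~ST~ is Hudson's 1 − H~w~/H~b~ with H~w~ the unweighted mean of the two
within-population diversities and H~b~ the mean cross-population pairwise
difference per site (d~xy~). When H~b~ = 0 the statistic is defined as 0.
Negative estimates are reported as computed, not clamped, because the
classifier consumes *ranks* and clamping would create artificial ties.
Per-site diversity is the unbiased heterozygosity (n/(n−1))(1 − Σp²) over
called bases, and the per-site F~ST~ aggregates back to the regional value
exactly (summing numerators and denominators) on complete data.

## K~a~:K~s~ estimation

**NG86.** Each codon position contributes its fraction of synonymous changes
among viable (non-stop-producing) single-nucleotide changes, averaged over
the two sequences, so synonymous + nonsynonymous sites always total three
per codon. Codons differing at k > 1 positions average the syn/nonsyn step
classification over all k! mutational orderings, skipping orderings that
pass through a stop codon (if every ordering does, all are used). The
proportions are Jukes–Cantor corrected, d = −¾ log(1 − 4p/3); p ≥ ¾
saturates and the distance is `NA`, as is the ratio whenever K~s~ = 0.
Codons containing `N` or a gap in either sequence are dropped from both,
matching the pairwise-deletion policy.

**MYN-style.** The approximate method models distinct purine (κ_R) and
pyrimidine (κ_Y) transition rates. Differences are pathway-averaged as in
NG86 but resolved into purine-transition, pyrimidine-transition and
transversion steps; site counts weight each possible change by its class
rate. Distances use an equal-frequency Tamura–Nei-form three-class
correction with observed difference fractions P₁ (purine ts), P₂
(pyrimidine ts) and Q (tv):

d = −¼ [ log(1 − 4P₁ − Q) + log(1 − 4P₂ − Q) + log(1 − 2Q) ],

which reduces to Kimura's two-parameter formula when P₁ = P₂ = P/2. The
rate components recovered from the same inversion (α₁t, α₂t, βt) re-estimate
κ_R = α₁t/βt and κ_Y = α₂t/βt, which feed back into the site weighting;
the loop runs until successive (K~a~, K~s~) change by less than 1e-8 (at
most 100 iterations). Saturated configurations return a flagged
(`converged = FALSE`) result rather than an error. Where the published
protocol leaves sub-choices open, agreement with NG86 in the symmetric
limit (κ = 1, uniform composition) is the acceptance authority; the test
suite verifies both estimators against exhaustive codon-neighbour and
pathway enumeration, and against simulation truth across ω ∈ {0.2, 1, 3}.
Significance of K~a~ ≠ K~s~ is a two-sided Fisher exact test on the rounded
difference/site 2×2 table. Population-level columns average per-pair K~a~
and K~s~ over all within-group (or cross-group) sequence pairs and report
the ratio of the means — a per-pair ratio is undefined whenever that pair
has K~s~ = 0, so averaging the rates first is the stable choice (recorded
in the output's `scheme` attribute).

## Empirical-quantile classification

Percentiles use inclusive ranks — 100 × (#values ≤ x)/N, ties taking the
higher rank — which is deterministic and conservative in the lower tail.
The thresholds (5/95 for purifying, 75/95/10/90 for balancing) are the
published criteria and are configurable via `scan_thresholds()`. An
undefined descendant Tajima's D (an invariant gene) *satisfies* the
negative-D clause of the purifying rule: complete sweeps produce exactly
this pattern, and the published calls include invariant purifying genes.
The site-level rules compare each site's diversity change (descendant −
ancestral) against the mean per-gene change magnitude of the background,
require per-site F~ST~ > 0, and take the D sign clause at gene level, since
a per-site Tajima's D is not meaningful.

The background universe is configurable: the analysed gene set itself
(self-inclusive ranking) or a genome-wide surrogate. The published
thresholds were derived from genome-wide empirical distributions, and a
quantile clause evaluated against a small self-inclusive universe that is
itself rich in selected genes cannot call more than the tail fraction of
genes by construction; the recovery experiments therefore rank against the
dataset's neutral panel, which plays the genome's role.

Sweep extent is delimited by extending 10-kb windows (configurable) from
the focal purifying gene while window descendant diversity stays below the
genome lower-5% quantile; the method is this package's own, since published
sweep spans rarely state one.

## HKA-family validation

`classic_hka()` moment-fits per-locus θ and a divergence time τ from
E[S] = θ a₁(n) L and E[D] = θL(τ + 1) (the +1 carries the expected
ancestral coalescence) and sums standardised squared deviations with
Var[S] = E[S] + a₂(θL)² and Var[D] = E[D] + (θL)², referred to χ² with
2k − (k + 1) degrees of freedom.

The mlHKA-style test substitutes bounded maximum likelihood with a
**Poisson observation model** for the original MCMC machinery:
S ~ Poisson(k·θ·a₁·L) and D ~ Poisson(θL(τ+1)), with the selection
parameter k free at designated loci and 1 elsewhere. Per-locus nuisance
parameters are profiled in closed form, so the optimisation is
one-dimensional in τ (run from multiple deterministic starts); the LRT uses
df = number of selected loci. This keeps the likelihood-ratio logic of the
original test with deterministic desk-scale behaviour. The trade-off is
stated openly: the Poisson model ignores the coalescent overdispersion of
S, so each test is calibrated under its own null — classic HKA on
coalescent-simulated panels (S Poisson-mixed over the coalescent tree
length, D over an Exp(1) ancestral time, which reproduces exactly the
moment variances above), the likelihood test on panels from its own
Poisson model. Divergence D is counted between the outgroup sequence and
the within-species majority consensus, with polymorphic sites still counted
in S, avoiding double counting.

## Haplotype networks

Alignment columns containing any `N` or gap are removed *before* collapsing
(complete deletion — unlike the pairwise deletion used for diversity),
because haplotype identity must be transitive. The network is a Kruskal
minimum spanning tree over Hamming distances with deterministic
tie-breaking (ascending distance, then lexicographic haplotype id), plus
every non-tree edge whose length equals the maximum edge on the tree path
between its endpoints, flagged as an alternative link — a minimum spanning
network. Node compositions are stratified by genotype group, geography or
race from the metadata table.

## The synthetic-data generator

The generator is first-class, tested code: a forward discrete-generation
Wright–Fisher simulation of 2N haplotypes with infinite-sites mutation
(codon genes use a finite-sites codon model with back-mutation), chosen
over a coalescent so that selection regimes can be imposed as explicit,
exact frequency manipulations. Defaults emulate a 44-genotype sorghum-like
panel:

| parameter | default | meaning |
|---|---|---|
| `n_ancestral` / `n_descendant` | 14 / 36 | sampled wild / landrace haplotypes |
| `effective_size_ancestral` | 50 diploids | 2N = 100 haplotypes simulated |
| `per_site_mutation_rate` | 1.5e-5 | gives θ = 4Nμ = 0.003/site, a sorghum-scale diversity |
| `bottleneck_fraction` / `bottleneck_duration` | 0.1 / 8 | domestication bottleneck (see below) |
| `post_bottleneck_generations` | 10 | recovery before sampling |
| `burn_in_factor` | 8 | burn-in of 8·2N generations to mutation–drift equilibrium |
| `outgroup_divergence_time` | 400 | generations before sampling at which the outgroup lineage splits |
| `gene_length` | 1500 bp | multiple of 3 so codon genes stay in frame |

The bottleneck was calibrated once, against replicate simulations, so that
mean descendant diversity is reduced ≈1.7-fold — the genome-wide
domestication figure for this system; fraction 0.1 for 8 generations plus
recovery measured 1.72-fold over 400 neutral replicate genes. Note the
reduction is *not* simply exp(−t/N~b~): new post-split mutations add back
≈2μt of diversity, which the calibration accounts for. The outgroup is a
lineage snapshot taken from the ancestral population at the split time and
evolved independently, so shared ancestry of mutations is exact and the
divergence truth is well defined. The demographic parameters of sorghum
domestication are nowhere published as such; these defaults are tuning
knobs pinned to the observable (the 1.7-fold reduction), not estimates.

**Selection regimes are phenomenological**, because the scan detects
signatures, not fitness, and explicit manipulation keeps truth labels
exact:

* **purifying** — a post-bottleneck selective sweep: one haplotype rises to
  `sweep_completeness` (default 1) of the descendant sample. The swept
  haplotype is the most divergent standing haplotype plus
  `sweep_extra_divergence` (default 0.004/site) of private hitchhiking
  divergence. This matters: a sweep onto a random common haplotype is
  statistically indistinguishable from the bottleneck drift every neutral
  gene experiences, and would not produce the elevated F~ST~ that defines
  this signature class; directional selection during domestication
  characteristically fixes a previously rare allele together with linked
  variation.
* **balancing** — the two most divergent ancestral haplotype classes are
  maintained at intermediate frequency (`balancing_freq`, default 0.5) in
  the descendant sample, sampled from the ancestral population so
  within-class variation is retained, with `balancing_extra_divergence`
  (default 0.004/site) of class-private divergence modelling a balanced
  polymorphism whose coalescence predates the neutral TMRCA — the
  rare-in-wild, intermediate-in-landrace pattern that produces large
  diversity *increases* under domestication.
* **positive** — the gene is simulated as a codon sequence; the descendant
  lineage fixes substitutions drawn under ω = `positive_omega` (default 3)
  with the same event-count codon model used by `simulate_codon_pair()`.

What the generator does **not** emulate: recombination within genes,
missing data and genotyping error, diploid heterozygous calls, population
structure beyond the two-population contrast, gene flow, and selection via
actual fitness differences. Passing recovery tests therefore demonstrates
that the pipeline's statistics and decision rules behave correctly on data
matching its assumptions — not that real resequencing panels will yield the
same sensitivity, where linked selection, structure and missingness all
blur the signatures.

The balancing mid-band F~ST~ clause filters genuine balanced loci whose
differentiation is low; gene-level balancing sensitivity in the recovery
experiments is accordingly modest (~0.3) while purifying sensitivity
exceeds 0.9 at a neutral false-positive rate below 5%. That asymmetry
mirrors the published scan, which called an order of magnitude fewer
balancing than site-level purifying signatures.

## Numerical choices and conventions

* Coordinates are 1-based inclusive externally (GFF convention), 0-based
  half-open internally, converted at one boundary.
* Heterozygous VCF genotypes resolve to the first-listed allele with a
  warning — the panels this pipeline targets are homozygous inbreds.
* Reported percentages are truncated (not rounded) to one decimal;
  diversity fold changes round to one decimal; table floats print with six
  decimals and undefined statistics as literal `NA`, so repeated runs are
  byte-identical.
* Optimisation: the mlHKA profile likelihood is maximised by Brent's method
  on log τ from 5+ deterministic starts; convergence tolerances are 1e-8
  (MYN) and optimizer defaults (HKA).
* Ties in the spanning network break by haplotype id; empirical-quantile
  ties take the higher rank.
* Degenerate inputs: all-zero HKA counts raise a degenerate-data error;
  `fold_change(x, 0)` flags infinity and `0/0` is `NA`; a zero Poisson
  expectation facing a nonzero count yields −Inf log-likelihood, returned
  not raised.

## Problem sizes used by the tests and acceptance script

The oracle-equivalence suite uses 50 randomised instances per statistic;
neutral calibration uses 200 simulated genes and 500 simulated locus panels
per HKA variant; classifier recovery uses datasets of 50 neutral + 10
purifying + 10 balancing genes (20 seeds in the test suite, 10 in the
acceptance script); estimator recovery uses 50 codon pairs per ω. These
sizes give stable Monte-Carlo estimates at desk scale and are the package's
choices.

## Interface

The stage functions are the interface; `run_scan()` orchestrates them
(simulate → `generate_dataset()`; diversity → `diversity_summary()`,
`pairwise_pop_stats()`, `per_site_stats()`; kaks → `kaks_ng86()`,
`kaks_myn()`, `group_kaks()`; scan → `classify_gene()`, `classify_sites()`,
`detect_sweep()`; hka → `classic_hka()`, `fit_and_test()`; haplonet →
`collapse_haplotypes()`, `build_network()`, `network_report()`), and
`write_scan_report()` emits the TSV/JSON/DOT outputs. Fitted HKA objects
support `tidy()`/`glance()`; reports support `tidy()`, `glance()` and the
`plot_*()`/`autoplot()` functions.
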