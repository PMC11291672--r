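---
title: "Monitoring an adaptive introgression island with KASP genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring an adaptive introgression island with KASP genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspop)
```

## The problem

When the Pacific sea squirt *Ciona robusta* was introduced into the European
range of the native *Ciona intestinalis*, hybridization left a localized
introgression island on chromosome 5 of the native species: long tracts of
*C. robusta* ancestry surrounding a putatively selected core variant (next
to a cytochrome P450 tandem repeat). Population-genetic theory predicts a
characteristic temporal signature if the core allele is locally adaptive and
maintained by a balance between selection and immigration of non-introgressed
natives: the core allele frequency should be stable through time, while the
hitchhiked alien alleles in the flanking "shoulders" should erode as
recombination uncouples them from the core and purging or gene flow removes
them. The linkage disequilibrium (LD) between core and shoulder markers
should fall accordingly.

`kaspop` implements the full analysis chain needed to test this signature
with ancestry-informative KASP (competitive allele-specific PCR) assays,
plus a forward-in-time simulator that generates data with exactly the
statistical structure the analysis assumes, so every stage can be validated
against known truth.

## Genotype calling from two-channel fluorescence

A KASP reaction reports two end-point fluorescence values per sample, one
per diagnostic allele. The variant allele fluorescent fraction

$$\mathrm{VAFF} = \frac{f_\mathrm{rob}}{f_\mathrm{rob} + f_\mathrm{int}}$$

maps homozygotes near 0 or 1 and heterozygotes near 0.5, and is invariant
to overall signal intensity. Calling is one-dimensional on the VAFF scale:
two cutoffs split it into dosages 0 / 1 / 2 of the *robusta* allele.

Rather than hardcoding cutoffs, `calibrate_cutoffs()` reproduces the
geometry of manual per-run curation from the plate's positive controls (one
*C. robusta*, one plain *C. intestinalis*, two introgressed *C.
intestinalis*): the lower cutoff is the midpoint between the
intestinalis-homozygote and heterozygote cluster means, the upper between
heterozygote and robusta-homozygote. When the introgressed controls are not
heterozygous at an assay (they are homozygous native outside the island),
the heterozygote anchor is synthesised as the homozygote midpoint; an
introgressed-control VAFF is accepted as a heterozygote anchor only if it
falls in the middle half between the homozygote means, which keeps the rule
deterministic without knowing the control's true genotype in advance. A
run without usable homozygote controls falls back to configured defaults
(1/3, 2/3) with a warning. Calls within `margin` (default 0.05) of a cutoff
are flagged `near_cutoff`; they are listed in QC output but count as
missing in all frequency computations, mirroring how ambiguous wells are
treated in manual scoring.

The 11 SNPs pooled in one multiplex reaction estimate the genome-wide
hybrid index: under balanced pooling, an individual heterozygous at $k$ of
the 11 loci has expected multiplex VAFF $k/22$. The default category
thresholds (0.125, 0.875) therefore classify anything heterozygous at three
or more multiplex loci as admixed, enough to flag F1s, F2s and first- and
second-generation backcrosses while leaving the pure-species clusters
untouched. Both thresholds are configurable; the balanced-pooling
assumption (equal amplification efficiency across the 11 assays) is a known
simplification and is stated where the simulator makes it.

## Temporal tests of allele-frequency change

All frequency analyses run on classified *C. intestinalis* individuals
only. For the core SNP, each population sampled in both periods is tested
for a change in allele counts (2×2) and genotype counts (2×3) with
complete-enumeration exact tests; the per-population p values are
Benjamini–Hochberg adjusted (via `stats::p.adjust`). Shoulder SNPs are
tested pooled over the whole dataset. Because the literature is split on
whether such pooled tests should use allele or genotype tables, both are
computed and reported side by side.

Conventions, stated because they matter to the third decimal:

* Two-sided exact p values use the point-probability (minimum-likelihood)
  rule: the p value sums the probabilities of all tables with fixed margins
  that are at most as probable as the observed one (with a `1e-7` relative
  tie tolerance, the same guard base R's `fisher.test` uses). Tables of two
  rows are enumerated vectorised; larger tables recurse; beyond a
  configurable enumeration bound (`max_tables`, default 2·10⁶) the test
  refuses and offers a seeded Monte Carlo fallback based on
  `stats::r2dtable` with the add-one estimator.
* The one-sided Wilcoxon signed-rank test (populations as replicates,
  testing for a frequency decrease) discards zero differences and reports
  how many were discarded. With ≤ 15 non-zero differences and no ties the p
  value is exact, from the full $2^n$ enumeration of sign assignments;
  otherwise a normal approximation with tie and continuity corrections is
  used.
* The sign test is the exact two-sided binomial test,
  $p = 2\min\{P(X \le k), P(X \ge k)\}$ capped at 1. Applied to the LD
  decrease counts this is the only sidedness convention consistent with
  both reported values (8/9 decreases giving 0.039 and 9/10 giving 0.021).

## Linkage disequilibrium from unphased genotypes

Pairwise $r^2$ is computed from the four two-locus haplotype frequencies,
estimated from unphased diploid dosages by a Hill-type EM. Every genotype
class except the double heterozygote resolves into known gametes; the
double heterozygotes are split between the two phase resolutions in
proportion to the current haplotype-frequency products
$p_{AB}p_{ab} / (p_{AB}p_{ab} + p_{Ab}p_{aB})$, iterating from the
linkage-equilibrium start $p_{AB}^{(0)} = p_A p_B$ until the largest
haplotype-frequency change falls below `tol` (default `1e-8`). Exactly tied
products split 50/50 — the deterministic resolution of the EM saddle, which
leaves $D = 0$ (a single double-heterozygote individual therefore yields
$r^2 = 0$ rather than an arbitrary phase guess). The observed-data
log-likelihood is non-decreasing across iterations and is asserted to be so
in debug mode; the test suite also checks the converged solution against a
grid search over the haplotype simplex. $r^2$ is undefined (NA) when either
locus is monomorphic in the sample, and such pairs are dropped from that
population's contribution only.

LD matrices are computed per population and period, restricted to
populations whose core *robusta* frequency exceeds 0.05 in that period
(elsewhere diversity is too low for LD to be informative); retention is
decided per period. Mean $r^2$ depends on the aggregation order, which is
genuinely ambiguous in summary reports, so all three are available:
unweighted over (population, pair) values (the primary), pairs averaged
across populations first, and pooled-individual estimates. The temporal
comparison averages each pair across retained populations within a period,
takes the later-minus-earlier difference, and summarises the direction of
change within the core–shoulder, left-shoulder, right-shoulder and
cross-shoulder pair classes with the exact sign test and the one-sided
Wilcoxon test. The pair classes derive solely from the panel's region
labels; with 10 island markers (core + 4 left + 5 right) the partition is
9 + 6 + 10 + 20 = 45 pairs.

## The simulator: what it emulates

`sim_config()` / `run_scenario()` implement a single-deme Wright–Fisher
model of the post-sweep phase: $2N$ haplotypes over the island marker map,
initialised as a fraction $p_0$ of full-length alien tracts; each
generation draws Binomial($2N$, $m$) haplotypes replaced by all-native
immigrants, pairs haplotypes into diploids, assigns multiplicative fitness
$w = (1+s_\mathrm{core})^{d_\mathrm{core}} (1-s_\mathrm{del})^{d_\mathrm{sh}}$
(core dosage and summed alien shoulder dosages), samples parents
proportionally to $w$, and recombines with independent per-interval
crossover probabilities (inter-marker distance × per-bp rate, no
interference). Two cohorts are sampled `gap` generations apart (default
20, the sampling design's spacing). `emit_fluorescence()` then applies the
measurement model — channel means by dosage, truncated Gaussian noise, the
multiplex pooling over 11 assays (total signal scales with pool size,
noise only with its square root), and the four control wells per run — so
the synthetic plates flow through the identical calling path as real ones.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `N` | 2000 | diploid deme size; large enough that 20-generation drift does not swamp the shoulder signal |
| `s_core` | 0.2 | selection favouring the alien core allele |
| `m` | 0.13 | immigration of non-introgressed natives; set so that `p0` is the migration–selection equilibrium (per-generation gamete gain ≈ $s q$ balancing loss ≈ $m/(1-m)$) |
| `s_del` | 0.005 | per-locus cost of alien shoulder alleles ("mildly deleterious hitchhikers"); light enough that the core is not dragged far from equilibrium while shoulders remain attached |
| `p0` | 0.3 | initial full-tract frequency, matching the observed core-frequency scale |
| `rec_per_bp` | 8e-8 | ≈ 8 cM/Mb; leaves the shoulders mid-erosion at the first sampling |
| `burn_in`, `gap` | 30, 20 | generations before the first sample and between samples |
| `n_sample` | 400 | individuals per period, the per-period sample-size scale of the field design |
| `channel_high/low`, `noise_sd` | 1000/50, 40 | KASP endpoint signal levels; clusters ≥ 6 noise SD apart on the VAFF scale |

The selection/migration/recombination values are illustrative, not
inferred: no field estimate exists for any of them. They follow the
equilibrium reasoning above: a core allele at a migration–selection balance
is the only
configuration in which the core stays flat while attached hitchhikers still
erode. A full-tract initialisation with a heavy per-locus burden instead
produces a crash-and-recovery core trajectory (the tract's net fitness is
negative until recombination strips its hitchhikers), which is a different
— and biologically interesting — regime, reachable by raising `s_del`, but
it is not the observed signature.

Setting `s_del = 0` and `m = 0` isolates the claimed mechanism: with
neither purging nor immigration, shoulder erosion disappears (the shoulders
instead hitchhike upward with the now-unopposed core sweep).

### What the simulator does not emulate

One focal deme only (immigration summarises the metapopulation mosaic); no
new introgression after initialisation; no F1 hybridization dynamics
(hybrid multiplex signals can be injected directly to test the
classifier); balanced multiplex pooling; no plate or instrument effects
beyond isotropic Gaussian channel noise; no crossover interference; no
tract-length analytics. Passing validation on simulated plates therefore
demonstrates correctness of the statistical machinery under the model's
assumptions, not robustness to, e.g., per-assay amplification bias or
cluster rotation in the raw fluorescence plane — those still require
run-level control inspection on real plates.

## Validation problem sizes

The validation suite runs complete-enumeration cross-checks on 200 random
contingency tables and 100 random signed-rank inputs, a simplex grid
search oracle on 100 random dosage tables (coarse step 0.01 plus a fine
profile scan at the fixed sample margins, step 1e-5), calling-fidelity
checks on 11,000 noisy synthetic records, and 50 replicate erosion
scenarios pushed through the full pipeline (plus 10 no-purge controls).
These sizes keep the full suite in the low tens of seconds on one CPU
while leaving each check statistically meaningful.

## Known limitations

* The Freeman–Halton enumeration is practical only for small tables; the
  Monte Carlo fallback is provided (seeded) but changes the test from exact
  to estimated.
* The EM saddle at exactly tied phase products is resolved to $D = 0$ by
  construction; data that are genuinely bimodal in phase will simply report
  the equilibrium solution.
* Real deposited genotype tables vary in encoding; the reader's dialect
  block (missing tokens, allele letters, separator) must be set once per
  source rather than auto-detected.
* The hybrid-index thresholds assume balanced multiplex pooling; strongly
  unbalanced amplification would shift the admixed band and should be
  recalibrated against F1 controls.
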