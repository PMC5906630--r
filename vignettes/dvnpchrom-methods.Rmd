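---
title: "Models and methods behind dvnpchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dvnpchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvnpchrom)
```

`dvnpchrom` quantifies how a histone-displacing viral nucleoprotein (DVNP)
remodels yeast chromatin, from aligned sequencing fragments to the final
statistics. This vignette explains the models each stage assumes, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## Coverage and normalization

All coordinates are 0-based and half-open, in the BED convention, on disk
and in memory; a single convention eliminates off-by-one drift between
readers, writers, and arithmetic.

A fragment set becomes a per-base track either by **full-span** counting
(every covered base gets +1; used for ChIP occupancy) or by **midpoint**
counting (+1 only at `floor((start+end)/2)`; used for MNase data, where
the fragment midpoint estimates the nucleosome dyad). The midpoint of an
even-length fragment is the floor of the arithmetic mean — deterministic
and consistent with the half-open convention.

Tracks are normalized to the genome-wide mean, so 1.0 means "average
genomic coverage". This removes sequencing depth but *also* removes any
genuine genome-wide shift — which is exactly why the RNAP II analysis
needs spike-in scaling (below). Gaussian smoothing (default σ = 4 bp,
applied to MNase midpoint tracks) uses a kernel truncated at 4σ and
renormalized to unit sum; truncation loses < 1e-4 of the mass and bounds
the compute. At chromosome ends the kernel is renormalized over its
in-bounds support rather than padding with zeros, so no signal is
fabricated outside the genome. Smoothing and mean-normalization are both
linear and commute, so their order is immaterial. Fragment-size filters
default to 120–200 bp for MNase (mono-nucleosome protection) and
50–500 bp for ChIP (sonication range); the bounds are config-exposed
because only the rule, not the bounds, is canonical. Duplicate-fragment
removal is available behind a flag and off by default.

## Metagene profiles

Profiles average a normalized track across genes aligned at the TSS in
transcription orientation, 500 bp upstream to 2500 bp downstream by
default. Each gene contributes only until its polyadenylation site
(minus a 3′ `end_buffer`, 300 bp for RNAP II profiles where 3′-end peaks
skew quantification). The per-offset mean divides by the number of genes
*still contributing* at that offset (ragged averaging): zero-filling
beyond short genes would fabricate depletion, contradicting the
truncation rule. The upstream flank is never truncated by neighboring
genes and window overlap with adjacent genes is permitted — no such
exclusions are part of the procedure. When replicate libraries exist they
are pooled at the fragment level before coverage; the alternative
(averaging per-replicate profiles) differs only by depth weighting.

## The quintile association engine

The genome is tiled into 500 bp windows advancing by 250 bp. Per window
the table carries DVNP enrichment (IP/input ratio of mean-normalized
tracks, or IP alone — both modes exist because input-independence of the
result is itself a check), the input signal, and the occupancy change
`control − treatment` of mean-normalized MNase tracks, so positive values
mean nucleosome **loss**. The simple difference (not a log-ratio) is the
default because it is defined at zero-coverage windows; a log2-ratio mode
is available. Because both tracks have genome mean 1, a uniform loss is
invisible by construction: the statistic measures *differential* loss,
and windows losing less than average show a relative gain (negative
values).

Windows whose control MNase occupancy falls below 1.2 genome-mean units
are excluded before binning. Occupancy change is undefined where there
are no nucleosomes, and because the difference statistic scales with the
occupancy level itself, mixing sparse and dense windows within a quintile
blurs the trend; the retained and dropped counts are always reported.

Quintile labels come from rank binning with boundaries at
`ceiling(k·n/5)`, ties broken by stable input order (sizes differ by at
most one). Per-bin summaries use Tukey-hinge (midpoint-rule) quartiles,
whiskers at the most extreme data within 1.5·IQR, and notches
`median ± 1.58·IQR/√n` — the standard approximate 95% CI of the median.
The top-vs-bottom comparison is a two-sided Welch *t*-test (unequal
variances, Welch–Satterthwaite df). To control DNA-accessibility bias the
association is additionally re-run inside quantile strata of the input
signal; a trend that is driven by accessibility alone disappears under
this stratification, which the test suite demonstrates with a planted
confounder.

The same engine serves the stability analysis: nucleosome sites (planted
dyads in simulations, or any user-supplied dyad table) are scored by
**GC-predicted occupancy** — the GC fraction of the 147 bp window
centered on the dyad, with N bases excluded from numerator and
denominator. GC content is a documented, transparent proxy for
sequence-encoded nucleosome stability (GC-rich DNA forms more stable
nucleosomes); a full thermodynamic positioning model is out of scope.
Calling nucleosome positions de novo from MNase data is likewise out of
scope.

## Spike-in normalized RNAP II quantification

Spike-in counts give per-sample factors
`factor_s = (spike_ref / spike_s) · (mass_s / mass_ref)` with the
reference factor 1; genomic coverage is multiplied by its factor before
any cross-condition comparison. The interface is a read-count table
rather than a second reference genome because defined oligo amounts are
the minimal faithful abstraction of the spike-in. Gene-body occupancy is
the strand-aware mean from the TSS to 300 bp before the polyA site, and
the global change is the **ratio of condition means**,
`100·(1 − mean_t/mean_c)` — robust to low-coverage genes — with the
mean-of-per-gene-ratios variant also reported since the arithmetic behind
a "percent global reduction" admits both readings. The per-gene change
distribution and its Welch test accompany the headline number. The stage
also reports the estimate *without* spike-in factors: on depth-matched
libraries it is ~0, demonstrating that the spike-in normalization is
load-bearing rather than decorative.

## SGA screen statistics

Colony sizes are normalized per plate (each size divided by its plate
median, per condition and replicate — the minimal defensible core of
spatial correction; a row/column polish could be added, but plate-median
is what the tests guarantee), and relative growth is
`median(norm exp) / median(norm ctrl)`. Strains with a zero control
median are flagged and excluded from tests. Default thresholds are
`1 ± 2·(1.4826·MAD)` of the relative-growth distribution, exposed as
parameters since threshold choice is a screening policy, not a fact.

Two χ² tests formalize the histone connection: H₀1 asks whether
histone-level-affecting deletions distribute across
rescuer/neutral/sensitizer classes like all strains (2×3 table); H₀2
asks whether histone-increasing vs histone-decreasing deletions fall
below vs above the growth thresholds by chance (2×2 table of non-neutral
set members). No continuity correction is applied, matching the classical
test on large screens; when an expected cell drops below 5 a Fisher exact
test substitutes with a warning. Functional-category enrichment of
rescuers is an upper-tail hypergeometric test per category over a
user-supplied category map, Bonferroni-corrected.

## The synthetic-data generator

The generator exists so every stage can be validated by parameter
recovery. Its defaults define the study conditions used throughout the
tests and the acceptance script:

* **Genome** — two 650 kb chromosomes (5198 tiled windows at 500/250),
  GC drawn blockwise (500 bp blocks, AR(1) with stationary SD 0.1 around
  mean 0.39) so GC varies smoothly on the scale the stability analysis
  reads.
* **Genes** — 300 non-overlapping genes of 1–2.5 kb with 500 bp reserved
  flanks, random strands.
* **Nucleosomes** — per gene: an NDR (140 bp) upstream of the TSS, a −1
  dyad at TSS−213, a +1 dyad at TSS+73, then phasing every 165 bp to the
  polyA site. Site weights encode stability:
  `weight = 0.8·(1 + γ·(GC₁₄₇ − mean GC₁₄₇))` clipped to (0,1], γ = 2 by
  default.
* **DVNP affinity** — a per-base track of unit 147 bp footprints over the
  dyads, with the −1/+1 footprints boosted 1.6× (DVNP enrichment peaks at
  promoter-proximal nucleosomes) and only a 0.02 floor in NDRs/linkers,
  multiplied by a smooth lognormal concentration field (2 kb blocks,
  log-SD 0.6). The field gives genuine region-to-region variation in DVNP
  binding; without it, affinity would be a near-constant function of the
  site weights and the planted loss would be uniform — undetectable after
  mean normalization. Affinity footprints are deliberately *not* scaled
  by site weight: weight-scaled affinity (∝ w) would cancel the
  weak-site susceptibility (∝ 1/w^γ) exactly. A `free_dna` affinity mode
  (the complement) exists to show the pipeline distinguishes
  nucleosome-tracking from free-DNA binding.
* **MNase libraries** — 4×10⁵ fragments per condition, drawn per site
  ∝ weight (control) or ∝ `weight · max(0, 1 − β·affinity·(w̄/w)^γ)`
  (DVNP condition, β = 0.8): loss is proportional to local DVNP and,
  for γ > 0, inversely to nucleosome stability. Midpoints jitter
  Normal(0, 10 bp) around the dyad — realistic peak widths without
  obscuring phasing; lengths are Normal(147, 12) truncated to 120–200 bp
  (the truncated mean stays within 1 bp of 147). Digestion depth is
  matched between conditions by default; a mismatch nuisance can be
  emulated by changing per-condition fragment counts.
* **Rpb3 with spike-ins** — gene-body midpoints ∝ expression
  (log-normal, sdlog 0.6); the treatment multiplies every gene's rate by
  the planted global ratio r = 0.65, then **both** libraries are
  resampled to exactly 10⁵ genomic fragments, so the reduction is
  invisible without the spike-in. Spike reads are Poisson with
  expectation `depth · 0.2 / r_condition`: fixed spike mass against
  r-scaled cellular material makes the treatment spike fraction exceed
  control by 1/r. The generous 20% spike representation keeps Poisson
  counting noise (~0.5%) well below the planted effect; at a few percent
  representation, spike-count noise alone would dominate a 10% effect.
* **SGA** — 5426 strains; latent growth `1 + effect + Normal(0, 0.05)`,
  with +0.3 planted on a 21-gene histone-down set and −0.3 on a 21-gene
  histone-up set (42 histone-level genes in total); colony sizes add
  per-plate lognormal scale factors (SD 0.15, 384 strains/plate, two
  replicates per condition) and 1% per-colony noise, giving the
  plate-median normalization real work.

What the generator does **not** emulate: sequence-level reads (errors,
quality, mappability), PCR duplicates, replicate batch effects,
MNase sequence bias, chromatin remodeler dynamics, or any coupling
between transcription and nucleosome loss. Passing tests therefore show
that the *estimators recover planted effects under their own model
assumptions* — they do not certify performance on real libraries with
unmodeled biases.

## Numerical choices and degenerate inputs

* Welch's test on two zero-variance samples returns the degenerate limit
  (t = 0, p = 1 for equal constants; |t| = ∞, p = 0 otherwise) instead of
  erroring, so idealized constant tracks flow through the reporting path.
* Quantile binning with heavy ties falls back to stable input order with
  a warning rather than producing unequal bins.
* bedGraph output writes zero runs explicitly so genome-mean
  normalization is reconstructible from the file alone; run-length
  merging keeps files small; values round-trip to 15 significant digits.
* Windows extending past a chromosome end are dropped (count
  `floor((L − size)/step) + 1`), never clipped, so all windows are the
  same width and window means are comparable.
* Sites whose 147 bp GC window runs off the chromosome are dropped with a
  warning rather than computed on a shorter window.
* The circular-chromosome smoothing mode exists for validating exact mass
  conservation; linear chromosomes necessarily redistribute (but never
  lose) mass within 4σ of the ends.

## Statistical calibration

The null calibration of the quintile association (no planted coupling)
runs on **non-overlapping** windows (step = size) with **midpoint** MNase
counting. Both choices serve independence of the Welch samples:
overlapping windows share bases, and full-span counting lets a single
boundary-spanning fragment contribute to two adjacent windows, which
inflates the test's size by a few percent when high-enrichment windows
cluster. With midpoint counting every fragment lands in exactly one
window and the empirical rejection rate at α = 0.05 sits at the nominal
5% (200-replicate calibration in both the test suite and the acceptance
script). The main analyses use the same midpoint occupancy for
consistency.

## Problem sizes

The default study — 1.3 Mb genome, 300 genes, ~3400 nucleosome sites,
4×10⁵ MNase and 2×10⁵ ChIP fragments per library, 10⁵ Rpb3 fragments per
condition, 5426 SGA strains — was chosen as the smallest scale at which
all planted effects are comfortably detectable and quintile trends are
stable across seeds; a full simulated study plus every analysis stage
runs in seconds, and the entire verification suite in well under a
minute of compute per replicate batch.

## Known limitations

* The GC proxy compresses the dynamic range of true sequence preferences;
  it orders nucleosomes by stability but its absolute values are not
  occupancy probabilities.
* The spike-in interface assumes counts already assigned to spike vs
  genome; aligning reads to a composite genome is upstream of this
  package.
* The Fisher fallback for sparse χ² tables changes the test, not just the
  p-value; the `method` field of the result records which was used.
* Relative growth assumes plate medians are dominated by unaffected
  strains; a plate consisting mostly of true hits would be
  over-normalized.
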