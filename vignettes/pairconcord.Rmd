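---
title: "Paired tumour–metastasis concordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired tumour–metastasis concordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairconcord)
```

`pairconcord` quantifies how faithfully a synchronous metastasis mirrors
the somatic mutation and copy-number profile of its primary tumour, from
per-patient trios (primary, metastasis, matched normal) of variant call
tables and binned copy-ratio profiles. This vignette explains the models
behind each stage, the parameters that matter, and the design choices
made where the design was genuinely open.

## The filtering cascade

Each tumour site is filtered independently:

1. **Germline subtraction.** Any tumour variant whose exact key
   `(chrom, pos, ref, alt)` carries ≥ 10 alt-supporting reads in the
   matched normal is removed outright (`max_normal_alt = 9`, inclusive).
   Removed keys never re-enter later stages: a germline variant must not
   be rescued as a shared somatic call.
2. **Evidence filters.** Alt reads > 5, depth > 9, VAF ≥ `min_vaf`
   (default 0.2), and per-strand balance
   `min(alt_fwd, alt_rev)/alt_count` strictly > 0.2. Strictly-greater
   thresholds are stored as inclusive integer bounds ("> 5" is
   `min_alt_count = 6`) so boundary behaviour is exact and testable.
   The 0.2 bound is applied *both* to the VAF and to the strand balance,
   each independently configurable; a Fisher strand test was considered
   and rejected as out of scope at exome depths.
3. **Annotation filters.** Population frequency < 1%, consequence among
   loss-of-function / frameshift / in-frame / stop-codon / missense,
   pathogenicity `pathogenic` or `likely_pathogenic`. Annotations
   (consequence, SIFT class, population frequency, pathogenicity) are
   consumed as input columns produced by upstream annotation engines;
   the package never computes them. Unknown consequence strings are
   excluded with a warning and counted separately, never silently kept.

The three filters are pure per-variant predicates, so the cascade is
order-invariant, idempotent, and monotone in every threshold — all
property-tested. Variants failing a filter go to a side **ledger** with
the failing criterion; the ledger is what makes the pair classifier's
rescue and coverage guards possible.

## Shared / private classification

A variant passing in both sites is **shared**. A variant passing in one
site only is:

* **shared (rescued)** if the counterpart ledger holds the same key with
  ≥ `rescue_min_alt` alt reads (default 2 — the smallest support
  distinguishable from a lone sequencing error). This formalises manual
  re-inspection of paired sites: a truncal variant sitting just under a
  filter threshold at one site must not inflate the private count.
* **private** to the passing site if the counterpart is covered with
  depth ≥ `counterpart_min_depth` (default 10, matching the coverage
  filter) at that position.
* **unevaluable** otherwise — reported, but excluded from every
  concordance denominator, since a "private" call at an uncovered
  position is an artefact of sequencing, not biology.

Indels are keyed by a normalised representation (shared flanking bases
trimmed, position advanced, at least one base retained per allele) so
the same event spelled two ways matches across sites. Full
left-alignment against the reference sequence is out of scope; the
normalisation handles the padded spellings that annotation pipelines
emit.

## Clonality shifts (Δ30)

For shared variants, `Δ = 100 × (VAF_met − VAF_prim)` percentage points;
`Δ > 30` (strict, with a 1e-9 guard against binary-representation ties)
flags a subclonal→clonal expansion. VAFs are compared raw by default
because tumour purity is rarely known per sample; when both purities are
supplied, each VAF is divided by its sample's purity first. Rescued
variants contribute their ledger VAF, so a variant subclonal in the
primary and clonal in the metastasis is evaluated, not lost.

## Cohort statistics

* **TI/TV**: transitions are A↔G and C↔T (strand-symmetric); the ratio
  is undefined (reported absent) without transversions. Indels and
  multi-nucleotide variants are excluded from both counts and tallied
  separately — per-patient ratios are computed over classified SNVs
  only.
* **Patient summaries**: burden (shared + private, unevaluable
  excluded), shared fraction, SIFT composition per status, driver-gene
  overlap by symbol (drivers are never a filter).
* **Gene × patient matrix**: per cell, `shared` dominates
  `both_private`, which dominates one-sided private states; genes are
  ordered by number of mutated patients, ties alphabetical.
* **Contrasts**: Mann–Whitney U (two groups) and Kruskal–Wallis. For
  combined n ≤ 12 the two-sided p comes from exhaustive enumeration of
  group assignments over pooled mid-ranks — valid under ties, and
  exact for layouts like the 9-vs-12 sidedness split's subgroups;
  larger layouts use the tie-corrected normal
  (continuity-corrected, via `stats::wilcox.test`) or chi-square
  (`stats::kruskal.test`) approximations. Two-sided p-values throughout;
  no multiple-testing correction is applied by default, matching
  common practice for small exploratory cohorts.

## Copy-number analysis

Profiles arrive as constant-width binned log2 copy ratios (optionally
with a B-allele-fraction track). Segmentation is recursive binary
segmentation with a circular-style statistic: within the current window
the candidate interval maximising the two-sample t-statistic against
the remainder is located (a boundary-touching interval is an ordinary
split), accepted when |t| > `t_thresh` (default 5) and every resulting
part holds ≥ `min_bins` (3) bins, recursing into all parts; adjacent
segments closer than `merge_eps` (0.1) in mean are re-merged. The
interval form was chosen deliberately: a plain best-single-split rule
cannot expose a short interior event (a 10-bin event in a 100-bin
chromosome yields best split |t| ≈ 2.3, indistinguishable from noise),
whereas the interval statistic detects it at |t| ≈ 12. Segmentation is
deterministic, and segments always cover each chromosome disjointly.

Calls use mean log2 ≥ +0.2 (gain) / ≤ −0.2 (loss). Events are
**numerical** when spanning ≥ 95% of the chromosome and **segmental**
when ≥ `band_size` (default 1/20 of the chromosome — an explicit proxy
for single-cytoband resolution, since "one band" has no universal bp
size); smaller events are `sub_band` and excluded from pair counts.
Pairs are compared by greedy reciprocal-overlap (≥ 0.5) matching within
(chromosome, direction): matched events are shared, metastasis-only
novel, primary-only lost — anti-symmetric under sample swap. LOH is
read from the BAF track only (segment mean |BAF − 0.5| > 0.15); without
a BAF track the LOH flag is absent, never false.

## The synthetic cohort generator

`simulate_cohort()` draws per-patient trios under branched clonal
evolution with known truth. Defaults are the study conditions of a
21-patient synchronous colorectal-liver-metastasis exome cohort:

| parameter | default | meaning |
|---|---|---|
| `depth_*_mean` | 47 / 44 / 40 | mean coverage, primary / metastasis / normal |
| `depth_dispersion` | 10 | negative-binomial size (overdispersed depth; only means are typically reported, so dispersion is a modelling choice) |
| `purity_*` | 0.7 | tumour-cell fraction, matching a ≥ 70% tumour-content inclusion rule |
| `burden_mean` | 94 | pre-annotation-filter somatic variants per left-sided patient; with the 0.7 annotation pass rate this yields *observed* burdens with medians near 66 (left) and 102 (right) |
| `private_*_rate` | 0.11 each | giving a truncal (expected-shared) fraction of 0.78 |
| `sidedness_effect` | ×1.55, −0.07 | right-sided burden factor and shared-fraction deficit |
| `ti_fraction` | 2/3 | transition probability (TI/TV = 2) |
| `indel_fraction` | 0.068 | non-SNV share of the burden |
| `subclonal_fraction` | 0.04 | truncal variants subclonal in the primary; yields a median of 2 observed Δ30 variants per pair |
| `subclonal_vaf` | 0.15 | expected primary VAF of a shift variant (CCF ≈ 0.43 at purity 0.7); in the metastasis the variant is clonal with LOH, expected VAF ≈ purity |
| `annotation_pass_rate` | 0.7 | somatic variants whose annotations survive the filters |
| `error_rate` | 0.001 | per-base noise generating alt reads at variant-free sites |

Read evidence per sample and variant: depth ~ NB(mean, size), alt reads
~ Binomial(depth, expected VAF), strand split ~ Binomial(alt, 1/2).
Expected VAF is purity × clonal fraction / 2 (heterozygous, copy-neutral
loci); germline variants sit at 0.5 in all three samples. Tumour tables
keep zero-alt rows at somatic sites as coverage observations — the
stand-in for counterpart coverage that a real pipeline reads from
alignments. The model genome is 24 chromosomes of 10 Mb at desk scale;
positions matter only through keys and CNA overlap, so the scale is
immaterial to the statistics.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: CNA–VAF interaction (variants sit on
copy-neutral loci so truth stays analytic; real VAFs are distorted by
copy state), mutational-signature context, mapping artefacts and
FFPE-style damage, inter-site purity differences beyond the single
parameters, and subclonal structure richer than one subclone level.
Recovery rates measured here are therefore upper bounds for real
cohorts.

`simulate_cna_profiles()` places disjoint events (each on its own
chromosome) split into shared / novel / lost × numerical / segmental,
renders piecewise-constant log2 means (gain log2(3/2), loss log2(1/2))
with Gaussian noise (sd 0.15), and shifts BAF by 0.2 over LOH (loss)
events.

## Numerical choices and degenerate inputs

* Exact p-value enumeration is capped at 1e5 assignments (relevant only
  for many-group Kruskal–Wallis layouts); beyond it the approximation
  is used.
* Depth 0 yields an undefined VAF: the row is flagged `no_coverage`,
  excluded from passes, and its position counts as uncovered for the
  guard.
* A rise of exactly 30 points never flags (strict inequality with an
  epsilon guard); an all-transition patient reports an absent TI/TV
  ratio rather than infinity; an empty evaluable set reports burden 0
  and an absent shared fraction.
* Segmentation tie-breaks: the first maximal-|t| interval (scan order)
  wins; merging collapses the closest adjacent pair first and
  re-checks, so chains merge deterministically.

## Problem sizes used in validation

The shipped validation suite simulates cohorts of 50 patients
(classification and Δ30 recovery), 2000 null cohorts of 9 vs 12 for the
empirical size of the Mann–Whitney test, and 100 profile pairs (2400
chromosome tracks per arm) for copy-number recovery — sizes at which
the Monte-Carlo error of each measured rate is a few percent, chosen as
the package's own desk-scale validation conditions.

## Known limitations

Multi-region or metachronous designs (three or more tumour samples) are
not modelled — the unit is the pair. Cancer-cell-fraction estimation,
subclone deconvolution and phylogenetics are out of scope; Δ30 is a
deliberately simple screen. Gene-level CNA calls take the
maximum-overlap segment, not a weighted consensus. The exact-with-ties
enumeration treats mid-ranks as fixed, the standard conditional-on-ties
convention.
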