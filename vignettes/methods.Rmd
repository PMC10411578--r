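---
title: "Calling stress-induced DMRs and DhMRs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling stress-induced DMRs and DhMRs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressDMR)
```

## The analysis problem

Enrichment sequencing of 5-methylcytosine (5mC, MeDIP-style capture) and
5-hydroxymethylcytosine (5hmC, chemical-labeling capture) yields, per
biological sample, a set of peaks: genomic regions where the modification
is enriched. In a social defeat stress design, mice are exposed to acute
(ASDS, 3-day), chronic (CSDS, 10-day), or longitudinal (LSDS, chronic
plus incubation and re-exposure) defeat; stressed animals split into
*susceptible* and *resilient* phenotypes by their social interaction
ratio. The question is which regions gain or lose each modification under
stress, whether those changes travel with gene expression, and how they
evolve across the ASDS→CSDS→LSDS time course.

stressDMR implements that analysis chain as reusable, tested components:
replicate consensus, presence/absence differential calling, CPM
quantification with log2 fold changes, nearest-gene and feature
annotation, concomitance classification against expression, temporal
trajectory grouping, and behavioral scoring — plus a synthetic-data
generator with planted ground truth that exercises all of it without any
external download.

## Windowed overlap and replicate consensus

All interval logic is BED-style (0-based, half-open) and strandless —
antibody and chemical-labeling capture do not resolve strand. Two peaks
*window-overlap* at window $w$ when their spans extended by $w$ bp
up- and downstream intersect:

$$ a.start < b.end + w \quad\text{and}\quad b.start < a.end + w $$

so a gap of exactly $w$ does **not** count as overlap. The default
$w = 300$ bp mirrors the common practice of windowed peak matching for
technical replicates and is exposed everywhere as a parameter.

A *consensus peak set* keeps only peaks supported by every replicate.
Which coordinates a consensus peak carries is a genuine design choice; we
report the **anchor replicate's** coordinates (the first replicate in the
configured order) whenever the anchor peak window-overlaps at least one
peak in every other replicate. This is deterministic and makes the
consensus directly comparable to the anchor's raw peak calls; a merged
union of supporting peaks is available via `merge_intervals()` if
preferred.

## Presence/absence differential calling

A region is a *gained* DMR/DhMR when it appears in the stress consensus
and has no windowed overlap with any control consensus peak; *lost* is
the symmetric definition on the control side. This is deliberately a
presence/absence rule — no count-based test, no FDR — because the
differential sets are defined by peak membership, not by read-level
statistics. The run manifest records this explicitly so downstream users
do not mistake the sets for statistically tested calls. Two invariants
are enforced at call time: calling a set against itself is empty in both
directions, and no gained region may window-overlap any control peak.

*Condition-specific* sets (e.g. susceptible-specific gains) are windowed
subtraction: regions of one differential set with no overlap in the
other. We subtract at the region level rather than the gene level, so a
gene can legitimately appear in both susceptible- and resilient-specific
sets through different regions; gene-level reconciliation happens later
in the concomitance step.

## Quantification

Reads are counted per region by fragment midpoint (a read is in a region
iff `start <= midpoint < end`), which is unambiguous at boundaries;
any-overlap counting is available behind a flag. Counts are normalized to
counts per million mapped reads (CPM); the normalization unit cancels in
any fold change and is kept for interpretability. Replicates are averaged
as the arithmetic mean of normalized counts (not pooled), and

$$ \mathrm{LFC}_i = \log_2\frac{\bar{x}^{stress}_i + p}{\bar{x}^{ctrl}_i + p} $$

with an additive pseudocount $p = 0.5$ CPM (configurable) keeping every
fold change finite at zero counts. The worked example in the test suite:
30 reads at 2M mapped depth (15 CPM) versus 10 reads at 1M (10 CPM)
gives $\log_2(15.5 / 10.5) \approx 0.562$.

## Annotation

A minimal gene model (spans, strands, exons over known chromosome
lengths) drives two independent assignments per region midpoint:

- **nearest gene** — the gene minimizing |midpoint − TSS|, ties broken by
  smaller transcription start then lexicographic gene id, so the result
  is invariant to gene order; the distance is signed in gene orientation
  (negative = upstream of the TSS);
- **feature class** — the highest-priority feature containing the
  midpoint, priority promoter > TTS > exon > intron > intergenic, with
  promoter = TSS −1000/+100 bp and TTS (termination) = −100/+1000 bp,
  both strand-oriented, inclusive, and configurable.

The two are resolved independently: a region can classify as exonic
through one gene while lying nearest another gene's TSS; both facts are
recorded. The five feature classes form an exact partition of the genome
(verified base-by-base in the tests), which makes observed-vs-expected
feature enrichment well defined: expected fractions are each class's
share of genome bases under the identical priority partition. Regions
classifying intergenic carry no interpretable gene link and are removed
before any expression correlation.

## Concomitance

A gene linked to a gained region whose expression log2 fold change is
positive is *concomitantly increasing*; a lost-region gene with negative
expression change is *concomitantly decreasing*; everything else —
including an expression change of exactly zero, since the definitions
are strict inequalities — is nonconcomitant. Expression q-values are
carried through but never filtered on. When one gene carries regions of
both directions within a phenotype, it appears once per direction and
the explicit deduplication step then removes it from both lists rather
than inventing a winner rule. Top candidates across ages require a
direction-consistent expression change exceeding 0.25 (strict) at both 3
and 6 months; external gene-list intersection is case-insensitive on
symbols.

## Temporal trajectories

Across the acute→chronic→longitudinal course, each region's three
modification fold changes (each stress paradigm against its own matched
control, which is what makes the three comparable) are classified by the
signs of the between-stage deltas $\Delta_1 = \mathrm{lfc}_C -
\mathrm{lfc}_A$ and $\Delta_2 = \mathrm{lfc}_L - \mathrm{lfc}_C$ with a
dead zone $\varepsilon$ (default 0.1; $\varepsilon = 0$ is pure sign
logic): both up → Group I (continual gain), both down → Group II
(continual loss), up-then-down → Group III, down-then-up → Group IV,
anything in the dead zone → unclassified. We chose the delta rule because
the trajectory classes are described by between-stage changes
("increased between acute and chronic, decreased between chronic and
longitudinal"); an alternative reading based on per-stage absolute signs
is reachable by setting `require_baseline = TRUE`, which additionally
demands $|\mathrm{lfc}_L| \le \varepsilon$ for the return-to-baseline
groups III/IV. The rule depends only on deltas, so it is invariant to
adding a constant to all three values, and negating all three swaps
I↔II and III↔IV — both properties are tested exhaustively on a grid.

Expression matching uses the same dead-zoned delta signs: a profile is
expression-matched iff the expression deltas reproduce the modification
deltas' sign pattern at both transitions.

Regions shared between the 3- and 6-month analyses are categorized as
gained-at-both (both fold changes positive), lost-at-both, or
discordant, with the sign-concordance fraction reported alongside.

## Behavior

The social interaction ratio is time in the interaction zone with the
target over time without it; susceptible means SIR < 1, resilient SIR ≥ 1
(the boundary animal is resilient). Animals with a no-target time under
1 s or an SIR above 300 are excluded with recorded reasons before any
classification. Two-scorer inputs are averaged at the time level, before
the ratio. Sucrose preference is $100 \cdot s/(s + w)$ percent; zero
total consumption yields a missing value, not zero.

## The synthetic-data generator

The generator emulates every input the pipeline consumes, on a toy
two-chromosome genome (2 Mb by default), and emits the planted truth
separately from the data files. Its defaults are the study conditions:

- 3 replicate peak sets per condition; 300 bp peaks; Gaussian boundary
  jitter (sd 30 bp, small against the 300 bp window); 5% per-replicate
  dropout of background peaks; 200 background peaks shared by all
  conditions; 40 gained and 25 lost regions planted per stress
  condition, 30% shared between the susceptible and resilient conditions
  so condition-specific subtraction has structure to find.
- Negative-binomial region counts (dispersion 0.2, a typical
  overdispersion for enrichment data), mean = 50 CPM × planted fold ×
  library size/10^6, library sizes drawn from 0.8–1.2M mapped reads;
  planted regions carry a true two-fold change.
- Expression fold changes correlated with the planted modification
  changes at the study's concomitance rates: 40% of gain-hosting genes
  up, 58% of loss-hosting genes down, effect magnitudes |N(0.5, 0.2)|,
  null genes N(0, 0.1).
- 1,000 temporal profiles (250 per group I–IV) whose between-stage
  margins are at least 3ε before additive N(0, 0.05) noise; half the
  profiles get a matching expression trajectory, the rest flat
  expression.
- A behavioral cohort of 200 stressed and 20 control animals with 20%
  of stressed animals resilient, interaction times constructed to
  reproduce the planted SIR exactly, plus two injected
  exclusion-triggering records.

Three generator design choices deserve explanation:

- **Planted effects are intragenic with consistent annotation.** Planted
  gained/lost regions (80% of them; 20% are placed intergenic so the
  intergenic filter has work to do) sit in gene bodies, at most one per
  host gene, at positions whose nearest-TSS gene is the host. This
  matches the analysis focus on gene-body modifications and makes the
  generator's gene-level truth coincide with what annotation recovers —
  otherwise "truth" would be ill-defined at region–gene boundary cases.
- **Exact-count planting of proportions.** Conditional rates (40% up
  given gain, 58% down given loss, 20% resilient, 50%
  expression-matched) are planted as exactly `round(p*n)` of `n` hosts,
  assigned to a uniformly random subset, rather than independent
  Bernoulli draws. The configured rate is then realized exactly for
  every seed, so recovery tests measure the pipeline, not the planting
  noise of a particular random draw.
- **Condition-symmetric background dropout.** A background peak dropped
  from replicate *k* is dropped from replicate *k* of every condition —
  modeling regions of weak enrichment that fail peak calling in matched
  technical replicates — so presence/absence differences between
  consensus sets reflect only planted biology. Independent per-condition
  dropout would manufacture false gained/lost calls out of replicate
  noise; that failure mode of presence/absence calling is real, but it
  is a property of the input peak caller's sensitivity, not of this
  pipeline, and the generator is not trying to simulate peak-caller
  error.

One global seed fans out to fixed per-component child seeds
(`(seed + 97·stage) mod 2147483629`), so any component can be
regenerated independently and every artifact is byte-identical for a
fixed seed.

### What the generator does not emulate

Peaks are placed on a well-separated slot grid (2 kb spacing), so
consensus and differential calling never face partially overlapping or
nested peak clusters; real MACS2 output does contain such clusters, and
there the anchor-coordinate consensus convention matters more. Counts
have no GC or CpG-density bias, no input-normalization structure, and no
between-mark contamination. Expression effects are independent across
genes. Passing the planted-truth tests therefore demonstrates
correctness of the set logic, normalization arithmetic and
classification rules — not robustness to the full messiness of real
enrichment data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the default conditions
above: a 2 Mb genome with 160 genes for the end-to-end pipeline
(sub-minute on one CPU), a 18 Mb genome with 1,500 genes and 500 planted
regions per direction for the concomitance-rate check, 1,000 profiles
for the temporal check, and brute-force oracle comparisons (all-pairs
loops, per-base masks, exhaustive scans) on ≤100 kb toy instances.
Tolerances: hand-computable fold-change arithmetic is checked to 1e-9;
proportion recoveries are checked against 95% binomial confidence
intervals at their planted denominators; temporal recovery under noise
must reach 99%. Degenerate inputs are defined, not errors: empty peak
sets yield empty differential sets; an empty overlap denominator reports
a missing fraction rather than zero; zero fluid consumption yields a
missing preference.

## Known limitations

Presence/absence differential calling inherits the sensitivity of the
upstream peak caller; a peak just under the calling threshold in one
replicate removes a region from the consensus entirely. The package
deliberately does not attempt count-based differential testing, isoform
level annotation, CpG-island context, GO/STRING enrichment (external
services), or peak calling from alignments — it consumes peak calls and
produces region/gene tables that such tools can take downstream.
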