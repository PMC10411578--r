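# stressDMR

Differential DNA methylation (5mC) and hydroxymethylation (5hmC) region
analysis for social defeat stress studies — replicate consensus peaks,
gained/lost region calling, CPM quantification, gene annotation,
methylation–expression concomitance, temporal trajectory classification,
and behavioral phenotyping, with a planted-truth synthetic data
generator that makes the whole chain testable offline.

## Who this is for

Labs profiling cytosine modifications by enrichment sequencing
(MeDIP-seq / 5hmC capture) across stress paradigms — acute (ASDS),
chronic (CSDS), and longitudinal (LSDS) social defeat — who need a
reproducible path from per-replicate peak calls and count tables to
condition-specific differentially modified regions and
expression-correlated candidate genes. The package consumes standard
upstream outputs (BED/narrowPeak peaks, count TSVs, Cuffdiff-style
expression tables, behavior CSVs); it does not call peaks or align
reads.

## The method

All intervals are BED-style (0-based, half-open) and strandless. Two
peaks *window-overlap* at window *w* (default 300 bp) when their spans
extended by *w* intersect: `a.start < b.end + w` and
`b.start < a.end + w`.

- **Consensus**: a peak survives iff it window-overlaps at least one
  peak in *every* replicate; consensus regions carry the anchor (first)
  replicate's coordinates.
- **Differential**: *gained* = stress consensus peaks with no windowed
  overlap to any control peak; *lost* = the symmetric control-side set.
  Presence/absence by design — no count-based test.
- **Quantification**: counts per million mapped reads (CPM), replicate
  means, `lfc = log2((mean_stress + p) / (mean_control + p))` with
  pseudocount `p = 0.5` CPM.
- **Annotation**: nearest gene by signed TSS distance from the region
  midpoint; feature class by priority promoter > TTS > exon > intron >
  intergenic (promoter −1000/+100 bp, TTS −100/+1000 bp,
  strand-oriented); intergenic regions are dropped before expression
  correlation.
- **Concomitance**: gained region + positive expression log2FC =
  concomitantly increasing; lost + negative = concomitantly decreasing;
  strict inequalities. Cross-age candidates need |expression log2FC| >
  0.25 in the planted direction at both ages.
- **Temporal groups**: with deltas Δ1 = lfc(chronic) − lfc(acute), Δ2 =
  lfc(longitudinal) − lfc(chronic) and dead zone ε = 0.1: Group I
  (both > ε, continual gain), II (both < −ε, continual loss), III
  (gain-then-loss), IV (loss-then-gain).
- **Behavior**: SIR = time with target / time without; susceptible
  SIR < 1, resilient SIR ≥ 1; exclusions at no-target time < 1 s or
  SIR > 300; sucrose preference = 100·s/(s+w).

See `vignettes/methods.Rmd` for the full model description and design
rationale.

## Worked example

Simulate a complete input bundle (peak BEDs per replicate and condition,
gene model GTF, count and expression TSVs, behavior CSV, planted truth)
and run the whole chain:

```r
library(stressDMR)
simulate_all(sim_config(seed = 1), "simdata")
manifest <- run_full_analysis(default_run_config("simdata"), "results")
```

The run logs per-stage record counts:

```
[peaks_in_susceptible] 747 records
[consensus_susceptible] 234 records
[peaks_in_control] 702 records
[consensus_control] 219 records
[gained_susceptible] 40 records
[lost_susceptible] 25 records
[quantified_regions] 310 records
[annotated] 65 records
[genic] 58 records
[concomitant_classified] 58 records
[top_candidates] 11 records
[temporal_profiles] 1000 records
[behavior_scored] 222 records
```

Reading this: each condition's ~750 replicate peaks collapse to ~220–234
consensus peaks; differential calling recovers exactly the 40 planted
gained and 25 planted lost regions (the generator's truth.json confirms
the ids); 58 of the 65 annotated susceptible differential regions are
genic and get classified against expression; 11 genes survive the
cross-age 0.25-LFC candidate filter; the 222-animal cohort is scored
with 2 injected records excluded. Outputs land as BED/TSV/CSV files plus
`manifest.json` recording parameters, input checksums and counts; a
rerun on the same inputs is byte-identical.

The same stages are exposed individually (`consensus_peaks`,
`call_differential`, `condition_specific`, `overlap_regions`,
`normalize_and_lfc`, `annotate_regions`, `classify_concomitant`,
`classify_trajectory`, `score_behavior`, ...), and
`inst/cli/stressdmr.R` provides `simulate` / `run-all` shell
subcommands.

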