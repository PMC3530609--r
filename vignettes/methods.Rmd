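---
title: "Methods: from probe remapping to visual motor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from probe remapping to visual motor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The package implements an analysis chain that links eye gene expression to
the maturation of visual function in larval zebrafish: a custom microarray
re-annotation, moderated differential expression between developmental
stages (3, 4, 5 days post-fertilisation, dpf), a Splicing-Index gate for
gene-level aggregation, cross-species functional enrichment and disease
locus mapping, and quantification of the visual motor response (VMR). A
seeded generator produces synthetic inputs with the same statistical
structure, so every stage is testable without external downloads. This
vignette describes each model, its assumptions, the tunable parameters, and
the design choices made where the method left room.

## Re-annotation and probe sets

Transcript models (CDS exons only) from several source databases are
redundant: the same locus appears under different accessions with slightly
different exon boundaries. `clusterTranscripts()` merges them into genes by
the rule that two transcripts belong to one gene iff they are connected —
directly or transitively — by at least one base pair of coding-exon overlap
on the same chromosome and strand. Internally coordinates are 0-based
half-open (GFF3's 1-based inclusive convention is converted at I/O), the
overlap graph is built with `GenomicRanges::findOverlaps`, and components
come from `igraph`. Antisense overlap does not connect genes by default
(coding exons of antisense transcripts are distinct genes); set
`ignoreStrand = TRUE` to change that. Gene ids are assigned
deterministically by chromosome, hull start, then smallest member id, so
the output is invariant to input order.

Probes (25-mers, coordinates only — no stage consumes sequence content) are
kept by `filterProbeAlignments()` only when perfect (0 mismatches),
genome-unique (one hit), fully inside a CDS exon, and assignable to one
gene cluster. This is the strictest defensible reading of "problematic
probes removed"; every removal is logged with a reason code.
`buildProbeSets()` then groups retained probes by their *exact* set of
covered transcripts, giving transcript-level probe sets: a gene whose
transcripts differ in exon content can own several probe sets, which is
what makes alternative-splicing detection possible downstream. Groups below
`minProbes` (default 3 — below that a robust summary is statistically
meaningless) are dropped and reported.

Cross-species annotation: `filterHomologHits()` keeps BLAST-style hits with
at least 30% identity over at least 30% of the query length (both bounds
inclusive; the length bound is evaluated in integer arithmetic so exact
boundary hits never fall to floating-point rounding) and returns the
highest-bitscore survivor per query, ties broken by e-value then subject
id. `combineAnnotations()` unions zebrafish term membership with membership
transferred from the human side through the homolog map.

## Expression model and differential expression

Intensities arrive on the linear scale. `quantileNormalize()`
log2-transforms and maps every column onto the mean sorted profile
(`limma::normalizeQuantiles`, ties receive the mean of their destination
quantiles). `summarizeProbeSets()` fits the additive probes-by-samples
model by median polish (at most 10 sweeps, tolerance 1e-6) and reports
overall plus column effects — an RMA-style robust summary without the
sequence-affinity background model, which needs probe sequences and is out
of scope here. Probe sets whose maximal log2 intensity stays strictly below
6 in every sample are removed (`lowSignalFilter()`).

The test is a moderated two-sample t: per probe set, the pooled residual
variance \(s_g^2\) on \(d_g = n_1+n_2-2\) df is shrunk toward a prior,
\(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)\), and
\(t = \Delta/(\tilde s\sqrt{1/n_1+1/n_2})\) is referred to \(d_0+d_g\) df.
`fitVariancePrior()` estimates \((d_0, s_0^2)\) by moment matching on
\(\log s_g^2\) (digamma/trigamma equations, Newton inversion of the
trigamma); when the observed log-variances show no excess dispersion the
prior df is infinite and all posterior variances collapse to a common
value. The test suite checks this estimator against `limma::fitFDist` and
the full pipeline against `limma::eBayes`, but the implementation is
independent. P-values are Benjamini-Hochberg adjusted, and a probe set is
called up iff q < 0.05 and linear fold change ≥ 1.5, down iff q < 0.05 and
fold change ≤ 0.67 — asymmetric exactly as stated, on the scale
\(2^{\Delta}\) of the difference of log2 means.

For genes with several probe sets a Splicing Index is computed per probe
set: its log2 fold change minus the gene's *median* probe-set fold change.
The exact centring was an open choice (the originating definition is in
prior work not restated here); the median makes the index of a
two-probe-set gene symmetric and robust for larger genes, and mean-centring
is available via `center = "mean"`. If every index lies inside [-1, 1] the
probe-set log2 expressions are averaged per sample and the moderated test
is re-run at the gene level, with q-values recomputed over the gene-level
set — multiplicity belongs to the reported unit. Otherwise the gene is
flagged and its probe sets reported separately as candidate alternative
splicing. Samples are clustered on 1 − Pearson correlation of row z-scores
with average linkage, matching the usual expression heat-map convention.

## Enrichment and disease loci

`fisherEnrichment()` is the one-sided hypergeometric upper-tail test
(enrichment only; depletion is not reported), with BH adjustment within
each namespace (GO_BP, GO_CC, GO_MF, KEGG), significance at q < 0.05. The
universe defaults to the genes represented by probe sets surviving the
signal filter — only measured entities are tested; any gene set can be
passed instead. GO ancestor propagation is deliberately not performed: the
catalog is taken as given. Up- and down-regulated sets are tested
separately.

`resolveCytobands()` turns locus strings ("6q14-q16.2", "Xp22",
"Xq28-qter", "17q") into intervals against a UCSC-format band table: a
label covers every band it prefixes and a range spans first-band start to
last-band end. `diseaseLocusCandidates()` lists DE genes whose best human
homolog's interval overlaps a disease locus by at least 1 bp — any overlap
counts, including straddling the boundary.

## Visual motor response

Traces are per-larva activity at 1 Hz with a light-state channel;
`binActivity()` integrates finer-grained input into 1-second bins
(conserving totals, light state by within-bin majority). The protocol is
30 min settling followed by alternating 20-min light OFF/ON phases (four
cycles by default). For each transition after settling, `vmrPeaks()` takes
the peak as the maximal 1-s bin within `peakWindow` (default 30 s; the
windowed mean is available via `peakStat = "mean"` — which of the two the
original assay used is not recoverable, and the maximal bin is the stricter
reading of "peak") and the baseline as the mean over `baseWindow` (30 s)
before it. Window lengths are not dictated by the assay description; 30 s
comfortably contains the transient burst while staying clear of the
adjacent transition. Peaks are averaged per larva across that transition
type's occurrences before any group statistic, and normalized peaks
(peak/baseline, the fold increase in locomotor activity) use per-transition
baselines. Larvae with a zero baseline get a missing normalized value —
excluded and counted, never infinite. `groupCompare()` applies the
two-sided Wilcoxon rank-sum test (exact null for combined n ≤ 20 without
ties, normal approximation with tie correction otherwise) or Welch's t,
with Bonferroni correction across the comparisons in one report;
`recoveryCompare()` applies the same machinery to pre- versus post-washout
summaries.

## The synthetic generator

`simConfig()` fixes the study conditions: three stages × three biological
replicates, 11 probes per probe set, probe-set baselines Uniform(4, 12) in
log2 (low-signal fraction at Uniform(2, 3.5), safely under the floor of 6),
per-probe offsets Uniform(-0.5, 0.5) drawn once, log2 noise Normal(0,
0.35), 7.5% of probe sets spiked at |log2FC| = 1.5 (full effect at 5 dpf,
half at 4 dpf, random sign per gene), splice-flagged genes spiked
discordantly at +1.25/-1.25 (Splicing Index magnitude 1.25 by
construction), one spiked 30-gene pathway with half its members DE, homolog
hits engineered exactly at and just below the 30/30 boundary, disease loci
built to contain or avoid DE homologs, and noiseless or Poisson baseline
traces with a burst of known amplitude in the first second after every
light transition. One RNG stream per output family is derived from the
master seed, so regenerating one family never perturbs another, and an
identical configuration yields byte-identical files.

What the generator does *not* emulate — and hence what passing tests do not
show about real arrays: probe GC-content affinity bias, spatial artefacts
and background (there is no image-level simulation), cross-hybridisation,
the heavier-than-normal tails of real log intensities, and correlated
biological replicate structure. The intensity noise model is a stand-in,
not an estimate of the real arrays' noise.

Two numerical consequences of the pipeline are worth knowing. First,
quantile normalization compresses genuine fold changes at the extreme ends
of the intensity distribution (the largest value of every column maps to
the same normalized value); the splicing-gate recovery checks therefore run
on plain log2 summaries — the generator puts all arrays on a common scale
by construction — while normalization is verified by its own invariants.
Second, near-zero residual variances (possible for degenerate rows) are
floored at 1e-10 with a warning rather than producing infinite t-values.

## Problem sizes used by the checks

The recovery checks run at sizes chosen to make the claims sharp yet quick
to verify: the oracle comparisons use 200 random clustering instances of up
to 200 transcripts, all permutations of up to 8 p-values, a hypergeometric
grid up to N = 60, and 20-sample UPGMA instances; the false-discovery-rate
and sensitivity simulation uses 2,000 probe sets with 150 spiked at
|log2FC| = 1.5, sd 0.35, three replicates per group, averaged over 20
seeds; the splicing gate runs 10 seeds at 300 probe sets; the enrichment
recovery uses a 3,000-gene universe with 300 DE genes and the spiked
30-gene term over 20 seeds. `scripts/acceptance.R` recomputes all of these
from scratch.

## Known limitations

The pipeline fixes a two-group contrast (default 5 vs 3 dpf); time-course
trend tests and multi-factor models are out of scope. GC-RMA's
sequence-affinity background is replaced by quantile normalization plus
median polish. GO topology is ignored. The enrichment universe choice
(expressed vs annotated genes) materially affects p-values and is exposed
as an argument. Wilcoxon p-values with heavy ties rely on the normal
approximation.
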