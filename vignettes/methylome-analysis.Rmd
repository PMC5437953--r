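---
title: "Quantifying vertebrate and invertebrate methylomes from WGBS call tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertebrate and invertebrate methylomes from WGBS call tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylomap)
```

## The analysis problem

Whole-genome bisulfite sequencing (WGBS) reads out cytosine methylation:
after bisulfite conversion, unmethylated cytosines appear as thymines, so
each aligned read contributes a "methylated" or "unmethylated" call at each
cytosine it covers. Downstream of alignment and call extraction, the
analytical questions are the same across species: how methylated is the
genome globally and per CpG dinucleotide; how is methylation organised along
chromosomes, over transposable elements (TEs), and around genes; and how
does promoter methylation relate to transcription. These questions
discriminate sharply between the two known architectures of animal
methylomes. Vertebrate somatic methylomes are pervasively methylated
(roughly 70–80% at CpG sites), with hypomethylated transcription start
sites (TSSs) whose methylation is inversely related to expression, and
hypermethylated TEs. Invertebrate "mosaic" methylomes are mostly
unmethylated, with methylated domains biased toward gene bodies and no
TSS–expression relationship. methylomap implements the downstream
quantitation needed to place a methylome on that axis, working entirely
from per-cytosine call tables, gene and repeat annotation, and per-gene
expression counts.

## Data model and conventions

The universal substrate is the **site call table**: one record per
(scaffold, position, strand) with methylated and unmethylated call counts
and the sequence context (CG, CHG, CHH), plus a manifest of scaffold
lengths and an optional set of scaffolds designated mitochondrial. Readers
are provided for the per-cytosine (CX) report dialect and the six-column
coverage dialect; the latter encodes neither strand nor context, so records
are taken as CG-context + strand calls by a documented, overridable
convention, and its percentage column is always recomputed from the counts.

All coordinates are 1-based inclusive throughout, both at the file boundary
(the native convention of every dialect read or written here, after
converting the 0-based starts of UCSC rmsk tables) and internally, where
interval work is delegated to GenomicRanges/IRanges, which share that
convention. Keeping one convention end to end removes the main source of
off-by-one drift.

A CpG dinucleotide carries a methylatable cytosine on both strands; the two
records are pooled into one site anchored at the + strand C
(`merge_symmetric_cg()`), and membership of a site in any interval is
decided by that single anchor coordinate, so a dinucleotide straddling a
window edge is counted exactly once.

Two distinct summaries are deliberately both exposed, because each answers
a different question:

* **call-weighted** percentages (total methylated calls over total calls)
  for global levels and per-interval quantitation — the arithmetic of
  aligner mapping reports, robust at low depth;
* the **unweighted mean of per-site M** (M = 100·n_meth/n_calls per pooled
  site) for trend profiles and site-level distributions, where each CpG
  should weigh equally regardless of its depth.

## Filters and tunable parameters

Every inclusion rule is a parameter with a package-wide default, carried in
one threshold block that is echoed (with its hash) into every report:

| parameter | default | unit | role |
|---|---|---|---|
| `min_site_calls` | 5 | calls | minimum pooled calls for a per-site M |
| `window` | 2000 | bp | running-window and gene-body window width |
| `min_window_calls` | 50 | calls | minimum calls per gene-body window |
| `tss_width` | 200 | bp | TSS window centred on the mRNA's first nucleotide |
| `exclude_5prime` | 1000 | bp | 5' gene span excluded from body methylation |
| `flank` | 10000 | bp | trend-profile flank width |
| `smooth_k` | 100 | points | running-mean width for flank smoothing |
| `scaffold_min` | 277000 | bp | scaffolds at or below this length are dropped |
| `mapq_min` | 60 | — | uniquely-aligned read threshold for RNA-seq counts |

Notes on the less obvious choices:

* The scaffold filter is a strict inequality ("larger than"), so a
  scaffold of exactly the threshold length is dropped; mitochondrial
  scaffolds are exempt because the mitochondrial genome is analysed as its
  own compartment. Which scaffold names are mitochondrial varies by
  assembly, so the set is user-supplied rather than guessed.
* A 200 bp window cannot be centred symmetrically on a single nucleotide;
  the extra base is placed downstream, strand-aware, deterministically.
* Running windows default to non-overlapping tiling (step = size), which
  covers the genome exactly once without double-weighting calls; an
  overlapping step is available. The terminal partial window of each
  scaffold is retained and flagged, so coverage of the genome is complete.
* Gene bodies are tiled strand-aware from (first nucleotide +
  `exclude_5prime`) toward the 3' end; the gene value is the unweighted
  mean over windows passing the call threshold. Genes shorter than the
  exclusion, or with no passing window, are excluded with a named reason.
* Trend profiles standardise each feature to 100 body bins (the bin count
  is a resolution choice, not a biological one, and is configurable) and
  key flank sites by bp offset from the feature edge; the per-offset mean
  series is smoothed with a centred 100-point running mean whose window
  truncates at the series ends, so the series keeps its length, a constant
  series is unchanged, and `smooth_k = 1` is the identity. Sites weigh
  equally across features by default (`weight_features = TRUE` averages
  within features first); empty bins stay undefined rather than being
  interpolated.
* Expression values are exonic read counts, corrected for DNA
  contamination and then by transcript (summed exon) length. The
  contamination correction estimates a uniform background density from
  reads falling entirely outside gene spans and subtracts density ×
  exonic length per gene, floored at zero; this is a declared,
  parameterised model of the correction, since the field's GUI tools do
  not document their exact algorithm. Quintiles are assigned by stable
  (value, gene id) ranking, label 5 = highest; when the gene count is not
  divisible by five the extra genes go one each to the lowest quintiles,
  so sizes differ by at most one and ties never reorder across runs.

## Conversion efficiency

In genomes whose true non-CG methylation is negligible, apparent CHG/CHH
methylation measures bisulfite conversion failure, so
`conversion_efficiency()` returns 100 minus the call-weighted nuclear
non-CG percentage — a lower bound on the true conversion rate. It is
reported alongside every global summary because unconverted reads inflate
every other number in the analysis.

## Bootstrap depth calibration

How many CG calls does a low-coverage library need before its global
methylation estimate is trustworthy? The package answers by resampling
reads (the natural unit of correlated calls) with replacement from a deep
dataset until a target call count is reached — the last read is kept whole,
so targets may be overshot by at most one read — recomputing global CG
methylation per iteration, and taking the half-width of the central 99%
interval (0.5th to 99.5th percentiles, 1000 iterations by default) as the
margin of error at that depth. An asymptotic curve is then fitted by least
squares. Both y = a/x and y = a/√x are implemented; the default is the
square-root form, because for independent calls the binomial standard
error scales as 1/√n — the package's own simulations recover a log–log
slope of −0.5 — and because only that form makes a constant near 2.2
(on the methylation-fraction scale) consistent with a margin near ±1.8
percentage points at 15,000 calls. The fitted constant is reported on the
same scale as the input half-widths; fits of fraction-scale and
percentage-point-scale curves differ by exactly a factor of 100, a unit
ambiguity worth checking whenever constants are compared across analyses.
Within-read correlation can only inflate the margin relative to the
independent-call closed form, which the test suite checks on clustered
read pools.

## What the synthetic generator emulates

Every stage is testable without external data through a seeded generator
(`synth_config()`, `simulate_methylome_dataset()`). It emulates, by
construction:

* a genome of scaffolds with CpG anchors at a configurable density
  (default 20/kb), non-overlapping multi-exon genes, and LINE/SINE
  elements confined to non-exonic territory;
* **vertebrate mode**: per-site methylation probabilities drawn from a
  Beta distribution with mean 0.74 and concentration 2 (a bounded,
  unimodal family parameterised by mean and concentration; this setting
  reproduces the regime in which most CpGs are ≥80% methylated, under a
  tenth are unmethylated, and the global level sits in the low 70s), TE
  sites around 0.85, and TSS windows drawn per gene from a two-component
  mixture whose methylated-component weight falls from 0.70 in the lowest
  expression tier to 0.02 in the highest — methylated as a unit, which is
  what makes the low-tier TSS distribution bimodal;
* **mosaic mode**: methylated domains (mean level 0.80) seeded
  preferentially on gene bodies until they cover 25% of the genome, over
  a 0.02 background — mixture arithmetic puts the global level near
  21.5%, the regime of invertebrate somatic methylomes — with no TSS
  treatment at all;
* calls at Poisson depth (default mean 20, split over the two strands),
  each methylated with probability p + (1−p)·f where f is the conversion
  failure rate (default 0.01); non-CG cytosines are emitted with true
  p = 0, so their observed methylation estimates f;
* read records covering runs of consecutive CpG sites (mean two calls per
  read), the correlated-call structure the bootstrap resamples;
* negative-binomial expression counts with tier means spanning 1 to 256
  reads per exonic kb, a 5% low-mapping-quality read fraction, and
  uniform DNA-contamination reads at 0.2 reads/kb.

The default genome is 2 × 250 kb with 100 genes — small enough that the
full simulate-and-recover loop runs in seconds, large enough that global
estimates carry ~200,000 calls and quintile statistics rest on 20 genes
each. What passing tests on this generator demonstrate is that the
*quantitation* is correct and that the two architectures are recovered
when present; they do not demonstrate robustness to features real data
have and the generator does not: sequence-composition biases, mapping
artefacts, copy-number variation, partially methylated domains,
non-uniform contamination, or true non-CG methylation.

## Numerical and degenerate-input conventions

Percentages are undefined (NA, flagged) rather than zero wherever the
denominator is empty: strata without calls, intervals below their call
threshold, bins without sites. Duplicate records at one (scaffold,
position, strand), duplicate gene identifiers, and intervals whose
scaffold is missing from the manifest are errors, not warnings. The
two-sample location test defaults to the unpooled-variance (Welch)
variant — the variant used is recorded in its output, since reported
p-values are not comparable across variants — and two identical constant
groups return p = 1 by convention. All randomness flows from explicit
integer seeds; reports echo their threshold block and its hash so that
cross-dataset tables (`compare_datasets()`) can refuse mismatched
definitions instead of silently comparing different statistics.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config("vertebrate", seed = 1)
ds <- simulate_methylome_dataset(cfg)
report <- run_pipeline(ds$calls, ds$genome$genes, ds$genome$repeats,
                       ds$expression$counts,
                       thresholds = list(scaffold_min = 100000))
print(report)
bc <- bootstrap_margin(ds$reads, iterations = 200, seed = 1)
predict_margin(bc$a, bc$model_form, 15000)
```

The same sequence with `synth_config("mosaic", seed = 2)` produces the
invertebrate contrast; `compare_datasets()` aligns the two reports row by
row and flags the statistics that separate the architectures.

## Known limitations

The package consumes post-alignment call tables; trimming, alignment,
deduplication and repeat masking are upstream tools' responsibility.
Differential methylation between conditions, CpG-island or enhancer
detection, smoothing/imputation of site-level methylation, and
isoform-level expression are out of scope. The contamination correction is
a uniform-background model; structured contamination will leak into
counts. TSS definitions inherit annotation quality: where 5' ends are
poorly annotated, the TSS dip will blur accordingly.
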