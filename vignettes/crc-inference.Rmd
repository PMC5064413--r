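---
title: "Inferring core regulatory circuitry from cofactor occupancy"
author: "coreCRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring core regulatory circuitry from cofactor occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreCRC)
```

## The problem

A cell's transcriptional program is maintained by a small set of
interconnected, typically autoregulatory transcription factors (TFs) — its
core transcriptional regulatory circuitry (CRC).  These master and pioneer
TFs recruit large coactivator machines: the Mediator complex (assayed by
ChIP of its MED1 subunit), the Cohesin ring (SMC1A) and the Cohesin loader
NIPBL, which together mark active enhancers and promoters.  A recurring
inference strategy is therefore *cofactor-centred*: map where Mediator,
Cohesin and NIPBL sit genome-wide, then ask which sequence-specific TFs (i)
co-occupy those regions, (ii) have binding motifs enriched in them, and
(iii) bind their own gene's regulatory region together with the cofactors.
TFs passing all three filters are the leading CRC candidates.

`coreCRC` implements this strategy as a tested pipeline over standard file
formats (BED peaks, GTF/BED12 gene models, FASTA genome, plain-text PWM
collections, ChromHMM-dense segmentations, GMT gene sets), plus a
synthetic-data generator that plants a known CRC so the whole chain can be
validated end to end with no external data.

## Pipeline stages and their statistics

**Occupancy structure.**  All peak sets are merged into atomic union
regions; a binary matrix records which regulator overlaps each region
(`build_occupancy_matrix()`).  Binary membership rather than read densities
is used deliberately: it requires no signal files, and the qualitative
structure of interest — which regulators co-vary — is a property of
membership patterns.  Principal components are extracted by SVD of the
column-centered matrix (`pca_regulators()`); columns are not
variance-scaled because all variables share the 0/1 scale (scaling is
available via an argument).  The *variable factor map* coordinates are the
Pearson correlations between each regulator's column and the region scores.
The SVD sign ambiguity is fixed by forcing the lexicographically smallest
regulator to non-negative coordinates, making outputs reproducible across
platforms.  Pairwise occupancy correlations (`regulator_correlation()`)
report Pearson's R with a p-value from the t transform with n − 2 degrees
of freedom.  Per-regulator densities of component-1 scores are rescaled to
a maximum of exactly 1; `is_bimodal()` flags a split distribution when two
local maxima are separated by a valley at least 20% below both peaks — the
signature of Cohesin's two subpopulations (CTCF-associated versus
Mediator/NIPBL-associated), which `partition_by_ctcf()` separates
explicitly by CTCF overlap.

**Interval conventions.**  All coordinates are 0-based half-open (the BED
convention); GTF input (1-based closed) is converted on read.  Overlap
means ≥ 1 shared base (`a.start < b.end && b.start < a.end`); abutting
intervals merge (they are contiguous in base space); chromosome names are
matched verbatim.  "Percentage of overlap" counts regions of the query set,
not shared base pairs, because the TF ranking is keyed on each cofactor's
regions; a base-pair Jaccard variant is exposed via
`overlap_fraction(method = "jaccard")`.  The colocalization heat map orders
regulators by average-linkage clustering under the distance 1 − Pearson
correlation between rows of the overlap matrix; linkage and distance are
recorded in the output metadata since different choices change only the
display order, not the fractions.

**Motif enrichment.**  PWMs are loaded from HOCOMOCO-style count matrices
with a per-cell pseudocount (default 0.8) applied before normalization.
Scanning uses log2-odds scores against a genome-estimated background;
both strands are scanned and windows containing N are skipped.  The hit
threshold is a quantile of the *exact* score distribution of a background
window, computed by dynamic programming over positions on a 10⁻³-bit
lattice.  The default quantile is 0.9999 (per-window exceedance 10⁻⁴, the
conventional stringency of genome-scale scanners).  A more permissive
threshold such as the 99.5th percentile is unusable here: with ~400 bp
regions and ~700 scanned windows each, a per-window exceedance of 5×10⁻³
drives the per-region "has ≥ 1 hit" indicator to ≈ 0.9 for *every* PWM, and
a region-level statistic cannot discriminate anything.  Enrichment per
motif is an upper-tail binomial test on the number of target regions with
≥ 1 hit, with the background hit rate estimated from length-matched regions
shuffled to random non-target positions and floored at 1/(2·n_bg) to avoid
zero rates.  This statistic was chosen over soft-affinity scores because it
is transparent, exact, and directly testable by summation; "most frequent
motifs" is precisely a hit-count notion.  Ranking is by ascending p, ties
broken by descending hit count then motif id.

**Candidates and circuitry.**  TFs are ranked by the mean fraction of
MED1/SMC1A/NIPBL regions their peaks overlap (`rank_tf_overlap()`, top 20
kept).  Candidates are the top-k TFs whose gene symbol matches a top-k
enriched motif (case-insensitive, through a small shipped alias table that
maps informal protein names such as ERa to gene symbols such as ESR1); ChIP
evidence is mandatory, so a motif without a peak set can never create a
candidate.  The regulatory window of a gene runs from 10 kb upstream of the
TSS to the end of the gene, strand-aware and clamped at zero
(`regulatory_window()`).  A directed edge A → B is drawn when any peak of A
overlaps B's window (`build_circuitry()`); a self-edge marks
autoregulation.  The leading candidates are the autoregulatory TFs whose
own window also overlaps the MED1 ∩ SMC1A ∩ NIPBL regions — the
conjunction of "regulates its own gene" and "does so together with the
cofactors".  Promoter-level statements are subsumed by the window rule; no
separate promoter-only edge class exists.  Edges are unweighted but carry
peak counts as metadata.

**Peak-to-gene assignment and pathways.**  A peak is assigned to the gene
whose regulatory window contains the peak midpoint (nearest TSS wins among
overlapping windows); otherwise to the nearest TSS within 50 kb; otherwise
it stays unassigned.  The window-then-nearest rule and its cap are package
choices (annotation tools differ here) and are recorded in run reports.
Pathway enrichment is the one-sided hypergeometric (equivalently Fisher
exact) upper tail per gene set, restricted to the chosen universe (default:
all genes in the annotation), with Benjamini–Hochberg q-values across
tested sets and significance tiers at raw p < 0.05/0.01/0.001.

## What the synthetic generator emulates

`generate_bundle()` draws, from a single seeded RNG stream, a complete
input bundle whose defaults *are* the study conditions used throughout the
tests:

* two 500 kb chromosomes of i.i.d. sequence at GC 0.41, 60 genes in
  non-colliding slots (gene bodies 0.8–1.2 kb);
* 150 cofactor sites (log-normal widths, median 400 bp) at promoters of
  active genes and intergenic enhancer positions.  Every site carries MED1;
  one Bernoulli draw with `coocc_prob = 0.8` adds both SMC1A and NIPBL
  (otherwise each joins independently at rate 0.1).  This makes the
  probability of a full trio equal to `coocc_prob` and the MED1→NIPBL
  overlap fraction ≈ q + 0.1(1 − q);
* CTCF sites disjoint from cofactor sites, sized so that 40% of SMC1A
  peaks sit at CTCF-only sites — the planted origin of Cohesin's bimodal
  component-1 distribution;
* 3 CRC TFs with sharp length-10 motifs planted in the genome at the
  centre of 60% of cofactor sites (plus scattered background copies at 5%
  of the site count), peaks at those sites, and peaks in every CRC gene's
  window (the self-peak only for the autoregulatory subset, all three by
  default); 27 decoy TFs with 60 uniformly random peaks each; 30 decoy
  PWMs of moderate information content;
* decoy motifs are mapped to TF symbols *without* ChIP peak sets,
  emulating the real situation that motif databases cover far more TFs
  than any cell's ChIP compendium — and making exact recovery of the
  planted candidate set a well-posed expectation;
* a segmentation that tiles each chromosome exactly (promoter sites →
  `1_TssA`, enhancers → `9_EnhA1`, CTCF sites → `16_CTCF`, elsewhere
  `18_Quies`), and a GMT whose planted pathway is the genes with a
  promoter cofactor site, plus random decoy sets.

Per-regulator peak boundaries are jittered ±40 bp around each site so the
sets overlap without being identical.  What the generator does *not*
emulate: read-level noise, repeat sequence, peak-caller artefacts,
signal-strength variation, enhancer–promoter looping, or correlated decoy
binding.  Passing tests therefore demonstrate correctness of the inference
chain under its stated assumptions, not robustness to every failure mode of
real ChIP data.

## Numerical and degenerate-input choices

Exact score distributions use a 10⁻³-bit lattice (error ≤ L/2 · 10⁻³ bits
per window score, negligible against typical thresholds).  Zero-variance
occupancy columns produce a warning and zero variable coordinates rather
than an error in PCA, but a hard error in pairwise correlation where the
quantity is undefined.  Perfect correlations clamp the p-value to the
smallest positive double so that p ∈ (0, 1] always holds.  Empty
CTCF input yields an empty "with CTCF" part; an empty co-occupancy set
skips the motif stage with a warning; an empty candidate intersection warns
and produces an empty graph.  Ties are broken deterministically everywhere
(symbols and ids lexicographically, distances then gene ids in peak
assignment), so identical inputs give byte-identical outputs.

## Problem sizes used in the test suite

The shipped suite validates the interval algebra, the hypergeometric and
binomial tails, BH adjustment and the PWM machinery against brute-force
oracles (per-base boolean arrays, all-pairs scans, exhaustive enumeration
of draws, hand-written summation), and then runs the full pipeline on 20
seeded default bundles for structure recovery and planted-CRC recovery, and
200 null simulations (universe 2000, target 200, 50 pathways of 40 genes)
for type-I calibration.  The null simulation sizes were chosen so that the
discreteness of the hypergeometric tail — which makes small-sample rejection
rates conservative — is mild at the 0.05 level.

## Known limitations

* The enrichment background is an i.i.d. base model; dinucleotide or
  Markov backgrounds are out of scope, so CpG-related biases in real
  genomes are not corrected.
* Candidate matching is symbol-based; paralogous motifs (shared family
  consensus) can cross-match in real databases and are only handled as far
  as the alias table goes.
* The pipeline starts from called peaks; peak calling itself, signal
  tracks and alignment are out of scope.
* Manual, rule-external candidate additions (e.g. including a pioneer
  factor found across all cell types even where the autoregulation filter
  does not select it) are supported only as flagged annotations in the run
  report (`extra_candidates`), never as silent automation.
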