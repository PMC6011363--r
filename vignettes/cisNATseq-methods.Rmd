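---
title: "Methods and models in cisNATseq"
author: "cisNATseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in cisNATseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisNATseq)
```

# Scope

cisNATseq implements the computational core of a gibberellin-response
transcriptome analysis in a fast-growing grass: genome-wide discovery and
classification of cis-natural antisense transcripts (cis-NATs) from
full-length transcript models, strand-specific quantification and
negative-binomial differential expression, alternative-splicing (AS) event
enumeration and differential testing, hypergeometric GO enrichment, and
the two leaf-physiology formulas used to phenotype hormone treatments.
Every stage is exercisable on synthetic data with planted truth, so the
package is testable end to end without any sequencing download.

Read alignment, transcript assembly, and coding-potential prediction are
deliberately upstream of this package: it consumes transcript models
(GTF), fragment or junction counts (TSV), an optional noncoding flag, and
a gene-to-term table.

# cis-NAT discovery

## Transcript units

Transcripts whose genomic spans (introns included) overlap are grouped
into *transcript units* by single-linkage closure: any chain of pairwise
span overlaps of at least `minOverlap` nucleotides joins its members into
one unit.  Clustering is strand-blind on purpose — a unit must hold both
strands of a locus, because that is the within-unit scope for
opposite-strand comparison.  The implementation is a per-chromosome sweep
over spans sorted by start, which for one-dimensional intervals is exactly
the connected-components partition of the pairwise overlap graph; the test
suite checks this equivalence against a brute-force O(n²) union-find
oracle.

`minOverlap` defaults to 1 nt, the most permissive reading of
"overlapping coordinates"; it is exposed because some studies require
larger overlaps.  Overlap is computed on spans, not exon intersections:
an antisense partner frequently overlaps only the intron of its sense
mate, and exon-gated pairing would silently drop such pairs.  The
exon-level intersection length is still reported (`exonic_overlap`) for
downstream filtering.

## Overlap classification

For a plus-strand span P = [pS, pE] and minus-strand span M = [mS, mE]
(1-based, closed) that overlap:

* **fully overlapping** — one span contains the other.  Containment
  includes boundary equality: the staggered classes are reserved for
  geometries where each transcript has one end outside the overlap.
* **head-to-head (5'–5')** — otherwise, when mS < pS.  The overlap then
  covers P's 5' end and M's 5' end (divergent promoters).
* **tail-to-tail (3'–3')** — otherwise (M extends past pE); the overlap
  covers both 3' ends (convergent transcription).

These three outcomes are mutually exclusive and exhaustive for any
overlapping opposite-strand pair; the acceptance suite verifies agreement
with an independent oracle that tests membership of each terminal base in
the overlap interval, over 10,000 random geometries.

A pair is labelled **lncNAT** when either member carries the noncoding
flag (produced upstream by a coding-potential tool and read from the GTF
attribute `noncoding`).

## Coordinate conventions

Internally all features are `GRanges`/`GRangesList` objects, i.e. 1-based
closed coordinates — the Bioconductor convention, chosen so that every
interval operation delegates to IRanges.  Conversion happens only at
format boundaries: GTF is read/written 1-based inclusive, BED 0-based
half-open, and junction-count TSVs use the 0-based donor/acceptor
convention in which the intron is `[donor, acceptor)` (`junctionKey`
documents the mapping).

# Alternative splicing

## Event taxonomy

Within each gene, all ordered pairs of same-strand isoforms are compared:

* **IR** — an intron of one isoform fully contained in an exon of the
  other; the alternative region is the retained intron.
* **ES** — an internal exon of one isoform absent from the other with
  both flanking junction anchors shared, i.e. the other isoform carries
  the direct exclusion junction.
* **AltA / AltD** — two introns sharing exactly one boundary.  The labels
  follow transcription direction: the acceptor is the intron boundary
  nearer the 3' end of the transcript, so a genomic-right shift is AltA
  on "+" but AltD on "-".  Two consequences are property-tested: flipping
  the strand of a gene at fixed coordinates swaps AltA and AltD (IR and
  ES unchanged), while the mirror transcript — coordinates reflected
  *and* strand flipped — has identical transcription-direction geometry
  and leaves every type invariant.

One disambiguation rule is needed that the four definitions alone do not
give: the exclusion junction of an ES event shares one boundary with each
flanking inclusion junction and would otherwise also match the AltA/AltD
pattern.  A boundary-shift pair is therefore only called AltA/AltD when
the shift region does not fully contain an exon of the shorter-intron
isoform.  Events are deduplicated across isoform pairs by (type, region,
junction sets), so multi-isoform genes emit each event once.

Mutually exclusive exons and alternative first/last exons are out of
scope — the four types above are the inventory this workflow targets.

## Support counting and PSI

Inclusion support is the fragment count summed over the inclusion
junctions — for IR, the read coverage of the retained intron — and
exclusion support the count on the exclusion junction(s).  Because the
inclusion form of an ES event owns two junctions while the exclusion form
owns one, raw counts overweight inclusion; PSI therefore divides each
side by its number of distinct supporting junction positions (for the IR
coverage term, by region length / read length) before forming
inclusion / (inclusion + exclusion).  Raw counts are reported alongside;
events with zero total support get `NA` PSI and are untestable.

## Differential test

Replicates are pooled within condition and a binomial likelihood-ratio
test compares one shared PSI against one PSI per condition, with the
statistic referred to χ²(1).  This deliberately replaces the
rMATS stage of alignment-based workflows: the contribution here is the
event inventory and the P < 0.05 calling rule, not the rMATS
hierarchical model.  The
simplification has a stated cost — between-replicate overdispersion is
not modelled, so p-values are calibrated for binomial sampling around a
per-condition PSI (verified on 5,000 null events) but will be
anti-conservative if biological replicates disagree in PSI beyond
counting noise.  Events with pooled total below `minCount` (default 10)
return p = 1 rather than an unstable statistic.

# Quantification and differential expression

Fragment counting is strand-specific: under the dUTP protocol (default
mode `"reverse"`) the recorded fragment strand is the reverse of the
transcript strand and is flipped before matching; counting is exon-aware
by default with a span-level switch for sensitivity analysis.  FPKM is
counts × 10⁹ / (librarySize × exonicLength).  Library-size normalisation
throughout is total-count scaling; TMM is out of scope.

## Dispersion estimation

A common negative-binomial dispersion φ is estimated by the method of
moments: per feature and replicated condition, φ_f = max(0, (v − m)/m²)
on library-size-normalised counts, averaged over conditions, then pooled
across features by the mean.  The pooling mean is *untrimmed* by
default.  This was a deliberate design revision: with three replicates
the φ_f are strongly right-skewed, and a symmetric 20% trim loses about
15% of the dispersion signal (≈0.084 estimated at true φ = 0.1), which
in turn inflates the exact test's null type-I error to ~0.06–0.07.  The
untrimmed mean is nearly unbiased (≈0.097–0.100 at φ = 0.1) and restores
the null fraction of p < 0.05 to 0.044–0.055 in the package's own
calibration simulations; the Poisson case still estimates ≈0.003.  A
`trim` argument remains for heavy-tailed contaminated data.

## Exact test

Differential expression uses a conditional exact test in the spirit of
the classical two-group NB exact test: replicate counts are scaled to a
common library size and pooled; conditional on the pooled total
t = a + b, the two-sided p-value sums the probabilities of all splits
(a', t − a') no more likely than the observed one, with each group's
marginal a negative binomial (pooled group of n replicates: mean n·µ,
size n/φ; φ = 0 degenerates to the Poisson/binomial conditional test).
Ties are included in the rejection sum — the standard exact-test
convention, and what the enumeration oracle asserts.  This is a
behavioural, not bit-exact, stand-in for edgeR's qCML machinery; the
contract is statistical calibration, verified by simulation, and the
suite cross-checks the dispersion estimate against edgeR's common
dispersion on shared input.

Calling rules follow the study: genes need |FC| > 1.5 *and* FDR < 0.01;
NAT transcripts are called on FDR < 0.01 alone.  log2 fold changes add a
pseudocount of one normalised count.  BH correction is delegated to
`stats::p.adjust`.

# Enrichment and physiology

GO enrichment is the upper-tail hypergeometric test per term with BH
correction and a corrected-p ≤ 0.05 rule; the gene-to-term map is an
input, not computed.  The two physiology formulas are implemented
verbatim and vectorised: Arnon total chlorophyll
(20.2·A645 + 8.02·A663)·V/W — total chlorophyll only, no a/b split — and
open-system net photosynthesis
(CO2R − CO2S·(1000 − H2OR)/(1000 − H2OS))·fda.  Units are documentation
only; no conversion engine is attempted.

# The synthetic-data generator

The generator's defaults *are* the emulated study conditions: two
conditions (H2O mock vs GA3), three biological replicates, dUTP
strand-specific libraries of 10⁶ fragments, 125-nt reads, 30 NAT loci
split evenly over the three classes, 40 two-isoform AS genes split evenly
over the four types, 2,000 expression features of which 10% are
differential at |log2FC| = 2, NB dispersion 0.1, and 200
junction-supporting fragments per AS event per condition with a PSI shift
of 0.3 for differential events.  Values the design left open (locus
lengths 0.8–2 kb, exon/intron sizes 80–150/100–200 nt, inter-locus gaps
of 1 kb, lognormal relative expression with σ = 1) were fixed once at
desk-realistic magnitudes for a plant transcriptome and are not
revisited.

Geometry is integer arithmetic on one synthetic chromosome; every planted
NAT locus satisfies exactly one class definition and every planted AS
gene realises exactly one event type, with ≥1 kb spacing so no unplanted
overlap arises.  All outputs are deterministic functions of the seed (R's
default Mersenne-Twister stream).

What the generator does *not* emulate — and hence what green tests do not
show about real data: mapping ambiguity and mappability gradients,
fragment-level GC or length biases, >2-isoform genes with entangled
events, overdispersed PSI between biological replicates, and any
sequence-level error model.  Passing the planted-recovery tests means the
algorithms are correct on their own definitions, not that any given
experiment's headline counts would be reproduced from raw reads; those
depend on external aligners and assemblers that are out of scope.

Physiology simulation plants treatment means ordered PAC > H2O > GA3 for
chlorophyll and H2O > GA+PAC > PAC > GA3 for net photosynthesis —
matching the direction of the reported GA effect — with Gaussian noise;
zero-noise configurations reproduce the planted means exactly.

# Numerical choices and degenerate inputs

* Empty intervals, zero-length introns, mixed-strand or unstranded
  transcripts are rejected at construction; downstream code never sees
  them.
* `classifyOverlap` refuses non-overlapping input rather than returning a
  fourth class.
* The exact test rounds pooled scaled counts to integers (the conditional
  distribution is over integer splits); a zero total returns p = 1.
* Tie handling in the exact test uses a 1 + 1e-10 relative tolerance so
  float noise cannot drop the observed outcome itself from the rejection
  sum.
* PSI is `NA`, not 0.5, when no fragment supports either form.
* BH monotonicity and the q ≥ p floor are property-tested.

# Problem sizes

The validation suite runs at desk scale, chosen as the package's own
test design: 10,000 random pair classifications, 500-span clustering,
1,000 planted AS genes, 5,000-feature null calibrations for both the
expression and splicing tests, and a full simulate-then-analyse pipeline
at the default configuration.  All of it completes in a few minutes on a
single CPU.

# Known limitations

* No TMM or GLM/quasi-likelihood machinery; batch structure is out of
  scope.
* The splicing test ignores between-replicate overdispersion (above).
* trans-NATs and nat-siRNA prediction are out of scope.
* The GTF reader performs no isoform collapsing/deduplication; if the
  input contains duplicate transcript models they will pair and count
  independently.
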