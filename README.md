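# cisNATseq

Genome-wide discovery of **cis-natural antisense transcripts (cis-NATs)**
and the analyses that surround them in a hormone-response transcriptome
study: strand-specific differential expression, alternative-splicing (AS)
event detection and testing, GO-term enrichment, and leaf physiology
formulas — with a seeded synthetic-data generator so every stage is
testable end to end without sequencing data.

The package is aimed at plant transcriptomics analysts who have
full-length transcript models (e.g. PacBio isoforms or assembled
transcripts, as GTF) and strand-specific RNA-seq counts (dUTP libraries),
and want the reference-based cis-NAT workflow as reusable, validated R
functions rather than one-off scripts.

## What it computes

**cis-NAT discovery.** Transcripts with overlapping genomic spans are
clustered into *transcript units* (single-linkage closure on span
overlap, strand-blind). Within each unit, every oppositely oriented pair
whose spans overlap by ≥ `minOverlap` nt becomes one cis-NAT pair,
classified by overlap geometry:

* *head-to-head* (5′–5′): the overlap covers both transcripts' 5′ ends
  (divergent orientation);
* *tail-to-tail* (3′–3′): the overlap covers both 3′ ends (convergent);
* *fully overlapping*: one span contains the other.

Pairs with a noncoding member are flagged **lncNAT**.

**Differential expression.** A common NB dispersion φ is estimated by the
method of moments (per feature, φ̂ = max(0, (v − m)/m²) on
library-size-normalised counts, pooled across features); each feature is
then tested with a conditional exact test: replicates pooled after
scaling, and conditional on the pooled total t = a + b, the two-sided
p-value sums all splits no more likely than the observed one under NB
marginals (φ = 0 reduces to the binomial conditional test). Calling
rules: genes |FC| > 1.5 and BH-FDR < 0.01; NAT transcripts FDR < 0.01
alone. FPKM = counts × 10⁹ / (librarySize × length).

**Alternative splicing.** Pairwise isoform comparison enumerates the four
classical event types — intron retention (IR), exon skipping (ES),
alternative acceptor (AltA) and alternative donor (AltD), named in
transcription direction — and a pooled binomial likelihood-ratio test on
inclusion/exclusion junction counts (PSI with effective-length
correction) calls differential events at P < 0.05.

**Enrichment and physiology.** Upper-tail hypergeometric test per GO
term with BH correction (corrected P ≤ 0.05); Arnon total chlorophyll
(20.2·A645 + 8.02·A663)·V/W; net photosynthesis
(CO2R − CO2S·(1000 − H2OR)/(1000 − H2OS))·fda.

See `vignettes/cisNATseq-methods.Rmd` for models, assumptions, parameter
defaults and limitations.

## Worked example

Simulate a small study (12 planted NAT loci, 12 planted AS genes, 300
features, 2 × 3 stranded libraries) and run the discovery and testing
stages:

```r
library(cisNATseq)

cfg <- simulationConfig(seed = 8, nUnits = 12, nAsGenes = 12,
                        nFeatures = 300)
ann <- generateAnnotation(cfg)
ann$transcripts
#> TranscriptSet with 300 transcripts, 288 genes
#>   exons per transcript: 1 - 3 | noncoding: 7

nps <- findNatPairs(ann$transcripts)
nps
#> NatPairSet with 12 cis-NAT pairs
#>   head_to_head: 4  tail_to_tail: 4  fully_overlapping: 4
#>   lncNAT pairs: 7
head(as.data.frame(nps)[, c("plus_tx", "minus_tx", "overlap_len",
                            "nat_class", "lnc_nat")], 3)
#>   plus_tx minus_tx overlap_len    nat_class lnc_nat
#> 1 NATP001  NATM001         111 head_to_head   FALSE
#> 2 NATP002  NATM002         966 head_to_head    TRUE
#> 3 NATP003  NATM003        1483 head_to_head    TRUE

enumerateEvents(ann$transcripts)
#> AsEventSet with 12 events
#>   IR: 3  ES: 3  AltA: 3  AltD: 3

sim <- simulateCounts(ann$truth, cfg)
de <- nbDifferentialExpression(sim$se)   # FC > 1.5, FDR < 0.01
table(planted = ann$truth$features$differential,
      called = de$significant[match(ann$truth$features$feature_id,
                                    de$feature_id)])
#>        called
#> planted FALSE TRUE
#>   FALSE   270    0
#>   TRUE      0   30
```

All 12 planted NAT pairs are recovered with their planted class, the
planted AS inventory is reproduced exactly, and at this depth every
planted 4-fold change is called with no false positives.

`runPipeline(pipelineConfig(simulate = TRUE, sim = cfg), "outdir")`
orchestrates all stages (NAT discovery, AS enumeration, differential
expression for genes and NATs, differential AS, enrichment) and writes
per-stage TSVs plus a JSON summary and manifest; reruns are
byte-identical. A command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

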