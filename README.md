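# lncweave

Integrated lncRNA/mRNA analysis for multi-group bulk RNA-seq designs, in
R — built for studies that compare transcriptomes across a small number
of tissue conditions (for example, differently pigmented skin samples
with three replicates per condition) and ask three questions: which
assembled transcripts are novel long non-coding RNAs, which genes and
lncRNAs are differentially expressed between conditions, and which
coding genes does each lncRNA plausibly regulate in *cis* or in *trans*.

The package re-implements the full analysis as tested, dependency-light
R code, and ships a synthetic-data module that generates every input the
pipeline consumes — reference annotation, genome, assembled transcripts,
similarity hit tables, count matrices, FASTQ reads, Ct tables — with
planted ground truth, so every stage is verified against known answers.

## What is implemented

**Novel-lncRNA discovery.** Assembled transcripts are classified against
the reference annotation (class codes `=`, `o`, `x`, `i`, `u`) and pass
a filter cascade: excluded biotypes out; similarity to known lncRNAs
(E ≤ 1e-10) assigns the known catalogue; then intergenic (`u`) class,
length ≥ 200 nt, no annotated-lncRNA overlap, longest ORF ≤ 300 nt, no
protein similarity at E ≤ 1e-5, and a coding-potential score

    S = z(ORF length) + z(ORF coverage) + 0.5·z(Fickett) + 0.5·hexamer LLR

with `S < 0` declaring a transcript noncoding. Fickett TESTCODE uses the
published lookup tables; the hexamer log-likelihood ratio is computed
over in-frame codon pairs of the longest ORF.

**Differential expression.** FPKM (`count · 10⁹ / (length · total)`),
TMM normalization, per-gene method-of-moments dispersion with shrinkage
to a skew-corrected common value, and a conditional negative-binomial
exact test (at φ = 0 it reduces to the conditional binomial test, which
is how it is verified). Calls use FDR ≤ 0.05 (Benjamini–Hochberg, per
comparison) and |log2FC| ≥ 1.

**Targets and networks.** *Cis*: coding genes whose genomic gap from a
lncRNA locus lies in 10–100 kb (inclusive annulus; configurable).
*Trans*: Pearson r ≥ 0.95 with p < 0.05 across samples on
log2(FPKM + 1). Pairs become a bipartite igraph network exported as SIF
or GraphML.

**Enrichment and qPCR.** Hypergeometric over-representation with BH
adjustment and namespace tallies; 2^−ΔΔCt relative quantification with
dual reference genes and one-way ANOVA.

## Worked example

Run the whole pipeline on the default synthetic study design (three
groups × three replicates, ~510 assembled transcripts, planted truth):

```r
library(lncweave)
cfg <- pipeline_config(out_dir = "lncweave_demo", seed = 42)
res <- run_pipeline(cfg)
print(res$report)
```

```
lncweave pipeline summary
=========================
reads: 600 raw, 578 clean (96.33%)
  failed: adaptor=8, N-fraction=5, low-quality=9
lncRNAs: 40 known (11.8%), 300 novel (88.2%) of 340; rejected: biotype=20, not_u=30, too_short=40, known_lnc_overlap=0, long_orf=40, protein_hit=30, coding_score=10
DE: 52 distinct significant genes (35 up, 28 down)
  BS_vs_WS: 19 up / 15 down
  BS_vs_RS: 19 up / 14 down
  WS_vs_RS: 13 up / 13 down
  lncRNAs: 15 (13 known + 2 novel), other: 37
cis: 272 pairs (14 lncRNAs, 62 genes)
trans: 34 pairs (33 lncRNAs, 34 genes)
network: 103 nodes, 306 edges
enrichment: 30 terms tested; significant by namespace: none
```

Reading it: 96.33% of simulated reads survive the three discard rules
(the 22 failures are the planted violations, one rule each). Of 510
assembled transcripts, the cascade assigns 40 to the known-lncRNA
catalogue via similarity hits, calls 300 novel — exactly the planted
novel set — and rejects each decoy class for its planted reason
(`known_lnc_overlap` is structurally zero: an intergenic transcript
cannot overlap an annotated exon). The DE caller finds 52 distinct
significant genes across the three pairwise comparisons at FDR ≤ 0.05
and |log2FC| ≥ 1; the cis finder reports every coding gene within the
10–100 kb annulus of a DE lncRNA (including the three planted
exact-offset neighbours), and the trans finder recovers the planted
latent-correlated pairs at r ≥ 0.95. The enrichment line is honestly
null here: the demo term map is random, so no term should be enriched.

Every number above is recomputed on rerun; the same config and seed give
byte-identical outputs.

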