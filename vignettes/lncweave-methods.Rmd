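---
title: "lncweave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncweave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncweave)
```

# What the package does

`lncweave` implements an integrated long non-coding RNA (lncRNA) / mRNA
analysis for multi-group bulk RNA-seq designs — the kind of study that
compares, say, black, white and red skin tissue in a fish with three
replicates per group. The pipeline covers read quality filtering, novel
lncRNA discovery by a filter cascade, FPKM quantification, pairwise
differential expression with a negative-binomial exact test, cis and trans
target prediction, co-expression network export, over-representation
statistics, and qPCR validation arithmetic. A synthetic-data module
generates every input with planted ground truth, so each stage is tested
against known answers rather than against itself.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

# Read quality filtering

Reads are discarded by three rules applied in a fixed order: presence of
the adaptor as an exact substring; more than 10% unknown bases; more than
50% of bases with Phred quality at or below 5. Both fraction rules are
strict inequalities, so a 100-nt read with exactly 10 Ns is kept. The
first matching rule is the recorded failure reason, and every input read
lands in exactly one tally.

Two interpretive choices, both stated rather than hidden: "reads with
adaptors" is read as an exact substring match (no mismatch tolerance —
determinism matters more than sensitivity here, and no trimmer or
tolerance is specified by the upstream protocol); and mates of a pair are
filtered independently, since pair-aware discarding is a protocol detail
we cannot verify. Only discarding is implemented, not trimming.

# Transcript classification

Assembled transcripts are compared with the reference annotation and
assigned one of five class codes, assigned in precedence order:

* `=` — a same-strand reference transcript with an identical intron chain
  (for single-exon transcripts, identical exon ends within a tolerance
  that defaults to 0 bp, i.e. exact);
* `o` — any other same-strand exonic overlap;
* `x` — exonic overlap on the opposite strand only;
* `i` — contained in an intron of a same-strand reference transcript;
* `u` — intergenic: no exonic overlap on either strand and not intronic.

Only the `u` class feeds the novelty cascade, so the other codes collapse
the finer taxonomy used by annotation-comparison tools into the single
"not intergenic" decision the cascade needs. The `u` definition is
deliberately strand-agnostic (overlap on either strand disqualifies):
whether the original comparison was run strand-aware is not stated in the
protocol this emulates, and the strand-agnostic reading is the
conservative one for declaring novelty. Internally all coordinates are
0-based half-open, converting at the GTF boundary.

The implementation is interval-index based; its correctness is checked in
the test suite against an exhaustive brute-force checker on over a
thousand randomized instances.

# The novel-lncRNA cascade

Transcripts pass through the steps in fixed order, and the first failing
step is the recorded rejection reason:

1. **biotype** — transcripts whose reference match carries an excluded
   biotype (protein-coding, pseudogene, rRNA, tRNA, miRNA) are removed;
2. **known-lncRNA assignment** — a similarity hit against the known
   lncRNA set at E ≤ 1e-10 (inclusive) assigns the transcript to the
   known catalogue rather than rejecting it;
3. **not_u** — class code must be `u`;
4. **too_short** — spliced length must be ≥ 200 nt;
5. **known_lnc_overlap** — exonic overlap with annotated lncRNA loci.
   Under the strand-agnostic `u` definition this step cannot remove
   anything (an intergenic transcript overlaps no annotated exon); it is
   retained, and its count reported, precisely to document that the
   overlap reading of this filter is subsumed by step 3;
6. **long_orf** — longest ORF must not exceed 300 nt. The ORF scanner
   counts the stop codon, so the conventional "100 amino acids" boundary
   is 303 nt and a 300-nt ORF passes. Partial (stop-less) ORFs at
   transcript ends are not counted — a deliberate divergence from
   TransDecoder-style scanners, chosen for determinism;
7. **protein_hit** — similarity to a known protein at E ≤ 1e-5
   (inclusive, matching the "≤" convention of the similarity search);
8. **coding_score** — the combined coding-potential score `S` must be
   below the threshold (default 0).

Because every filter is conjunctive, membership of the surviving novel
set does not depend on step order; only the recorded reasons do. The
test suite asserts this monotonicity (relaxing the length or ORF
thresholds never shrinks the novel set).

## The coding-potential score

External coding-potential calculators are SVMs over protein-database
features; here the decision rule ("score below zero means noncoding") is
preserved but the score is an explicit, dependency-free linear
combination:

$$S = w_1 z(\mathrm{ORF\ length}) + w_2 z(\mathrm{ORF\ coverage})
    + w_3 z(\mathrm{Fickett}) + w_4 \cdot \mathrm{hexamer\ LLR}$$

with `z(x) = (x - center)/scale`. Defaults: weights (1, 1, 0.5, 0.5);
centers 300 nt, 0.5 and 0.95; scales 300 nt, 0.5 and 0.15. The centers
put the decision surface where the cascade's own semantics put it: an
ORF at the 300-nt boundary covering half its transcript with a Fickett
score at the conventional coding threshold (0.95) and no hexamer bias
scores exactly 0. The Fickett TESTCODE statistic uses the published
position/composition lookup tables. The hexamer log-likelihood ratio
averages, over in-frame codon pairs of the longest ORF, the log ratio of
dicodon frequency under a fixed codon-usage model versus a uniform
background; it is 0 when there is no ORF. The codon-usage model itself
(position-specific base preferences, G-rich first positions, GC-ended
codons) is shared with the synthetic generator's coding sequences, so
scorer and generator agree on what "coding-like" means — and the score
is pluggable for anyone who wants to substitute a trained table.

On synthetic data the margins are wide: planted noncoding transcripts
score below −2 and planted coding-composition decoys above +1.4, so the
threshold at 0 is not a tuned constant.

# Expression and differential expression

FPKM is the closed formula `count * 1e9 / (length * column total)`.
Between-sample normalization is trimmed mean of M-values (TMM): 30% trim
on log-ratios, 5% on abundance, inverse-asymptotic-variance weights,
factors rescaled to geometric mean 1. Testing uses a conditional
negative-binomial exact test: counts are scaled to equalized effective
library sizes, group sums are modeled NB (a sum of n independent
NB(μ, φ) is NB(nμ, φ/n)), and conditional on the observed total the
two-sided p-value sums the probabilities of all splits at most as likely
as the observed one. At φ = 0 this reduces to the conditional binomial
(Poisson) exact test, which is how the implementation is verified — by
exhaustive enumeration on small totals. The fold change reported is
`log2((meanA + c)/(meanB + c))` with pseudo-count c = 0.125 on
normalized counts; the pseudo-count affects reporting only, never the
test. Significance calls use FDR ≤ 0.05 (Benjamini–Hochberg, applied
within each pairwise comparison separately, mirroring per-comparison
reporting) and |log2FC| ≥ 1.

Dispersion is estimated per gene by method of moments on normalized
counts, pooled across groups by degrees of freedom, floored at zero and
shrunk toward a common value with weight n/(n + n0), n0 = 10. The common
value is the all-gene median raw estimate corrected for the chi-square
skew of small-sample variances: with d pooled degrees of freedom the
median of S² sits at qchisq(0.5, d)/d of its mean, so the uncorrected
median understates φ by that factor (about 0.84 at d = 4). Without this
correction a 3-vs-3 design is measurably anticonservative (null
fraction of p ≤ 0.05 near 0.07); with it the null fraction sits at
0.05–0.06 in the calibration tests. Exact numeric parity with any
external DE package is explicitly out of scope; calibration properties
(type-I control, recall and false-discovery proportion on planted
effects) take its place. Quantile-adjusted pseudo-counts were considered
for library-size equalization and rejected in favour of plain scaling:
simpler, deterministic, and the calibration tests bound the
consequences.

# Target prediction and networks

**Cis**: a coding gene is a cis target of a lncRNA when the gap between
the two loci (0 if the spans overlap, otherwise bases between nearest
feature ends — not midpoints, not TSSs) lies within 10–100 kb, both ends
inclusive. The "10–100 kb upstream or downstream" window is read
literally as an annulus; setting the lower bound to 0 reproduces the
common "within 100 kb" alternative. Signed distances are reported in
reference-forward coordinates (negative = gene upstream of the lncRNA).

**Trans**: Pearson correlation across samples on log2(FPKM + 1) (the
transform is configurable; the log stabilizes variance), with the
two-sided p-value from the t transform on n − 2 degrees of freedom.
Pairs pass at r ≥ 0.95 (signed by default — "R ≥ 0.95" is read as
positive correlation, with an absolute-value option documenting the
common alternative) and p < 0.05 (strict). No multiple-testing
correction is applied to correlation p-values, matching the emulated
protocol. Same-chromosome neighbours are not excluded from trans
candidates; with only nine samples the r ≥ 0.95 threshold is the
dominant gate, and the exclusion is a documented non-choice.

Networks are bipartite (lncRNA/gene node types, no self-loops), built on
igraph, and exported as SIF (`lnc TAB interacts TAB gene`) and GraphML
with edge attributes (mode, r, p, distance).

# Enrichment

Over-representation uses the plain upper hypergeometric tail
P(X ≥ k) with BH adjustment across tested terms; an EASE-style variant
(testing k − 1) is available behind a flag for users who want the more
conservative score some web tools report. The default background is the
full gene universe supplied by the caller (in the pipeline, all genes in
the expression matrix); term maps are flat TSVs, with no ontology-graph
propagation. Namespace tallies report counts and percentages (rounded to
two decimals) of the significant set at p ≤ 0.05.

# qPCR arithmetic

Relative expression is 2^−ΔΔCt with dual reference genes combined by the
arithmetic mean of their replicate-mean Cts — equivalent to the
geometric mean of the reference expression levels, the standard choice
for multi-reference normalization when the protocol does not state its
combination rule. The calibrator group's mean ΔΔCt is exactly 0, so its
geometric-mean fold change is exactly 1 (the arithmetic mean exceeds 1
whenever there is any within-group spread — Jensen's inequality — which
is why the identity tests use the geometric mean). Adding any constant
to every Ct leaves all fold changes unchanged. One-way ANOVA is the
classical between/within decomposition with explicit degenerate
contracts: all values identical gives F = 0, p = 1; zero within-group
variance with unequal means is flagged and reported as p → 0. Post-hoc
letter grouping (Duncan-style) is not implemented: it affects no
downstream output of the pipeline. Amplification-efficiency correction
is likewise out of scope.

# The synthetic-data module

The generator is first-class, tested code, and its defaults are the
study conditions, not dials: three groups ("BS", "WS", "RS") with three
replicates (nine libraries), an assembly of ~510 transcripts, planted
differential expression at log2FC = 2 with NB dispersion 0.1, planted
trans pairs at latent correlation 0.99, and cis neighbours at exact
15/50/100-kb gaps. Every cascade filter has a dedicated decoy class —
short (< 200 nt), long-ORF (> 300 nt), annotation-overlapping,
protein-hit, coding-score and excluded-biotype — so each filter has a
positive control, and the discovery cascade is required to return
exactly the planted truth, reason by reason, across seeds.

Specific constructions worth recording:

* **Noncoding sequence** contains no ATG on either strand (removing
  `ATG` and its reverse-complement image `CAT`), so planted lncRNAs
  provably have no ORF at all. This is stronger than real lncRNAs, which
  carry short ORFs; the cascade's ORF threshold is therefore exercised
  by the dedicated decoy classes, not by the novel class.
* **Coding sequence** is one sense-codon ORF spanning the whole CDS,
  sampled from the same codon-usage model the scorer uses.
* **Score decoys** carry an ORF of exactly 300 nt (the boundary) inside
  a 312-nt transcript: high coverage and coding composition push S > 0
  while every other filter passes. Their construction
  rejection-samples until the longest ORF on either strand is exactly
  300 nt, because a reverse-strand ORF longer than 300 nt can arise by
  chance in ~1% of draws.
* **Trans pairs** share a per-sample latent log2 profile with
  correlation `target_r` plus independent noise, so realized r is
  strictly below 1 and the detection threshold is genuinely exercised
  (copying columns would test nothing). Pair members get a high
  baseline mean and near-zero dispersion so that count-level noise does
  not swamp the latent correlation at n = 9, and a moderate latent sd
  (1.2 on the log2 scale) so that pair genes do not dominate library
  totals — heavy-tailed latents induce compositional correlation in
  FPKM across *unrelated* genes, which is exactly the artifact the
  null-decoy check guards against.
* **Reads** are labelled with the single rule they violate, and about
  a tenth of passing reads sit exactly at the 10% N boundary so the
  strict inequality is pinned. Default failure fractions put clean
  retention near 96%, in the range a well-behaved modern library shows.
  Phred+33 encoding is fixed throughout.
* **Library sizes** vary lognormally with sd 0.1; the emulated study
  does not state its spread, so it is an exposed parameter rather than
  a guess.

What the generator does *not* emulate: alignment/assembly at the read
level (no SAM/BAM), sequencing-error structure beyond the three QC rule
classes, overdispersion heterogeneity across genes, GC or length biases
in counting, and ontology structure in term maps. Passing the planted
truth suite therefore demonstrates the correctness of the pipeline's
logic under its stated model, not robustness to every artifact of real
libraries.

# Problem sizes in the test and acceptance suites

The calibration and recovery suites run at sizes chosen to make the
binomial error of the measured proportions small relative to the bands
they are checked against: 2,000 genes for type-I and recall/FDP checks
(binomial sd on a 0.05 proportion ≈ 0.005), 30 planted trans pairs with
1,000 null decoy pairs, ~1,000 randomized instances for each oracle
comparison (classifier, ORF scanner, cis windows, hypergeometric), and
five seeds for the end-to-end cascade recovery on the default ~510
transcript assembly. All randomness flows from explicit seeds; reruns
are byte-identical.

# Known limitations

* The coding-potential score is a fixed linear discriminant, not a
  trained classifier; on real data its hexamer table should be rebuilt
  from a reference transcriptome (the table is an explicit argument
  everywhere).
* The exact test conditions on rounded library-size-equalized group
  sums; for very unequal library sizes the rounding is a source of
  (small) discreteness not present in quantile-adjusted approaches.
* Classification implements only the five class codes the cascade
  consumes; finer codes (junction-sharing, containment, etc.) collapse
  into `o`.
* Correlation-based trans prediction at n = 9 has wide sampling error
  (Fisher-z sd ≈ 0.41); the r ≥ 0.95 gate is a screen, not an
  inference, and the package deliberately reports it without a
  multiplicity correction.
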