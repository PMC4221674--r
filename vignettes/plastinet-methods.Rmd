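---
title: "Methods: detecting phenotypically plastic miRNAs, transcripts and histone marks"
author: "plastinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting phenotypically plastic miRNAs, transcripts and histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinet)
```

# The design and the question

Female *Drosophila melanogaster* undergo profound physiological changes
after mating, and mated females age faster than virgins. The analyses in
this package ask which molecular features — miRNAs, transcripts, and
H3K4me1/H3K4me3/H3K9ac histone-mark peaks — change with mating, with age,
or with both, across a two-by-two factorial of age (young, 3–5 days vs
aged, 4 weeks) and mating state (virgin vs mated), with replicate samples
per condition. Everything downstream is keyed on the four conditions
returned by `conditions()` and the four pairwise contrasts of
`contrast_table()`, always signed **mated − virgin** within an age and
**aged − young** within a mating state.

The package operates strictly post-alignment: its inputs are count
tables, peak calls, read intervals and annotation tables, not reads.
A synthetic-data generator with planted ground truth stands in for
sequencing data so that every stage is testable end to end.

# The shared differential engine

Abundances of one feature are modelled as a one-way layout
$Y = \mu + C + \epsilon$, with $\mu$ the grand mean, $C$ a
four-level condition effect and $\epsilon$ the error. Significance is
assessed by permuting condition labels:

1. **Quantile normalization** (`quantile_normalize()`): every sample
   column is forced onto the common distribution of per-rank row means;
   ties within a column receive the mean of the normalized values at
   their tied ranks. The operation is idempotent, and on tie-free data
   all columns share one sorted vector exactly. Implementation is
   delegated to `limma::normalizeQuantiles(ties = TRUE)`, whose tie rule
   is precisely this one.
2. **Permutation one-way ANOVA** (`permutation_anova()`): the statistic
   is the classical $F$; the p-value is the fraction of evaluated label
   assignments — always including the identity, so $p > 0$ — with
   $F \ge F_{obs}$, ties counted inclusively (a small relative tolerance
   keeps mathematically exact ties immune to floating-point summation
   order). With two replicates per condition there are
   $8!/(2!)^4 = 2520$ distinct assignments; whenever the assignment
   space is at most `exhaustive_cap` (default 10,000) it is enumerated
   completely and the p-value is exact. Larger designs fall back to
   seeded Monte Carlo with the identity included.
3. **FDR under dependency** (`fdr_adjust()`): Benjamini–Yekutieli,
   $q_{(i)} = \min_{j\ge i} \min(1,\; p_{(j)}\, m\, c(m)/j)$ with
   $c(m)=\sum_{k\le m} 1/k$, via `p.adjust(method = "BY")`. BY is valid
   under arbitrary dependence among features, which matters here because
   quantile normalization and shared Monte Carlo permutations both
   induce cross-feature dependence.
4. **Pooled-SD post hoc gate** (`pooled_sd()`): the square root of the
   within-condition mean-square error. A pairwise contrast is *called*
   only when the omnibus $q < \alpha$ (default 0.05) **and** the
   absolute mean difference exceeds one pooled SD.

`differential_analysis()` chains these per feature and emits, per
feature: omnibus $p$ and $q$, the four condition means, the pooled SD,
and per contrast the signed difference, the effect-size flag and the
call. An optional `transform = "log2"` analyzes $\log_2(x+1)$ of the
normalized values; counts are analyzed untransformed by default.

## The permutation granularity of small designs

A fact with far-reaching consequences: the $F$ statistic is invariant
under relabelling the four groups, so the $4! = 24$ relabelings of any
grouping tie exactly. With two replicates per condition the exact
permutation p-value can therefore never fall below $24/2520 = 1/105
\approx 0.0095$, for any feature and any effect size. Plugging that
floor into BY (or even plain Benjamini–Hochberg) shows that **no
feature can reach $q < 0.05$ in the 2-replicate design**, regardless of
how many features are tested: with a planted fraction $\pi$ the best
attainable $q$ is $\approx 0.0095\,c(m)/\pi$, far above 0.05. Exact
permutation inference at this depth supports valid omnibus p-values
(the type-I-error suite runs on the 2-replicate design and verifies the
$\approx 0.048$ rejection rate at $p<0.05$), but not FDR-controlled
discovery. Sequential permutation samplers that report estimated
p-values near zero do not share this floor — and do not share its
guarantee.

Two further consequences shape the benchmark suites:

* **Recovery benchmarks use deeper designs.** The planted-truth
  recovery study runs 2,000 features, 5% planted, on a 4-replicate
  layout with 49,999 Monte Carlo permutations. The permutation count
  comes from an a priori resolution bound: BY at level $\alpha$ with
  $m$ tests and $k$ true effects needs p-values resolvable below
  $\alpha k/(m\,c(m)) \approx 3\times10^{-4}$, hence
  $n_{perm} \gg 3\times10^3$; 49,999 leaves an order of magnitude of
  headroom. Planted effects are graded across the four conditions
  (steps of one log2 unit, ≈3.4 pooled SDs on the log2 analysis scale)
  because graded patterns have the smallest tie classes; they are
  direction-balanced, half up and half down, both because the data this
  emulates show similar numbers of up- and down-regulated features and
  because one-sided planting skews the column distributions that
  quantile normalization equalizes, bleeding spurious signal into null
  features.
* **Zero-noise data maximize ties.** With noise switched off, all
  samples sharing an expected value tie exactly, so a peak raised in
  three of four conditions keeps its 3-vs-9 tie class
  ($6720/369600 \approx 0.018$ of assignments at three replicates) and
  its p-value is floored there. The zero-noise marker-logic study
  therefore calls contrasts at a threshold above the resulting BY
  $q \approx 0.17$ and below the null $q = 1$ — any value in that wide
  gap is equivalent, since null peaks are additionally excluded by the
  zero-effect pooled-SD gate.

# ChIP peak processing

`merge_peaks()` reduces overlapping peaks within each sample (one
contribution per sample), pools all samples, and clusters by
single-linkage overlap of at least `min_overlap_bp` (default 1 bp — the
least-assumption reading of "the same peak"; configurable). A cluster
becomes a merged peak (the union interval) when it is supported by at
least two distinct samples and its width strictly exceeds 146 bp, the
mono-nucleosome span. Merging is order-independent.

`count_and_fpkm()` computes
$\mathrm{FPKM} = \mathrm{count} / ((\mathrm{width}/10^3)\,
(\mathrm{library}/10^6))$, with library sizes supplied as total mapped
reads per sample. `background_correct()` tiles the genome outside the
merged peaks with fixed 1 kb bins (a fixed tiling makes the "median of
non-peak intervals" well defined and testable), computes each sample's
median background FPKM, subtracts it and floors at zero — negative
signal is not meaningful — then quantile-normalizes across samples.
`assign_genes()` attaches candidate genes whose span, widened by 2 kb
on both sides, intersects the peak; strand is ignored, and the mapping
is many-to-many. All interval work is 0-based half-open internally
(BED convention), converted at the GRanges boundary.

# Small-RNA length classes and degradation fragments

Length histograms of small-RNA reads show the miRNA mode at 22 nt and
the rasiRNA/piRNA mode at 30 nt; a transient 15–18 nt population of
maternal-mRNA degradation fragments appears only in young mated
females. `call_degradation_genes()` calls a gene a degradation source
when 15–18 nt fragments overlap its span (≥1 bp, strand-ignored) with
at least `min_reads` reads in **every** young-mated replicate and
**zero** such fragments touch it in any other sample. Requiring all
replicates is the strictest, replicate-robust reading of "exclusively
after mating"; a single-replicate mode (`require_all = FALSE`) is
provided because the replication requirement is not settled. Raising
`min_reads` is monotone: it can only remove calls.

The generator draws the 22/30 nt mixture truncated at ≥19 nt so the
degradation window stays unambiguous — the three length classes are
non-overlapping by construction, and a synthetic run at zero background
recovers the planted source genes with sensitivity and specificity 1.

# Persistence and accelerated-aging markers

From the per-feature contrast calls, `persistent_marks()` finds
post-mating changes that persist in aged mated flies. "Persisted" is
not operationally defined in the source material; the default reads it
as the **absence of a significant reversal** — the mated aged-vs-young
contrast is either non-significant or significant in the direction that
maintains the post-mating state. An alternative reading (the aged
mated-vs-virgin contrast is still significant with the same sign) is
available as `definition = "still_significant"`; the two differ on
features whose post-mating change fades without reversing.

`accelerated_aging_markers()` intersects the persistent set with
features whose virgin aged-vs-young contrast is significant **in the
same direction** as the post-mating change — the same modification
ultimately arising in virgins, only later in life. It reports the
markers, the fraction of persistent marks that qualify, and the unique
candidate genes attached through the peak-to-gene map. The containment
`markers ⊆ persistent ⊆ mating-responsive` holds by construction.

# Plastic regulatory networks

`build_network()` assembles the three layers: plastic miRNAs (inner),
genes that are both predicted miRNA targets and differentially
expressed (middle), and interaction partners of those targets (outer).
Partners are kept only when they interact with **more than one
distinct** target gene (two edges to one target do not count);
interactions are undirected, self-loops are dropped, and a gene already
in the target layer is never demoted to a partner. miRNAs with no
surviving target edge are dropped from the inner layer.
`overlay_histone_marks()` annotates any node — including miRNA loci —
with each histone mark that has a differential peak assigned to the
node's gene; multi-mark annotation is allowed. Exports cover lossless
TSV and GraphML round trips and Cytoscape-ready SIF.

# Functional-validation statistics

`call_overexpression_effect()` implements the significance-discordance
rule for miRNA overexpression qPCR: a miRNA affects a target gene
(`"+"`) when the virgin-vs-mated difference is significant at
$P < 0.05$ in exactly one of the control and overexpression crosses.
The rule is symmetric in the two crosses. Applied to the bundled
20-gene table (`mirna_overexpression_qpcr()`), it reproduces the
published marks row by row and yields 14/20 = 70% affected; the
screen's accompanying summary counts 13 of 20 affected while its marks
and percentage imply 14, a discrepancy the package reports as computed
rather than resolves. Expression values are
compared with the classical pooled-variance Student's t-test
(`ttest_expression()`), on reference-normalized expression;
`mean_normalize()` implements the plainest reading of Gapdh "mean
normalization" (divide by the reference, scale by the cross-sample
mean) and is deliberately replaceable.

`dunnett_test()` performs many-to-one comparisons of egg-laying counts
against a shared control: Dunnett statistics share the control mean and
the pooled error, and the familywise-adjusted p-value is the Monte
Carlo tail probability of the null maximum absolute statistic (default
$10^5$ seeded draws). With a single comparison it reduces to the plain
two-sided pooled t-test within Monte Carlo error, which the tests
verify, alongside agreement with `multcomp`'s single-step Dunnett.

# The synthetic-data generator

Counts are negative binomial with per-feature log-normal baselines
(median 500, log2 SD 1) and dispersion 0.04 — overdispersed like
sequencing counts and simple to invert for power calculations; none of
the noise parameters are inferences about any real dataset. Planted
features carry log2 fold changes over a target condition set; an
optional on/off class is expressed only in mated conditions, emulating
the mir-309-cluster pattern. `noise = "exact"` replaces draws with
rounded expectations for zero-noise runs. ChIP peaks are master
intervals anchored one-per-gene, realized per sample with ±20 bp
boundary jitter, widths straddling 146 bp, per-sample recurrence for
null peaks, reads scattered inside peaks and sample-specific background
depths outside them. The planted peak classes encode the marker logic
(marker: up after mating, persisting, echoed in aging virgins;
transient: reversing; persistent-only; aging-only). All draws flow from
one master seed through named per-stage substreams, so identical
configurations are byte-identical and independent of the caller's RNG
state.

What the generator does **not** emulate — and what passing tests
therefore do not certify about real data: read-level sequences and
alignment artifacts, GC and mappability bias, fragment-size effects in
ChIP libraries, correlated features (co-regulated modules), batch
effects, and compositional library-size effects beyond a global depth
multiplier.

# Problem sizes, defaults and reproducibility

The test and acceptance suites run at desk scale, chosen as the
package's own benchmark sizes: 2,000 features for the null and recovery
studies, 40 master peaks and 60 genes on a 2 Mb toy genome for the
ChIP chain, 20 permutation-oracle vectors against the full $8!$
enumeration. `run_all()` executes the whole chain from one
configuration (R list or YAML), derives every stage seed from one
master seed, and writes a manifest with MD5 checksums; re-running a
configuration reproduces the checksums exactly. The package's interface
is its functions plus `run_all()`; no shell wrapper is provided, since
every entry point is a documented R call on standard TSV/BED/GFF3
files.

# Known limitations

* Exact permutation inference cannot support FDR-level discovery at
  two replicates per condition (see the granularity analysis above);
  the package states this rather than papering over it.
* "Persisted" and the degradation-call replication rule are
  under-specified upstream; both readings are implemented, defaults
  documented above.
* The FPKM library size is taken as total mapped reads per sample;
  an in-peak-only convention would change background medians.
* Network layers are structural only: no layout, no topology statistics
  beyond the partner-degree filter.
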