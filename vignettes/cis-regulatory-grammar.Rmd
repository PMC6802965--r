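---
title: "Comparing cis-regulatory grammars of sister cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cis-regulatory grammars of sister cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregrammar)
library(dplyr)
```

## The problem this package addresses

Retinal photoreceptors and bipolar cells are a canonical pair of *sister
cell types*: closely related interneuron classes thought to descend from a
single ancestral photoreceptor-like cell. Although their transcriptomes
differ at thousands of genes, their open chromatin landscapes are organized
by strikingly similar sets of transcription-factor binding motifs — above
all K50 homeodomain sites (TAATCC, bound by CRX/OTX2). What distinguishes
them is quantitative: Q50 homeodomain motifs (TAATTA/TAATTG, bound by
RAX/VSX2) are enriched only in photoreceptor-specific open chromatin, while
E-box motifs (bHLH sites) are preferentially enriched in bipolar-specific
regions.

`cregrammar` re-implements, as a tested and reusable pipeline, the
comparative analysis that supports this picture:

1. **`simulate_*`** — synthetic genomes, peak sets, count matrices and
   single-cell matrices with planted ground truth;
2. **interval algebra** — peak unions, promoter/enhancer classification,
   nearest-TSS assignment, overlap fractions, tissue-specificity
   filtering;
3. **motif grammar** — IUPAC consensus scanning, enrichment against a
   shuffled background, differential enrichment, positional density,
   co-occurrence, spacing, and in-silico motif mutagenesis;
4. **differential counts** — normalization, dispersion estimation, an NB
   Wald test, and correlation-based sample clustering;
5. **contamination filtering** — the rule-based removal of photoreceptor
   transcripts from sorted-bipolar differential-expression lists;
6. **integration** — the accessibility-by-expression quadrant
   classification of peaks;
7. **pseudo-bulk** — aggregation of clustered single-cell counts and
   comparison to bulk profiles.

Every statistical claim the package makes is exercised on synthetic data
whose truth is known, so sensitivity, false-discovery and calibration
properties are measured rather than assumed.

## The synthetic-data model

`sim_config()` collects every tunable quantity. The defaults describe a
desk-scale version of a two-cell-class open-chromatin study.

**Genome and peaks.** The genome is i.i.d. nucleotide sequence at a
mouse-like composition (A/T 0.29, C/G 0.21), split over two chromosomes.
Peaks are fixed-width (500 bp), non-overlapping, with the summit defined as
the interval midpoint — real summits come from a peak caller, which is out
of scope. Four peak classes carry the planted grammar
(`default_motif_densities()`): K50 sites in both cell classes (2 per peak),
Q50 sites only in photoreceptor peaks (1.5 per peak), E-boxes
preferentially in bipolar peaks (1.5 vs 0.3), and CTCF sites mainly in
shared and control peaks — the qualitative pattern the comparative analysis
is expected to recover. Occurrence counts per peak are Poisson; positions
are uniform within the central 80% of the peak (avoiding edge truncation);
strands are random; degenerate IUPAC positions are realized uniformly.
Every planting is recorded in a truth table, and a scanner re-scan recovers
100% of plantings by construction.

**Counts.** Bulk counts are negative binomial with variance
$\mu + \alpha\mu^2$; $\alpha$ is called the *dispersion* throughout
(default 0.05, a typical replicate-level value for sorted-population
ATAC/RNA-seq). Baseline means are log-uniform on [50, 2000]; per-sample
library-size factors are uniform on [0.7, 1.4]; each group has 4
replicates, the replicate scale of the study the pipeline emulates. A
configurable fraction of features carries a planted log2 fold-change
(default magnitude 2, split symmetrically around the baseline so base means
stay comparable); the rest share a common mean across groups.

**Contamination.** Sorted bipolar populations carry low-level
photoreceptor material. The generator models contaminant genes as
rod-specific — very high rod mean (1600–6400), background-level blue-cone
expression (5–25 counts; the genes this emulates, such as phototransduction
genes, are essentially absent from cones), zero true bipolar expression —
and adds `contamination_fraction` (default 0.05) times the rod mean to the
bipolar samples' means. Contamination is an additive mean shift, not a
mixture resampling: the simplest model consistent with low-level
contamination of a sorted population.

**Single cells.** Six clusters (three ON, three OFF bipolar) with
Poisson counts per cell around cluster means; cluster means are the
population profile times a lognormal jitter (sd 0.1) and a depth factor
(0.02) mapping bulk-scale means to per-cell Drop-seq-scale counts.

What the generator does **not** emulate: read-level data (FASTQ),
fragment-length and Tn5 insertion bias, realistic gene annotation, linked
peak–gene architecture beyond the test harness's constructions, and
correlated motif placement. Passing tests therefore demonstrate that the
statistics do what they claim under their own model assumptions — not that
those assumptions hold in any particular real dataset.

## Motif statistics

**Scanning.** IUPAC consensi are matched exactly on both strands
(`Biostrings` matching underneath); occurrences are anchored at the
leftmost genomic base and reported as signed offsets from the peak summit.
A palindromic consensus would be found at the same positions on both
strands, so its hits are collapsed to a single "+" occurrence — otherwise
every E-box would be counted twice.

**Presence, not counts.** All proportion statistics use peak-level
presence (at least one occurrence), matching the "proportion of peaks
containing a motif" framing. This makes the shipped motif models matter:
a degenerate family consensus like CANNTG matches random sequence every
~128 bp, so nearly every 500 bp peak "contains" it and proportions
saturate. The built-in set (`cre_motifs()`) therefore represents the E-box
family by the high-information palindromic instance CAGCTG, and the two
Q50 variants by the single degenerate model TAATTR.

**Enrichment vs background.** The background model is dinucleotide-
preserving shuffles of the peak sequences themselves
(`shuffle_dinucleotides()`, a rejection-sampled random Eulerian path on the
dinucleotide transition graph): composition and CpG content are preserved,
grammar is destroyed. The test is a one-sided binomial test of the peak
presence proportion against the background proportion, with the background
proportion smoothed to $(x_b + 0.5)/(n_b + 1)$ so the null stays proper
when a long motif never appears in the finite background sample. BH
correction is applied within the analysis (across motifs), not globally.

**Differential enrichment** is the classical two-sample test of equal
proportions — a pooled-proportion z-test without continuity correction,
two-sided, with a `correct` flag for the Yates variant.

**Co-occurrence.** For a motif pair, the expected number of peaks
containing both under independence is $n_1 n_2 / N$ and enrichment is
$\log_2\frac{\mathrm{obs} + 1}{\mathrm{exp} + 1}$. Independently planted
motifs give mean absolute enrichment near zero — the independence model the
comparative analysis reports for real peak sets. Differential
co-occurrence between two peak sets is a two-sided Fisher exact test on the
2×2 pair-present-by-set table, BH-corrected across pairs.

**Density and spacing.** Density profiles report motifs per base pair per
1000 peaks: $d_b = c_b / (w_b \cdot N/1000)$ for bin count $c_b$, bin
width $w_b$ and $N$ peaks, so $\sum_b d_b \, w_b \, N/1000$ recovers the
total occurrence count. Spacing profiles histogram secondary-motif
positions relative to each anchor occurrence, with offset sign and strand
normalized to the anchor's strand and anchor self-pairs excluded.

**Mutagenesis.** `mutate_motif_sites()` implements the two reporter edits
as pure sequence operations: inactivation rewrites a TAAT core to TGGT;
Q50 conversion rewrites the 6-mer at the site to TAATTA. Length is always
preserved and a site that does not start with TAAT is an error.

## The differential stage

The differential stage is written out explicitly rather than delegated:

* **Normalization** is median-of-ratios: sample $j$'s size factor is the
  median over features (nonzero in all samples) of
  $c_{ij}/(\prod_k c_{ik})^{1/m}$.
* **Dispersion** is per-feature method-of-moments on normalized counts,
  $\hat\alpha = \max\!\big((s^2 - \bar\mu)/\bar\mu^2,\ 10^{-8}\big)$, with
  $s^2$ the within-group pooled variance. There is deliberately no
  empirical-Bayes shrinkage toward a fitted trend; this is the main
  approximation relative to full DESeq2-style inference, and it is why
  dataset-scale discovery counts from real data are not targets of this
  package.
* **Testing** uses the log2 ratio of normalized group means with a +0.5
  pseudocount (finite fold-changes for zero groups) and a delta-method
  standard error under the NB variance function. The Wald statistic is
  referred to a *t* distribution with the residual degrees of freedom
  (samples in the contrast minus two): with plug-in dispersions at 4 vs 4
  replicates the normal reference is measurably anticonservative (~0.10
  empirical type-I at nominal 0.05), while the t reference restores
  calibration (0.044–0.051 across dispersions 0.05–0.2, with uniform null
  p-values).
* **Calling** applies the conventional post-hoc filter: |log2FC| ≥ 1 and
  BH FDR < 0.05. Whether the fold threshold is a filter or a shifted test
  null is genuinely ambiguous in common practice; the filter is the
  default and `shifted_null = TRUE` moves the threshold into the Wald
  statistic.

Sample clustering is Pearson correlation of log2(normalized + 1) profiles
with average-linkage clustering on $1 - r$; `hclust`'s deterministic merge
order makes leaf order reproducible.

## Intervals, contamination, integration, pseudo-bulk

**Coordinates** are BED convention (0-based, half-open); chromosome names
are compared as raw strings and distinct chromosomes never overlap.
A peak is a **promoter** when its *summit* lies between 1000 bp upstream
and 100 bp downstream of a TSS (strand-aware, bounds inclusive); the
summit rule is chosen over whole-peak overlap for determinism.
**Nearest-TSS** distance is summit-to-TSS with equidistant ties broken by
the lexicographically smaller gene id, reproducible across platforms.
**Overlap** anywhere in the package means ≥ 1 shared base.

The **contamination filter** follows the study's wording literally:
"more than 16-fold" specific is strict (>), "at least four-fold" enriched
is inclusive (≥); ratios use normalized means with a +0.5 pseudocount. The
filter runs after, not inside, the DE test, and removed genes are always
reported with their triggering ratios. Whether the original rule also
required statistical significance of the specificity contrast is unstated;
this implementation uses fold-changes only.

**Quadrant classification** requires four-fold (|log2FC| ≥ 2, inclusive)
*and* FDR < 0.05 in both the accessibility and expression dimensions for a
concordant or discordant call; peaks significant in one dimension only are
`shared_or_modest`. Peaks whose assigned gene lacks an expression record
are flagged and excluded from counts rather than imputed.

**Pseudo-bulk** weights are cluster cell counts — equivalently a plain
mean over all member cells — stated explicitly so alternatives are
deliberate choices. Rescaling to bulk is a single global total-matching
factor (correlations are unaffected by it), and bulk/pseudo-bulk
correlations are Pearson on log2(x + 1).

## Problem sizes and numerical conventions

The test and acceptance runs use: 2000 peaks and 595 synthetic motif pairs
for the independence null; 300 peaks per class for grammar recovery; 2000
features at 4 vs 4 replicates for calibration and recovery; 2000 genes
(5% contaminants) for the filter; 1500 peak–gene pairs for the quadrant
pipeline; and 100 seeded runs of 6 clusters × 200 cells × 300 genes for
the pseudo-bulk comparison. These sizes give the property checks stable
sampling distributions while keeping a full run in minutes.

Ties, floors and degenerate inputs are handled explicitly: dispersion
floor $10^{-8}$; pseudocount 0.5 wherever ratios of means are formed;
empty peak sets, one-replicate groups, constant samples, all-zero
pseudo-bulk vectors and TSS-free chromosomes are errors or flagged
records, never silent.

## Known limitations

* Consensus matching is binary; the optional PWM-with-threshold route of
  real motif databases is not implemented, and motif-match score
  thresholds are therefore not a tunable.
* No empirical-Bayes dispersion moderation; power at very low counts is
  below what shrinkage-based tools achieve.
* Two-group contrasts only; no GLM designs or batch covariates.
* Nearest-TSS is the only peak–gene linking rule; no 3D-contact-based
  assignment.
* The synthetic single-cell model is Poisson around cluster means; it does
  not model dropout beyond Poisson zeros or cell-level depth variation.
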