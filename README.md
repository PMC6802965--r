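# cregrammar

Comparative *cis*-regulatory grammar analysis of open chromatin, for
regulatory genomicists studying how closely related cell classes — the
motivating case is retinal photoreceptors versus bipolar cells — encode
divergent transcriptomes in similar enhancer landscapes.

A cell class's *cis-regulatory grammar* is the number, identity, spacing
and orientation of transcription-factor binding motifs within its open
chromatin regions. `cregrammar` provides the statistics used to compare
grammars between two peak sets, together with the differential-count,
interval and integration machinery around them, and a synthetic-data
module that generates every input with planted ground truth so the whole
pipeline is testable end to end.

## What it computes

**Motif grammar.** For peak-level presence proportions $p_a = x_a/n_a$ and
$p_b = x_b/n_b$ of a motif in two peak sets:

- enrichment against a dinucleotide-shuffled background (one-sided
  binomial test, BH across motifs);
- differential enrichment via the two-sample test of equal proportions,
  $z = (p_a - p_b)\big/\sqrt{\hat p(1-\hat p)(1/n_a + 1/n_b)}$ with the
  pooled $\hat p$, no continuity correction;
- pair co-occurrence enrichment
  $\log_2\!\frac{\mathrm{obs}+1}{\mathrm{exp}+1}$ with
  $\mathrm{exp} = n_1 n_2 / N$, and differential pair co-occurrence by
  Fisher's exact test;
- summit-anchored density profiles (motifs per bp per 1000 peaks) and
  strand-resolved spacing profiles around anchor motifs;
- in-silico mutagenesis of homeodomain sites (TAAT → TGGT inactivation,
  6-mer → TAATTA Q50 conversion).

**Differential counts.** Median-of-ratios size factors, per-feature
method-of-moments NB dispersion ($\mathrm{var} = \mu + \alpha\mu^2$), and
a delta-method Wald test on log2 fold-changes of normalized group means
(+0.5 pseudocount, small-sample *t* reference), calling features at
|log2FC| ≥ 1 and BH FDR < 0.05. Plus Pearson-correlation sample
clustering.

**Around them:** peak unions, promoter/enhancer classification (summit
within −1000/+100 bp of a TSS, strand-aware), nearest-TSS assignment,
tissue-specificity filtering, the >16-fold / ≥4-fold photoreceptor-
contamination filter for sorted-bipolar DE lists, four-fold/FDR quadrant
classification of accessibility versus expression, and pseudo-bulk
aggregation of clustered single-cell counts with bulk comparison.

## Worked example

Simulate a genome with the default planted grammar, scan the built-in
motif set, and compare photoreceptor against bipolar peaks:

```r
library(cregrammar)
library(dplyr)

cfg <- sim_config(seed = 42)
genome <- simulate_genome(cfg)
ps <- simulate_peak_sets(cfg, genome)

motifs <- cre_motifs()
pres <- function(cls) {
  s <- peak_sequences(filter(ps$peaks, class == cls), ps$genome)
  motif_presence(scan_motifs(s, motifs), s$peak_id, motifs$motif)
}
gram <- diff_motif_enrichment(pres("photoreceptor"), pres("bipolar"))
select(gram, motif, proportion_a, proportion_b, statistic, fdr)
#> # A tibble: 6 × 5
#>   motif       proportion_a proportion_b statistic      fdr
#>   <chr>              <dbl>        <dbl>     <dbl>    <dbl>
#> 1 Ebox              0.317        0.807    -12.1   6.75e-33
#> 2 Q50_HD            0.87         0.483     10.1   1.29e-23
#> 3 CTCF              0.0433       0.0367     0.417 1   e+ 0
#> 4 K50_HD            0.913        0.907      0.285 1   e+ 0
#> 5 MADS              0.0967       0.1       -0.137 1   e+ 0
#> 6 NR_halfsite       0.403        0.403      0     1   e+ 0
```

The comparison recovers the planted grammar: K50 homeodomain sites are
ubiquitous in both cell classes (proportions 0.91 vs 0.91, no differential
signal), Q50 sites are strongly photoreceptor-enriched (z = +10.1), and
E-boxes are bipolar-enriched (z = −12.1), each at vanishing FDR — the
signature pattern that distinguishes the two grammars. Set a is the
photoreceptor class, so positive z means photoreceptor-enriched.

Differential accessibility on the matching simulated counts:

```r
atac <- simulate_atac_counts(ps$peaks, cfg)
fit <- nb_wald_test(atac$counts, atac$samples,
                    contrast = c("photoreceptor", "bipolar"))
glance(fit)
#> # A tibble: 1 × 7
#>   n_features n_called  n_up n_down median_dispersion lfc_threshold alpha_fdr
#>        <int>    <int> <int>  <int>             <dbl>         <dbl>     <dbl>
#> 1       1200      113    62     51            0.0429             1      0.05
```

113 of 1200 peaks are called differentially accessible — the generator
plants 10% — with the median dispersion estimate (0.043) close to the
configured 0.05. `tidy(fit)` returns the per-feature table and
`autoplot(fit)` an MA plot; `classify_quadrants()` output likewise has an
`autoplot()` giving the accessibility-by-expression scatter.

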