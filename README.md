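# chipmark

Downstream analysis of ChIP-seq peak calls for chromatin factors and histone
marks, plus the clinical-cohort expression statistics that typically accompany
such studies. The motivating setting is a factor like WDR5 (a scaffold subunit
of MLL H3K4 methyltransferase complexes) profiled alongside the promoter mark
H3K4me3 in leukemia cells: where does the factor bind relative to genes, and
how tightly does the histone mark co-localize with it?

The package consumes standard BED / narrowPeak peak files and BED12 / minimal
GTF gene models and provides:

* **Peak annotation** — nearest gene by center-to-TSS distance, and
  classification into promoter / 5'UTR / 3'UTR / exon / intron / intergenic
  (optionally enhancer) by the highest-priority feature containing the peak
  center.
* **Feature distribution** — the percentage of peaks per regulatory category
  (a true partition, since classification is center-based).
* **Position profiles** — peaks covering each strand-oriented position around
  the TSS or TES, as percent of the maximum position.
* **Co-localization density (HMd)** — query peaks are mapped onto their
  nearest anchor peak at distance thresholds
  X = 50, 100, 200, 500 bp, 1–5 kb, and each annulus is scored as

  ```
  HMd_i = (Y_i − Y_{i−1}) · 100 / ((X_i − X_{i−1}) · M)
  ```

  with Y_i the cumulative query count within X_i, M the anchor-peak count and
  X in kb — query peaks per 100 anchor peaks per kb.
* **Cohort statistics** — qPCR standard-curve quantification
  (OLS of Ct on log10 quantity), GOI/GAPDH normalization, median
  dichotomization into high/low expression groups, and χ² / Mann–Whitney
  association tests.
* **Synthetic data** — deterministic generators for genomes, feature-weighted
  peak sets, distance-decay co-localized peaks and patient cohorts, so every
  stage is testable end to end without external data.

Everything is tibble-in / tibble-out and pipe-friendly; results support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(chipmark)
library(dplyr)

cfg     <- simulation_config(seed = 1)
genome  <- simulate_genome(cfg)
anchors <- simulate_peaks_by_feature(genome, cfg)   # factor peaks, planted weights
queries <- simulate_colocalized(anchors, cfg)       # mark peaks, Laplace decay

feature_distribution(anchors, genome, chrom_sizes = cfg$chrom_sizes)
#> # A tibble: 6 × 3
#>   category   count percentage
#>   <chr>      <int>      <dbl>
#> 1 promoter     121       6.05
#> 2 utr5          54       2.7
#> 3 utr3         136       6.8
#> 4 exon         206      10.3
#> 5 intron       382      19.1
#> 6 intergenic  1101      55.0
```

More than half of the peaks sit in intergenic space and ~6% in promoters —
exactly the weights the generator planted, recovered through the
classification pipeline.

```r
prof <- colocalization_profile(anchors, queries)
tidy(prof)
#> # A tibble: 9 × 6
#>   bin_lower bin_upper midpoint cumulative increment    hmd
#>       <int>     <int>    <dbl>      <int>     <int>  <dbl>
#> 1         0        50       25       3342      3342 3342
#> 2        50       100       75       6037      2695 2695
#> 3       100       200      150       9725      3688 1844
#> 4       200       500      350      14748      5023  837.
#> 5       500      1000      750      16770      2022  202.
#> 6      1000      2000     1500      17723       953   47.6
#> 7      2000      3000     2500      18249       526   26.3
#> 8      3000      4000     3500      18622       373   18.6
#> 9      4000      5000     4500      18924       302   15.1
autoplot(prof)
```

The density is front-loaded — over 200× higher within 50 bp of an anchor
center than in the 4–5 kb annulus — the signature of genuine co-localization;
uniform query placement gives a flat curve instead.

```r
curve  <- fit_standard_curve(simulate_standards())
curve
#> qPCR standard curve: Ct = -3.3200 * log10(quantity) + 38.0000 (r^2 = 1.0000, n = 6)

cohort <- simulate_cohort(cfg) |>
  add_expression(curve, curve) |>
  mutate(group = dichotomize(expression))
associate(cohort, group, covariates = "phenotype")
#> # A tibble: 1 × 6
#>   covariate test       statistic    df  p_value summary
#>   <chr>     <chr>          <dbl> <int>    <dbl> <list>
#> 1 phenotype chi_square      13.1     1 0.000301 <tibble [2 × 3]>
```

The planted 1-SD expression shift in phenotype-positive patients surfaces as
a strong association between the high/low expression group and phenotype.

See `vignettes/chipmark-methods.Rmd` for the model conventions (coordinate
system, promoter window, center rule, nearest-anchor assignment), the
synthetic generators' assumptions, and known limitations.

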