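---
title: "Methods: peak annotation, co-localization density, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, co-localization density, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmark)
```

chipmark implements the downstream stages of a chromatin-factor ChIP-seq
study: given peak calls (e.g. for WDR5, a scaffold subunit of MLL H3K4
methyltransferase complexes) and gene models, it annotates each peak with its
nearest gene and regulatory category, profiles peak coverage around
transcription start and end sites, and quantifies how strongly a second peak
set (e.g. the promoter mark H3K4me3) accumulates around the first. A separate
cohort stage covers qPCR-based expression quantification and the
nonparametric group comparisons typical of clinical correlation tables.
Everything upstream — alignment and peak calling — is out of scope: peaks
enter as BED or narrowPeak files.

## Coordinates, centers, and gene models

All coordinates are 0-based half-open (the BED convention); GTF input is
converted at the parser boundary, which confines every off-by-one risk to one
place. A peak's *center* is the midpoint base of its closed span,
`floor((start + end - 1) / 2)`; for even widths the midpoint rounds down,
a deterministic choice where any convention would do. When a narrowPeak
summit is available, `mode = "summit"` uses `start + summit_offset` instead.
All classification and distance computations are center-based. Center-based
classification forces each peak into exactly one category, which is what
makes a category *distribution* (percentages summing to 100) well defined;
any-overlap classification would double-count.

Gene models carry strand-aware anchors: TSS = `start` on the plus strand and
`end - 1` on the minus strand, TES the opposite end. Chromosome names are
compared as exact strings; no `chr`-prefix normalization is attempted,
because silent aliasing of `1` and `chr1` miscounts quietly.

## Regulatory features and classification

`gene_features()` derives, per gene: a promoter window, 5'/3' UTRs (exonic
sequence outside the coding bounds, labels swapping on the minus strand),
remaining exonic intervals, and introns (inter-exon gaps). The promoter
window is `[TSS - upstream, TSS + downstream)` in transcription orientation,
mirrored exactly on the minus strand. The defaults (2000 bp upstream, 500 bp
downstream) follow common ChIP-seq practice, but the window is a parameter
because the derived category percentages depend directly on it — there is no
universal definition of "promoter". Likewise there is no portable enhancer
definition, so an `enhancer` category exists only when the user supplies
enhancer intervals.

Classification takes the highest-priority feature containing the peak center
(promoter > enhancer > 5'UTR > 3'UTR > exon > intron), falling back to
`intergenic`. Overlapping genes contribute features independently; priority
resolves conflicts. Nearest-gene assignment minimizes |center − TSS| on the
same chromosome — the TSS is the standard anchor for regulatory distance —
with ties broken deterministically by smallest `gene_id`. Internally both
queries use indexed searches (sorted vectors, `findInterval`); the test suite
checks them peak-for-peak against exhaustive linear scans on 100 random
genomes.

## Position profiles

`position_profile()` counts, for each offset in a window around the TSS (or
TES), how many peaks cover that strand-oriented position, pooled across all
genes, then rescales so the best-covered position is 100%. Pooling (rather
than per-gene averaging) is the convention implemented and documented here;
with a single profile per peak set the two differ only by gene weighting.
When nothing is covered the profile is all zero rather than undefined.

## The HMd co-localization density

Query peaks are mapped onto anchor peaks at a ladder of center-to-center
distance thresholds X = 50, 100, 200, 500 bp, 1–5 kb. With Y_i the
cumulative number of query peaks whose center lies within X_i of their
nearest anchor center, and M the number of anchor peaks, the per-annulus
density is

    HMd_i = (Y_i − Y_{i−1}) · 100 / ((X_i − X_{i−1}) · M)

with the implicit origin (X₀, Y₀) = (0, 0) and X in kb, so the unit is
"query peaks per 100 anchor peaks per kb". Three design choices matter:

* **Cumulative Y.** The threshold list is a ladder, and the differencing in
  the formula presupposes cumulative counts; the differenced form then gives
  per-annulus densities.
* **Nearest-anchor assignment.** Each query is counted once, against its
  single nearest anchor, not once per anchor within range. This bounds Y by
  the number of queries and makes the conservation identity
  Σ HMd_i·ΔX_i(kb)·M/100 = Y_last exact, which the tests verify to 1e-9 on
  random ladders. Counting per anchor pair is a different (unbounded)
  statistic; the nearest-assignment choice is the documented one.
* **Within-chromosome distances.** Queries on anchor-free chromosomes get
  infinite distance and are never binned.

Under uniform, independent anchors and queries the distance to the nearest
anchor is approximately exponential with rate 2λ (λ = anchor density), so
HMd is nearly flat across a 5 kb window when anchors are sparse — the null
the test suite checks by regression. A planted two-sided exponential
(Laplace) kernel concentrates HMd in the first bins and produces the
monotone, front-loaded curve characteristic of genuine co-localization.

## Synthetic data

The generators exist so that every pipeline stage can be tested against
known ground truth without downloads; they are first-class, tested code.

* `simulate_genome()` places non-overlapping genes uniformly (bounded
  rejection sampling), draws exon chains from uniform interior breakpoints,
  and gives 80% of genes coding bounds.
* `simulate_peaks_by_feature()` draws a category per peak from
  `feature_weights` and places the center uniformly over that category's
  genomic bp, redrawing the rare placements claimed by a higher-priority
  feature of another gene, so classification recovers the planted category
  exactly and recovery error is pure multinomial noise.
* `simulate_colocalized()` mixes uniform background with Laplace-displaced
  copies of anchor centers. With `background_fraction = 1` it is a uniform
  null generator.
* `simulate_cohort()` plants a mean shift of `effect_size` standard
  deviations of log normalized expression in the phenotype-positive half of
  the cohort, and back-computes Ct values through a reference standard curve
  (slope −3.32 Ct/decade, i.e. 100% PCR efficiency; intercept 38), so the
  full fit → quantify → normalize → dichotomize → test path is exercised.

Default conditions: one 10 Mb toy chromosome (`chrS1`; toy names prevent
conflation with real assemblies), 50 genes of 5–20 kb, feature weights
dominated by intergenic space (0.55) with 6% promoters, 20 000 query peaks of
which 80% decay around anchors with scale 300 bp, and a 60-patient cohort.
The anchor count defaults to 2000 (≈5 kb spacing, promoter-scale density).
That density is chosen on variance grounds: the background component of the
nearest-anchor distance decays with scale 1/(2λ), and it must decay
measurably across the 2–5 kb bins for the expected HMd curve to be strictly
monotone relative to sampling noise. With very sparse anchors (tens of kb
apart) the far-field background is flat to within noise and bin-wise
monotonicity is not an identifiable property of a single draw; at ≈5 kb
spacing it is, and the planted-decay recovery test checks it across seeds.

What the generators do *not* emulate: real hg19 gene architecture (overlapping
and nested transcripts, isoforms), peak-calling artifacts, copy-number or
mappability biases, correlated clinical covariates. Passing tests show the
algorithms are correct on data whose structure matches their assumptions,
not that any particular biological dataset satisfies those assumptions.

## Cohort statistics

Expression is quantified by inverting an OLS standard curve (Ct on
log10 quantity) and normalized as GOI/GAPDH. Dichotomization implements the
literal quartile rule (Q3–4 vs Q1–2): strictly above the sample median is
`high`, ties at the median go `low`, so an even cohort of distinct values
splits in half. Published cohorts sometimes report unequal splits whose
cutoffs came from other software; an explicit numeric `cutoff` argument
reproduces those rather than guessing the rule.

Group association uses Pearson's χ² without continuity correction by default
(a `correct` flag enables Yates), and a two-sided Mann–Whitney U test that
switches to exact enumeration when both groups have ≤8 observations and no
ties; beyond that the normal approximation with tie and continuity
correction applies. These are deliberately thin wrappers over R's `stats`
machinery — the value added is the cohort pipeline around them, and the test
suite pins the hand-checkable cases (χ² = 20 for a perfectly associated
10+10 table, exact p = 0.1 for {1,2,3} vs {4,5,6}).

Calibration at the study scale (n = 60, balanced): across 1000 simulated
null cohorts the Mann–Whitney rejection rate at α = 0.05 stays within
[0.035, 0.065], and a planted 1-SD shift is detected in >90% of cohorts.
These replicate counts (1000 for calibration, 100 random genomes for the
oracle-equivalence checks, 20 seeds for the flatness/decay properties) are
the problem sizes used throughout the test suite.

## Numerical and degenerate-input choices

* Empty peak sets: `feature_distribution()` errors (percentages undefined);
  `position_profile()` returns an all-zero profile; `cumulative_counts()`
  returns zeros.
* `hmd_density()` validates M ≥ 1, strictly increasing X, non-decreasing Y.
* Record-level parser errors name the offending line (BED/narrowPeak) or
  `gene_id` (gene models) rather than failing wholesale.
* All RNG flows through per-generator streams derived from a single config
  seed, so fixtures are reproducible and generators can be re-run
  independently.

## Known limitations

* Nearest-gene distance is center-to-TSS only; gene-body-edge distance is
  not offered.
* The position profile is pooled, not per-gene-normalized.
* No statistical significance machinery for co-localization (the density
  curve is descriptive), and no survival modelling — remission duration is
  treated as a binary covariate.
* The minimal GTF reader handles the `gene`/`exon`/`CDS` dialect with
  `gene_id` attributes; it is not a general-purpose GTF/GFF3 parser.
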