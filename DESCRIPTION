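Package: chipmark
Title: ChIP-Seq Peak Annotation, Histone-Mark Co-Localization Density and
    Cohort Expression Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq peak calls: nearest-gene peak
    annotation with strand-aware regulatory-feature classification (promoter,
    UTRs, exon, intron, intergenic), genomic feature distributions, percent-of-
    maximum positional profiles around transcription start and end sites, and a
    co-localization density statistic (HMd) that measures the accumulation of a
    query histone-mark peak set (e.g. H3K4me3) around an anchor peak set (e.g. a
    chromatin factor) in distance annuli, expressed per 100 anchor peaks per kb.
    Also includes qPCR standard-curve expression quantification with
    housekeeping-gene normalization, median dichotomization into high/low
    expression groups, and the chi-square / Mann-Whitney association tests used
    in clinical cohort comparisons, plus a deterministic synthetic-data
    generator (gene models, feature-weighted peak sets, distance-decay
    co-localized peaks, patient cohorts) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
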