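test_that("gene_features derives strand-aware promoter windows", {
  plus <- gene_models("G1", "chr1", 10000L, 20000L, "+")
  f <- gene_features(plus, promoter_upstream = 2000L, promoter_downstream = 500L)
  prom <- f[f$category == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(8000L, 10500L))

  # minus strand: the exact mirror image of the plus-strand window
  minus <- gene_models("G1", "chr1", 10000L, 20000L, "-")
  f <- gene_features(minus, promoter_upstream = 2000L, promoter_downstream = 500L)
  prom <- f[f$category == "promoter", ]
  expect_equal(prom$end - prom$start, 2500L)
  expect_equal(c(prom$start, prom$end), c(19500L, 22000L))
})

test_that("gene_features partitions exonic sequence into UTRs and coding exons", {
  g <- gene_models("G1", "chr1", 0L, 10000L, "+", cds_start = 1500L,
                   cds_end = 8500L,
                   exons = list(data.frame(start = c(0L, 3000L, 8000L),
                                           end = c(2000L, 4000L, 10000L))))
  f <- gene_features(g)
  expect_equal(f$start[f$category == "utr5"], 0L)
  expect_equal(f$end[f$category == "utr5"], 1500L)
  expect_equal(f$start[f$category == "utr3"], 8500L)
  expect_equal(sort(f$start[f$category == "intron"]), c(2000L, 4000L))

  # single-exon non-coding gene: one exon, no UTRs, no introns
  nc <- gene_models("G2", "chr1", 1000L, 3000L, "+")
  f <- gene_features(nc)
  expect_equal(sort(unique(f$category)), c("exon", "promoter"))
  expect_equal(sum(f$category == "exon"), 1L)

  # on the minus strand the UTR labels swap
  gm <- gene_models("G3", "chr1", 0L, 10000L, "-", cds_start = 1500L,
                    cds_end = 8500L)
  f <- gene_features(gm)
  expect_equal(f$end[f$category == "utr3"], 1500L)
  expect_equal(f$start[f$category == "utr5"], 8500L)
})

test_that("classification follows the category priority and falls back to intergenic", {
  genes <- gene_models(
    c("GA", "GB"), "chr1", c(1000L, 4500L), c(4000L, 9000L), c("+", "+"),
    cds_start = c(NA, 5000L), cds_end = c(NA, 8000L)
  )
  f <- gene_features(genes, promoter_upstream = 1000L, promoter_downstream = 500L)
  # GA exon body overlaps GB promoter window [3500, 5000): promoter wins
  p_conflict <- peaks("chr1", 3600L, 3700L)
  expect_equal(classify_peaks(p_conflict, f), "promoter")
  # far from everything -> intergenic
  expect_equal(classify_peaks(peaks("chr1", 900000L, 900100L), f), "intergenic")
  expect_equal(classify_peaks(peaks("chr9", 1000L, 1100L), f), "intergenic")
})

test_that("nearest_gene picks the closest TSS with deterministic tie-breaking", {
  genes <- gene_models(c("A", "B"), "chr1", c(5000L, 20000L),
                       c(12000L, 28000L), c("+", "+"))
  pk <- peaks("chr1", 5950L, 6051L) # center 6000
  res <- nearest_gene(pk, genes)
  expect_equal(res$gene_id, "A")
  expect_equal(res$tss_distance, 1000L)

  # equidistant center 12500 (7500 from both): smaller gene_id wins
  tie <- peaks("chr1", 12450L, 12551L)
  expect_equal(nearest_gene(tie, genes)$gene_id, "A")

  # no gene on the chromosome -> NA assignment
  off <- peaks("chr7", 100L, 200L)
  res <- nearest_gene(off, genes)
  expect_true(is.na(res$gene_id) && is.na(res$tss_distance))

  # signed distance is orientation-aware
  minus <- gene_models("M", "chr2", 1000L, 5000L, "-")
  up <- peaks("chr2", 4000L, 4101L) # center 4050, downstream of TSS 4999
  expect_equal(nearest_gene(up, minus)$tss_distance, 949L)
})

test_that("indexed nearest_gene and classify_peaks match brute-force oracles", {
  for (seed in c(5L, 17L, 23L, 59L, 101L)) {
    inst <- random_instance(seed)
    f <- gene_features(inst$genome, chrom_sizes = inst$config$chrom_sizes)
    expect_equal(nearest_gene(inst$peaks, inst$genome),
                 oracle_nearest_gene(inst$peaks, inst$genome))
    expect_equal(classify_peaks(inst$peaks, f), oracle_classify(inst$peaks, f))
  }
})

test_that("feature_distribution partitions every peak and sums to 100 percent", {
  genes <- gene_models("G1", "chr1", 10000L, 20000L, "+")
  pk <- peaks("chr1", c(9000L, 9100L, 9200L, 9300L, 50000L, 50100L,
                        50200L, 50300L, 50400L, 50500L),
              c(9050L, 9150L, 9250L, 9350L, 50050L, 50150L,
                50250L, 50350L, 50450L, 50550L))
  fd <- feature_distribution(pk, genes)
  expect_s3_class(fd, "feature_distribution")
  expect_equal(sum(fd$count), nrow(pk))
  expect_equal(sum(fd$percentage), 100, tolerance = 1e-9)
  expect_equal(fd$percentage[fd$category == "promoter"], 40)
  expect_equal(fd$percentage[fd$category == "intergenic"], 60)
  expect_error(feature_distribution(pk[0, ], genes), "no peaks")

  # partition property under random genomes
  for (seed in c(7L, 77L)) {
    inst <- random_instance(seed)
    fd <- feature_distribution(inst$peaks, inst$genome,
                               chrom_sizes = inst$config$chrom_sizes)
    expect_equal(sum(fd$count), nrow(inst$peaks))
    expect_equal(sum(fd$percentage), 100, tolerance = 1e-9)
  }
})

test_that("feature_distribution is invariant under genome mirroring", {
  # mirror: x -> L - x flips strands and reverses coordinates; with odd peak
  # widths the floor-midpoint maps exactly, so the distribution is unchanged
  L <- 2e6
  inst <- random_instance(31L)
  genome <- inst$genome
  genome <- genome[genome$chrom == "chrS1", ]
  pk <- inst$peaks[inst$peaks$chrom == "chrS1", ]
  pk$end <- pk$start + (pk$end - pk$start) - ((pk$end - pk$start + 1L) %% 2L)

  mirror_genes <- genome
  mirror_genes$start <- as.integer(L - genome$end)
  mirror_genes$end <- as.integer(L - genome$start)
  mirror_genes$strand <- ifelse(genome$strand == "+", "-", "+")
  mirror_genes$cds_start <- as.integer(L - genome$cds_end)
  mirror_genes$cds_end <- as.integer(L - genome$cds_start)
  mirror_genes$exons <- lapply(genome$exons, function(ex) {
    tibble::tibble(start = as.integer(L - rev(ex$end)),
                   end = as.integer(L - rev(ex$start)))
  })
  mirror_pk <- pk
  mirror_pk$start <- as.integer(L - pk$end)
  mirror_pk$end <- as.integer(L - pk$start)

  sizes <- c(chrS1 = L)
  fd <- feature_distribution(pk, genome, chrom_sizes = sizes)
  fd_m <- feature_distribution(mirror_pk, mirror_genes, chrom_sizes = sizes)
  expect_equal(fd$count, fd_m$count)
})

test_that("position_profile counts peaks passing each strand-oriented position", {
  g <- gene_models("G1", "chr1", 50000L, 60000L, "+")
  pk <- peaks("chr1", 49900L, 50100L) # covers [TSS-100, TSS+100)
  prof <- position_profile(pk, g, anchor = "tss", half_window = 500L, step = 50L)
  inside <- prof$offset >= -100 & prof$offset < 100
  expect_true(all(prof$count[inside] == 1))
  expect_true(all(prof$count[!inside] == 0))
  expect_true(all(prof$percent_of_max[inside] == 100))

  # no coverage anywhere: all-zero profile, percent stays 0
  far <- peaks("chr1", 1000L, 1100L)
  prof0 <- position_profile(far, g, half_window = 500L, step = 50L)
  expect_true(all(prof0$count == 0) && all(prof0$percent_of_max == 0))

  # two peaks stacked at TSS, one at +3 kb: 100% vs 50%
  stack <- peaks("chr1", c(49950L, 49950L, 52950L),
                 c(50050L, 50050L, 53050L))
  prof2 <- position_profile(stack, g, half_window = 5000L, step = 50L)
  expect_equal(max(prof2$percent_of_max), 100)
  expect_equal(prof2$percent_of_max[prof2$offset == 3000], 50)

  # minus-strand gene: offsets run 5' to 3'
  gm <- gene_models("G2", "chr1", 50000L, 60000L, "-")
  pkm <- peaks("chr1", 59949L, 60050L) # around TSS 59999
  profm <- position_profile(pkm, gm, half_window = 200L, step = 50L)
  expect_equal(profm$count[profm$offset == 50], 1)
  expect_error(position_profile(pk, g[0, ]), "no gene models")
})

test_that("percent_of_max attains exactly 100 whenever any position is covered", {
  for (seed in c(13L, 29L)) {
    inst <- random_instance(seed)
    prof <- position_profile(inst$peaks, inst$genome, half_window = 2000L,
                             step = 100L)
    if (any(prof$count > 0)) {
      expect_equal(max(prof$percent_of_max), 100)
    }
    expect_true(all(prof$percent_of_max >= 0 & prof$percent_of_max <= 100))
  }
})

test_that("enhancer category exists only when enhancer intervals are supplied", {
  genes <- gene_models("G1", "chr1", 10000L, 20000L, "+")
  enh <- tibble::tibble(chrom = "chr1", start = 40000L, end = 41000L)
  pk <- peaks("chr1", c(40400L, 9000L), c(40600L, 9100L))
  ann <- annotate_peaks(pk, genes, enhancers = enh)
  expect_equal(ann$category, c("enhancer", "promoter"))
  fd <- feature_distribution(pk, genes)
  expect_false("enhancer" %in% fd$category)
  fd2 <- feature_distribution(pk, genes, enhancers = enh)
  expect_true("enhancer" %in% fd2$category)
})
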