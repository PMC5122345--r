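# Brute-force oracles and fixture builders shared across tests. The oracles
# deliberately use exhaustive scans, independent of the indexed
# implementations they check.

# Nearest gene by linear scan over every gene on the peak's chromosome;
# ties resolved by lexicographically smallest gene_id.
oracle_nearest_gene <- function(pks, genes) {
  genes <- gene_anchors(genes)
  centers <- peak_center(pks)
  out_id <- rep(NA_character_, nrow(pks))
  out_d <- rep(NA_integer_, nrow(pks))
  for (i in seq_len(nrow(pks))) {
    gc <- genes[genes$chrom == pks$chrom[i], , drop = FALSE]
    if (nrow(gc) == 0L) next
    d <- abs(centers[i] - gc$tss)
    best <- which(d == min(d))
    best <- best[order(gc$gene_id[best])][1]
    out_id[i] <- gc$gene_id[best]
    signed <- centers[i] - gc$tss[best]
    if (gc$strand[best] == "-") signed <- -signed
    out_d[i] <- signed
  }
  tibble::tibble(gene_id = out_id, tss_distance = out_d)
}

# Peak classification by testing the center against every feature interval.
oracle_classify <- function(pks, features,
                            priority = c("promoter", "enhancer", "utr5",
                                         "utr3", "exon", "intron")) {
  centers <- peak_center(pks)
  vapply(seq_len(nrow(pks)), function(i) {
    hit <- features$chrom == pks$chrom[i] &
      features$start <= centers[i] & centers[i] < features$end
    cats <- unique(features$category[hit])
    for (p in priority) if (p %in% cats) return(p)
    "intergenic"
  }, character(1))
}

# Random genome + peak instance used by the oracle-equivalence tests.
random_instance <- function(seed, max_genes = 50L, max_peaks = 200L) {
  cfg <- simulation_config(
    seed = seed,
    chrom_sizes = c(chrS1 = 2e6, chrS2 = 1e6),
    n_genes = sample_n_for(seed, max_genes),
    gene_length_range = c(2000L, 15000L),
    n_anchor_peaks = 0L,
    n_query_peaks = sample_n_for(seed + 1L, max_peaks),
    background_fraction = 1,
    peak_width_range = c(100L, 800L)
  )
  genome <- simulate_genome(cfg)
  pks <- simulate_colocalized(peaks(character(), integer(), integer()), cfg)
  list(genome = genome, peaks = pks, config = cfg)
}

# Deterministic size draw in [1, max] without touching the instance streams.
sample_n_for <- function(seed, max) {
  1L + (as.integer(seed) * 2654435761 %% 2^31) %% max
}
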