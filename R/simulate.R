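# Deterministic synthetic-data generators: gene models, feature-weighted peak
# sets, distance-decay co-localized peaks, and patient cohorts with a planted
# expression-phenotype association. Every generator is a pure function of its
# config (including the seed); each draws from its own seeded stream so the
# pieces can be regenerated independently.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic generators. Defaults
#' emulate a compact study: one 10 Mb toy chromosome (`chrS1`, deliberately
#' not a real assembly name), 50 non-overlapping genes, 2000 anchor peaks
#' (about one per 5 kb, promoter-scale spacing), 20 000 query peaks of which
#' 80% decay around anchor centers with a Laplace kernel of scale 300 bp and
#' 20% are uniform background, feature placement weights dominated by
#' intergenic space (0.55) with 6% promoters, and a 60-patient cohort with a
#' 1-SD planted expression shift in the phenotype-positive subgroup.
#'
#' @param seed Integer RNG seed; every generator derives its stream from it.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_genes Number of genes to place.
#' @param gene_length_range,exons_per_gene_range,peak_width_range Min/max
#'   ranges (bp, count, bp).
#' @param n_anchor_peaks,n_query_peaks Peak counts for the co-localization
#'   generators.
#' @param feature_weights Named probabilities over placement categories
#'   (`intergenic`, `promoter`, `utr5`, `utr3`, `exon`, `intron`); must sum
#'   to 1.
#' @param decay_scale Laplace scale of the co-localization kernel (bp).
#' @param background_fraction Probability that a query peak is uniform
#'   background, in `[0, 1]`.
#' @param cohort_n Number of patients.
#' @param effect_size Planted group difference, in SD units of log normalized
#'   expression.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_sizes = c(chrS1 = 10e6),
                              n_genes = 50L,
                              gene_length_range = c(5000L, 20000L),
                              exons_per_gene_range = c(1L, 8L),
                              n_anchor_peaks = 2000L,
                              n_query_peaks = 20000L,
                              peak_width_range = c(200L, 600L),
                              feature_weights = c(intergenic = 0.55,
                                                  promoter = 0.06,
                                                  intron = 0.20, exon = 0.09,
                                                  utr5 = 0.03, utr3 = 0.07),
                              decay_scale = 300,
                              background_fraction = 0.2,
                              cohort_n = 60L,
                              effect_size = 1) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    length(chrom_sizes) >= 1L, !is.null(names(chrom_sizes)),
    all(chrom_sizes > 0),
    n_genes >= 0L, n_anchor_peaks >= 0L, n_query_peaks >= 0L, cohort_n >= 0L,
    length(gene_length_range) == 2L, gene_length_range[1] <= gene_length_range[2],
    length(exons_per_gene_range) == 2L, exons_per_gene_range[1] >= 1L,
    length(peak_width_range) == 2L, peak_width_range[1] >= 1L,
    decay_scale >= 0, background_fraction >= 0, background_fraction <= 1
  )
  if (abs(sum(feature_weights) - 1) > 1e-9) {
    stop("feature_weights must sum to 1", call. = FALSE)
  }
  if (any(feature_weights < 0)) stop("feature_weights must be non-negative", call. = FALSE)
  structure(list(
    seed = as.integer(seed), chrom_sizes = chrom_sizes,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    exons_per_gene_range = as.integer(exons_per_gene_range),
    n_anchor_peaks = as.integer(n_anchor_peaks),
    n_query_peaks = as.integer(n_query_peaks),
    peak_width_range = as.integer(peak_width_range),
    feature_weights = feature_weights,
    decay_scale = decay_scale,
    background_fraction = background_fraction,
    cohort_n = as.integer(cohort_n),
    effect_size = effect_size
  ), class = "simulation_config")
}

# Per-generator seed streams, derived from the config seed.
stream_seed <- function(config, k) {
  as.integer((as.numeric(config$seed) + 7919 * k) %% 2147483647)
}

# Uniform integer draw(s) on [lo, hi]; safe for lo == hi (base sample() would
# misread a scalar as a range).
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Simulate a genome of non-overlapping gene models
#'
#' Genes are placed uniformly without overlap (chromosomes drawn
#' length-proportionally, bounded rejection sampling), given a random strand
#' and an exon chain whose breakpoints are drawn uniformly inside the gene;
#' 80% of genes receive coding bounds inside their first/last exon. The result
#' satisfies every gene-model invariant and is deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A tibble of gene models.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(gene_models(character(), character(), integer(), integer(),
                       character()))
  }
  withr::with_seed(stream_seed(config, 0L), {
    sizes <- config$chrom_sizes
    chroms <- sample(names(sizes), n, replace = TRUE, prob = sizes)
    placed <- stats::setNames(vector("list", length(sizes)), names(sizes))
    lens <- sample_range(config$gene_length_range[1], config$gene_length_range[2], n)
    starts <- integer(n)
    attempts_left <- 200L * n
    for (i in seq_len(n)) {
      repeat {
        if (attempts_left <= 0L) {
          stop("could not place ", n, " non-overlapping genes; enlarge the genome",
               call. = FALSE)
        }
        attempts_left <- attempts_left - 1L
        L <- sizes[[chroms[i]]]
        if (L <= lens[i]) next
        s <- sample.int(L - lens[i], 1L) - 1L
        others <- placed[[chroms[i]]]
        clash <- FALSE
        if (!is.null(others)) {
          clash <- any(s < others[, 2] & others[, 1] < s + lens[i])
        }
        if (!clash) {
          placed[[chroms[i]]] <- rbind(others, c(s, s + lens[i]))
          starts[i] <- s
          break
        }
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    exons <- vector("list", n)
    cds_s <- rep(NA_integer_, n)
    cds_e <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      gs <- starts[i]
      ge <- gs + lens[i]
      k_max <- min(config$exons_per_gene_range[2], (lens[i] + 1L) %/% 2L)
      k <- sample_range(min(config$exons_per_gene_range[1], k_max), k_max, 1L)
      if (k == 1L) {
        ex <- tibble(start = gs, end = ge)
      } else {
        b <- sort(sample(seq.int(gs + 1L, ge - 1L), 2L * (k - 1L)))
        ex <- tibble(start = c(gs, b[seq(2L, length(b), by = 2L)]),
                     end = c(b[seq(1L, length(b), by = 2L)], ge))
      }
      exons[[i]] <- ex
      if (runif(1) < 0.8) {
        first <- ex[1, ]
        last <- ex[nrow(ex), ]
        lo <- first$start
        hi <- last$end
        if (hi - lo >= 2L) {
          cs <- lo + sample.int(min(first$end - first$start, hi - lo - 1L), 1L) - 1L
          ce_lo <- max(cs + 1L, last$start)
          ce <- ce_lo + sample.int(hi - ce_lo, 1L)
          cds_s[i] <- cs
          cds_e[i] <- ce
        }
      }
    }
    o <- order(chroms, starts)
    gene_models(
      gene_id = sprintf("G%03d", seq_len(n)),
      chrom = chroms[o], start = starts[o], end = starts[o] + lens[o],
      strand = strand[o], cds_start = cds_s[o], cds_end = cds_e[o],
      exons = exons[o]
    )
  })
}

#' Simulate peaks planted in weighted regulatory categories
#'
#' For each peak a category is drawn from `feature_weights`; the peak center
#' is then placed uniformly over the genomic bp belonging to that category
#' (intergenic space is the complement of all gene features). Placements whose
#' center would be claimed by a higher-priority feature of another gene are
#' redrawn, so classification recovers the planted category exactly.
#'
#' @param genome A gene-model table (from [simulate_genome()]).
#' @param config A [simulation_config()]; uses `n_anchor_peaks` peaks.
#' @param n Number of peaks (default `config$n_anchor_peaks`).
#' @return A tibble of peaks with `name` recording the planted category.
#' @export
simulate_peaks_by_feature <- function(genome, config, n = config$n_anchor_peaks) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- validate_genes(genome)
  w <- config$feature_weights
  features <- gene_features(genome, chrom_sizes = config$chrom_sizes)
  pools <- list()
  for (cat in names(w)) {
    if (cat == "intergenic") {
      rows <- lapply(names(config$chrom_sizes), function(chr) {
        f <- features[features$chrom == chr, , drop = FALSE]
        cmp <- complement_intervals(f$start, f$end, config$chrom_sizes[[chr]])
        if (nrow(cmp) == 0L) return(NULL)
        tibble(chrom = chr, start = as.integer(cmp[, "start"]),
               end = as.integer(cmp[, "end"]))
      })
      pools[[cat]] <- dplyr::bind_rows(rows)
    } else {
      f <- features[features$category == cat, c("chrom", "start", "end")]
      pools[[cat]] <- as_tibble(f)
    }
    if (w[[cat]] > 0 && (is.null(pools[[cat]]) || nrow(pools[[cat]]) == 0L)) {
      stop("category '", cat, "' has positive weight but no genomic space",
           call. = FALSE)
    }
  }
  if (n == 0L) {
    return(peaks(character(), integer(), integer()))
  }
  withr::with_seed(stream_seed(config, 1L), {
    cats <- sample(names(w), n, replace = TRUE, prob = w)
    chrom <- character(n)
    center <- integer(n)
    draw_centers <- function(cat, k) {
      pool <- pools[[cat]]
      lens <- pool$end - pool$start
      idx <- sample.int(nrow(pool), k, replace = TRUE, prob = lens)
      pos <- pool$start[idx] + floor(runif(k) * lens[idx])
      list(chrom = pool$chrom[idx], center = as.integer(pos))
    }
    for (cat in unique(cats)) {
      sel <- cats == cat
      d <- draw_centers(cat, sum(sel))
      chrom[sel] <- d$chrom
      center[sel] <- d$center
    }
    # redraw placements whose center is claimed by a higher-priority feature
    for (round in 1:100) {
      probe <- peaks(chrom, center, center + 1L)
      got <- classify_peaks(probe, features)
      bad <- got != cats
      if (!any(bad)) break
      if (round == 100L) {
        stop("could not realize planted categories; weights unrealizable",
             call. = FALSE)
      }
      for (cat in unique(cats[bad])) {
        sel <- bad & cats == cat
        d <- draw_centers(cat, sum(sel))
        chrom[sel] <- d$chrom
        center[sel] <- d$center
      }
    }
    widths <- sample_range(config$peak_width_range[1], config$peak_width_range[2], n)
    sizes <- config$chrom_sizes[chrom]
    start <- pmin(pmax(center - widths %/% 2L, 0L), as.integer(sizes - widths))
    peaks(chrom, as.integer(start), as.integer(start + widths),
          name = cats, score = NA_real_)
  })
}

#' Simulate a query peak set co-localized with anchors
#'
#' Each query is either uniform background (probability
#' `background_fraction`) or signal: its center is a uniformly chosen anchor
#' center plus a two-sided exponential (Laplace) offset of scale
#' `decay_scale`, clipped to the chromosome. With `background_fraction = 1`
#' the anchors are ignored and the result is a uniform null peak set.
#'
#' @param anchors Anchor peak table (may be empty only when
#'   `background_fraction = 1`).
#' @param config A [simulation_config()]; uses `n_query_peaks` queries.
#' @param n Number of query peaks (default `config$n_query_peaks`).
#' @return A tibble of peaks.
#' @export
simulate_colocalized <- function(anchors, config, n = config$n_query_peaks) {
  stopifnot(inherits(config, "simulation_config"))
  anchors <- validate_peaks(anchors)
  bf <- config$background_fraction
  if (nrow(anchors) == 0L && bf < 1) {
    stop("empty anchor set with background_fraction < 1", call. = FALSE)
  }
  sizes <- config$chrom_sizes
  if (n == 0L) {
    return(peaks(character(), integer(), integer()))
  }
  withr::with_seed(stream_seed(config, 2L), {
    is_bg <- runif(n) < bf
    chrom <- character(n)
    center <- numeric(n)
    n_bg <- sum(is_bg)
    if (n_bg > 0L) {
      chrom[is_bg] <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes)
      center[is_bg] <- floor(runif(n_bg) * sizes[chrom[is_bg]])
    }
    n_sig <- n - n_bg
    if (n_sig > 0L) {
      apos <- peak_center(anchors)
      idx <- sample.int(nrow(anchors), n_sig, replace = TRUE)
      offset <- sample(c(-1, 1), n_sig, replace = TRUE) *
        round(rexp(n_sig, rate = 1 / max(config$decay_scale, 1e-12)))
      if (config$decay_scale == 0) offset <- rep(0, n_sig)
      chrom[!is_bg] <- anchors$chrom[idx]
      center[!is_bg] <- pmin(pmax(apos[idx] + offset, 0), sizes[chrom[!is_bg]] - 1)
    }
    widths <- sample_range(config$peak_width_range[1], config$peak_width_range[2], n)
    start <- pmin(pmax(center - widths %/% 2L, 0), sizes[chrom] - widths)
    peaks(chrom, as.integer(start), as.integer(start + widths),
          name = sprintf("q%05d", seq_len(n)))
  })
}

# Reference qPCR curve through which synthetic cohorts are back-computed:
# 100% amplification efficiency (slope -3.32), Ct 38 at quantity 1.
qpcr_reference_curve <- function() {
  structure(list(slope = -3.32, intercept = 38, r_squared = 1, n = 0L),
            class = "standard_curve")
}

#' Simulate serial-dilution qPCR standards
#'
#' Generates a dilution series lying exactly on the package's reference curve
#' (slope -3.32 Ct/decade, intercept 38), optionally with Gaussian Ct noise,
#' so the full fit-quantify pipeline can be exercised end to end.
#'
#' @param quantities Template quantities (default six decades from 1).
#' @param ct_sd Gaussian noise SD on Ct (default 0, exact points).
#' @param seed Seed used when `ct_sd > 0`.
#' @return Tibble with `quantity` and `ct`.
#' @export
simulate_standards <- function(quantities = 10^(0:5), ct_sd = 0, seed = 1L) {
  curve <- qpcr_reference_curve()
  ct <- curve$intercept + curve$slope * log10(quantities)
  if (ct_sd > 0) {
    ct <- withr::with_seed(seed, ct + rnorm(length(ct), 0, ct_sd))
  }
  tibble(quantity = quantities, ct = ct)
}

#' Simulate a patient cohort with a planted expression shift
#'
#' Gene-of-interest expression is log-normal with a mean shift of
#' `effect_size` SD (of log normalized expression) planted in the
#' phenotype-positive half of the cohort; housekeeping (GAPDH) expression is
#' phenotype-independent. Both are back-computed to Ct values through the
#' reference standard curve, so quantification, normalization,
#' dichotomization and testing can all run on the output.
#'
#' @param config A [simulation_config()]; uses `cohort_n` and `effect_size`.
#' @return Tibble with `patient_id`, `phenotype` (`"pos"`/`"neg"`, balanced),
#'   `goi_ct`, `gapdh_ct`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$cohort_n < 4L) stop("cohort_n must be at least 4", call. = FALSE)
  curve <- qpcr_reference_curve()
  sdlog_goi <- 0.8
  sdlog_gapdh <- 0.3
  sd_expr <- sqrt(sdlog_goi^2 + sdlog_gapdh^2)
  withr::with_seed(stream_seed(config, 3L), {
    n <- config$cohort_n
    phenotype <- sample(rep(c("pos", "neg"), length.out = n))
    shift <- config$effect_size * sd_expr * (phenotype == "pos")
    goi <- exp(rnorm(n, log(50), sdlog_goi) + shift)
    gapdh <- exp(rnorm(n, log(500), sdlog_gapdh))
    tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      phenotype = phenotype,
      goi_ct = curve$intercept + curve$slope * log10(goi),
      gapdh_ct = curve$intercept + curve$slope * log10(gapdh)
    )
  })
}
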