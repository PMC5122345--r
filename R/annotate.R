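# Peak annotation: regulatory-feature derivation, center-based classification,
# nearest-gene assignment, and the category distribution behind genome-wide
# peak-location summaries.

feature_priority_default <- c("promoter", "enhancer", "utr5", "utr3", "exon", "intron")

#' Derive regulatory feature intervals from gene models
#'
#' For every gene, emits the strand-aware feature intervals used for peak
#' classification:
#' * `promoter` — the window from `promoter_upstream` bp upstream of the TSS
#'   to `promoter_downstream` bp downstream, in transcription orientation
#'   (mirrored exactly on the minus strand);
#' * `utr5` / `utr3` — exonic sequence 5' of `cds_start` / 3' of `cds_end`
#'   (strand-aware; absent for non-coding genes);
#' * `exon` — the remaining (coding or fully non-coding) exonic intervals;
#' * `intron` — gaps between consecutive exons.
#'
#' Intervals are clipped to `[0, chrom_size)` when `chrom_sizes` supplies a
#' length for the chromosome.
#'
#' @param genes A gene-model table.
#' @param promoter_upstream,promoter_downstream Promoter window half-widths in
#'   bp (defaults 2000 and 500, the common ChIP-seq convention; the derived
#'   category distribution depends on this choice, so it is a parameter).
#' @param chrom_sizes Optional named vector of chromosome lengths (bp).
#' @return A tibble with columns `gene_id`, `category`, `chrom`, `start`, `end`.
#' @examples
#' g <- gene_models("G1", "chr1", 10000L, 20000L, "+")
#' gene_features(g)[1, ] # promoter [8000, 10500)
#' @export
gene_features <- function(genes, promoter_upstream = 2000L,
                          promoter_downstream = 500L, chrom_sizes = NULL) {
  stopifnot(promoter_upstream >= 0, promoter_downstream >= 0)
  genes <- gene_anchors(genes)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    add <- function(cat, s, e) list(category = cat, start = s, end = e)
    feats <- list()
    if (g$strand == "+") {
      feats[[length(feats) + 1L]] <- add("promoter",
        g$tss - promoter_upstream, g$tss + promoter_downstream)
    } else {
      # exact mirror of the plus-strand window around the strand-aware TSS
      feats[[length(feats) + 1L]] <- add("promoter",
        g$tss - promoter_downstream + 1L, g$tss + promoter_upstream + 1L)
    }
    coding <- !is.na(g$cds_start)
    for (k in seq_len(nrow(ex))) {
      s <- ex$start[k]; e <- ex$end[k]
      if (!coding) {
        feats[[length(feats) + 1L]] <- add("exon", s, e)
      } else {
        left <- c(s, min(e, g$cds_start))   # exonic sequence before cds_start
        mid <- c(max(s, g$cds_start), min(e, g$cds_end))
        right <- c(max(s, g$cds_end), e)    # exonic sequence after cds_end
        lab_left <- if (g$strand == "+") "utr5" else "utr3"
        lab_right <- if (g$strand == "+") "utr3" else "utr5"
        if (left[1] < left[2]) feats[[length(feats) + 1L]] <- add(lab_left, left[1], left[2])
        if (mid[1] < mid[2]) feats[[length(feats) + 1L]] <- add("exon", mid[1], mid[2])
        if (right[1] < right[2]) feats[[length(feats) + 1L]] <- add(lab_right, right[1], right[2])
      }
      if (k < nrow(ex)) {
        feats[[length(feats) + 1L]] <- add("intron", ex$end[k], ex$start[k + 1L])
      }
    }
    cat <- vapply(feats, `[[`, "", "category")
    fs <- vapply(feats, function(f) as.numeric(f$start), numeric(1))
    fe <- vapply(feats, function(f) as.numeric(f$end), numeric(1))
    fs <- pmax(fs, 0)
    if (!is.null(chrom_sizes) && g$chrom %in% names(chrom_sizes)) {
      fe <- pmin(fe, chrom_sizes[[g$chrom]])
    }
    keep <- fs < fe
    rows[[i]] <- tibble(
      gene_id = g$gene_id, category = cat[keep], chrom = g$chrom,
      start = as.integer(fs[keep]), end = as.integer(fe[keep])
    )
  }
  dplyr::bind_rows(rows)
}

#' Classify peaks into gene-regulatory categories
#'
#' Each peak is assigned the highest-priority category whose feature interval
#' contains the peak center; peaks contained in no feature are `intergenic`.
#' Features from overlapping genes all contribute; the priority order resolves
#' conflicts. The `enhancer` category exists only when enhancer intervals are
#' supplied (the package refuses to invent an enhancer definition).
#'
#' @param x A peak table.
#' @param features A feature table from [gene_features()], optionally with
#'   extra `enhancer` rows.
#' @param priority Category priority, highest first.
#' @param center `"midpoint"` or `"summit"` (see [peak_center()]).
#' @return Character vector of categories, one per peak.
#' @export
classify_peaks <- function(x, features,
                           priority = feature_priority_default,
                           center = c("midpoint", "summit")) {
  x <- validate_peaks(x)
  pos <- peak_center(x, match.arg(center))
  category <- rep("intergenic", nrow(x))
  for (cat in priority) {
    f <- features[features$category == cat, , drop = FALSE]
    if (nrow(f) == 0L) next
    open <- category == "intergenic"
    if (!any(open)) break
    for (chr in unique(x$chrom[open])) {
      sel <- open & x$chrom == chr
      fc <- f[f$chrom == chr, , drop = FALSE]
      if (nrow(fc) == 0L) next
      hit <- points_in_intervals(pos[sel], fc$start, fc$end)
      category[which(sel)[hit]] <- cat
    }
  }
  category
}

#' Nearest gene by TSS distance
#'
#' For each peak, finds the gene on the same chromosome whose TSS is closest
#' to the peak center (indexed search over TSS-sorted genes). Ties are broken
#' by the lexicographically smallest `gene_id`. The signed distance is
#' positive when the peak center lies downstream of the TSS in the gene's
#' transcription orientation. Peaks on chromosomes without genes get `NA`.
#'
#' @param x A peak table.
#' @param genes A gene-model table.
#' @param center `"midpoint"` or `"summit"`.
#' @return A tibble with columns `gene_id` and `tss_distance`, one row per
#'   peak, in input order.
#' @export
nearest_gene <- function(x, genes, center = c("midpoint", "summit")) {
  x <- validate_peaks(x)
  genes <- gene_anchors(genes)
  if (nrow(genes) == 0L) stop("no gene models supplied", call. = FALSE)
  pos <- peak_center(x, match.arg(center))
  out_id <- rep(NA_character_, nrow(x))
  out_d <- rep(NA_integer_, nrow(x))
  for (chr in unique(x$chrom)) {
    gc <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(gc) == 0L) next
    o <- order(gc$tss, gc$gene_id)
    gc <- gc[o, , drop = FALSE]
    # first index of each run of equal TSS values holds the smallest gene_id
    first_of_run <- cummax(ifelse(!duplicated(gc$tss), seq_len(nrow(gc)), 0L))
    sel <- which(x$chrom == chr)
    nb <- nearest_sorted(pos[sel], gc$tss)
    left <- first_of_run[nb$left]
    right <- nb$right
    pick <- integer(length(sel))
    use_left <- nb$d_left < nb$d_right
    use_right <- nb$d_right < nb$d_left
    pick[use_left] <- left[use_left]
    pick[use_right] <- right[use_right]
    tie <- !use_left & !use_right
    if (any(tie)) {
      lid <- gc$gene_id[left[tie]]
      rid <- gc$gene_id[right[tie]]
      pick[tie] <- ifelse(lid <= rid, left[tie], right[tie])
    }
    out_id[sel] <- gc$gene_id[pick]
    signed <- pos[sel] - gc$tss[pick]
    flip <- gc$strand[pick] == "-"
    signed[flip] <- -signed[flip]
    out_d[sel] <- as.integer(signed)
  }
  tibble(gene_id = out_id, tss_distance = out_d)
}

#' Annotate peaks with nearest gene and regulatory category
#'
#' One-stop annotation: computes the peak center, assigns the nearest gene by
#' TSS distance and classifies the peak into a regulatory category.
#'
#' @inheritParams classify_peaks
#' @inheritParams gene_features
#' @param genes A gene-model table.
#' @param enhancers Optional peak/interval table of enhancer regions; when
#'   supplied, an `enhancer` category participates in classification.
#' @return The peak table with `center`, `gene_id`, `tss_distance` and
#'   `category` columns appended.
#' @export
annotate_peaks <- function(x, genes, promoter_upstream = 2000L,
                           promoter_downstream = 500L, enhancers = NULL,
                           priority = feature_priority_default,
                           center = c("midpoint", "summit"),
                           chrom_sizes = NULL) {
  center <- match.arg(center)
  x <- validate_peaks(x)
  features <- build_features(genes, promoter_upstream, promoter_downstream,
                             enhancers, chrom_sizes)
  ng <- nearest_gene(x, genes, center = center)
  pos <- peak_center(x, center)
  cats <- classify_peaks(x, features, priority = priority, center = center)
  dplyr::mutate(
    x,
    center = pos,
    gene_id = ng$gene_id,
    tss_distance = ng$tss_distance,
    category = cats
  )
}

build_features <- function(genes, promoter_upstream, promoter_downstream,
                           enhancers, chrom_sizes) {
  features <- gene_features(genes, promoter_upstream, promoter_downstream,
                            chrom_sizes)
  if (!is.null(enhancers)) {
    enh <- as_tibble(enhancers)
    features <- dplyr::bind_rows(features, tibble(
      gene_id = NA_character_, category = "enhancer",
      chrom = as.character(enh$chrom), start = as.integer(enh$start),
      end = as.integer(enh$end)
    ))
  }
  features
}

#' Distribution of peaks across gene-regulatory categories
#'
#' Tabulates [classify_peaks()] categories and converts counts to percentages
#' of all peaks (the classification is center-based, so the categories
#' partition the peak set and percentages sum to 100).
#'
#' @inheritParams annotate_peaks
#' @return A `feature_distribution` tibble with columns `category`, `count`,
#'   `percentage`; zero-count categories are retained. The `enhancer` row is
#'   present only when `enhancers` is supplied.
#' @export
feature_distribution <- function(x, genes, promoter_upstream = 2000L,
                                 promoter_downstream = 500L, enhancers = NULL,
                                 priority = feature_priority_default,
                                 center = c("midpoint", "summit"),
                                 chrom_sizes = NULL) {
  x <- validate_peaks(x)
  if (nrow(x) == 0L) {
    stop("no peaks supplied: percentages are undefined", call. = FALSE)
  }
  features <- build_features(genes, promoter_upstream, promoter_downstream,
                             enhancers, chrom_sizes)
  cats <- classify_peaks(x, features, priority = priority,
                         center = match.arg(center))
  levels <- c(priority, "intergenic")
  if (is.null(enhancers)) levels <- setdiff(levels, "enhancer")
  counts <- table(factor(cats, levels = levels))
  out <- tibble(
    category = names(counts),
    count = as.integer(counts),
    percentage = 100 * as.integer(counts) / nrow(x)
  )
  class(out) <- c("feature_distribution", class(out))
  attr(out, "n_peaks") <- nrow(x)
  out
}
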