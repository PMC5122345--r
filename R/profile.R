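#' Positional peak profile around TSS or TES
#'
#' For every offset in `[-half_window, +half_window]` at the given step,
#' counts the peaks whose interval covers the position `anchor + offset` in
#' each gene's transcription orientation (offsets run 5' to 3'; on the minus
#' strand the genomic position is `anchor - offset`). Counts are pooled over
#' all genes and rescaled so the maximum position equals 100 ("percent of the
#' number of peaks passing each position over the maximum number of peaks at a
#' position").
#'
#' @param x A peak table.
#' @param genes A gene-model table.
#' @param anchor `"tss"` or `"tes"`.
#' @param half_window Half-width of the window in bp (> 0).
#' @param step Offset step in bp (>= 1).
#' @return A `position_profile` tibble with columns `offset`, `count`,
#'   `percent_of_max`. When no peak covers any position all counts and
#'   percentages are 0.
#' @export
position_profile <- function(x, genes, anchor = c("tss", "tes"),
                             half_window = 5000L, step = 50L) {
  anchor <- match.arg(anchor)
  stopifnot(half_window > 0, step >= 1)
  x <- validate_peaks(x)
  genes <- gene_anchors(genes)
  if (nrow(genes) == 0L) stop("no gene models supplied", call. = FALSE)
  offsets <- seq(-as.integer(half_window), as.integer(half_window),
                 by = as.integer(step))
  counts <- numeric(length(offsets))
  anchor_pos <- if (anchor == "tss") genes$tss else genes$tes
  orient <- ifelse(genes$strand == "+", 1L, -1L)
  for (chr in unique(genes$chrom)) {
    gsel <- genes$chrom == chr
    pk <- x[x$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0L) next
    starts <- sort(pk$start)
    ends <- sort(pk$end)
    # positions: genes on rows, offsets on columns (strand-oriented)
    pos <- matrix(anchor_pos[gsel], nrow = sum(gsel), ncol = length(offsets)) +
      outer(orient[gsel], offsets)
    # coverage of half-open peaks at a point: #(start <= p) - #(end <= p)
    cov <- findInterval(pos, starts) - findInterval(pos, ends)
    counts <- counts + colSums(matrix(cov, nrow = sum(gsel)))
  }
  max_count <- max(counts)
  out <- tibble(
    offset = offsets,
    count = counts,
    percent_of_max = if (max_count > 0) 100 * counts / max_count else counts * 0
  )
  class(out) <- c("position_profile", class(out))
  attr(out, "anchor") <- anchor
  attr(out, "n_genes") <- nrow(genes)
  attr(out, "n_peaks") <- nrow(x)
  out
}
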