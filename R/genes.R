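#' Construct a gene-model table
#'
#' Gene models are tibbles with one row per gene: `gene_id`, `name` (display
#' symbol), `chrom`, `start`, `end` (0-based half-open gene span), `strand`
#' (`"+"` or `"-"`, required), optional coding bounds `cds_start`/`cds_end`
#' (`NA` for non-coding genes) and an `exons` list-column, each element a
#' data frame of `start`/`end` intervals sorted and non-overlapping within the
#' gene span.
#'
#' The transcription start site (TSS) and end site (TES) are strand-aware:
#' for a `+` gene TSS = `start` and TES = `end - 1`; for a `-` gene TSS =
#' `end - 1` and TES = `start` (see [gene_anchors()]).
#'
#' @param gene_id Unique identifiers.
#' @param chrom,start,end Gene span.
#' @param strand `"+"` or `"-"`.
#' @param name Display symbols (defaults to `gene_id`).
#' @param cds_start,cds_end Half-open coding bounds or `NA`.
#' @param exons List of data frames with `start`/`end`; defaults to one exon
#'   spanning the whole gene.
#' @return A validated tibble of gene models.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, name = gene_id,
                        cds_start = NA_integer_, cds_end = NA_integer_,
                        exons = NULL) {
  n <- length(gene_id)
  if (is.null(exons)) {
    exons <- purrr::map2(start, end, ~ tibble(start = as.integer(.x), end = as.integer(.y)))
  }
  out <- tibble(
    gene_id = as.character(gene_id),
    name = as.character(name),
    chrom = as.character(chrom),
    start = start, end = end,
    strand = as.character(strand),
    cds_start = cds_start, cds_end = cds_end,
    exons = exons
  )
  validate_genes(out)
}

#' Validate a gene-model table
#'
#' Enforces the gene-model invariants: unique `gene_id`, explicit strand,
#' exons sorted, non-overlapping and contained in the gene span, and coding
#' bounds (when present) inside the gene span.
#'
#' @param x A data frame of gene models (see [gene_models()]).
#' @return The validated tibble.
#' @export
validate_genes <- function(x) {
  x <- as_tibble(x)
  req <- c("gene_id", "chrom", "start", "end", "strand", "exons")
  for (col in req) {
    if (!col %in% names(x)) stop("gene table lacks column '", col, "'", call. = FALSE)
  }
  if (!"name" %in% names(x)) x$name <- x$gene_id
  if (!"cds_start" %in% names(x)) x$cds_start <- NA_integer_
  if (!"cds_end" %in% names(x)) x$cds_end <- NA_integer_
  if (nrow(x) == 0L) {
    return(x[, c("gene_id", "name", "chrom", "start", "end", "strand",
                 "cds_start", "cds_end", "exons")])
  }
  if (anyDuplicated(x$gene_id)) {
    stop("duplicated gene_id: ", x$gene_id[duplicated(x$gene_id)][1], call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-"))) {
    bad <- x$gene_id[!x$strand %in% c("+", "-")][1]
    stop("gene ", bad, ": strand must be '+' or '-'", call. = FALSE)
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$start < 0L | x$start >= x$end)) {
    bad <- x$gene_id[x$start < 0L | x$start >= x$end][1]
    stop("gene ", bad, ": invalid span", call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    ex <- as.data.frame(x$exons[[i]])
    if (nrow(ex) == 0L) stop("gene ", x$gene_id[i], ": no exons", call. = FALSE)
    ex$start <- as.integer(ex$start)
    ex$end <- as.integer(ex$end)
    if (is.unsorted(ex$start)) {
      o <- order(ex$start)
      ex <- ex[o, , drop = FALSE]
    }
    if (any(ex$start >= ex$end)) {
      stop("gene ", x$gene_id[i], ": empty exon", call. = FALSE)
    }
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("gene ", x$gene_id[i], ": overlapping exons", call. = FALSE)
    }
    if (ex$start[1] < x$start[i] || ex$end[nrow(ex)] > x$end[i]) {
      stop("gene ", x$gene_id[i], ": exon outside gene bounds", call. = FALSE)
    }
    x$exons[[i]] <- tibble(start = ex$start, end = ex$end)
    cs <- x$cds_start[i]; ce <- x$cds_end[i]
    if (!is.na(cs) || !is.na(ce)) {
      if (is.na(cs) || is.na(ce) || cs >= ce || cs < x$start[i] || ce > x$end[i]) {
        stop("gene ", x$gene_id[i], ": cds bounds outside gene interval", call. = FALSE)
      }
    }
  }
  x$cds_start <- as.integer(x$cds_start)
  x$cds_end <- as.integer(x$cds_end)
  x[, c("gene_id", "name", "chrom", "start", "end", "strand",
        "cds_start", "cds_end", "exons")]
}

#' Strand-aware TSS and TES positions
#'
#' @param genes A gene-model table.
#' @return The table with `tss` and `tes` columns added (single-base
#'   positions; for a minus-strand gene the TSS is `end - 1`).
#' @examples
#' g <- gene_models("G1", "chr1", 1000L, 5000L, "-")
#' gene_anchors(g)[, c("tss", "tes")] # TSS 4999, TES 1000
#' @export
gene_anchors <- function(genes) {
  genes <- validate_genes(genes)
  dplyr::mutate(
    genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
  )
}
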