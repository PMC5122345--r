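#' Read peaks from a BED file
#'
#' Reads BED3/BED4/BED5/BED6 records into a peak table. Coordinates are taken
#' as 0-based half-open per the BED standard. Lines beginning with `track`,
#' `browser` or `#` and blank lines are skipped; record order is preserved.
#' Malformed records (fewer than 3 fields, non-integer coordinates,
#' `start >= end`) raise an error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return A tibble of peaks (see [peaks()]).
#' @export
read_bed <- function(path) {
  parse_bed_lines(read_record_lines(path), min_fields = 3L, narrowpeak = FALSE)
}

#' Read peaks from an ENCODE narrowPeak file
#'
#' narrowPeak is the 10-column BED6+4 dialect emitted by MACS. Column 10 is
#' the summit offset from `start`; the sentinel `-1` means no summit and maps
#' to `NA`. Records must have exactly 10 columns; a summit offset outside the
#' peak raises an error naming the line.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble of peaks with `summit_offset` filled.
#' @export
read_narrowpeak <- function(path) {
  parse_bed_lines(read_record_lines(path), min_fields = 10L, narrowpeak = TRUE)
}

read_record_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_bed_lines <- function(rec, min_fields, narrowpeak) {
  fields <- strsplit(rec$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (narrowpeak) {
    bad <- which(nf != 10L)
    if (length(bad)) {
      stop("line ", rec$lineno[bad[1]], ": expected 10 columns, found ",
           nf[bad[1]], call. = FALSE)
    }
  } else {
    bad <- which(nf < min_fields)
    if (length(bad)) {
      stop("line ", rec$lineno[bad[1]], ": expected at least ", min_fields,
           " tab-separated fields, found ", nf[bad[1]], call. = FALSE)
    }
  }
  n <- length(fields)
  get <- function(k, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, character(1))
  }
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start != trunc(start) | end != trunc(end))
  if (length(bad)) {
    stop("line ", rec$lineno[bad[1]], ": non-integer coordinates", call. = FALSE)
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("line ", rec$lineno[bad[1]], ": start >= end (", start[bad[1]], " >= ",
         end[bad[1]], ")", call. = FALSE)
  }
  name <- get(4)
  name[name == "."] <- NA_character_
  score <- suppressWarnings(as.numeric(get(5)))
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  summit <- rep(NA_integer_, n)
  if (narrowpeak) {
    s10 <- suppressWarnings(as.numeric(get(10)))
    bad <- which(is.na(s10) | s10 != trunc(s10))
    if (length(bad)) {
      stop("line ", rec$lineno[bad[1]], ": non-integer summit offset", call. = FALSE)
    }
    bad <- which(s10 != -1 & (s10 < 0 | s10 >= end - start))
    if (length(bad)) {
      stop("line ", rec$lineno[bad[1]], ": summit offset ", s10[bad[1]],
           " outside peak of width ", end[bad[1]] - start[bad[1]], call. = FALSE)
    }
    summit <- ifelse(s10 == -1, NA_integer_, as.integer(s10))
  }
  if (n == 0L) {
    return(peaks(character(), integer(), integer()))
  }
  peaks(chrom, as.integer(start), as.integer(end), name = name, score = score,
        strand = strand, summit_offset = summit)
}

#' Write peaks to a BED file
#'
#' Writes `chrom`, `start`, `end` and, when any peak carries them, `name`,
#' `score` and `strand` (missing values become `.` / `0` placeholders as the
#' format requires). Input order is preserved, so
#' `read_bed(write_bed(p))` reproduces `(chrom, start, end, name)` exactly.
#'
#' @param x A peak table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_peaks(x)
  cols <- list(x$chrom, x$start, x$end)
  has_name <- any(!is.na(x$name))
  has_score <- any(!is.na(x$score))
  has_strand <- any(x$strand %in% c("+", "-"))
  last <- if (has_strand) 6L else if (has_score) 5L else if (has_name) 4L else 3L
  if (last >= 4L) {
    nm <- x$name
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
  }
  if (last >= 5L) {
    sc <- x$score
    sc[is.na(sc)] <- 0
    cols <- c(cols, list(sc))
  }
  if (last >= 6L) cols <- c(cols, list(x$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED12 or minimal GTF
#'
#' BED12 records map directly: `name` becomes `gene_id`, blocks become exons,
#' `thickStart`/`thickEnd` become the coding bounds (equal thick bounds mean
#' non-coding). The minimal GTF dialect understands `gene`, `exon` and `CDS`
#' features carrying a `gene_id` attribute (an optional `gene_name` attribute
#' supplies the display symbol); GTF's 1-based closed coordinates are converted
#' to 0-based half-open at this boundary. Strand is required in both formats.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return A tibble of gene models (see [gene_models()]).
#' @export
read_genes <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  rec <- read_record_lines(path)
  if (format == "bed12") read_genes_bed12(rec) else read_genes_gtf(rec)
}

read_genes_bed12 <- function(rec) {
  fields <- strsplit(rec$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop("line ", rec$lineno[bad[1]], ": BED12 requires 12 fields, found ",
         nf[bad[1]], call. = FALSE)
  }
  rows <- purrr::map2(fields, rec$lineno, function(f, ln) {
    start <- as.integer(f[2]); end <- as.integer(f[3])
    strand <- f[6]
    if (!strand %in% c("+", "-")) {
      stop("line ", ln, ": gene strand must be '+' or '-'", call. = FALSE)
    }
    thick_s <- as.integer(f[7]); thick_e <- as.integer(f[8])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offs <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop("line ", ln, ": blockCount does not match block lists", call. = FALSE)
    }
    ex_start <- start + offs
    list(
      gene_id = f[4], name = f[4], chrom = f[1], start = start, end = end,
      strand = strand,
      cds_start = if (thick_s < thick_e) thick_s else NA_integer_,
      cds_end = if (thick_s < thick_e) thick_e else NA_integer_,
      exons = tibble(start = ex_start, end = ex_start + sizes)
    )
  })
  genes_from_rows(rows)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

read_genes_gtf <- function(rec) {
  fields <- strsplit(rec$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad)) {
    stop("line ", rec$lineno[bad[1]], ": GTF requires 9 fields, found ",
         nf[bad[1]], call. = FALSE)
  }
  tab <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    feature = vapply(fields, `[`, "", 3),
    start = as.integer(vapply(fields, `[`, "", 4)) - 1L, # 1-based closed -> 0-based half-open
    end = as.integer(vapply(fields, `[`, "", 5)),
    strand = vapply(fields, `[`, "", 7),
    attrs = vapply(fields, `[`, "", 9),
    lineno = rec$lineno
  )
  tab <- tab[tab$feature %in% c("gene", "exon", "CDS"), , drop = FALSE]
  tab$gene_id <- gtf_attr(tab$attrs, "gene_id")
  tab$gene_name <- gtf_attr(tab$attrs, "gene_name")
  bad <- which(is.na(tab$gene_id))
  if (length(bad)) {
    stop("line ", tab$lineno[bad[1]], ": missing gene_id attribute", call. = FALSE)
  }
  rows <- lapply(split(tab, tab$gene_id), function(g) {
    gid <- g$gene_id[1]
    strand <- unique(g$strand)
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("gene ", gid, ": missing or inconsistent strand", call. = FALSE)
    }
    chrom <- unique(g$chrom)
    if (length(chrom) != 1L) stop("gene ", gid, ": records on multiple chromosomes", call. = FALSE)
    gene_row <- g[g$feature == "gene", , drop = FALSE]
    ex <- g[g$feature == "exon", , drop = FALSE]
    cds <- g[g$feature == "CDS", , drop = FALSE]
    span_s <- if (nrow(gene_row)) gene_row$start[1] else min(g$start)
    span_e <- if (nrow(gene_row)) gene_row$end[1] else max(g$end)
    if (nrow(ex)) {
      o <- order(ex$start)
      exons <- tibble(start = ex$start[o], end = ex$end[o])
      if (exons$start[1] < span_s || exons$end[nrow(exons)] > span_e) {
        stop("gene ", gid, ": exon outside gene bounds", call. = FALSE)
      }
    } else {
      exons <- tibble(start = span_s, end = span_e)
    }
    nm <- g$gene_name[!is.na(g$gene_name)]
    list(
      gene_id = gid, name = if (length(nm)) nm[1] else gid, chrom = chrom,
      start = span_s, end = span_e, strand = strand,
      cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
      exons = exons
    )
  })
  genes_from_rows(rows)
}

genes_from_rows <- function(rows) {
  if (length(rows) == 0L) {
    return(validate_genes(tibble(
      gene_id = character(), name = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      cds_start = integer(), cds_end = integer(), exons = list()
    )))
  }
  rows <- unname(rows)
  validate_genes(tibble(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    name = vapply(rows, `[[`, "", "name"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    strand = vapply(rows, `[[`, "", "strand"),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), integer(1)),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), integer(1)),
    exons = lapply(rows, `[[`, "exons")
  ))
}
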