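#' Construct a peak table
#'
#' Peaks are plain tibbles with one row per genomic interval in 0-based
#' half-open coordinates (the BED convention, used throughout the package).
#' Columns: `chrom`, `start`, `end`, `name`, `score`, `strand` and
#' `summit_offset` (bp offset of the called summit from `start`; `NA` when no
#' summit was reported).
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start,end 0-based half-open interval bounds; `start < end`.
#' @param name Peak identifiers; recycled, `NA` allowed.
#' @param score Numeric peak scores; `NA` allowed.
#' @param strand One of `"+"`, `"-"`, `"."` (unstranded).
#' @param summit_offset Offset of the summit from `start`, in
#'   `[0, end - start)`, or `NA`.
#' @return A tibble of peaks.
#' @examples
#' peaks(c("chr1", "chr1"), c(100L, 500L), c(300L, 650L))
#' @export
peaks <- function(chrom, start, end, name = NA_character_, score = NA_real_,
                  strand = ".", summit_offset = NA_integer_) {
  out <- tibble(
    chrom = as.character(chrom),
    start = start,
    end = end,
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    summit_offset = summit_offset
  )
  validate_peaks(out)
}

#' Validate a peak table
#'
#' Checks the interval invariants (`0 <= start < end`, non-empty `chrom`,
#' summit offset inside the peak) and returns the table with canonical column
#' types, filling optional columns that are absent.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A validated tibble of peaks.
#' @export
validate_peaks <- function(x) {
  x <- as_tibble(x)
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(x)) {
      stop("peak table lacks required column '", col, "'", call. = FALSE)
    }
  }
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"strand" %in% names(x)) x$strand <- "."
  if (!"summit_offset" %in% names(x)) x$summit_offset <- NA_integer_
  if (nrow(x) == 0L) {
    return(x[, c("chrom", "start", "end", "name", "score", "strand", "summit_offset")])
  }
  if (!is_integerish(x$start) || !is_integerish(x$end)) {
    stop("peak start/end must be integer-valued", call. = FALSE)
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(!nzchar(x$chrom) | is.na(x$chrom))) {
    stop("peak chrom must be non-empty", call. = FALSE)
  }
  bad <- which(x$start < 0L | x$start >= x$end)
  if (length(bad)) {
    stop("invalid peak interval at row ", bad[1], ": start=", x$start[bad[1]],
         ", end=", x$end[bad[1]], call. = FALSE)
  }
  so <- x$summit_offset
  bad <- which(!is.na(so) & (so < 0L | so >= x$end - x$start))
  if (length(bad)) {
    stop("summit_offset out of range at row ", bad[1], call. = FALSE)
  }
  x$summit_offset <- as.integer(x$summit_offset)
  x[, c("chrom", "start", "end", "name", "score", "strand", "summit_offset")]
}

#' Peak center positions
#'
#' The midpoint base of the closed base span: `floor((start + end - 1) / 2)`.
#' For even-width peaks the midpoint rounds down. In `"summit"` mode the called
#' summit (`start + summit_offset`) is used where available, falling back to
#' the midpoint for peaks without a summit. The center is the coordinate on
#' which all classification and co-localization distances in this package are
#' based.
#'
#' @param x A peak table.
#' @param mode `"midpoint"` (default) or `"summit"`.
#' @return Integer vector of genomic positions, one per peak.
#' @examples
#' peak_center(peaks("chr1", 100L, 200L)) # 149
#' @export
peak_center <- function(x, mode = c("midpoint", "summit")) {
  mode <- match.arg(mode)
  x <- validate_peaks(x)
  center <- as.integer((x$start + x$end - 1L) %/% 2L)
  if (mode == "summit") {
    has <- !is.na(x$summit_offset)
    center[has] <- x$start[has] + x$summit_offset[has]
  }
  center
}
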