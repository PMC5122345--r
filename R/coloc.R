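# Co-localization of a query peak set (e.g. H3K4me3) around an anchor peak
# set (e.g. WDR5): center-to-center distances, cumulative counts at a ladder
# of distance thresholds, and the HMd density per 100 anchor peaks per kb.

#' Default HMd distance thresholds (bp)
#'
#' The ladder at which query peaks are mapped onto anchor peaks:
#' 50, 100, 200, 500 bp and 1-5 kb.
#'
#' @return Integer vector of 9 thresholds.
#' @export
hmd_default_bins <- function() {
  c(50L, 100L, 200L, 500L, 1000L, 2000L, 3000L, 4000L, 5000L)
}

#' Center-to-center distance to the nearest anchor peak
#'
#' For each query peak, the absolute distance from its center to the center of
#' the nearest anchor peak on the same chromosome. Queries on chromosomes
#' without anchors get `Inf` (they can never fall in a distance bin).
#'
#' @param anchors Anchor peak table (must be non-empty).
#' @param queries Query peak table.
#' @param center `"midpoint"` or `"summit"` (applied to both sets).
#' @return Numeric vector of distances, one per query, in input order.
#' @export
center_distances <- function(anchors, queries, center = c("midpoint", "summit")) {
  center <- match.arg(center)
  anchors <- validate_peaks(anchors)
  queries <- validate_peaks(queries)
  if (nrow(anchors) == 0L) stop("empty anchor set", call. = FALSE)
  apos <- peak_center(anchors, center)
  qpos <- peak_center(queries, center)
  d <- rep(Inf, nrow(queries))
  for (chr in unique(queries$chrom)) {
    ac <- sort(apos[anchors$chrom == chr])
    if (length(ac) == 0L) next
    sel <- queries$chrom == chr
    nb <- nearest_sorted(qpos[sel], ac)
    d[sel] <- pmin(nb$d_left, nb$d_right)
  }
  d
}

#' Cumulative query counts at distance thresholds
#'
#' `Y[i]` is the number of distances `<= X[i]`; a query is counted at every
#' threshold it satisfies, so `Y` is a non-decreasing cumulative ladder (not
#' per-annulus counts).
#'
#' @param distances Numeric vector of nearest-anchor distances (may contain
#'   `Inf`).
#' @param thresholds Strictly increasing positive thresholds in bp.
#' @return Integer vector `Y`, same length as `thresholds`.
#' @export
cumulative_counts <- function(distances, thresholds = hmd_default_bins()) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing and positive", call. = FALSE)
  }
  vapply(thresholds, function(x) sum(distances <= x), integer(1))
}

#' HMd co-localization density
#'
#' The histone-mark density per 100 anchor peaks per kb for each distance
#' annulus:
#' \deqn{HMd_i = (Y_i - Y_{i-1}) \cdot 100 / ((X_i - X_{i-1}) \cdot M)}
#' with the implicit origin \eqn{(X_0, Y_0) = (0, 0)}, `X` converted from bp
#' to kb so the stated unit is honored literally, and `M` the number of anchor
#' peaks. Summing `HMd_i * dX_i(kb) * M / 100` over bins recovers the last
#' cumulative count exactly (conservation).
#'
#' @param y Cumulative counts (non-decreasing, see [cumulative_counts()]).
#' @param x Thresholds in bp, strictly increasing and positive.
#' @param m Number of anchor peaks (>= 1).
#' @return Numeric vector of densities, one per bin.
#' @examples
#' hmd_density(c(2, 5), c(50, 100), 10) # 400, 600
#' @export
hmd_density <- function(y, x, m) {
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("anchor count m must be a single value >= 1", call. = FALSE)
  }
  if (length(y) != length(x)) stop("y and x differ in length", call. = FALSE)
  if (any(x <= 0) || is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing and positive", call. = FALSE)
  }
  if (any(diff(c(0, y)) < 0)) stop("y must be non-decreasing", call. = FALSE)
  dy <- diff(c(0, y))
  dx_kb <- diff(c(0, x)) / 1000
  dy * 100 / (dx_kb * m)
}

#' Co-localization profile of queries around anchors
#'
#' Composes [center_distances()], [cumulative_counts()] and [hmd_density()]:
#' maps every query peak onto its nearest anchor, counts queries within each
#' distance threshold, and derives the per-annulus HMd density. Each query is
#' assigned to its single nearest anchor, which keeps `Y` bounded by the
#' number of queries and makes the conservation identity exact.
#'
#' @inheritParams center_distances
#' @param bins Distance thresholds in bp (default [hmd_default_bins()]).
#' @return A `coloc_profile` tibble with columns `bin_lower`, `bin_upper`,
#'   `midpoint` (bp), `cumulative` (Y), `increment` and `hmd`; attributes
#'   `m` (anchor count) and `n_queries`.
#' @export
colocalization_profile <- function(anchors, queries, bins = hmd_default_bins(),
                                   center = c("midpoint", "summit")) {
  center <- match.arg(center)
  anchors <- validate_peaks(anchors)
  queries <- validate_peaks(queries)
  d <- center_distances(anchors, queries, center = center)
  y <- cumulative_counts(d, bins)
  m <- nrow(anchors)
  out <- tibble(
    bin_lower = c(0L, head(bins, -1L)),
    bin_upper = as.integer(bins),
    midpoint = (c(0, head(bins, -1L)) + bins) / 2,
    cumulative = y,
    increment = diff(c(0L, y)),
    hmd = hmd_density(y, bins, m)
  )
  class(out) <- c("coloc_profile", class(out))
  attr(out, "m") <- m
  attr(out, "n_queries") <- nrow(queries)
  out
}

#' @exportS3Method generics::tidy
tidy.coloc_profile <- function(x, ...) {
  as_tibble(unclass_profile(x))
}

#' @exportS3Method generics::glance
glance.coloc_profile <- function(x, ...) {
  tibble(
    m = attr(x, "m"),
    n_queries = attr(x, "n_queries"),
    n_within_max_bin = x$cumulative[nrow(x)],
    frac_within_max_bin = x$cumulative[nrow(x)] / attr(x, "n_queries"),
    peak_hmd = max(x$hmd)
  )
}

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), c("coloc_profile", "feature_distribution",
                                  "position_profile"))
  x
}
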