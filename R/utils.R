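# Internal helpers shared across modules.

# Integer-valued check that tolerates numeric storage.
is_integerish <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x == trunc(x))
}

# Point-in-interval stabbing over possibly overlapping intervals.
# Returns, for each position, whether it falls in at least one [start, end).
# Indexed: sort by start, take the running max of ends, then one findInterval
# per query. Correct because a point p is covered iff some interval with
# start <= p has end > p, and the running max preserves that property.
points_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  o <- order(starts)
  s <- starts[o]
  e <- cummax(ends[o])
  i <- findInterval(pos, s)
  hit <- i > 0L
  hit[hit] <- e[i[hit]] > pos[hit]
  hit
}

# Nearest value in a sorted numeric vector for each query point; returns the
# index into the *sorted* vector and the absolute distance. Ties between the
# left and right neighbour are reported with both candidate indices so the
# caller can apply its own tie rule.
nearest_sorted <- function(query, sorted) {
  n <- length(sorted)
  i <- findInterval(query, sorted)
  left <- pmax(i, 1L)
  right <- pmin(i + 1L, n)
  d_left <- ifelse(i >= 1L, abs(query - sorted[left]), Inf)
  d_right <- ifelse(i < n, abs(sorted[right] - query), Inf)
  list(left = left, right = right, d_left = d_left, d_right = d_right)
}

# Merge possibly-overlapping half-open intervals given as a two-column matrix
# (start, end); returns a matrix of disjoint sorted intervals.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(cbind(start = integer(), end = integer()))
  }
  o <- order(starts, ends)
  s <- starts[o]
  e <- ends[o]
  out_s <- s[1]
  out_e <- e[1]
  for (k in seq_along(s)[-1]) {
    m <- length(out_s)
    if (s[k] <= out_e[m]) {
      out_e[m] <- max(out_e[m], e[k])
    } else {
      out_s <- c(out_s, s[k])
      out_e <- c(out_e, e[k])
    }
  }
  cbind(start = out_s, end = out_e)
}

# Complement of a set of half-open intervals within [0, size).
complement_intervals <- function(starts, ends, size) {
  m <- merge_intervals(pmax(starts, 0L), pmin(ends, size))
  keep <- m[, "end"] > m[, "start"]
  m <- m[keep, , drop = FALSE]
  edges_s <- c(0, m[, "end"])
  edges_e <- c(m[, "start"], size)
  keep <- edges_e > edges_s
  cbind(start = edges_s[keep], end = edges_e[keep])
}
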