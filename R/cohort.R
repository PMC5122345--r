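# Clinical-cohort stage: qPCR standard-curve quantification, housekeeping
# normalization, high/low dichotomization and the association tests used for
# expression-phenotype comparisons.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a serial-dilution
#' series. A valid amplification curve has negative slope (Ct falls as
#' template rises); a slope of -3.32 corresponds to 100% PCR efficiency.
#'
#' @param data Data frame of standards.
#' @param quantity,ct Columns holding template quantity (> 0) and Ct value
#'   (unquoted; default `quantity` and `ct`).
#' @return A `standard_curve` object with `slope` (Ct per decade), `intercept`
#'   (Ct at quantity 1) and `r_squared`.
#' @examples
#' std <- data.frame(quantity = 10^(0:4), ct = 40 - 3.32 * (0:4))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(data, quantity = quantity, ct = ct) {
  q <- eval_tidy(enquo(quantity), data)
  y <- eval_tidy(enquo(ct), data)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("all template quantities must be positive", call. = FALSE)
  }
  if (length(unique(q)) < 3L) {
    stop("need at least 3 distinct template quantities", call. = FALSE)
  }
  fit <- lm(y ~ log10(q))
  ss_tot <- sum((y - mean(y))^2)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot,
    n = length(q)
  )
  if (out$slope >= 0) {
    warning("standard curve has non-negative slope; Ct should fall as template rises")
  }
  structure(out, class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f * log10(quantity) + %.4f (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = x$n)
}

#' Quantify template from a Ct value
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept) / slope)`.
#' Downstream, normalized expression is `quantify(goi_ct) / quantify(gapdh_ct)`
#' with each gene read off its own curve.
#'
#' @param ct Numeric Ct values.
#' @param curve A `standard_curve`.
#' @return Numeric template quantities.
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve slope is zero", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Add normalized expression to a cohort table
#'
#' Quantifies the gene of interest and the housekeeping gene through their
#' standard curves and appends `goi_value`, `gapdh_value` and their ratio
#' `expression` (GOI/GAPDH).
#'
#' @param data Per-patient cohort table.
#' @param goi_curve,gapdh_curve `standard_curve` objects.
#' @param goi_ct,gapdh_ct Columns holding the Ct values (unquoted).
#' @return `data` with the three expression columns appended.
#' @export
add_expression <- function(data, goi_curve, gapdh_curve,
                           goi_ct = goi_ct, gapdh_ct = gapdh_ct) {
  gv <- quantify(eval_tidy(enquo(goi_ct), data), goi_curve)
  hv <- quantify(eval_tidy(enquo(gapdh_ct), data), gapdh_curve)
  dplyr::mutate(as_tibble(data), goi_value = gv, gapdh_value = hv,
                expression = gv / hv)
}

#' Split expression values into high and low groups
#'
#' Median dichotomization (the quartile rule Q3-4 vs Q1-2): values strictly
#' above the cutoff are `high`, others `low`, so ties at the median go low.
#' With distinct values and even n the split is n/2 : n/2. An explicit numeric
#' `cutoff` reproduces unequal splits chosen by other software.
#'
#' @param values Numeric expression values (n >= 4 for the median rule).
#' @param cutoff `"median"` (default) or an explicit numeric threshold.
#' @return Factor with levels `low`, `high`.
#' @examples
#' dichotomize(1:8) # low low low low high high high high
#' @export
dichotomize <- function(values, cutoff = "median") {
  if (identical(cutoff, "median")) {
    if (length(values) < 4L) stop("need at least 4 values", call. = FALSE)
    if (length(unique(values)) == 1L) {
      stop("all values identical: no high/low split exists", call. = FALSE)
    }
    cutoff <- median(values)
  } else if (!is.numeric(cutoff) || length(cutoff) != 1L) {
    stop("cutoff must be \"median\" or a single number", call. = FALSE)
  }
  factor(ifelse(values > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Chi-square association between groups and a categorical feature
#'
#' Pearson chi-square on the 2x2 contingency table of group label against a
#' binary feature, without continuity correction by default (set
#' `correct = TRUE` for the Yates-corrected variant). Group percentages of the
#' feature's second level are reported alongside.
#'
#' @param groups Two-level group labels.
#' @param feature Two-level categorical covariate.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, and a
#'   `summary` list-column with per-group `n` and `percent`.
#' @examples
#' test_categorical(rep(c("low", "high"), each = 10),
#'                  rep(c("no", "yes"), 10))
#' @export
test_categorical <- function(groups, feature, correct = FALSE) {
  g <- factor(groups)
  f <- factor(feature)
  if (nlevels(g) != 2L || nlevels(f) != 2L) {
    stop("groups and feature must each have exactly two levels", call. = FALSE)
  }
  tab <- table(g, f)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-square test undefined", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  summary <- tibble(
    group = levels(g),
    n = as.integer(rowSums(tab)),
    percent = unname(100 * tab[, 2] / rowSums(tab))
  )
  tibble(
    test = "chi_square",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    summary = list(summary)
  )
}

#' Mann-Whitney association between groups and a continuous covariate
#'
#' Two-sided Mann-Whitney U test. Exact enumeration is used when both groups
#' have at most 8 observations and no ties are present; otherwise the normal
#' approximation with tie correction (and continuity correction) applies. The
#' reported statistic is the U for the first group level.
#'
#' @param groups Two-level group labels.
#' @param values Numeric covariate.
#' @return One-row tibble: `test`, `statistic`, `p_value`, and a `summary`
#'   list-column with per-group `n` and `median`.
#' @export
test_continuous <- function(groups, values) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels", call. = FALSE)
  v1 <- values[g == levels(g)[1]]
  v2 <- values[g == levels(g)[2]]
  if (length(v1) == 0L || length(v2) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- length(v1) <= 8L && length(v2) <= 8L && !anyDuplicated(c(v1, v2))
  res <- suppressWarnings(
    wilcox.test(v1, v2, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  summary <- tibble(
    group = levels(g),
    n = c(length(v1), length(v2)),
    median = c(median(v1), median(v2))
  )
  tibble(
    test = "mann_whitney",
    statistic = unname(res$statistic),
    df = NA_real_,
    p_value = res$p.value,
    summary = list(summary)
  )
}

#' Association screen of covariates against a group label
#'
#' Runs [test_continuous()] for numeric covariates and [test_categorical()]
#' for categorical ones, one row per covariate.
#'
#' @param data Cohort table.
#' @param group Column holding the two-level group label (unquoted).
#' @param covariates Character vector of covariate column names; defaults to
#'   every column except the group column.
#' @param correct Continuity correction for the chi-square branch.
#' @return Tibble with one row per covariate: `covariate`, `test`,
#'   `statistic`, `df`, `p_value`, `summary`.
#' @export
associate <- function(data, group, covariates = NULL, correct = FALSE) {
  g <- eval_tidy(enquo(group), data)
  gname <- rlang::as_name(enquo(group))
  if (is.null(covariates)) covariates <- setdiff(names(data), gname)
  purrr::map_dfr(covariates, function(cv) {
    v <- data[[cv]]
    res <- if (is.numeric(v)) {
      test_continuous(g, v)
    } else {
      test_categorical(g, v, correct = correct)
    }
    dplyr::bind_cols(tibble(covariate = cv), res)
  })
}
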