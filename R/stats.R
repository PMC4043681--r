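# Group statistics used in the study design: two-sided Mann-Whitney,
# Wilcoxon signed-rank with Dunn's pairwise follow-up, Pearson correlation,
# and the radiographic percent-increase measure.
#
# Exact-vs-approximation branch points are fixed constants so p-values are
# bit-reproducible; the branch taken is recorded in the `method` column.

MW_EXACT_MAX_PRODUCT <- 2500L   # exact Mann-Whitney when n_x * n_y <= this and no ties
WSR_EXACT_MAX_N <- 15L          # exact signed-rank when n <= this and no ties

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Without ties and for
#' small samples the p-value is exact (enumeration over arrangements);
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. The statistic is U for the first sample
#' (0 on complete separation with all `x` below all `y`).
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A one-row tibble: `statistic` (U), `p_two_sided`, `method`
#'   (`"exact"` or `"normal-approximation"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) * length(y) <= MW_EXACT_MAX_PRODUCT)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_two_sided = ht$p.value,
    method = if (exact) "exact" else "normal-approximation",
    n_x = length(x), n_y = length(y)
  )
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; the reported statistic is the smaller of
#' the positive- and negative-signed rank sums. Exact p for small samples
#' without tied magnitudes, tie-corrected normal approximation otherwise.
#'
#' @param paired_diffs Numeric vector of paired differences with at least
#'   one non-zero value.
#' @return A one-row tibble: `statistic` (W = min signed-rank sum),
#'   `p_two_sided`, `method`, `n` (non-zero differences used).
#' @examples
#' wilcoxon_signed_rank(c(2, 1, 3, 5, 4)) # all positive: W = 0, p = 0.0625
#' @export
wilcoxon_signed_rank <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (!length(d))
    stop("all paired differences are zero: signed-rank test undefined",
         call. = FALSE)
  n <- length(d)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && n <= WSR_EXACT_MAX_N
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  v <- unname(ht$statistic)                    # positive-rank sum
  w <- min(v, n * (n + 1) / 2 - v)
  tibble::tibble(
    statistic = w, p_two_sided = ht$p.value,
    method = if (exact) "exact" else "normal-approximation", n = n
  )
}

#' Dunn's multiple-comparison test
#'
#' Pairwise rank-based z statistics on the pooled midranks with tie
#' correction, family-wise adjusted by the Bonferroni factor over the
#' k(k-1)/2 comparisons (Dunn's classical procedure), capped at 1.
#'
#' @param groups Named list of numeric samples (>= 2 groups, each
#'   non-empty). Unnamed lists get `group1`, `group2`, ... labels.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_multiple_comparison <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(!lengths(groups))) stop("a group is empty", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)                           # midranks
  gidx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, gidx, mean)
  n <- lengths(groups)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(s2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  p_un <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    z = as.numeric(z),
    p_unadjusted = as.numeric(p_un),
    p_adjusted = pmin(1, as.numeric(p_un) * m)
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A one-row tibble: `r`, `p_two_sided`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length samples of size >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ht$estimate), p_two_sided = ht$p.value,
                 n = length(x))
}

#' Radiographic percent increase of the injected limb
#'
#' `100 * (tumor_area - control_area) / control_area`: weekly tumor growth
#' as the percentage increase in soft-tissue silhouette area of the injected
#' tibia relative to the paired contralateral, non-injected tibia.
#'
#' @param tumor_area,control_area Areas in mm^2 (control > 0). Vectorized.
#' @return Percent increase (may be negative).
#' @examples
#' percent_increase(3.3, 3.0) # 10
#' @export
percent_increase <- function(tumor_area, control_area) {
  if (any(control_area <= 0))
    stop("`control_area` must be positive", call. = FALSE)
  100 * (tumor_area - control_area) / control_area
}
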