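#' Paired Wilcoxon signed-rank test
#'
#' Classic signed-rank handling: zero differences are dropped, absolute
#' differences are ranked with average ranks for ties, and
#' `W = min(W+, W-)`. For `n <= exact_max` retained pairs the two-sided
#' p-value is exact, computed by enumerating the null distribution of `W+`
#' over all `2^n` sign assignments (a subset-sum convolution over the
#' possibly tied rank values — ties are handled exactly, unlike the exact
#' path of [stats::wilcox.test()]); the p-value is `2 * P(W+ <= W)`, capped
#' at 1. Above `exact_max` a normal approximation with tie correction and a
#' 0.5 continuity correction is used. If every difference is zero the result
#' is `p = 1`, `direction = "none"` (a documented convention, not an error).
#'
#' @param a,b Paired numeric vectors of equal length (`a - b` is tested).
#' @param exact_max Largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return An object of class `paired_test`: list with `n_pairs` (pairs
#'   retained after dropping zero differences), `n_zero_diffs_dropped`, `W`,
#'   `p_value` and `direction` (`"a_greater"`, `"b_greater"` or `"none"`,
#'   from the sign of the median non-zero difference).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))$p_value  # 0.0625
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  if (length(a) != length(b) || length(a) < 1)
    .err("a and b must be paired vectors of equal length >= 1",
         "ploidyTE_value_error")
  if (anyNA(a) || anyNA(b))
    .err("NA values in paired vectors", "ploidyTE_value_error")
  d <- a - b
  nz <- d != 0
  dn <- d[nz]
  n <- length(dn)
  if (n == 0) {
    return(structure(list(n_pairs = 0L, n_zero_diffs_dropped = length(d),
                          W = 0, p_value = 1, direction = "none"),
                     class = "paired_test"))
  }
  r <- rank(abs(dn))
  w_plus <- sum(r[dn > 0])
  w_minus <- sum(r[dn < 0])
  W <- min(w_plus, w_minus)
  if (n <= exact_max) {
    p <- .wsr_exact_p(r, W)
  } else {
    ties <- table(abs(dn))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - n * (n + 1) / 4 + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
  }
  med <- median(dn)
  direction <- if (med > 0) "a_greater" else if (med < 0) "b_greater" else "none"
  structure(list(n_pairs = n, n_zero_diffs_dropped = sum(!nz),
                 W = W, p_value = p, direction = direction),
            class = "paired_test")
}

# Exact two-sided p: distribution of W+ over all 2^n sign assignments via
# subset-sum convolution on doubled ranks (average ranks can be half-integer).
.wsr_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  tot <- sum(s)
  f <- numeric(tot + 1)
  f[1] <- 1
  for (si in s) {
    f[(si + 1):(tot + 1)] <- f[(si + 1):(tot + 1)] + f[1:(tot + 1 - si)]
  }
  w2 <- as.integer(round(2 * W))
  min(1, 2 * sum(f[seq_len(w2 + 1)]) / 2^length(ranks))
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired Wilcoxon signed-rank: n=%d (%d zero diffs dropped), W=%g, p=%.4g, direction=%s\n",
              x$n_pairs, x$n_zero_diffs_dropped, x$W, x$p_value, x$direction))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, delegated to
#' [stats::p.adjust()] with `method = "BH"` after range validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    .err("p-values must lie in [0, 1]", "ploidyTE_value_error")
  p.adjust(p, method = "BH")
}

#' Squared Pearson correlation between replicates
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return `R^2`, the squared Pearson coefficient.
#' @export
replicate_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .err("x and y must have equal length >= 3", "ploidyTE_value_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    .err("zero variance in a replicate vector", "ploidyTE_value_error")
  cor(x, y)^2
}

#' Transcripts per million
#'
#' `rate_i = counts_i / length_i`; `TPM_i = 1e6 * rate_i / sum(rate)`. The
#' vector sums to 1e6 whenever any count is positive; an all-zero count
#' vector yields all-zero TPM.
#'
#' @param counts Non-negative counts per gene.
#' @param lengths_bp Positive gene lengths in bp.
#' @return TPM vector (names preserved from `counts`).
#' @export
tpm <- function(counts, lengths_bp) {
  if (length(counts) != length(lengths_bp))
    .err("counts and lengths_bp must have equal length", "ploidyTE_value_error")
  if (any(lengths_bp <= 0))
    .err("gene lengths must be positive", "ploidyTE_value_error")
  if (any(counts < 0))
    .err("counts must be non-negative", "ploidyTE_value_error")
  rate <- counts / lengths_bp
  s <- sum(rate)
  if (s == 0) return(rate)
  1e6 * rate / s
}

#' Call differential-expression labels from supplied statistics
#'
#' Applies the thresholds FDR < `fdr_max` and |log2FC| > `lfc_min` (both
#' strict) to a per-gene table of externally computed DE statistics;
#' q-values come from [bh_adjust()]. The fold-change threshold is applied to
#' the absolute value, with the sign giving `up` vs `down`.
#'
#' @param stats_table Data.frame with columns `log2fc` and `p_value` (other
#'   columns, e.g. `gene_id`, pass through).
#' @param fdr_max FDR threshold (default 0.01).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @return `stats_table` with added `q_value` and `label`
#'   (`"up"`/`"down"`/`"ns"`).
#' @export
call_de_labels <- function(stats_table, fdr_max = 0.01, lfc_min = 1) {
  need <- c("log2fc", "p_value")
  if (!all(need %in% names(stats_table)))
    .err("stats_table needs columns log2fc and p_value", "ploidyTE_value_error")
  stats_table$q_value <- bh_adjust(stats_table$p_value)
  sig <- stats_table$q_value < fdr_max & abs(stats_table$log2fc) > lfc_min
  stats_table$label <- ifelse(!sig, "ns",
                              ifelse(stats_table$log2fc > 0, "up", "down"))
  stats_table
}

# round half away from zero at `decimals` digits (reproduces printed
# percentages; base round() is round-half-to-even)
.round_half_away <- function(x, decimals) {
  m <- 10^decimals
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-set Venn partition with shared percentages
#'
#' Counts elements unique to each set and shared, plus the shared fraction
#' of each set as a percentage rounded (half away from zero) to one decimal.
#' An empty set has shared percentage 0.
#'
#' @param set_a,set_b Vectors of IDs (deduplicated internally).
#' @return List with `a_only`, `b_only`, `shared`, `pct_shared_of_a`,
#'   `pct_shared_of_b`.
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  a_only <- length(a) - shared
  b_only <- length(b) - shared
  pct <- function(total) if (total == 0) 0 else
    .round_half_away(100 * shared / total, 1)
  list(a_only = a_only, b_only = b_only, shared = shared,
       pct_shared_of_a = pct(a_only + shared),
       pct_shared_of_b = pct(b_only + shared))
}

#' Percentage of a total
#'
#' `round(100 * n / total, decimals)` with half-away-from-zero rounding.
#'
#' @param n Count, `0 <= n <= total`.
#' @param total Positive total.
#' @param decimals Decimal places to round to.
#' @return The percentage as a plain number.
#' @export
#' @examples
#' fraction_of_total(134, 40615, 2)  # 0.33
fraction_of_total <- function(n, total, decimals = 1) {
  if (total <= 0) .err("total must be > 0", "ploidyTE_value_error")
  if (n < 0 || n > total)
    .err("n must satisfy 0 <= n <= total", "ploidyTE_value_error")
  .round_half_away(100 * n / total, decimals)
}
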