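# Default verdict thresholds for group comparisons.
P_SIGNIFICANT <- 0.05
P_TREND <- 0.10

.check_ct <- function(ct, what = "Ct") {
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 45))
    stop(what, " values must be finite cycles in (0, 45)")
  invisible(ct)
}

#' Relative expression by the 2^-dCt method
#'
#' Expression of a target normalised to a reference RNA (typically U6):
#' `2^-(target_ct - reference_ct)`. Invariant to a common cycle offset,
#' so fold changes between samples equal ratios of relative expressions.
#'
#' @param target_ct,reference_ct Cycle thresholds (vectorised).
#' @return Relative expression values.
#' @export
relative_expression_dct <- function(target_ct, reference_ct) {
  .check_ct(target_ct, "target Ct")
  .check_ct(reference_ct, "reference Ct")
  2^-(target_ct - reference_ct)
}

#' Mature-tRNA / tRF fragmentation ratio
#'
#' The absolute Ct of the mature tRNA divided by the Ct of its fragment.
#' Because lower Ct means more template, a larger ratio indicates more
#' tRF relative to the mature tRNA — the ratio rises when the guiding
#' snoRNA is inhibited and cleavage increases.
#'
#' @param mature_ct,trf_ct Cycle thresholds (vectorised).
#' @return `mature_ct / trf_ct`.
#' @export
fragmentation_ratio <- function(mature_ct, trf_ct) {
  .check_ct(mature_ct, "mature Ct")
  .check_ct(trf_ct, "tRF Ct")
  mature_ct / trf_ct
}

#' Normalise expression to a baseline time point
#'
#' Fraction of RNA remaining at time t relative to t0, used to compare
#' degradation rates after transcription arrest.
#'
#' @param expr_t Relative expression at time t.
#' @param expr_t0 Relative expression at time 0.
#' @return `expr_t / expr_t0`.
#' @export
normalize_to_baseline <- function(expr_t, expr_t0) {
  if (any(expr_t0 <= 0)) stop("baseline expression must be positive")
  expr_t / expr_t0
}

#' Normalise a target to several reference genes
#'
#' Multi-reference 2^-dCt normalisation using the geometric mean of the
#' reference Cts (arithmetic mean on the cycle scale), as in degradation
#' assays normalised to two housekeeping RNAs.
#'
#' @param target_ct Target cycle thresholds.
#' @param reference_cts Numeric matrix or data frame, one column per
#'   reference gene (or a vector for a single reference).
#' @return Relative expression values.
#' @export
relative_expression_multi_ref <- function(target_ct, reference_cts) {
  ref <- as.matrix(reference_cts)
  .check_ct(as.numeric(ref), "reference Ct")
  relative_expression_dct(target_ct, rowMeans(ref))
}

#' Two-group comparison with significance and trend verdicts
#'
#' Two-tailed t tests as used throughout snoRNA knockdown experiments:
#' unpaired (Student) for independent treatment/control groups, paired
#' within experiments, or ratio-paired (a paired t test on
#' log-transformed values, appropriate when effects are multiplicative).
#' Verdicts: `significant` when p < `alpha`, `trend` when
#' `alpha <= p < trend`, else `ns`. Degenerate zero-variance inputs are
#' resolved by the sign of the mean difference (identical groups give
#' t = 0, p = 1).
#'
#' @param values_a,values_b Numeric vectors (equal length and matching
#'   order of pairing units when `paired` or `ratio_paired`).
#' @param paired Paired t test on `a - b`.
#' @param ratio_paired Paired t test on `log(a) - log(b)`; requires
#'   positive values. Implies `paired`.
#' @param alpha Significance threshold (default 0.05).
#' @param trend Trend threshold (default 0.1).
#' @param var_equal Pool variances in the unpaired test (default TRUE,
#'   the classical two-sample t test).
#' @return A list with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference, or mean log-ratio for ratio-paired), `method` and
#'   `verdict`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE,
                           ratio_paired = FALSE, alpha = P_SIGNIFICANT,
                           trend = P_TREND, var_equal = TRUE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group")
  if (ratio_paired) {
    if (any(a <= 0) || any(b <= 0))
      stop("ratio-paired comparison requires positive values")
    a <- log(a); b <- log(b)
    paired <- TRUE
  }
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes")

  near0 <- function(x) isTRUE(all.equal(x, 0))
  degenerate <- if (paired) near0(stats::sd(a - b))
                else near0(stats::sd(a)) && near0(stats::sd(b))
  if (degenerate) {
    d <- mean(a) - mean(b)
    statistic <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    res <- list(statistic = statistic, df = df, p_value = p, estimate = d)
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                        alternative = "two.sided")
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, estimate = unname(
                  if (paired) tt$estimate else tt$estimate[1] - tt$estimate[2]))
  }
  res$method <- if (ratio_paired) "ratio paired t test"
                else if (paired) "paired t test"
                else "unpaired t test"
  res$verdict <- verdict_from_p(res$p_value, alpha, trend)
  res
}

#' Map a p value to the significant / trend / ns verdict
#'
#' @param p P value.
#' @param alpha Significance threshold (default 0.05).
#' @param trend Trend threshold (default 0.1).
#' @return `"significant"`, `"trend"` or `"ns"`.
#' @export
verdict_from_p <- function(p, alpha = P_SIGNIFICANT, trend = P_TREND) {
  ifelse(p < alpha, "significant", ifelse(p < trend, "trend", "ns"))
}
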