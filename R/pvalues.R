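# P-value diagnostics and right-tail adjustment.

#' Right-tail p-value adjustment
#'
#' Preprocessing that consumes degrees of freedom (e.g. eigentrend removal,
#' imputation) can inflate test statistics and skew the null p-value
#' distribution. Because it is unknown which features are truly null, only
#' the right tail of the p-value distribution (p > \code{null_tail_start})
#' is taken as null: an inflation factor \eqn{\lambda} is estimated by
#' matching the median of \eqn{-\log p} in that tail to its uniform
#' expectation, all \eqn{-\log p} values are rescaled by \eqn{1/\lambda},
#' and mapped back (i.e. \eqn{p_{adj} = p^{1/\lambda}}). The transform is
#' monotone, so rankings are preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param null_tail_start left edge of the tail treated as null
#'   (default 0.5).
#' @param min_tail minimum number of tail p-values required (default 50).
#' @return Adjusted p-values, same order as the input, with the estimated
#'   inflation factor in attribute \code{"lambda"}.
#' @export
adjust_pvalues <- function(p, null_tail_start = 0.5, min_tail = 50L) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_("all p-values must lie in [0, 1]")
  if (null_tail_start <= 0 || null_tail_start >= 1)
    stop_("'null_tail_start' must lie in (0, 1)")
  tail <- p[p > null_tail_start]
  if (length(tail) < min_tail)
    stop_("only %d p-values exceed %.2f; need >= %d for tail calibration",
          length(tail), null_tail_start, min_tail)
  # ratio of the observed tail median of -log p to its uniform
  # expectation. The right tail identifies strong inflation only weakly,
  # so lambda is a stable but deliberately mild correction factor.
  expected <- -log((1 + null_tail_start) / 2)
  lambda <- stats::median(-log(tail)) / expected
  adj <- exp(-(-log(p)) / lambda)
  adj <- pmin(pmax(adj, 0), 1)
  attr(adj, "lambda") <- lambda
  adj
}

#' Uniformity diagnostic for a p-value collection
#'
#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1) plus histogram
#' counts — the standard "is my null flat?" plot behind differential
#' expression pipelines. Null p-values from a well-calibrated pipeline are
#' approximately uniform; an excess near 0 beyond the true signal spike, or
#' a global skew, indicates overfitting or residual bias.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param n_bins number of equal-width histogram bins (default 20).
#' @return List with \code{ks_statistic}, \code{ks_p} and
#'   \code{bin_counts} (length \code{n_bins}, summing to
#'   \code{length(p)}).
#' @export
pvalue_uniformity_diagnostic <- function(p, n_bins = 20L) {
  if (!length(p)) stop_("empty p-value vector")
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_("all p-values must lie in [0, 1]")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  counts <- graphics::hist(p, breaks = seq(0, 1, length.out = n_bins + 1L),
                           plot = FALSE, include.lowest = TRUE)$counts
  list(ks_statistic = unname(ks$statistic), ks_p = unname(ks$p.value),
       bin_counts = counts)
}

#' Per-peptide two-sample group tests
#'
#' Vectorized pooled-variance t-tests of the two-group difference for every
#' peptide row, over observed cells. Peptides with fewer than two observed
#' values in either group get \code{NA}.
#'
#' @param m an \code{abund_matrix}.
#' @param design a \code{study_design} with exactly two groups.
#' @return data.frame with columns \code{peptide_id}, \code{estimate}
#'   (group2 - group1), \code{t}, \code{df}, \code{p_value}.
#' @export
peptide_ttests <- function(m, design) {
  design <- align_design(m, design)
  if (nlevels(design$group) != 2L)
    stop_("peptide_ttests requires exactly two groups")
  g <- levels(design$group)
  v1 <- m$values[, design$group == g[1L], drop = FALSE]
  v2 <- m$values[, design$group == g[2L], drop = FALSE]
  n1 <- rowSums(!is.na(v1)); n2 <- rowSums(!is.na(v2))
  m1 <- rowMeans(v1, na.rm = TRUE); m2 <- rowMeans(v2, na.rm = TRUE)
  ss1 <- rowSums((v1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((v2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- m2 - m1
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df)
  ok <- n1 >= 2L & n2 >= 2L & is.finite(t)
  out <- data.frame(peptide_id = m$peptide_ids, estimate = est,
                    t = t, df = df, p_value = p, stringsAsFactors = FALSE)
  out[!ok, c("estimate", "t", "df", "p_value")] <- NA_real_
  out
}
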