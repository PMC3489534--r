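# Protein-level group-difference estimation: point estimates, confidence
# intervals and p-values, from either the censored-likelihood fit (Wald)
# or constrained least squares on a complete matrix (t reference).

# per-protein least-squares test with per-peptide variances and a
# Satterthwaite df for the protein-level difference
ls_test_protein <- function(y, grp) {
  J <- nrow(y); K <- nlevels(grp)
  obs <- !is.na(y)
  na_out <- list(estimate = NA_real_, se = NA_real_, df = NA_real_)
  if (!sum(obs)) return(na_out)
  jj <- row(y)[obs]; yy <- y[obs]
  grp_obs <- grp[col(y)[obs]]
  if (nlevels(droplevels(grp_obs)) < K) return(na_out)
  pep_f <- droplevels(factor(jj, levels = seq_len(J)))
  Jo <- nlevels(pep_f)
  X <- cbind(1,
             if (Jo > 1L) stats::contr.sum(Jo)[as.integer(pep_f), , drop = FALSE],
             stats::contr.sum(K)[as.integer(grp_obs), , drop = FALSE])
  qf <- qr(X)
  if (qf$rank < ncol(X)) return(na_out)
  beta <- qr.coef(qf, yy)
  # difference (group 2 - group 1); with contr.sum, Treat_1 = b, Treat_2 = -b
  cvec <- numeric(ncol(X)); cvec[ncol(X)] <- -2
  est <- sum(cvec * beta)
  # contrast weights on observations: a = c' (X'X)^{-1} X'
  XtX_inv_c <- backsolve(qr.R(qf), backsolve(qr.R(qf), cvec, transpose = TRUE))
  a <- drop(X %*% XtX_inv_c)
  res <- yy - drop(X %*% beta)
  n_j <- tabulate(jj, nbins = J)
  ssr_j <- vapply(seq_len(J), function(j) sum(res[jj == j]^2), numeric(1))
  df_j <- pmax(n_j - 1 - (K - 1) / max(Jo, 1L), 0.5)
  var_j <- ssr_j / df_j
  # pooled fallback for peptides that cannot support a variance estimate
  pool_df <- sum(df_j[n_j >= 2L])
  pool_var <- if (pool_df > 0) sum(ssr_j[n_j >= 2L]) / pool_df else NA_real_
  var_j[n_j < 2L] <- pool_var
  c_j <- vapply(seq_len(J), function(j) sum(a[jj == j]^2), numeric(1))
  contrib <- c_j * var_j
  if (any(!is.finite(contrib) & c_j > 0)) return(na_out)
  v <- sum(contrib, na.rm = TRUE)
  df_sat <- v^2 / sum(contrib^2 / ifelse(n_j >= 2L, df_j, pool_df),
                      na.rm = TRUE)
  list(estimate = est, se = sqrt(v), df = df_sat)
}

# Wald machinery for one ML fit: SE and an approximate df for the
# difference between the two groups
wald_from_fit <- function(fit) {
  J <- fit$J; K <- fit$K
  lay <- theta_layout(J, K)
  est <- -fit$delta[[1L]]                     # group2 - group1 for K = 2
  if (isTRUE(fit$complete)) {
    # complete data: the least-squares difference estimate is the plain
    # mean of the per-peptide group differences; its variance combines the
    # df-corrected per-peptide variances, referenced against a t with
    # Satterthwaite-pooled degrees of freedom.
    n_jk <- fit$n_jk
    n_j <- rowSums(n_jk)
    df_j <- pmax(n_j - 1 - (K - 1) / J, 0.5)
    sig2 <- fit$ssr / df_j
    contrib <- sig2 * (1 / n_jk[, 1L] + 1 / n_jk[, 2L]) / J^2
    v <- sum(contrib)
    df <- v^2 / sum(contrib^2 / df_j)
    return(list(estimate = unname(est), se = sqrt(v), df = df))
  }
  im <- fit$info_matrix
  if (is.null(im)) stop_("fit carries no information matrix")
  d_idx <- lay$delta
  n_idx <- setdiff(seq_len(nrow(im)), d_idx)
  blk <- tryCatch(
    im[d_idx, d_idx] - im[d_idx, n_idx, drop = FALSE] %*%
      solve(im[n_idx, n_idx], t(im[d_idx, n_idx, drop = FALSE])),
    error = function(e) NA_real_)
  v <- 1 / drop(blk)
  p_mean <- J + K - 1L
  n_eff <- fit$n_obs
  # finite-sample correction: ML variances divide by n rather than df
  v <- v * n_eff / max(n_eff - p_mean, 1)
  df <- max(n_eff - p_mean - J, 2)
  if (!is.finite(v) || v <= 0)
    return(list(estimate = unname(est), se = NA_real_, df = NA_real_))
  list(estimate = unname(est), se = sqrt(v), df = df)
}

#' Protein-level group-difference tests
#'
#' Estimates each protein's between-group difference on the log scale with
#' a confidence interval and two-sided p-value. Two methods:
#' \describe{
#'   \item{complete_data_anova}{constrained least squares per protein on
#'     the (complete or observed-cell) matrix; per-peptide residual
#'     variances are combined into the contrast variance and referenced
#'     against a t distribution with Satterthwaite-pooled degrees of
#'     freedom.}
#'   \item{wald_ml}{the censored/MCAR maximum-likelihood fit; the SE comes
#'     from the observed information with nuisance parameters profiled
#'     out, with a finite-sample variance correction and a t reference on
#'     approximate residual degrees of freedom.}
#' }
#' Intervals are currently defined for two-group designs.
#'
#' @param m an \code{abund_matrix}.
#' @param design a \code{study_design} with exactly two groups.
#' @param pmap a \code{protein_map}.
#' @param level confidence level (default 0.95).
#' @param method \code{"complete_data_anova"} or \code{"wald_ml"}.
#' @param params \code{missingness_params} for \code{wald_ml}; estimated
#'   from \code{m} when \code{NULL}.
#' @param ... passed to [fit_protein_ml()] for \code{wald_ml}.
#' @return data.frame of class \code{"protein_tests"}: one row per protein
#'   with \code{protein_id}, \code{estimate} (second group minus first),
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{se}, \code{df},
#'   \code{method}. Non-estimable proteins get \code{NA}s.
#' @export
test_protein_difference <- function(m, design, pmap, level = 0.95,
                                    method = c("complete_data_anova",
                                               "wald_ml"),
                                    params = NULL, ...) {
  method <- match.arg(method)
  design <- align_design(m, design)
  if (nlevels(design$group) != 2L)
    stop_("confidence intervals are defined for two-group designs; got %d groups",
          nlevels(design$group))
  if (level <= 0 || level >= 1) stop_("'level' must lie in (0, 1)")
  prot_of <- map_proteins(m, pmap)
  proteins <- unique(prot_of)
  grp <- design$group
  if (method == "wald_ml" && is.null(params))
    params <- estimate_missingness_params(m)

  rows <- lapply(proteins, function(pr) {
    idx <- which(prot_of == pr)
    if (method == "complete_data_anova") {
      r <- ls_test_protein(m$values[idx, , drop = FALSE], grp)
    } else {
      sub <- abundance_matrix(m$values[idx, , drop = FALSE],
                              m$peptide_ids[idx], m$sample_ids,
                              log_base = m$log_base)
      r <- tryCatch({
        fit <- fit_protein_ml(sub, design, params, ...)
        if (!fit$converged) stop("not converged")
        wald_from_fit(fit)
      }, error = function(e)
        list(estimate = NA_real_, se = NA_real_, df = NA_real_))
    }
    r
  })
  est <- vapply(rows, `[[`, numeric(1), "estimate")
  se <- vapply(rows, `[[`, numeric(1), "se")
  df <- vapply(rows, `[[`, numeric(1), "df")
  tq <- stats::qt(1 - (1 - level) / 2, df)
  tstat <- est / se
  out <- data.frame(protein_id = proteins, estimate = est,
                    ci_low = est - tq * se, ci_high = est + tq * se,
                    p_value = 2 * stats::pt(-abs(tstat), df),
                    se = se, df = df, method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_tests", "data.frame")
  out
}

#' Fraction of confidence intervals covering the truth
#'
#' @param truth named numeric vector of true per-protein differences.
#' @param results a \code{"protein_tests"} data.frame whose
#'   \code{protein_id}s match \code{names(truth)} as a set.
#' @return Fraction, over proteins with a defined interval, of intervals
#'   containing the true value.
#' @export
coverage_proportion <- function(truth, results) {
  if (is.null(names(truth)))
    stop_("'truth' must be a named vector of per-protein differences")
  if (!setequal(names(truth), results$protein_id))
    stop_("protein ids of 'truth' and 'results' do not match")
  tr <- truth[match(results$protein_id, names(truth))]
  ok <- is.finite(results$ci_low) & is.finite(results$ci_high)
  if (!any(ok)) stop_("no interval is defined")
  mean(results$ci_low[ok] <= tr[ok] & tr[ok] <= results$ci_high[ok])
}
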