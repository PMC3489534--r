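# Eigentrend machinery: SVD of (residual) matrices, permutation-based
# selection of significant bias trends, EigenMS-style normalization, and
# residual variance re-inflation.

as_resid_matrix <- function(x) {
  if (inherits(x, "abund_matrix")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) stop_("expected a numeric matrix")
  x
}

#' Eigentrends of a complete matrix
#'
#' Row-centers the matrix and applies the singular value decomposition.
#' The right singular vectors ("eigentrends") are systematic across-sample
#' trends; the squared singular value fractions give the variance each
#' trend explains.
#'
#' @param residuals complete numeric matrix (rows = peptides) or complete
#'   \code{abund_matrix}; typically ANOVA residuals restricted to complete
#'   rows, or a complete data matrix for raw-data diagnostics.
#' @return Object of class \code{"eigentrend_set"}: \code{trends} (columns
#'   are orthonormal length-N vectors), \code{singular_values}
#'   (non-increasing), \code{variance_fraction}.
#' @export
compute_eigentrends <- function(residuals) {
  x <- as_resid_matrix(residuals)
  if (anyNA(x)) stop_("matrix has missing cells; apply complete_rows() first")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_("need at least 2 rows and 2 columns")
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  structure(list(trends = sv$v, singular_values = sv$d,
                 variance_fraction = sv$d^2 / sum(sv$d^2)),
            class = "eigentrend_set")
}

#' @export
print.eigentrend_set <- function(x, ...) {
  cat(sprintf("eigentrend_set: %d trends over %d samples; top variance fractions: %s\n",
              ncol(x$trends), nrow(x$trends),
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 3)),
                    collapse = ", ")))
  invisible(x)
}

# permute entries independently within each row (vectorised)
permute_within_rows <- function(x) {
  o <- order(row(x), stats::runif(length(x)))
  matrix(x[o], nrow(x), ncol(x), byrow = TRUE)
}

# one random column permutation per block of rows, applied jointly to the
# block: preserves within-block row correlation, destroys cross-block
# column alignment
permute_within_blocks <- function(x, blocks) {
  for (b in unique(blocks)) {
    rows <- blocks == b
    x[rows, ] <- x[rows, sample.int(ncol(x)), drop = FALSE]
  }
  x
}

#' Number of significant bias eigentrends
#'
#' Tests the leading singular values of the row-centered matrix against a
#' permutation null obtained by independently scrambling the entries within
#' each row (destroying any across-sample structure while preserving row
#' distributions). Trends are tested sequentially against the
#' \code{(1 - alpha)} point of their null counterparts and testing stops at
#' the first non-significant trend.
#'
#' When rows are known to be correlated in groups (peptides of the same
#' protein share sample-level variation), supply \code{blocks}: the null
#' then permutes columns jointly within each block, preserving the
#' within-block correlation that would otherwise masquerade as trend
#' structure.
#'
#' @param residuals complete numeric matrix or \code{abund_matrix}.
#' @param n_perm number of permutations (>= 1; default 99).
#' @param alpha per-trend significance level (default 0.05).
#' @param seed integer seed for the permutation RNG.
#' @param blocks optional vector of length \code{nrow(residuals)} grouping
#'   correlated rows (e.g. protein ids); \code{NULL} permutes entries
#'   within each row independently.
#' @return Integer: the number of significant leading trends (possibly 0).
#' @export
select_significant_trends <- function(residuals, n_perm = 99L, alpha = 0.05,
                                      seed = 1L, blocks = NULL) {
  x <- as_resid_matrix(residuals)
  if (anyNA(x)) stop_("matrix has missing cells; apply complete_rows() first")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_("need at least 2 rows and 2 columns")
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1)
    stop_("'n_perm' must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_("'alpha' must lie in (0, 1)")
  n_perm <- as.integer(n_perm)
  if (!is.null(blocks) && length(blocks) != nrow(x))
    stop_("'blocks' must have one entry per row")
  obs <- svd(x - rowMeans(x), nu = 0, nv = 0)$d
  null_s <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- if (is.null(blocks)) permute_within_rows(x)
      else permute_within_blocks(x, blocks)
      svd(p - rowMeans(p), nu = 0, nv = 0)$d
    }, numeric(length(obs)))
  })                                            # L x n_perm
  # critical value: order statistic giving per-trend level <= alpha
  idx <- ceiling((1 - alpha) * (n_perm + 1))
  k <- 0L
  for (t in seq_along(obs)) {
    crit <- if (idx <= n_perm) sort(null_s[t, ])[idx] else max(null_s[t, ])
    if (obs[t] > crit) k <- k + 1L else break
  }
  k
}

#' EigenMS-style normalization
#'
#' Removes systematic bias of arbitrary shape from a peptide matrix while
#' protecting the group structure of interest. The pipeline is: (1) fit the
#' peptide ANOVA (protein, peptide and treatment effects, so treatment
#' differences are preserved); (2) compute eigentrends from the complete
#' rows of the residual matrix; (3) select the number of significant bias
#' trends by row permutation; (4) for every peptide, complete or not,
#' estimate its loading on the bias trends by least squares over its
#' observed cells and subtract the projection. Peptides observed in fewer
#' than \code{k + 2} samples are left unadjusted and flagged.
#'
#' @param m an \code{abund_matrix} (log scale).
#' @param design a \code{study_design}.
#' @param pmap a \code{protein_map}.
#' @param n_perm,alpha,seed passed to [select_significant_trends()].
#' @param include_batch also fit batch effects before forming residuals
#'   (default \code{FALSE}: bias is assumed unknown, which is the point of
#'   the eigentrend approach).
#' @return A \code{"norm_result"} with \code{$n_trends_removed},
#'   \code{$trends} (N x k matrix of removed trends), \code{$fit} (the
#'   underlying \code{anova_fit}) and \code{$adjusted} (logical per
#'   peptide). When no trend is significant the input is returned
#'   unchanged.
#' @seealso [reinflate_residuals()] to restore the residual degrees of
#'   freedom consumed by the removal before downstream testing.
#' @export
eigenms_normalize <- function(m, design, pmap, n_perm = 99L, alpha = 0.05,
                              seed = 1L, include_batch = FALSE) {
  stopifnot(inherits(m, "abund_matrix"))
  fit <- fit_peptide_anova(m, design, pmap, include_batch = include_batch)
  R <- fit$residuals
  complete <- rowSums(is.na(R)) == 0L
  if (!any(complete))
    stop_(paste("no peptide has residuals in every sample;",
                "eigentrend normalization is unavailable"))
  prot_blocks <- map_proteins(m, pmap)[complete]
  k <- select_significant_trends(R[complete, , drop = FALSE],
                                 n_perm = n_perm, alpha = alpha, seed = seed,
                                 blocks = prot_blocks)
  P <- nrow(R); N <- ncol(R)
  adjusted <- rep(FALSE, P)
  if (k == 0L) {
    return(new_norm_result(m, method = "eigenms", n_trends_removed = 0L,
                           rng_seed = seed, fit = fit,
                           trends = matrix(numeric(0), N, 0),
                           adjusted = adjusted))
  }
  ev <- compute_eigentrends(R[complete, , drop = FALSE])
  V <- ev$trends[, seq_len(k), drop = FALSE]          # N x k, orthonormal
  bias <- matrix(0, P, N)
  # complete rows: loadings are plain cross-products (V orthonormal)
  Rc <- R[complete, , drop = FALSE]
  bias[complete, ] <- (Rc %*% V) %*% t(V)
  adjusted[complete] <- TRUE
  for (p in which(!complete)) {
    o <- !is.na(R[p, ])
    if (sum(o) < k + 2L) next                         # too few cells: flag
    Vo <- V[o, , drop = FALSE]
    beta <- tryCatch(qr.solve(Vo, R[p, o]), error = function(e) NULL)
    if (is.null(beta)) next
    bias[p, o] <- drop(Vo %*% beta)
    adjusted[p] <- TRUE
  }
  bias[is.na(m$values)] <- 0
  out <- m$values - bias
  new_norm_result(abundance_matrix(out, m$peptide_ids, m$sample_ids,
                                   log_base = m$log_base),
                  method = "eigenms", n_trends_removed = k, rng_seed = seed,
                  fit = fit, trends = V, adjusted = adjusted)
}

#' Re-inflate residual variance after eigentrend removal
#'
#' Removing k eigentrends consumes k degrees of freedom from each adjusted
#' peptide's residual vector — all of it taken from the trend directions —
#' deflating the apparent residual variance by about (N - k)/N and making
#' downstream tests anti-conservative. This step restores the consumed
#' degrees of freedom by adding, for each adjusted peptide, fresh zero-mean
#' Gaussian noise placed in exactly the removed trend directions, with the
#' peptide's own (de-biased) residual variance as scale. The residual
#' scatter is thereby inflated back by the factor N/(N - k) and, because
#' the noise lives where variance was removed, downstream test statistics
#' regain their nominal null distribution without carry-over covariates.
#' With k = 0 the input is returned unchanged.
#'
#' @param r a \code{"norm_result"} produced by [eigenms_normalize()].
#' @param seed integer seed making the added noise reproducible.
#' @return A \code{"norm_result"} with method \code{"eigenms_reinflated"}.
#' @export
reinflate_residuals <- function(r, seed = 1L) {
  stopifnot(inherits(r, "norm_result"))
  if (!r$method %in% "eigenms")
    stop_("'r' must come from eigenms_normalize()")
  k <- r$n_trends_removed
  if (k == 0L) return(r)
  N <- ncol(r$normalized$values)
  if (k >= N) stop_("k = %d trends removed leaves no residual degrees of freedom (N = %d)",
                    k, N)
  fit <- r$fit
  v <- r$normalized$values
  V <- r$trends                                   # N x k, orthonormal
  post_res <- v - fit$fitted
  obs <- !is.na(v)
  n_obs <- rowSums(obs)
  # per-peptide residual variance, de-biased for the k consumed df
  sig2 <- rowSums(post_res^2, na.rm = TRUE) / pmax(n_obs - 1 - k, 1)
  sig2[!r$adjusted | n_obs < k + 2L] <- 0
  complete <- n_obs == N & r$adjusted
  out <- with_seed(seed, {
    if (any(complete)) {
      Z <- matrix(stats::rnorm(sum(complete) * k), ncol = k) *
        sqrt(sig2[complete])
      v[complete, ] <- v[complete, , drop = FALSE] + Z %*% t(V)
    }
    for (p in which(!complete & r$adjusted & sig2 > 0)) {
      o <- obs[p, ]
      # orthonormal basis of the trend span restricted to observed cells
      B <- qr.Q(qr(V[o, , drop = FALSE]))[, seq_len(k), drop = FALSE]
      v[p, o] <- v[p, o] +
        drop(B %*% stats::rnorm(k, 0, sqrt(sig2[p])))
    }
    v
  })
  new_norm_result(abundance_matrix(out, r$normalized$peptide_ids,
                                   r$normalized$sample_ids,
                                   log_base = r$normalized$log_base),
                  method = "eigenms_reinflated", n_trends_removed = k,
                  rng_seed = seed, fit = fit, trends = r$trends,
                  adjusted = r$adjusted)
}
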