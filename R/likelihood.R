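# Joint likelihood for observed, left-censored, and missing-completely-at-
# random (MCAR) peptide abundances. Each cell of a protein's peptide-by-
# sample grid is either observed (density contribution) or missing, in
# which case it was lost either at random, with probability pi, or by
# falling below the censoring cutoff c:
#   observed y:  log(1 - pi) + log N(y; mu, sigma^2)
#   missing:     log(pi + (1 - pi) * Phi((c - mu)/sigma))
# The protein model for the cell mean is
#   mu = Prot_i + Pep_ij + Treat_ik
# with sum-to-zero constraints and a separate sigma per peptide.

#' Missingness mechanism parameters
#'
#' @param pi_mcar probability, shared across all cells, that a measurement
#'   is missing completely at random.
#' @param cutoff left-censoring threshold on the log-abundance scale
#'   (\code{-Inf} disables censoring).
#' @return Object of class \code{"missingness_params"}.
#' @export
missingness_params <- function(pi_mcar, cutoff) {
  if (!is.numeric(pi_mcar) || pi_mcar < 0 || pi_mcar > 1)
    stop_("'pi_mcar' must lie in [0, 1]")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff == Inf)
    stop_("'cutoff' must be finite or -Inf")
  structure(list(pi_mcar = as.numeric(pi_mcar), cutoff = as.numeric(cutoff)),
            class = "missingness_params")
}

#' @export
print.missingness_params <- function(x, ...) {
  cat(sprintf("missingness_params: pi_mcar = %.4g, cutoff = %.4g\n",
              x$pi_mcar, x$cutoff))
  invisible(x)
}

#' Log-likelihood contribution of a single cell
#'
#' Observed cells contribute a normal density (times the probability of not
#' being MCAR); missing cells contribute the mixture of the MCAR
#' probability and the probability of falling below the censoring cutoff.
#' Vectorized over \code{y}, \code{mu} and \code{sigma}.
#'
#' @param y observed value(s); \code{NA} marks a missing cell.
#' @param mu cell mean(s).
#' @param sigma cell standard deviation(s), positive.
#' @param params a \code{missingness_params}.
#' @return Log-likelihood value(s).
#' @export
cell_loglik <- function(y, mu, sigma, params) {
  stopifnot(inherits(params, "missingness_params"))
  if (any(sigma <= 0)) stop_("'sigma' must be positive")
  pi <- params$pi_mcar; cc <- params$cutoff
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- numeric(n)
  obs <- !is.na(y)
  if (any(obs)) {
    if (pi == 1) {
      warning("observed value with pi_mcar = 1 is an impossible event")
      out[obs] <- -Inf
    } else {
      out[obs] <- log1p(-pi) +
        stats::dnorm(y[obs], mu[obs], sigma[obs], log = TRUE)
    }
  }
  if (any(!obs)) {
    z <- (cc - mu[!obs]) / sigma[!obs]
    if (pi == 0) {
      out[!obs] <- stats::pnorm(z, log.p = TRUE)
    } else {
      out[!obs] <- log(pi + (1 - pi) * stats::pnorm(z))
    }
  }
  out
}

# ---- internal model plumbing -----------------------------------------

# Parameter vector layout for one protein with J peptides, K groups:
#   theta = (Prot, Pep_1..Pep_{J-1}, d_1..d_{K-1}, log sigma_1..log sigma_J)
# where d_q = Treat_q - Treat_K (group differences against the last group),
# so the Treat block of the information matrix is directly on the
# difference scale. Treat_k = d_k - mean(d), with d_K = 0.

theta_layout <- function(J, K) {
  list(prot = 1L,
       pep = if (J > 1L) 1L + seq_len(J - 1L) else integer(0),
       delta = if (K > 1L) J + seq_len(K - 1L) else integer(0),
       lsig = J + K - 1L + seq_len(J),
       n = 2L * J + K - 1L)
}

theta_unpack <- function(theta, J, K) {
  lay <- theta_layout(J, K)
  pep_free <- theta[lay$pep]
  pep <- if (J > 1L) c(pep_free, -sum(pep_free)) else 0
  d_full <- c(theta[lay$delta], 0)
  treat <- d_full - mean(d_full)
  list(prot = theta[lay$prot], pep = pep, treat = treat,
       sigma = exp(theta[lay$lsig]), delta = theta[lay$delta])
}

theta_names <- function(J, K, peptide_ids, group_levels) {
  c("prot",
    if (J > 1L) paste0("pep:", peptide_ids[seq_len(J - 1L)]),
    if (K > 1L) paste0("delta:", group_levels[seq_len(K - 1L)]),
    paste0("lsig:", peptide_ids))
}

# mean matrix (J x N) for a parameter vector
theta_mu <- function(th, grp_idx) {
  outer(th$prot + th$pep, th$treat[grp_idx], `+`)
}

# negative log-likelihood and gradient, over the full J x N cell grid
protein_nll <- function(theta, y, grp_idx, J, K, pi, cc) {
  th <- theta_unpack(theta, J, K)
  mu <- theta_mu(th, grp_idx)
  sg <- th$sigma
  obs <- !is.na(y)
  ll <- 0
  if (any(obs)) {
    r <- (y - mu)[obs]
    s <- sg[row(y)[obs]]
    ll <- ll + sum(log1p(-pi) + stats::dnorm(r / s, log = TRUE) - log(s))
  }
  if (any(!obs)) {
    z <- (cc - mu[!obs]) / sg[row(y)[!obs]]
    ll <- ll + if (pi == 0) sum(stats::pnorm(z, log.p = TRUE))
    else sum(log(pi + (1 - pi) * stats::pnorm(z)))
  }
  -ll
}

protein_nll_grad <- function(theta, y, grp_idx, J, K, pi, cc) {
  th <- theta_unpack(theta, J, K)
  mu <- theta_mu(th, grp_idx)
  sig_row <- th$sigma[row(y)]
  dim(sig_row) <- dim(y)
  obs <- !is.na(y)
  g_mu <- matrix(0, J, ncol(y))     # d(-ll)/d mu per cell
  g_ls <- matrix(0, J, ncol(y))     # d(-ll)/d log sigma_j per cell
  if (any(obs)) {
    r <- (y[obs] - mu[obs]) / sig_row[obs]
    g_mu[obs] <- -r / sig_row[obs]
    g_ls[obs] <- 1 - r^2
  }
  if (any(!obs)) {
    z <- (cc - mu[!obs]) / sig_row[!obs]
    if (pi == 0) {
      lam <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
      w <- lam
    } else {
      num <- (1 - pi) * stats::dnorm(z)
      den <- pi + (1 - pi) * stats::pnorm(z)
      w <- num / den
    }
    g_mu[!obs] <- w / sig_row[!obs]
    g_ls[!obs] <- ifelse(w == 0, 0, w * z)   # guard 0 * Inf at c = -Inf
  }
  lay <- theta_layout(J, K)
  g <- numeric(lay$n)
  row_mu <- rowSums(g_mu)
  g[lay$prot] <- sum(row_mu)
  if (J > 1L) g[lay$pep] <- row_mu[seq_len(J - 1L)] - row_mu[J]
  if (K > 1L) {
    col_mu <- colSums(g_mu)
    by_grp <- vapply(seq_len(K), function(k) sum(col_mu[grp_idx == k]),
                     numeric(1))
    g[lay$delta] <- by_grp[seq_len(K - 1L)] - sum(by_grp) / K
  }
  g[lay$lsig] <- rowSums(g_ls)
  g
}

# least-squares initialization on the observed cells
theta_init <- function(y, grp_idx, J, K, sd_floor = 0.05) {
  lay <- theta_layout(J, K)
  grp_f <- factor(grp_idx, levels = seq_len(K))
  f <- ls_fit_protein(y, grp_f)
  prot <- if (is.finite(f$prot)) f$prot else mean(y, na.rm = TRUE)
  pep <- ifelse(is.na(f$pep), 0, f$pep)
  treat <- if (f$estimable && all(is.finite(f$treat))) f$treat else rep(0, K)
  delta <- (treat - treat[K])[seq_len(K - 1L)]
  res <- y - f$fitted
  sds <- apply(res, 1L, stats::sd, na.rm = TRUE)
  pooled <- stats::sd(res[!is.na(res)])
  sds[!is.finite(sds)] <- if (is.finite(pooled) && pooled > 0) pooled else 0.5
  sds <- pmax(sds, sd_floor)
  theta <- numeric(lay$n)
  theta[lay$prot] <- prot
  if (J > 1L) theta[lay$pep] <- pep[seq_len(J - 1L)]
  if (K > 1L) theta[lay$delta] <- delta
  theta[lay$lsig] <- log(sds)
  theta
}

# analytic observed information for the complete-data (no missing) case
complete_info <- function(theta, y, grp_idx, J, K) {
  th <- theta_unpack(theta, J, K)
  lay <- theta_layout(J, K)
  N <- ncol(y)
  # design matrix of d mu / d theta_mean for each cell (J*N rows)
  p_mean <- J + K - 1L
  jj <- rep(seq_len(J), times = N)
  kk <- rep(grp_idx, each = J)
  X <- matrix(0, J * N, p_mean)
  X[, 1L] <- 1
  if (J > 1L)
    for (p in seq_len(J - 1L))
      X[, 1L + p] <- (jj == p) - (jj == J)
  if (K > 1L)
    for (q in seq_len(K - 1L))
      X[, J + q] <- (kk == q) - 1 / K
  w <- 1 / th$sigma[jj]^2
  info <- matrix(0, lay$n, lay$n)
  info[seq_len(p_mean), seq_len(p_mean)] <- crossprod(X * sqrt(w))
  r <- as.vector(y) - as.vector(theta_mu(th, grp_idx))
  for (j in seq_len(J)) {
    sel <- jj == j
    idx <- lay$lsig[j]
    info[idx, idx] <- sum(2 * (r[sel] / th$sigma[j])^2)
    cross <- colSums(X[sel, , drop = FALSE] * (2 * r[sel] * w[sel]))
    info[idx, seq_len(p_mean)] <- cross
    info[seq_len(p_mean), idx] <- cross
  }
  info
}

#' Maximum-likelihood fit of the censored/MCAR protein model
#'
#' Fits, for one protein's peptide-by-sample sub-matrix, the model in which
#' each cell mean is protein mean + peptide offset + treatment effect
#' (sum-to-zero constraints, separate error SD per peptide) and every cell,
#' observed or missing, contributes [cell_loglik()] with the given
#' missingness parameters. With no missing cells the maximum is found by
#' iteratively reweighted least squares; otherwise by bounded quasi-Newton
#' optimization with analytic gradients, started from the least-squares
#' estimates plus jittered restarts.
#'
#' @param sub an \code{abund_matrix} holding one protein's peptides.
#' @param design a \code{study_design}.
#' @param params a \code{missingness_params}.
#' @param optimize if \code{FALSE}, return the (rough) least-squares
#'   initialization without numerical optimization — sufficient for
#'   model-based filtering and imputation when speed matters.
#' @param info compute the observed information matrix at the optimum
#'   (default \code{TRUE}; analytic for complete data, numeric otherwise).
#' @param n_restarts number of jittered restarts of the optimizer
#'   (default 2, after the least-squares start).
#' @param sd_floor lower bound for peptide error SDs (default 1e-3).
#' @return Object of class \code{"protein_fit"}: parameter estimates
#'   (\code{protein_mean}, \code{peptide_offset}, \code{treat_effect},
#'   \code{resid_sd}), \code{delta} (group differences against the last
#'   group), the fitted cell mean matrix \code{mu}, \code{loglik},
#'   \code{info_matrix}, and a \code{converged} flag.
#' @export
fit_protein_ml <- function(sub, design, params, optimize = TRUE,
                           info = TRUE, n_restarts = 2L, sd_floor = 1e-3) {
  stopifnot(inherits(sub, "abund_matrix"), inherits(params, "missingness_params"))
  design <- align_design(sub, design)
  y <- sub$values
  J <- nrow(y); K <- nlevels(design$group)
  grp_idx <- as.integer(design$group)
  obs <- !is.na(y)
  if (!any(obs)) stop_("protein is non-identifiable: every cell is missing")
  obs_groups <- unique(grp_idx[colSums(obs) > 0L])
  if (length(obs_groups) < K)
    stop_("protein is non-identifiable: group '%s' has no observed value",
          levels(design$group)[setdiff(seq_len(K), obs_groups)[1L]])

  pi <- params$pi_mcar; cc <- params$cutoff
  lay <- theta_layout(J, K)
  theta0 <- theta_init(y, grp_idx, J, K)
  complete <- all(obs)
  converged <- TRUE

  if (!optimize || complete) {
    # complete data (or rough-estimate mode): least-squares mean estimates
    # with per-peptide error SDs profiled at those means. The likelihood's
    # precision-weighting across peptides is deliberately not iterated:
    # weights estimated from a handful of observations degrade downstream
    # interval calibration, and the complete-data limit of the model is
    # defined here as the constrained least-squares fit.
    theta <- theta0
    if (complete) {
      th <- theta_unpack(theta, J, K)
      res <- y - theta_mu(th, grp_idx)
      theta[lay$lsig] <- log(pmax(sqrt(rowMeans(res^2)), sd_floor))
    }
  } else {
    lower <- rep(-Inf, lay$n); upper <- rep(Inf, lay$n)
    lower[lay$lsig] <- log(sd_floor); upper[lay$lsig] <- log(1e4)
    run <- function(start) {
      tryCatch(stats::optim(start, protein_nll, protein_nll_grad,
                            y = y, grp_idx = grp_idx, J = J, K = K,
                            pi = pi, cc = cc,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 500L, factr = 1e4)),
               error = function(e) NULL)
    }
    fits <- list(run(theta0))
    if (n_restarts > 0L) {
      jit <- with_seed(20131L, lapply(seq_len(n_restarts), function(i)
        theta0 + stats::rnorm(lay$n, 0, 0.2)))
      jit <- lapply(jit, function(t) pmin(pmax(t, lower), upper))
      fits <- c(fits, lapply(jit, run))
    }
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop_("optimizer failed for this protein")
    vals <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(vals)]]
    theta <- best$par
    converged <- best$convergence == 0L
  }

  th <- theta_unpack(theta, J, K)
  ll <- -protein_nll(theta, y, grp_idx, J, K, pi, cc)
  res <- y - theta_mu(th, grp_idx)
  ssr <- rowSums(res^2, na.rm = TRUE)
  n_jk <- t(apply(obs, 1L, function(o) tabulate(grp_idx[o], nbins = K)))
  dim(n_jk) <- c(J, K)
  nm <- theta_names(J, K, sub$peptide_ids, levels(design$group))
  im <- NULL
  if (info) {
    im <- if (complete) complete_info(theta, y, grp_idx, J, K)
    else pracma::hessian(protein_nll, theta, y = y, grp_idx = grp_idx,
                         J = J, K = K, pi = pi, cc = cc)
    im <- (im + t(im)) / 2
    dimnames(im) <- list(nm, nm)
  }
  structure(list(protein_mean = th$prot,
                 peptide_offset = stats::setNames(th$pep, sub$peptide_ids),
                 treat_effect = stats::setNames(th$treat, levels(design$group)),
                 delta = stats::setNames(th$delta,
                                         utils::head(levels(design$group), K - 1L)),
                 resid_sd = stats::setNames(th$sigma, sub$peptide_ids),
                 mu = structure(theta_mu(th, grp_idx),
                                dimnames = list(sub$peptide_ids,
                                                sub$sample_ids)),
                 loglik = ll, info_matrix = im, theta = theta,
                 converged = converged, complete = complete,
                 ssr = stats::setNames(ssr, sub$peptide_ids),
                 n_jk = structure(n_jk, dimnames = list(sub$peptide_ids,
                                                        levels(design$group))),
                 n_obs = sum(obs), J = J, K = K,
                 group_levels = levels(design$group),
                 params = params),
            class = "protein_fit")
}

#' @export
print.protein_fit <- function(x, ...) {
  cat(sprintf("protein_fit: %d peptides, %d groups, %d observed cells; loglik = %.3f%s\n",
              x$J, x$K, x$n_obs, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Estimate global missingness parameters from a matrix
#'
#' The censoring cutoff defaults to the median across samples of each
#' sample's minimum observed value (the effective detection floor). The
#' MCAR probability is estimated as the missing fraction among peptides
#' whose observed mean lies in the top abundance quartile, where censoring
#' is negligible and essentially all missingness is random.
#'
#' @param m an \code{abund_matrix}.
#' @return A \code{missingness_params}. A complete matrix yields
#'   \code{pi_mcar = 0}, \code{cutoff = -Inf}.
#' @export
estimate_missingness_params <- function(m) {
  stopifnot(inherits(m, "abund_matrix"))
  v <- m$values
  if (!any(!is.na(v))) stop_("matrix has no observed values")
  if (!anyNA(v)) return(missingness_params(0, -Inf))
  n_obs_col <- colSums(!is.na(v))
  if (any(n_obs_col == 0L))
    stop_("sample '%s' has no observed values", m$sample_ids[which(n_obs_col == 0L)[1L]])
  cutoff <- stats::median(apply(v, 2L, min, na.rm = TRUE))
  row_mean <- rowMeans(v, na.rm = TRUE)
  ok <- is.finite(row_mean)
  top <- row_mean >= stats::quantile(row_mean[ok], 0.75) & ok
  pi <- mean(is.na(v[top, , drop = FALSE]))
  missingness_params(pi, cutoff)
}
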