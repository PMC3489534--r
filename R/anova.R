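# Fixed-effects peptide ANOVA:
#   y_ijkb = Prot_i + Pep_ij + Treat_ik (+ Batch_ib) + e_ijkb,
# with sum-to-zero constraints on Pep, Treat and Batch within each protein
# and a separate error variance per peptide. Proteins are independent, so
# the fit streams protein by protein on small dense design matrices.

# Least-squares fit for one protein.
# y: J x N matrix (NA = missing); grp: factor length N; bat: factor or NULL.
ls_fit_protein <- function(y, grp, bat = NULL) {
  J <- nrow(y); N <- ncol(y)
  obs <- !is.na(y)
  jj <- row(y)[obs]; ss <- col(y)[obs]; yy <- y[obs]
  K <- nlevels(grp); B <- if (is.null(bat)) 0L else nlevels(bat)
  out <- list(prot = NA_real_, pep = rep(NA_real_, J),
              treat = rep(NA_real_, K),
              batch = if (B) rep(NA_real_, B) else NULL,
              fitted = matrix(NA_real_, J, N), estimable = FALSE,
              n_obs = length(yy))
  if (!length(yy)) return(out)

  pep_f <- factor(jj, levels = seq_len(J))
  pep_obs <- levels(droplevels(pep_f))           # peptides with any data
  grp_obs <- grp[ss]
  estimable <- all(levels(grp) %in% levels(droplevels(grp_obs))) &&
    (B == 0L || all(levels(bat) %in% levels(droplevels(bat[ss]))))

  build_X <- function(with_groups) {
    cols <- list(`(Intercept)` = rep(1, length(yy)))
    f_pep <- droplevels(pep_f)
    if (nlevels(f_pep) > 1L)
      cols$pep <- stats::contr.sum(nlevels(f_pep))[as.integer(f_pep), ,
                                                   drop = FALSE]
    if (with_groups && K > 1L)
      cols$grp <- stats::contr.sum(K)[as.integer(grp_obs), , drop = FALSE]
    if (with_groups && B > 1L)
      cols$bat <- stats::contr.sum(B)[as.integer(bat[ss]), , drop = FALSE]
    do.call(cbind, cols)
  }

  X <- build_X(estimable)
  qf <- qr(X)
  if (estimable && qf$rank < ncol(X)) {        # confounded design
    estimable <- FALSE
    X <- build_X(FALSE)
    qf <- qr(X)
  }
  beta <- qr.coef(qf, yy)
  beta[is.na(beta)] <- 0
  Jo <- length(pep_obs)
  pos <- 1L
  prot <- beta[pos]; pos <- pos + 1L
  pep <- rep(NA_real_, J)
  if (Jo > 1L) {
    pc <- beta[pos:(pos + Jo - 2L)]; pos <- pos + Jo - 1L
    pep[as.integer(pep_obs)] <- c(pc, -sum(pc))
  } else pep[as.integer(pep_obs)] <- 0
  treat <- rep(NA_real_, K)
  batch <- if (B) rep(NA_real_, B) else NULL
  if (estimable) {
    if (K > 1L) {
      tc <- beta[pos:(pos + K - 2L)]; pos <- pos + K - 1L
      treat <- c(tc, -sum(tc))
    } else treat <- 0
    if (B > 1L) {
      bc <- beta[pos:(pos + B - 2L)]
      batch <- c(bc, -sum(bc))
    } else if (B == 1L) batch <- 0
  }

  fitted <- matrix(NA_real_, J, N)
  has_pep <- !is.na(pep)
  mu_row <- prot + pep                                     # length J
  if (estimable) {
    mu_col <- treat[as.integer(grp)]
    if (B) mu_col <- mu_col + batch[as.integer(bat)]
  } else mu_col <- rep(0, N)
  fitted[has_pep, ] <- outer(mu_row[has_pep], mu_col, `+`)

  list(prot = prot, pep = pep, treat = treat, batch = batch,
       fitted = fitted, estimable = estimable, n_obs = length(yy))
}

#' Fit the per-protein peptide ANOVA model
#'
#' Fits, independently for each protein, the fixed-effects model in which a
#' log abundance decomposes into a protein mean, a peptide offset, a
#' treatment-group effect and (optionally) a batch effect, with sum-to-zero
#' constraints on the offset and effect terms and a separate residual
#' variance per peptide. Estimation is ordinary least squares on the
#' observed cells.
#'
#' Proteins whose observed cells do not represent every group (or batch),
#' or whose design is confounded, are flagged non-estimable: for those, a
#' reduced protein + peptide model supplies residuals, the group/batch
#' effects are \code{NA}, and their peptides are excluded from the residual
#' variance pool.
#'
#' @param m an \code{abund_matrix} on the log scale.
#' @param design a \code{study_design} covering the matrix samples.
#' @param pmap a \code{protein_map} covering the matrix peptides.
#' @param include_batch fit batch effects when the design has a
#'   \code{batch} column (default \code{FALSE}).
#' @return Object of class \code{"anova_fit"}: list with per-protein
#'   \code{protein_mean}, per-peptide \code{peptide_offset}, per-protein x
#'   group \code{treat_effect}, optional \code{batch_effect},
#'   \code{fitted} and \code{residuals} matrices aligned with the input
#'   (NA where the input is missing), per-peptide residual variances
#'   \code{resid_var}, and an \code{estimable} flag per protein.
#' @export
fit_peptide_anova <- function(m, design, pmap, include_batch = FALSE) {
  design <- align_design(m, design)
  prot_of <- map_proteins(m, pmap)
  grp <- design$group
  bat <- if (include_batch && !is.null(design$batch)) design$batch else NULL
  if (include_batch && is.null(design$batch))
    stop_("'include_batch = TRUE' but the design has no batch column")

  proteins <- unique(prot_of)
  P <- length(m$peptide_ids); N <- length(m$sample_ids)
  K <- nlevels(grp); B <- if (is.null(bat)) 0L else nlevels(bat)
  fitted <- matrix(NA_real_, P, N, dimnames = dimnames(m$values))
  protein_mean <- stats::setNames(rep(NA_real_, length(proteins)), proteins)
  peptide_offset <- stats::setNames(rep(NA_real_, P), m$peptide_ids)
  treat_effect <- matrix(NA_real_, length(proteins), K,
                         dimnames = list(proteins, levels(grp)))
  batch_effect <- if (B) matrix(NA_real_, length(proteins), B,
                                dimnames = list(proteins, levels(bat)))
  estimable <- stats::setNames(logical(length(proteins)), proteins)

  for (pr in proteins) {
    rows <- which(prot_of == pr)
    f <- ls_fit_protein(m$values[rows, , drop = FALSE], grp, bat)
    fitted[rows, ] <- f$fitted
    protein_mean[pr] <- f$prot
    peptide_offset[rows] <- f$pep
    treat_effect[pr, ] <- f$treat
    if (B) batch_effect[pr, ] <- f$batch
    estimable[pr] <- f$estimable
  }

  residuals <- m$values - fitted
  n_obs <- rowSums(!is.na(residuals))
  J_of <- ave(seq_len(P), prot_of, FUN = length)
  df <- pmax(n_obs - 1 - (K - 1) / J_of - (if (B) (B - 1) / J_of else 0), 1)
  resid_var <- rowSums(residuals^2, na.rm = TRUE) / df
  resid_var[n_obs < 2L] <- NA_real_
  resid_var[!estimable[prot_of]] <- NA_real_   # outside the variance pool
  names(resid_var) <- m$peptide_ids

  structure(list(protein_mean = protein_mean,
                 peptide_offset = peptide_offset,
                 treat_effect = treat_effect,
                 batch_effect = batch_effect,
                 fitted = fitted, residuals = residuals,
                 resid_var = resid_var, resid_df = stats::setNames(df, m$peptide_ids),
                 estimable = estimable, proteins = prot_of,
                 groups = grp, log_base = m$log_base),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("anova_fit: %d peptides, %d proteins, %d groups; %d/%d proteins estimable\n",
              length(x$peptide_offset), length(x$protein_mean),
              nlevels(x$groups), sum(x$estimable), length(x$estimable)))
  invisible(x)
}
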