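# Imputation: model-based single imputation from the censored/MCAR fit,
# and the naive baselines it is compared against.

# draws from Normal(mu, sd^2) truncated to (-Inf, upper]
rtrunc_below <- function(n, mu, sd, upper) {
  p_up <- stats::pnorm(upper, mu, sd)
  u <- stats::runif(n) * p_up
  u <- pmin(pmax(u, .Machine$double.xmin), 1)   # guard qnorm(0)
  stats::qnorm(u, mu, sd)
}

#' Model-based single imputation
#'
#' Replaces each missing cell with one draw from its fitted conditional
#' distribution: a normal truncated above at the censoring cutoff when the
#' cell is classified censored, the full normal when it is classified
#' MCAR. Cell means and SDs come from per-protein censored-likelihood
#' fits. Proteins without a usable fit keep their missing cells; these are
#' listed in the \code{"skipped"} attribute of the result.
#'
#' @param m an \code{abund_matrix}.
#' @param pmap a \code{protein_map}.
#' @param fits named list (by protein id) of \code{"protein_fit"} objects
#'   covering every protein of \code{m} that has missing cells.
#' @param params a \code{missingness_params}.
#' @param seed integer seed; identical seeds give identical output.
#' @param threshold posterior threshold for the censored label
#'   (default 0.5).
#' @return An \code{abund_matrix} with missing cells filled in (except in
#'   skipped proteins). Attribute \code{"skipped"} is a data.frame of
#'   cells left missing.
#' @seealso [fit_protein_ml()], [classify_missing()], [model_impute()] for
#'   the one-call pipeline.
#' @export
impute_model_based <- function(m, pmap, fits, params, seed = 1L,
                               threshold = 0.5) {
  stopifnot(inherits(m, "abund_matrix"))
  prot_of <- map_proteins(m, pmap)
  v <- m$values
  skipped <- list()
  with_seed(seed, {
    for (pr in unique(prot_of)) {
      rows <- which(prot_of == pr)
      miss <- is.na(v[rows, , drop = FALSE])
      if (!any(miss)) next
      sub <- abundance_matrix(m$values[rows, , drop = FALSE],
                              m$peptide_ids[rows], m$sample_ids,
                              log_base = m$log_base)
      fit <- fits[[pr]]
      if (is.null(fit) || !isTRUE(fit$converged)) {
        skipped[[pr]] <- data.frame(
          protein_id = pr,
          peptide_id = sub$peptide_ids[row(miss)[miss]],
          sample_id = sub$sample_ids[col(miss)[miss]],
          stringsAsFactors = FALSE)
        next
      }
      cls <- classify_missing(sub, fit, params, threshold = threshold)
      mi <- cbind(match(cls$peptide_id, sub$peptide_ids),
                  match(cls$sample_id, sub$sample_ids))
      mu <- fit$mu[cbind(match(cls$peptide_id, rownames(fit$mu)),
                         match(cls$sample_id, colnames(fit$mu)))]
      sg <- fit$resid_sd[match(cls$peptide_id, names(fit$resid_sd))]
      draw <- numeric(nrow(cls))
      cen <- cls$label == "censored"
      if (any(cen))
        draw[cen] <- rtrunc_below(sum(cen), mu[cen], sg[cen], params$cutoff)
      if (any(!cen))
        draw[!cen] <- stats::rnorm(sum(!cen), mu[!cen], sg[!cen])
      v[rows, ][mi] <- draw
    }
  })
  out <- abundance_matrix(v, m$peptide_ids, m$sample_ids,
                          log_base = m$log_base)
  attr(out, "skipped") <- if (length(skipped))
    do.call(rbind, unname(skipped))
  else data.frame(protein_id = character(0), peptide_id = character(0),
                  sample_id = character(0))
  out
}

#' One-call model-based imputation pipeline
#'
#' Fits the censored/MCAR model for every protein with missing cells and
#' imputes in a single call. Non-identifiable or non-convergent proteins
#' are skipped (their cells stay missing).
#'
#' @param m an \code{abund_matrix}.
#' @param design a \code{study_design}.
#' @param pmap a \code{protein_map}.
#' @param params a \code{missingness_params}; estimated from \code{m} when
#'   \code{NULL}.
#' @param seed integer seed.
#' @param optimize run the numerical optimizer per protein
#'   (\code{FALSE}, the default, uses the fast least-squares
#'   initialization — adequate for imputation).
#' @param threshold censored-label posterior threshold.
#' @return As [impute_model_based()].
#' @export
model_impute <- function(m, design, pmap, params = NULL, seed = 1L,
                         optimize = FALSE, threshold = 0.5) {
  if (is.null(params)) params <- estimate_missingness_params(m)
  prot_of <- map_proteins(m, pmap)
  need <- unique(prot_of[rowSums(is.na(m$values)) > 0L])
  fits <- stats::setNames(lapply(need, function(pr) {
    rows <- which(prot_of == pr)
    sub <- abundance_matrix(m$values[rows, , drop = FALSE],
                            m$peptide_ids[rows], m$sample_ids,
                            log_base = m$log_base)
    tryCatch(fit_protein_ml(sub, design, params, optimize = optimize,
                            info = FALSE),
             error = function(e) NULL)
  }), need)
  impute_model_based(m, pmap, fits, params, seed = seed,
                     threshold = threshold)
}

#' Naive imputation baselines
#'
#' Fast imputations that ignore the missingness mechanism:
#' \describe{
#'   \item{row_mean}{peptide's observed mean (deterministic).}
#'   \item{min_observed}{the matrix-wide minimum observed value — the
#'     classic "fill with the detection floor" heuristic for censored
#'     cells (deterministic).}
#'   \item{row_min}{the peptide's own minimum observed value
#'     (deterministic) — repeatedly imputing a value inside the peptide's
#'     observed range underestimates the true variation, the failure mode
#'     behind collapsing interval coverage under censoring.}
#'   \item{normal_draw}{draw from Normal(peptide observed mean, observed
#'     variance).}
#'   \item{group_normal_draw}{as \code{normal_draw} but with mean and
#'     variance per treatment group, for when group means differ.}
#' }
#'
#' @param m an \code{abund_matrix}.
#' @param method one of the above.
#' @param seed integer seed (used by the draw-based methods).
#' @param design a \code{study_design}; required for
#'   \code{group_normal_draw}.
#' @return A complete \code{abund_matrix}.
#' @export
impute_naive <- function(m, method = c("row_mean", "min_observed",
                                       "row_min", "normal_draw",
                                       "group_normal_draw"),
                         seed = 1L, design = NULL) {
  stopifnot(inherits(m, "abund_matrix"))
  method <- match.arg(method)
  v <- m$values
  miss_row <- which(rowSums(is.na(v)) > 0L)
  n_obs <- rowSums(!is.na(v))
  need_obs <- if (method %in% c("normal_draw")) 2L else 1L
  bad <- miss_row[n_obs[miss_row] < need_obs]
  if (method != "min_observed" && method != "group_normal_draw" &&
      length(bad))
    stop_("peptide '%s' has %d observed value(s); need >= %d for %s imputation",
          m$peptide_ids[bad[1L]], n_obs[bad[1L]], need_obs, method)
  if (method == "min_observed" && !any(!is.na(v)))
    stop_("no observed values in the matrix")

  out <- switch(method,
    row_mean = {
      rm_ <- rowMeans(v, na.rm = TRUE)
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- rm_[idx[, 1L]]
      v
    },
    min_observed = {
      v[is.na(v)] <- min(v, na.rm = TRUE)
      v
    },
    row_min = {
      rmin <- apply(v, 1L, min, na.rm = TRUE)
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- rmin[idx[, 1L]]
      v
    },
    normal_draw = with_seed(seed, {
      rm_ <- rowMeans(v, na.rm = TRUE)
      rs_ <- apply(v, 1L, stats::sd, na.rm = TRUE)
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- stats::rnorm(nrow(idx), rm_[idx[, 1L]], rs_[idx[, 1L]])
      v
    }),
    group_normal_draw = {
      if (is.null(design))
        stop_("'design' is required for group_normal_draw")
      design <- align_design(m, design)
      with_seed(seed, {
        for (g in levels(design$group)) {
          cols <- design$group == g
          vg <- v[, cols, drop = FALSE]
          ng <- rowSums(!is.na(vg))
          mr <- which(rowSums(is.na(vg)) > 0L)
          if (any(ng[mr] < 2L))
            stop_("peptide '%s' has %d observed value(s) in group '%s'; need >= 2",
                  m$peptide_ids[mr[ng[mr] < 2L][1L]],
                  ng[mr[ng[mr] < 2L][1L]], g)
          gm <- rowMeans(vg, na.rm = TRUE)
          gs <- apply(vg, 1L, stats::sd, na.rm = TRUE)
          idx <- which(is.na(vg), arr.ind = TRUE)
          vg[idx] <- stats::rnorm(nrow(idx), gm[idx[, 1L]], gs[idx[, 1L]])
          v[, cols] <- vg
        }
        v
      })
    })
  abundance_matrix(out, m$peptide_ids, m$sample_ids, log_base = m$log_base)
}
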