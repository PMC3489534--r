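# Information-based peptide filtering: Fisher information of the treatment
# difference parameters, greedy peptide subset selection, and missing-cell
# classification.

#' Information content of a protein fit
#'
#' Extracts the block of the observed Fisher information corresponding to
#' the treatment-difference parameters, profiles out the nuisance
#' parameters (protein mean, peptide offsets, error SDs) through the Schur
#' complement, and returns the scaled determinant det(block)^(1/d), where d
#' is the block dimension. A zero means the protein's group differences
#' are not identifiable from its observed cells.
#'
#' @param fit a converged \code{"protein_fit"} with an information matrix.
#' @return Non-negative scalar.
#' @export
information_content <- function(fit) {
  stopifnot(inherits(fit, "protein_fit"))
  if (!isTRUE(fit$converged)) stop_("fit did not converge")
  im <- fit$info_matrix
  if (is.null(im)) stop_("fit carries no information matrix (info = FALSE?)")
  lay <- theta_layout(fit$J, fit$K)
  d_idx <- lay$delta
  if (!length(d_idx)) return(0)
  n_idx <- setdiff(seq_len(nrow(im)), d_idx)
  I_dd <- im[d_idx, d_idx, drop = FALSE]
  I_dn <- im[d_idx, n_idx, drop = FALSE]
  I_nn <- im[n_idx, n_idx, drop = FALSE]
  sol <- tryCatch(solve(I_nn, t(I_dn)), error = function(e) NULL)
  if (is.null(sol)) return(0)
  blk <- I_dd - I_dn %*% sol
  dt <- det(blk)
  if (!is.finite(dt) || dt <= 0) return(0)
  dt^(1 / length(d_idx))
}

# info content for a peptide subset; errors (non-identifiable) count as 0
subset_info <- function(sub, design, params, ids, ...) {
  s <- subset_peptides(sub, ids)
  f <- tryCatch(fit_protein_ml(s, design, params, ...),
                error = function(e) NULL)
  if (is.null(f) || !f$converged) return(0)
  tryCatch(information_content(f), error = function(e) 0)
}

#' Greedy peptide subset selection for one protein
#'
#' Forward greedy search over a protein's peptides maximizing the Fisher
#' information content of the treatment-difference parameters: start from
#' the single most informative peptide, repeatedly add the peptide giving
#' the largest increase, and stop when no addition increases the
#' information. If no single peptide is informative, all peptide pairs are
#' tried as seeds (two peptides can jointly cover groups that neither
#' covers alone). The protein is flagged filtered when no examined subset
#' achieves positive information.
#'
#' Because the error SDs are re-estimated within every candidate subset,
#' the information is not exactly additive across peptides and a forward
#' search can settle one step short of the optimum. For small proteins
#' (up to \code{exact_max} peptides) the search is therefore exhaustive —
#' at most 31 subsets — and the greedy path is reserved for larger
#' proteins where it matters computationally.
#'
#' @param sub an \code{abund_matrix} with one protein's peptides.
#' @param design a \code{study_design}.
#' @param params a \code{missingness_params}.
#' @param exact_max proteins with at most this many peptides are searched
#'   exhaustively (default 5).
#' @param ... passed to [fit_protein_ml()] (e.g. \code{optimize = FALSE}
#'   for speed).
#' @return List with \code{selected} (character vector of peptide ids, in
#'   matrix order), \code{info_content}, and \code{filtered} (flag).
#' @export
greedy_select_peptides <- function(sub, design, params, exact_max = 5L,
                                   ...) {
  stopifnot(inherits(sub, "abund_matrix"))
  ids <- sub$peptide_ids
  if (!length(ids)) stop_("protein has no peptides")
  if (length(ids) <= exact_max) {
    best <- list(info = 0, set = character(0))
    for (k in seq_along(ids))
      for (set in utils::combn(ids, k, simplify = FALSE)) {
        info <- subset_info(sub, design, params, set, ...)
        if (info > best$info * (1 + 1e-9) + 1e-12)
          best <- list(info = info, set = set)
      }
    return(list(selected = ids[ids %in% best$set],
                info_content = best$info,
                filtered = best$info <= 0))
  }
  info1 <- vapply(ids, function(id)
    subset_info(sub, design, params, id, ...), numeric(1))
  if (max(info1) > 0) {
    cur <- ids[which.max(info1)]
    cur_info <- max(info1)
  } else {
    cur <- character(0); cur_info <- 0
    if (length(ids) >= 2L) {
      pairs <- utils::combn(ids, 2L, simplify = FALSE)
      pinfo <- vapply(pairs, function(pr)
        subset_info(sub, design, params, pr, ...), numeric(1))
      if (max(pinfo) > 0) {
        cur <- pairs[[which.max(pinfo)]]
        cur_info <- max(pinfo)
      }
    }
    if (!length(cur))
      return(list(selected = character(0), info_content = 0,
                  filtered = TRUE))
  }
  repeat {
    rest <- setdiff(ids, cur)
    if (!length(rest)) break
    gains <- vapply(rest, function(id)
      subset_info(sub, design, params, c(cur, id), ...), numeric(1))
    if (max(gains) > cur_info + 1e-9 * (abs(cur_info) + 1)) {
      cur <- c(cur, rest[which.max(gains)])
      cur_info <- max(gains)
    } else break
  }
  list(selected = ids[ids %in% cur], info_content = cur_info,
       filtered = FALSE)
}

#' Classify missing cells as censored or MCAR
#'
#' For each missing cell, the posterior probability that it was censored
#' (rather than lost at random) is
#' \deqn{P(cens | miss) = (1-\pi)\Phi((c-\mu)/\sigma) /
#'       (\pi + (1-\pi)\Phi((c-\mu)/\sigma))}
#' with \eqn{\mu} the fitted cell mean. Cells at or above the threshold
#' posterior are labeled censored (ties go to the censored label, the
#' informative mechanism).
#'
#' @param sub an \code{abund_matrix} with one protein's peptides.
#' @param fit a converged \code{"protein_fit"} for the same peptides.
#' @param params a \code{missingness_params}.
#' @param threshold posterior threshold for the censored label
#'   (default 0.5).
#' @return Object of class \code{"cell_classification"}: data.frame with
#'   one row per missing cell (\code{peptide_id}, \code{sample_id},
#'   \code{posterior_censored}, \code{label}).
#' @export
classify_missing <- function(sub, fit, params, threshold = 0.5) {
  stopifnot(inherits(sub, "abund_matrix"), inherits(fit, "protein_fit"),
            inherits(params, "missingness_params"))
  if (!isTRUE(fit$converged)) stop_("fit did not converge")
  miss <- which(is.na(sub$values), arr.ind = TRUE)
  pi <- params$pi_mcar; cc <- params$cutoff
  if (nrow(miss)) {
    mu <- fit$mu[cbind(match(sub$peptide_ids[miss[, 1L]],
                             rownames(fit$mu)), miss[, 2L])]
    sg <- fit$resid_sd[match(sub$peptide_ids[miss[, 1L]],
                             names(fit$resid_sd))]
    ph <- stats::pnorm((cc - mu) / sg)
    if (pi == 0) {
      # no MCAR channel: any missing cell must be censored (unless
      # censoring is disabled entirely)
      post <- rep(if (cc == -Inf) 0 else 1, length(ph))
    } else {
      post <- (1 - pi) * ph / (pi + (1 - pi) * ph)
    }
  } else {
    post <- numeric(0); mu <- numeric(0)
  }
  out <- data.frame(peptide_id = sub$peptide_ids[miss[, 1L]],
                    sample_id = sub$sample_ids[miss[, 2L]],
                    posterior_censored = as.numeric(post),
                    label = ifelse(post >= threshold, "censored", "mcar"),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_classification", "data.frame")
  out
}
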