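# Sample-level normalization: global centering and lowess MA-plot
# normalization against a reference sample.

new_norm_result <- function(normalized, method, n_trends_removed = 0L,
                            per_sample_offsets = NULL, rng_seed = NA_integer_,
                            ...) {
  structure(c(list(normalized = normalized, method = method,
                   n_trends_removed = as.integer(n_trends_removed),
                   per_sample_offsets = per_sample_offsets,
                   rng_seed = rng_seed),
              list(...)),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("norm_result (%s): %d x %d matrix", x$method,
              nrow(x$normalized$values), ncol(x$normalized$values)))
  if (x$method %in% c("eigenms", "eigenms_reinflated"))
    cat(sprintf(", %d bias trend(s) removed", x$n_trends_removed))
  cat("\n")
  invisible(x)
}

#' Global centering normalization
#'
#' Forces the per-sample distribution of log intensities to center on a
#' common constant: for each sample the chosen statistic (median or mean)
#' of its non-missing values, optionally restricted to a subset of peptides
#' (e.g. from housekeeping proteins), is shifted to \code{target}. Corrects
#' sample loading differences; cannot capture intensity-dependent bias.
#'
#' @param m an \code{abund_matrix} (log scale).
#' @param statistic \code{"median"} (default) or \code{"mean"}.
#' @param target the constant each sample is centered on (default 0).
#' @param subset optional character vector of peptide ids on which the
#'   centering statistic is computed.
#' @return A \code{"norm_result"}; \code{$per_sample_offsets} holds the
#'   subtracted per-sample shifts.
#' @export
global_center <- function(m, statistic = c("median", "mean"), target = 0,
                          subset = NULL) {
  stopifnot(inherits(m, "abund_matrix"))
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "median") stats::median else mean
  v <- m$values
  if (!is.null(subset)) {
    if (!length(subset)) stop_("'subset' must be non-empty when given")
    absent <- setdiff(subset, m$peptide_ids)
    if (length(absent))
      stop_("subset peptide '%s' not in the matrix", absent[1L])
    vs <- v[m$peptide_ids %in% subset, , drop = FALSE]
  } else vs <- v
  nn <- colSums(!is.na(vs))
  if (any(nn == 0L))
    stop_("sample '%s' has no non-missing values in the centering subset",
          m$sample_ids[which(nn == 0L)[1L]])
  offsets <- apply(vs, 2L, stat_fun, na.rm = TRUE) - target
  out <- sweep(v, 2L, offsets, `-`)
  new_norm_result(abundance_matrix(out, m$peptide_ids, m$sample_ids,
                                   log_base = m$log_base),
                  method = "global_center",
                  per_sample_offsets = stats::setNames(offsets, m$sample_ids),
                  statistic = statistic, target = target)
}

#' Lowess MA-plot normalization
#'
#' For each sample, forms an MA plot against a reference (M = sample minus
#' reference, A = their average, over jointly observed peptides), fits a
#' lowess curve of M on A, and subtracts the fitted curve from the sample.
#' Captures smooth intensity-dependent bias that global centering misses.
#'
#' The default reference is a median pseudo-sample (per-peptide median over
#' observed cells), avoiding the arbitrary choice of a single reference
#' run; a named sample may be used instead and is then left unchanged.
#'
#' @param m an \code{abund_matrix} (log scale).
#' @param reference \code{"median_pseudo"} (default) or a sample id.
#' @param fraction lowess smoother span in (0, 1]; 0.4 is the empirically
#'   established default for LC-MS intensity data.
#' @param min_joint minimum number of jointly observed peptides required
#'   between each sample and the reference (default 10).
#' @return A \code{"norm_result"} with the adjusted matrix; the reference
#'   definition is recorded in \code{$reference}.
#' @export
lowess_ma_normalize <- function(m, reference = "median_pseudo",
                                fraction = 0.4, min_joint = 10L) {
  stopifnot(inherits(m, "abund_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop_("'fraction' must lie in (0, 1]")
  v <- m$values
  if (identical(reference, "median_pseudo")) {
    r <- apply(v, 1L, stats::median, na.rm = TRUE)
    skip <- character(0)
  } else {
    if (!reference %in% m$sample_ids)
      stop_("reference sample '%s' not found", reference)
    r <- v[, reference]
    skip <- reference
  }
  out <- v
  for (s in setdiff(m$sample_ids, skip)) {
    x <- v[, s]
    joint <- !is.na(x) & !is.na(r)
    if (sum(joint) < min_joint)
      stop_("sample '%s' shares only %d observed peptides with the reference (need >= %d)",
            s, sum(joint), min_joint)
    A <- (x[joint] + r[joint]) / 2
    M <- x[joint] - r[joint]
    lw <- stats::lowess(A, M, f = fraction)
    # evaluate the curve at every observed cell of the sample that has a
    # reference value; cells without a reference A-coordinate are left as-is
    fit_at <- stats::approx(lw$x, lw$y, xout = A, rule = 2,
                            ties = mean)$y
    out[joint, s] <- x[joint] - fit_at
  }
  new_norm_result(abundance_matrix(out, m$peptide_ids, m$sample_ids,
                                   log_base = m$log_base),
                  method = "lowess_ma",
                  reference = reference, fraction = fraction)
}
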