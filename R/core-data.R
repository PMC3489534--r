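#' Peptide-by-sample abundance matrix
#'
#' The central container of the package: a numeric matrix of peptide
#' abundances with peptides in rows and samples in columns. Missing
#' measurements are carried explicitly as \code{NA}. The matrix is either on
#' the raw intensity scale (\code{log_base = "raw"}) or on a logarithmic
#' scale, in which case \code{log_base} records the base (base 2 is the
#' field's convention, so group differences read as log2 fold changes).
#'
#' @param values numeric matrix, peptides x samples. \code{NA} marks a
#'   missing cell; all non-missing values must be finite.
#' @param peptide_ids character vector of unique peptide identifiers; taken
#'   from \code{rownames(values)} when omitted.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from \code{colnames(values)} when omitted.
#' @param log_base either the string \code{"raw"} or a positive number
#'   giving the logarithm base of \code{values}.
#' @return An object of class \code{"abund_matrix"}: a list with elements
#'   \code{values}, \code{peptide_ids}, \code{sample_ids}, \code{log_base}.
#' @examples
#' m <- abundance_matrix(matrix(c(1, 2, NA, 4), 2, 2,
#'                              dimnames = list(c("p1", "p2"), c("s1", "s2"))),
#'                       log_base = "raw")
#' n_missing(m)
#' @export
abundance_matrix <- function(values, peptide_ids = rownames(values),
                             sample_ids = colnames(values), log_base = 2) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("'values' must be a numeric matrix")
  if (is.null(peptide_ids) || is.null(sample_ids))
    stop_("peptide and sample identifiers are required")
  peptide_ids <- as.character(peptide_ids)
  sample_ids <- as.character(sample_ids)
  if (length(peptide_ids) != nrow(values))
    stop_("length of 'peptide_ids' (%d) does not match rows (%d)",
          length(peptide_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stop_("length of 'sample_ids' (%d) does not match columns (%d)",
          length(sample_ids), ncol(values))
  if (anyDuplicated(peptide_ids))
    stop_("duplicate peptide id: '%s'",
          peptide_ids[anyDuplicated(peptide_ids)])
  if (anyDuplicated(sample_ids))
    stop_("duplicate sample id: '%s'", sample_ids[anyDuplicated(sample_ids)])
  if (any(!is.finite(values) & !is.na(values)))
    stop_("non-missing values must be finite")
  if (!identical(log_base, "raw")) {
    log_base <- as.numeric(log_base)
    if (length(log_base) != 1L || !is.finite(log_base) || log_base <= 0)
      stop_("'log_base' must be \"raw\" or a positive number")
  }
  dimnames(values) <- list(peptide_ids, sample_ids)
  structure(list(values = values, peptide_ids = peptide_ids,
                 sample_ids = sample_ids, log_base = log_base),
            class = "abund_matrix")
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("abund_matrix: %d peptides x %d samples (%s scale), %d missing cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values),
              if (identical(x$log_base, "raw")) "raw"
              else sprintf("log%g", x$log_base),
              n_missing(x), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abund_matrix <- function(x) dim(x$values)

#' Number of missing cells in an abundance matrix
#' @param m an \code{abund_matrix}.
#' @return integer count of \code{NA} cells.
#' @export
n_missing <- function(m) {
  stopifnot(inherits(m, "abund_matrix"))
  sum(is.na(m$values))
}

#' Study design: sample-to-group (and optional batch) assignment
#'
#' @param sample_id character vector of sample identifiers.
#' @param group vector (coerced to factor) of treatment-group labels, one
#'   per sample.
#' @param batch optional vector (coerced to factor) of batch labels.
#' @return Object of class \code{"study_design"}: a data.frame with columns
#'   \code{sample_id}, \code{group}, and optionally \code{batch}, plus a
#'   \code{sample_index} column giving the run order (1..N).
#' @export
study_design <- function(sample_id, group, batch = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop_("duplicate sample id in design: '%s'",
          sample_id[anyDuplicated(sample_id)])
  if (length(group) != length(sample_id))
    stop_("'group' must have one entry per sample")
  d <- data.frame(sample_id = sample_id, group = factor(group),
                  sample_index = seq_along(sample_id),
                  stringsAsFactors = FALSE)
  if (!is.null(batch)) {
    if (length(batch) != length(sample_id))
      stop_("'batch' must have one entry per sample")
    d$batch <- factor(batch)
  }
  class(d) <- c("study_design", "data.frame")
  d
}

#' Peptide-to-protein map
#'
#' @param peptide_id character vector of peptide identifiers.
#' @param protein_id character vector of parent protein identifiers, one
#'   per peptide (each peptide maps to exactly one protein).
#' @return Object of class \code{"protein_map"}: a data.frame with columns
#'   \code{peptide_id} and \code{protein_id}.
#' @export
protein_map <- function(peptide_id, protein_id) {
  peptide_id <- as.character(peptide_id)
  protein_id <- as.character(protein_id)
  if (length(peptide_id) != length(protein_id))
    stop_("'peptide_id' and 'protein_id' must have equal length")
  if (anyDuplicated(peptide_id))
    stop_("peptide '%s' maps to more than one protein",
          peptide_id[anyDuplicated(peptide_id)])
  d <- data.frame(peptide_id = peptide_id, protein_id = protein_id,
                  stringsAsFactors = FALSE)
  class(d) <- c("protein_map", "data.frame")
  d
}

# Check that a design/map covers a matrix; reorder design to matrix columns.
align_design <- function(m, design) {
  stopifnot(inherits(m, "abund_matrix"), inherits(design, "study_design"))
  if (!setequal(design$sample_id, m$sample_ids))
    stop_("design sample ids do not match matrix sample ids")
  design[match(m$sample_ids, design$sample_id), , drop = FALSE]
}

check_map <- function(m, pmap) {
  stopifnot(inherits(m, "abund_matrix"), inherits(pmap, "protein_map"))
  miss <- setdiff(m$peptide_ids, pmap$peptide_id)
  if (length(miss))
    stop_("peptide '%s' absent from the protein map", miss[1L])
  invisible(TRUE)
}

# protein id for each matrix row, in matrix order
map_proteins <- function(m, pmap) {
  check_map(m, pmap)
  pmap$protein_id[match(m$peptide_ids, pmap$peptide_id)]
}

#' Log-transform a raw-scale abundance matrix
#'
#' Applies \code{log} in the given base to every non-missing cell. Missing
#' cells are untouched. Zero or negative intensities are refused: whether a
#' zero should be treated as missing or as censored-at-zero is a judgement
#' about the upstream quantification tool, and is left to the caller to make
#' before transforming.
#'
#' @param m an \code{abund_matrix} flagged as raw scale.
#' @param base positive logarithm base (default 2, the fold-change
#'   convention).
#' @return An \code{abund_matrix} on the log scale.
#' @export
log_transform <- function(m, base = 2) {
  stopifnot(inherits(m, "abund_matrix"))
  if (!identical(m$log_base, "raw"))
    stop_("matrix is already on a log scale (base %g)", m$log_base)
  base <- as.numeric(base)
  if (length(base) != 1L || !is.finite(base) || base <= 0)
    stop_("'base' must be a positive number")
  v <- m$values
  if (any(v <= 0, na.rm = TRUE))
    stop_("non-positive abundance present; drop or recode zeros before log transform")
  v[!is.na(v)] <- log(v[!is.na(v)], base = base)
  abundance_matrix(v, m$peptide_ids, m$sample_ids, log_base = base)
}

#' Rows with no missing cells
#'
#' Returns the sub-matrix of peptides observed in every sample, preserving
#' row order. Eigentrend diagnostics operate on these rows only, since the
#' SVD requires a complete matrix.
#'
#' @param m an \code{abund_matrix}.
#' @return An \code{abund_matrix} containing only the complete rows.
#' @export
complete_rows <- function(m) {
  stopifnot(inherits(m, "abund_matrix"))
  keep <- rowSums(is.na(m$values)) == 0L
  if (!any(keep))
    stop_(paste("no peptide is observed in every sample;",
                "SVD eigentrend diagnostics are unavailable for this matrix"))
  abundance_matrix(m$values[keep, , drop = FALSE], m$peptide_ids[keep],
                   m$sample_ids, log_base = m$log_base)
}

# subset rows by peptide ids (keeps matrix row order)
subset_peptides <- function(m, ids) {
  keep <- m$peptide_ids %in% ids
  abundance_matrix(m$values[keep, , drop = FALSE], m$peptide_ids[keep],
                   m$sample_ids, log_base = m$log_base)
}
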