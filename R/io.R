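# Plain-text I/O. Matrix files: header "peptide_id<sep>sample1<sep>...",
# one row per peptide. Missing tokens accepted on input: "", "NA", "NaN"
# (case-insensitive); output always writes the empty string.

MISSING_TOKENS <- c("", "na", "nan")

sep_for <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (dialect == "tsv") "\t" else ","
}

#' Read a peptide-by-sample abundance table
#'
#' Expects a delimited text file whose first column holds peptide ids and
#' whose remaining columns hold one sample each. Empty cells and the tokens
#' \code{NA} / \code{NaN} (any case) are read as missing.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param log_base scale flag recorded on the result: \code{"raw"} or a
#'   positive number (default \code{"raw"}; transformation is never implied
#'   by reading).
#' @return An \code{abund_matrix}; row and column order follow the file.
#' @seealso [write_abundance_table()]
#' @export
read_abundance_table <- function(path, dialect = "tsv", log_base = "raw") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  sep <- sep_for(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 2L) stop_("no data rows in %s", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ncol_exp <- length(header)
  if (ncol_exp < 2L) stop_("header must contain at least one sample column")
  sample_ids <- header[-1L]
  rows <- fields[-1L]
  # trailing empty fields are dropped by strsplit; pad short rows only
  rows <- lapply(rows, function(f)
    if (length(f) < ncol_exp) c(f, rep("", ncol_exp - length(f))) else f)
  nf <- lengths(rows)
  if (any(nf != ncol_exp))
    stop_("ragged row %d: %d fields, expected %d",
          which(nf != ncol_exp)[1L] + 1L, nf[nf != ncol_exp][1L], ncol_exp)
  peptide_ids <- vapply(rows, `[[`, character(1), 1L)
  cells <- t(vapply(rows, function(f) f[-1L], character(ncol_exp - 1L)))
  if (ncol_exp == 2L) cells <- matrix(cells, ncol = 1L)
  cells <- trimws(cells)
  is_miss <- tolower(cells) %in% MISSING_TOKENS
  vals <- suppressWarnings(as.numeric(cells))
  bad <- !is_miss & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    ri <- ((idx - 1L) %% nrow(cells)) + 1L
    ci <- ((idx - 1L) %/% nrow(cells)) + 1L
    stop_("cannot parse value '%s' at peptide '%s', sample '%s'",
          cells[idx], peptide_ids[ri], sample_ids[ci])
  }
  vals[is_miss] <- NA_real_
  dim(vals) <- dim(cells)
  abundance_matrix(vals, peptide_ids, sample_ids, log_base = log_base)
}

#' Write an abundance table
#'
#' @param m an \code{abund_matrix}.
#' @param path output file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return \code{path}, invisibly. Missing cells are written as empty
#'   fields.
#' @export
write_abundance_table <- function(m, path, dialect = "tsv") {
  stopifnot(inherits(m, "abund_matrix"))
  sep <- sep_for(dialect)
  v <- m$values
  ch <- format(v, trim = TRUE, digits = 15)
  ch[is.na(v)] <- ""
  dim(ch) <- dim(v)
  lines <- c(paste(c("peptide_id", m$sample_ids), collapse = sep),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(m$peptide_ids[i], ch[i, ]), collapse = sep),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a study design table
#'
#' Delimited file with columns \code{sample_id}, \code{group} and
#' optionally \code{batch}.
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return A \code{study_design}.
#' @export
read_study_design <- function(path, dialect = "tsv") {
  d <- utils::read.table(path, sep = sep_for(dialect), header = TRUE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stop_("design file must have columns 'sample_id' and 'group'")
  study_design(d$sample_id, d$group,
               batch = if ("batch" %in% names(d)) d$batch else NULL)
}

#' Read a peptide-to-protein map table
#'
#' Delimited file with columns \code{peptide_id} and \code{protein_id}.
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return A \code{protein_map}.
#' @export
read_protein_map <- function(path, dialect = "tsv") {
  d <- utils::read.table(path, sep = sep_for(dialect), header = TRUE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("peptide_id", "protein_id") %in% names(d)))
    stop_("map file must have columns 'peptide_id' and 'protein_id'")
  protein_map(d$peptide_id, d$protein_id)
}

#' Write a study design table
#' @param design a \code{study_design}; @param path output path;
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_study_design <- function(design, path, dialect = "tsv") {
  cols <- intersect(c("sample_id", "group", "batch"), names(design))
  utils::write.table(as.data.frame(design)[, cols, drop = FALSE], path,
                     sep = sep_for(dialect), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peptide-to-protein map table
#' @param pmap a \code{protein_map}; @param path output path;
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_protein_map <- function(pmap, path, dialect = "tsv") {
  utils::write.table(as.data.frame(pmap), path, sep = sep_for(dialect),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
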