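# In-code fixtures shared across test files.

# small abundance matrix with explicit values; NA = missing
mk_matrix <- function(values, peptides = NULL, samples = NULL,
                      log_base = 2) {
  if (is.null(peptides)) peptides <- sprintf("pep%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  abundance_matrix(values, peptides, samples, log_base = log_base)
}

# two-group design over N samples (blocked)
mk_design <- function(n_per_group, groups = c("a", "b")) {
  n <- n_per_group * length(groups)
  study_design(sprintf("s%d", seq_len(n)),
               rep(groups, each = n_per_group))
}

mk_map <- function(m, protein_of) protein_map(m$peptide_ids, protein_of)

# simulate one protein on the cell-mean model: J peptides x (2 groups of n),
# true difference `diff` (group b - group a), error sd `sd`
sim_protein <- function(J, n, diff = 0, sd = 0.5, prot = 20,
                        pep = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(pep)) pep <- stats::rnorm(J); pep <- pep - mean(pep)
  mu <- outer(prot + pep, rep(c(-diff / 2, diff / 2), each = n), `+`)
  y <- mu + matrix(stats::rnorm(J * 2 * n, 0, sd), J)
  mk_matrix(y)
}
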