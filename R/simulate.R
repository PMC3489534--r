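# Synthetic data generator. Each cell of the peptide-by-sample matrix is
#   y = Prot_i + Pep_ij + Treat_ik + Samp_im + e,
# with sum-to-zero peptide offsets and treatment effects within each
# protein and a per-protein-by-sample loading term Samp_im. Missingness is
# applied afterwards: each cell is deleted completely at random with
# probability pi_mcar, and of the remaining cells those below the
# censor_quantile of the complete value distribution are censoring-deleted.

#' Simulation configuration
#'
#' Defaults describe a two-group label-free experiment on the log2 scale:
#' protein means around 20 (SD 2), peptide offsets with SD 1, 2-12
#' peptides per protein (uniform), per-protein sample loadings with SD
#' 0.5, cell error SD 0.5, 10% of proteins differential with group-effect
#' draws of SD 1, 5% MCAR and a censoring quantile of 8.4% (about 13%
#' missing overall).
#'
#' @param n_proteins number of proteins.
#' @param peptides_min,peptides_max range of the uniform
#'   peptides-per-protein distribution.
#' @param n_groups number of treatment groups (>= 2).
#' @param samples_per_group samples in each group (>= 2).
#' @param protein_mean,protein_sd normal distribution of protein means.
#' @param peptide_sd SD of peptide offsets (centered within protein).
#' @param treat_frac fraction of differential proteins.
#' @param treat_sd SD of the per-group effect draws for differential
#'   proteins (centered within protein).
#' @param sample_sd SD of the per-protein sample loading term.
#' @param error_sd cell error SD.
#' @param pi_mcar MCAR deletion probability.
#' @param censor_quantile quantile of the complete-value distribution
#'   below which non-MCAR cells are censoring-deleted (in [0, 1)).
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_proteins = 1400L, peptides_min = 2L,
                       peptides_max = 12L, n_groups = 2L,
                       samples_per_group = 10L, protein_mean = 20,
                       protein_sd = 2, peptide_sd = 1, treat_frac = 0.1,
                       treat_sd = 1, sample_sd = 0.5, error_sd = 0.5,
                       pi_mcar = 0.05, censor_quantile = 0.084,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_min = as.integer(peptides_min),
              peptides_max = as.integer(peptides_max),
              n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              protein_mean = protein_mean, protein_sd = protein_sd,
              peptide_sd = peptide_sd, treat_frac = treat_frac,
              treat_sd = treat_sd, sample_sd = sample_sd,
              error_sd = error_sd, pi_mcar = pi_mcar,
              censor_quantile = censor_quantile, seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1L || peptides_min < 1L || peptides_max < peptides_min)
      stop_("invalid protein/peptide counts")
    if (n_groups < 2L) stop_("need at least two groups")
    if (samples_per_group < 2L)
      stop_("need at least two samples per group")
    if (any(c(protein_sd, peptide_sd, treat_sd, sample_sd, error_sd) < 0))
      stop_("standard deviations must be non-negative")
    if (treat_frac < 0 || treat_frac > 1 || pi_mcar < 0 || pi_mcar > 1)
      stop_("probabilities must lie in [0, 1]")
    if (censor_quantile < 0 || censor_quantile >= 1)
      stop_("'censor_quantile' must lie in [0, 1)")
  })
  structure(cfg, class = "sim_config")
}

#' Named simulation presets
#'
#' \describe{
#'   \item{main_study}{1400 proteins, two groups of 10 samples, 5% MCAR
#'     plus 8.4% censoring quantile (about 13% missing overall).}
#'   \item{coverage_study}{200 proteins, two groups of 5 samples, a true
#'     difference drawn for every protein, no sample-loading term (the
#'     protein-model world, so nominal coverage is attainable), missingness
#'     set by the caller (used for the coverage sweep).}
#'   \item{null_study}{400 proteins, two groups of 10, no differential
#'     proteins, complete data (bias and missingness are added by the
#'     caller as needed).}
#'   \item{ordering_study}{the \code{main_study} layout with a large
#'     differential fraction (40% of proteins, effect SD 1.5) so that the
#'     group-difference step accounts for roughly a third of the
#'     eigentrend variance, as in a strongly differential comparison.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_config()].
#' @return A \code{"sim_config"}.
#' @export
sim_preset <- function(name = c("main_study", "coverage_study",
                                "null_study", "ordering_study"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    main_study = list(),
    coverage_study = list(n_proteins = 200L, samples_per_group = 5L,
                          sample_sd = 0, treat_frac = 1,
                          pi_mcar = 0, censor_quantile = 0),
    null_study = list(n_proteins = 400L, treat_frac = 0,
                      pi_mcar = 0, censor_quantile = 0),
    ordering_study = list(treat_frac = 0.4, treat_sd = 1.5))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Simulate a peptide-level dataset with ground truth
#'
#' Draws all model terms, applies MCAR and left-censoring deletion, and
#' returns the observed matrix together with the study design, the
#' peptide-to-protein map, and a \code{"sim_truth"} object recording the
#' complete matrix, every cell's missingness mechanism, the realized
#' cutoff and the true per-protein group differences.
#'
#' MCAR deletion is applied first; a cell can be counted under only one
#' mechanism (MCAR wins ties), so the labels partition the cells.
#'
#' @param config a \code{"sim_config"}.
#' @return List with elements \code{matrix} (an \code{abund_matrix},
#'   log2 scale), \code{design}, \code{pmap}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    npep <- sample(cfg$peptides_min:cfg$peptides_max, cfg$n_proteins,
                   replace = TRUE)
    P <- sum(npep)
    K <- cfg$n_groups
    N <- K * cfg$samples_per_group
    protein_ids <- sprintf("PROT%05d", seq_len(cfg$n_proteins))
    prot_of <- rep(protein_ids, npep)
    peptide_ids <- sprintf("%s_PEP%02d", prot_of,
                           unlist(lapply(npep, seq_len)))
    sample_ids <- sprintf("S%03d", seq_len(N))
    group <- factor(rep(paste0("G", seq_len(K)),
                        each = cfg$samples_per_group))
    design <- study_design(sample_ids, group)

    prot_mean <- stats::rnorm(cfg$n_proteins, cfg$protein_mean,
                              cfg$protein_sd)
    pep_off <- stats::rnorm(P, 0, cfg$peptide_sd)
    # enforce sum-to-zero within protein
    pep_off <- pep_off - ave(pep_off, prot_of)
    diff_prot <- stats::runif(cfg$n_proteins) < cfg$treat_frac
    treat <- matrix(0, cfg$n_proteins, K)
    if (any(diff_prot)) {
      draws <- matrix(stats::rnorm(sum(diff_prot) * K, 0, cfg$treat_sd),
                      ncol = K)
      treat[diff_prot, ] <- draws - rowMeans(draws)
    }
    samp <- matrix(stats::rnorm(cfg$n_proteins * N, 0, cfg$sample_sd),
                   cfg$n_proteins, N)
    err <- matrix(stats::rnorm(P * N, 0, cfg$error_sd), P, N)

    prot_idx <- rep(seq_len(cfg$n_proteins), npep)
    grp_idx <- as.integer(group)
    complete <- prot_mean[prot_idx] + pep_off +
      treat[cbind(rep(prot_idx, N), rep(grp_idx, each = P))] +
      samp[cbind(rep(prot_idx, N), rep(seq_len(N), each = P))] + err
    dim(complete) <- c(P, N)
    dimnames(complete) <- list(peptide_ids, sample_ids)

    mcar <- matrix(stats::runif(P * N) < cfg$pi_mcar, P, N)
    cutoff <- if (cfg$censor_quantile > 0)
      stats::quantile(complete, cfg$censor_quantile, names = FALSE)
    else -Inf
    cens <- !mcar & complete < cutoff
    mechanism <- matrix("observed", P, N,
                        dimnames = dimnames(complete))
    mechanism[mcar] <- "mcar"
    mechanism[cens] <- "censored"

    values <- complete
    values[mcar | cens] <- NA_real_

    truth <- structure(
      list(complete_matrix = abundance_matrix(complete, peptide_ids,
                                              sample_ids, log_base = 2),
           true_treat_diff = stats::setNames(treat[, 2L] - treat[, 1L],
                                             protein_ids),
           treat_effects = structure(treat,
                                     dimnames = list(protein_ids,
                                                     levels(group))),
           mechanism = mechanism, cutoff = cutoff,
           differential = stats::setNames(diff_prot, protein_ids),
           config = cfg),
      class = "sim_truth")

    list(matrix = abundance_matrix(values, peptide_ids, sample_ids,
                                   log_base = 2),
         design = design,
         pmap = protein_map(peptide_ids, prot_of),
         truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  tab <- table(factor(x$mechanism, c("observed", "mcar", "censored")))
  cat(sprintf("sim_truth: %d cells (%.1f%% mcar, %.1f%% censored), cutoff %.3f\n",
              sum(tab), 100 * tab[["mcar"]] / sum(tab),
              100 * tab[["censored"]] / sum(tab), x$cutoff))
  invisible(x)
}

#' Inject a rank-one sample bias trend
#'
#' Adds \code{loading * trend} to every peptide row, with per-peptide
#' loadings drawn from Normal(0, loading_sd^2) — a systematic across-
#' sample bias of the kind eigentrend normalization is designed to remove.
#' The missing mask is preserved.
#'
#' @param m an \code{abund_matrix}.
#' @param trend numeric vector, one value per sample.
#' @param loading_sd SD of the per-peptide loadings (0 leaves the matrix
#'   unchanged).
#' @param seed integer seed.
#' @return An \code{abund_matrix} with the bias added to observed cells.
#' @export
inject_bias_trend <- function(m, trend, loading_sd, seed = 1L) {
  stopifnot(inherits(m, "abund_matrix"))
  if (length(trend) != ncol(m$values))
    stop_("trend length %d does not match %d samples", length(trend),
          ncol(m$values))
  if (loading_sd < 0) stop_("'loading_sd' must be non-negative")
  if (loading_sd == 0) return(m)
  lam <- with_seed(seed, stats::rnorm(nrow(m$values), 0, loading_sd))
  v <- m$values + outer(lam, as.numeric(trend))
  abundance_matrix(v, m$peptide_ids, m$sample_ids, log_base = m$log_base)
}

# standardized within-group linear drift: orthogonal to both the constant
# and the group-step direction, so technical bias and biology separate
sawtooth_trend <- function(design) {
  g <- design$group
  x <- numeric(nrow(design))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    x[idx] <- seq(-1, 1, length.out = length(idx))
  }
  x / stats::sd(x)
}

# +/- group-step indicator, standardized
group_step <- function(design) {
  s <- as.integer(design$group == levels(design$group)[2L])
  (s - mean(s)) / stats::sd(s)
}
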