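# End-to-end simulation-study drivers: confidence-interval coverage under
# increasing censoring, the normalization/imputation ordering comparison,
# and null p-value calibration. Every driver is reproducible bit-for-bit
# from (config, seed) and emits numbers, not figures.

new_experiment_report <- function(results, config, seed, sub_seeds, ...) {
  structure(c(list(results = results, config = config, seed = seed,
                   sub_seeds = sub_seeds,
                   timestamp = format(Sys.time(), usetz = TRUE)),
              list(...)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  print(x$results)
  invisible(x)
}

#' Confidence-interval coverage across missingness levels
#'
#' For each total missingness level, simulates datasets with 5% MCAR (0%
#' at the zero level) and enough left-censoring to reach the level,
#' applies an analysis strategy, and reports the empirical coverage of
#' nominal \code{level} confidence intervals for the protein group
#' differences against the simulated truth.
#'
#' Strategies: \code{complete_case} (least squares on the observed cells,
#' ignoring the mechanism), \code{naive_min_impute} (fill missing cells
#' with the minimum observed value, then least squares), \code{model_ml}
#' (the censored/MCAR likelihood with Wald intervals).
#'
#' @param n_sims simulated datasets per level (default 100).
#' @param n_proteins proteins per dataset (default 200).
#' @param missing_levels total-missingness levels in [0, 1) (default 0 to
#'   0.40 in steps of 0.05).
#' @param pi_mcar MCAR component at non-zero levels (default 0.05).
#' @param level nominal confidence level (default 0.95).
#' @param strategy analysis strategy (see above).
#' @param seed master seed.
#' @param samples_per_group samples per group (default 5).
#' @param ... further [sim_config()] overrides.
#' @return An \code{"experiment_report"}; \code{$results} has one row per
#'   level with mean coverage, its Monte-Carlo SE, the realized missing
#'   fractions (total and censored-only), and the interval count.
#' @export
run_coverage_experiment <- function(n_sims = 100L, n_proteins = 200L,
                                    missing_levels = seq(0, 0.40, by = 0.05),
                                    pi_mcar = 0.05, level = 0.95,
                                    strategy = c("naive_min_impute",
                                                 "complete_case",
                                                 "model_ml"),
                                    seed = 1L, samples_per_group = 5L,
                                    ...) {
  strategy <- match.arg(strategy)
  if (any(missing_levels < 0 | missing_levels >= 1))
    stop_("missing levels must lie in [0, 1)")
  seeds <- derive_seeds(seed, n_sims * length(missing_levels))
  dim(seeds) <- c(n_sims, length(missing_levels))
  rows <- vector("list", length(missing_levels))
  for (li in seq_along(missing_levels)) {
    L <- missing_levels[li]
    pi <- if (L <= 0) 0 else min(pi_mcar, L)
    q <- if (L <= pi) 0 else (L - pi) / (1 - pi)
    cov <- tot_miss <- cens_miss <- numeric(n_sims)
    n_int <- 0L
    for (si in seq_len(n_sims)) {
      cfg <- sim_preset("coverage_study", n_proteins = n_proteins,
                        samples_per_group = samples_per_group,
                        pi_mcar = pi, censor_quantile = q,
                        seed = seeds[si, li], ...)
      sim <- simulate_dataset(cfg)
      res <- switch(strategy,
        complete_case = test_protein_difference(
          sim$matrix, sim$design, sim$pmap, level = level,
          method = "complete_data_anova"),
        naive_min_impute = {
          mm <- sim$matrix
          # peptides never observed cannot be imputed by any naive rule
          seen <- rowSums(!is.na(mm$values)) > 0L
          if (!all(seen)) mm <- subset_peptides(mm, mm$peptide_ids[seen])
          if (n_missing(mm) > 0L) mm <- impute_naive(mm, "row_min")
          test_protein_difference(mm, sim$design, sim$pmap, level = level,
                                  method = "complete_data_anova")
        },
        model_ml = test_protein_difference(
          sim$matrix, sim$design, sim$pmap, level = level,
          method = "wald_ml",
          params = if (n_missing(sim$matrix) > 0L)
            estimate_missingness_params(sim$matrix)
          else missingness_params(0, -Inf)))
      cov[si] <- coverage_proportion(
        sim$truth$true_treat_diff[names(sim$truth$true_treat_diff) %in%
                                    res$protein_id], res)
      n_int <- n_int + sum(is.finite(res$ci_low))
      mech <- sim$truth$mechanism
      tot_miss[si] <- mean(mech != "observed")
      cens_miss[si] <- mean(mech == "censored")
    }
    rows[[li]] <- data.frame(
      missing_level = L, mean_coverage = mean(cov),
      mc_se = stats::sd(cov) / sqrt(n_sims),
      realized_total_missing = mean(tot_miss),
      realized_censored = mean(cens_miss),
      n_intervals = n_int, n_sims = n_sims)
  }
  new_experiment_report(do.call(rbind, rows),
                        config = list(n_proteins = n_proteins,
                                      samples_per_group = samples_per_group,
                                      pi_mcar = pi_mcar, level = level),
                        seed = seed, sub_seeds = seeds,
                        strategy = strategy)
}

# Simulate a dataset whose raw (complete) values carry an injected bias
# trend, with MCAR and censoring applied to the *biased* values — bias is
# part of the measurement process, so it shapes which cells go missing.
simulate_biased_dataset <- function(config, loading_sd, bias_trend,
                                    bias_seed, mask_seed) {
  cfg0 <- sim_config_with_seed(config, config$seed)
  cfg0$pi_mcar <- 0; cfg0$censor_quantile <- 0
  sim <- simulate_dataset(cfg0)
  if (is.null(bias_trend)) bias_trend <- sawtooth_trend(sim$design)
  biased <- inject_bias_trend(sim$matrix, bias_trend, loading_sd,
                              seed = bias_seed)
  v <- biased$values
  with_seed(mask_seed, {
    mcar <- matrix(stats::runif(length(v)) < config$pi_mcar,
                   nrow(v), ncol(v))
    cutoff <- if (config$censor_quantile > 0)
      stats::quantile(v, config$censor_quantile, names = FALSE) else -Inf
    cens <- !mcar & v < cutoff
    v[mcar | cens] <- NA_real_
  })
  masked <- abundance_matrix(v, biased$peptide_ids, biased$sample_ids,
                             log_base = biased$log_base)
  mechanism <- matrix("observed", nrow(v), ncol(v),
                      dimnames = dimnames(v))
  mechanism[mcar] <- "mcar"; mechanism[cens] <- "censored"
  list(matrix = masked, design = sim$design, pmap = sim$pmap,
       truth = sim$truth, mechanism = mechanism,
       bias_trend = bias_trend)
}

# eigentrend summary of a matrix: top trends + |cor| with the group step
trend_summary <- function(m, design, n_top = 3L) {
  ev <- compute_eigentrends(complete_rows(m))
  step <- group_step(design)
  n_top <- min(n_top, ncol(ev$trends))
  data.frame(trend = seq_len(n_top),
             variance_fraction = ev$variance_fraction[seq_len(n_top)],
             abs_cor_group = vapply(seq_len(n_top), function(t)
               abs(stats::cor(ev$trends[, t], step)), numeric(1)))
}

#' Normalization/imputation ordering comparison
#'
#' Simulates a strongly differential two-group dataset, injects a rank-one
#' sample bias trend, and compares the top eigentrends of (a) the raw
#' biased data, (b) impute-then-normalize, and (c) normalize-then-impute.
#' The diagnostic for each condition is how strongly each top trend
#' correlates with the group-step indicator: a calibrated pipeline should
#' leave the group difference as the dominant trend.
#'
#' @param config a \code{"sim_config"} (default:
#'   \code{sim_preset("ordering_study")}).
#' @param loading_sd SD of the per-peptide bias loadings (default 0.6).
#' @param bias_trend length-N trend vector; default is a standardized
#'   within-group linear drift (orthogonal to the group step, so biology
#'   and bias are separable).
#' @param seed master seed.
#' @param n_perm,alpha trend-selection settings for the normalization.
#' @param n_top number of top trends reported (default 3).
#' @return An \code{"experiment_report"}; \code{$results} has one row per
#'   condition and trend with the variance fraction and the absolute
#'   correlation with the group step; \code{$trends} carries the trend
#'   vectors for plotting.
#' @export
run_ordering_experiment <- function(config = sim_preset("ordering_study"),
                                    loading_sd = 0.6, bias_trend = NULL,
                                    seed = 1L, n_perm = 49L, alpha = 0.05,
                                    n_top = 3L) {
  sseed <- derive_seeds(seed, 5L)
  cfg <- sim_config_with_seed(config, sseed[1L])
  sim <- simulate_biased_dataset(cfg, loading_sd, bias_trend,
                                 bias_seed = sseed[2L],
                                 mask_seed = sseed[5L])
  biased <- sim$matrix
  params <- if (n_missing(biased) > 0L)
    estimate_missingness_params(biased) else missingness_params(0, -Inf)

  conditions <- list()
  trends <- list()
  grab <- function(m) {
    ev <- compute_eigentrends(complete_rows(m))
    ev$trends[, seq_len(min(n_top, ncol(ev$trends))), drop = FALSE]
  }

  conditions$raw <- trend_summary(biased, sim$design, n_top)
  trends$raw <- grab(biased)

  imp_first <- model_impute(biased, sim$design, sim$pmap, params,
                            seed = sseed[3L])
  norm_after <- eigenms_normalize(imp_first, sim$design, sim$pmap,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = sseed[4L])
  conditions$impute_then_normalize <-
    trend_summary(norm_after$normalized, sim$design, n_top)
  trends$impute_then_normalize <- grab(norm_after$normalized)

  norm_first <- eigenms_normalize(biased, sim$design, sim$pmap,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = sseed[4L])
  imp_after <- model_impute(norm_first$normalized, sim$design, sim$pmap,
                            params, seed = sseed[3L])
  conditions$normalize_then_impute <-
    trend_summary(imp_after, sim$design, n_top)
  trends$normalize_then_impute <- grab(imp_after)

  results <- do.call(rbind, Map(function(nm, df) {
    df$condition <- nm
    df[, c("condition", "trend", "variance_fraction", "abs_cor_group")]
  }, names(conditions), conditions))
  rownames(results) <- NULL
  new_experiment_report(results, config = cfg, seed = seed,
                        sub_seeds = sseed, trends = trends,
                        bias_trend = sim$bias_trend, loading_sd = loading_sd,
                        n_trends_removed = c(
                          impute_then_normalize = norm_after$n_trends_removed,
                          normalize_then_impute = norm_first$n_trends_removed))
}

#' Null p-value calibration study
#'
#' Simulates a dataset with no true group differences, injects a bias
#' trend, and compares the per-peptide group-test p-value distribution
#' under two pipelines: raw (tests on the biased data) and
#' normalized_reinflated (eigentrend normalization followed by residual
#' re-inflation, then the same tests). A calibrated pipeline yields
#' approximately uniform null p-values; bias or overfitting shows up as a
#' skewed histogram and a significant Kolmogorov-Smirnov statistic.
#'
#' @param config a \code{"sim_config"} with \code{treat_frac = 0}
#'   (default: \code{sim_preset("null_study")}).
#' @param pipelines subset of \code{c("raw", "normalized_reinflated")}.
#' @param loading_sd SD of the per-peptide bias loadings (default 0.6).
#' @param bias_trend length-N trend vector (default: within-group drift).
#' @param seed master seed.
#' @param n_perm,alpha trend-selection settings.
#' @param n_bins histogram bins (default 20).
#' @return An \code{"experiment_report"}; \code{$results} has one row per
#'   pipeline with the KS statistic and p-value and the number of
#'   peptides tested; \code{$histograms} holds the bin counts.
#' @export
run_null_pvalue_experiment <- function(config = sim_preset("null_study"),
                                       pipelines = c("raw",
                                                     "normalized_reinflated"),
                                       loading_sd = 0.6, bias_trend = NULL,
                                       seed = 1L, n_perm = 49L,
                                       alpha = 0.05, n_bins = 20L) {
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  if (config$treat_frac != 0)
    stop_("null study requires a config with treat_frac = 0")
  sseed <- derive_seeds(seed, 4L)
  cfg <- sim_config_with_seed(config, sseed[1L])
  sim <- simulate_dataset(cfg)
  if (is.null(bias_trend)) bias_trend <- sawtooth_trend(sim$design)
  biased <- inject_bias_trend(sim$matrix, bias_trend, loading_sd,
                              seed = sseed[2L])
  rows <- list(); hists <- list()
  for (pl in pipelines) {
    m <- if (pl == "raw") biased else {
      nr <- eigenms_normalize(biased, sim$design, sim$pmap,
                              n_perm = n_perm, alpha = alpha,
                              seed = sseed[3L])
      if (nr$n_trends_removed > 0L)
        reinflate_residuals(nr, seed = sseed[4L])$normalized
      else nr$normalized
    }
    p <- peptide_ttests(m, sim$design)$p_value
    p <- p[is.finite(p)]
    diag <- pvalue_uniformity_diagnostic(p, n_bins = n_bins)
    rows[[pl]] <- data.frame(pipeline = pl,
                             ks_statistic = diag$ks_statistic,
                             ks_p = diag$ks_p, n_peptides = length(p))
    hists[[pl]] <- diag$bin_counts
  }
  new_experiment_report(do.call(rbind, c(rows, make.row.names = FALSE)),
                        config = cfg, seed = seed, sub_seeds = sseed,
                        histograms = hists, loading_sd = loading_sd,
                        bias_trend = bias_trend)
}

# replace the seed inside a sim_config
sim_config_with_seed <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  config$seed <- as.integer(seed)
  config
}
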