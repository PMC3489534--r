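test_that("the generator is deterministic and labels partition the cells", {
  cfg <- sim_preset("main_study", n_proteins = 80L, seed = 100)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$mechanism, b$truth$mechanism)
  mech <- a$truth$mechanism
  expect_setequal(unique(as.vector(mech)), c("observed", "mcar",
                                             "censored"))
  expect_identical(mech == "observed", !is.na(a$matrix$values))
  # censored cells sit below the realized cutoff
  expect_true(all(a$truth$complete_matrix$values[mech == "censored"] <=
                    a$truth$cutoff))
  # observed values agree with the complete matrix
  obs <- mech == "observed"
  expect_identical(a$matrix$values[obs],
                   a$truth$complete_matrix$values[obs])
})

test_that("missingness rates converge to their targets", {
  cfg <- sim_preset("main_study", seed = 101)   # 1400 proteins
  sim <- simulate_dataset(cfg)
  mech <- sim$truth$mechanism
  q <- cfg$censor_quantile; pi <- cfg$pi_mcar
  expect_lt(abs(mean(mech == "censored") - (1 - pi) * q), 0.01)
  expect_lt(abs(mean(mech == "mcar") - pi), 0.005)
  expect_lt(abs(mean(mech != "observed") - (pi + (1 - pi) * q)), 0.01)
  # pure censoring preset used in the studies
  cfg2 <- sim_preset("main_study", pi_mcar = 0, censor_quantile = 0.08,
                     seed = 102)
  sim2 <- simulate_dataset(cfg2)
  expect_equal(mean(sim2$truth$mechanism == "censored"), 0.08,
               tolerance = 0.01)
  # no missingness configured, none produced
  cfg3 <- sim_preset("null_study", n_proteins = 30L, seed = 103)
  expect_equal(n_missing(simulate_dataset(cfg3)$matrix), 0L)
})

test_that("group-mean differences of complete data match the drawn effects", {
  cfg <- sim_preset("main_study", n_proteins = 120L, treat_frac = 1,
                    seed = 104)
  sim <- simulate_dataset(cfg)
  v <- sim$truth$complete_matrix$values
  g2 <- sim$design$group == levels(sim$design$group)[2]
  prot_of <- sim$pmap$protein_id[match(sim$matrix$peptide_ids,
                                       sim$pmap$peptide_id)]
  emp <- tapply(seq_along(prot_of), prot_of, function(rows)
    mean(v[rows, g2, drop = FALSE]) - mean(v[rows, !g2, drop = FALSE]))
  tr <- sim$truth$true_treat_diff[names(emp)]
  err <- emp - tr
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
  expect_lt(max(abs(err)), 1)                 # errors are sampling noise
})

test_that("bias injection is rank one and preserves the mask", {
  sim <- simulate_dataset(sim_preset("main_study", n_proteins = 200L,
                                     seed = 105))
  trend <- lcmsprep:::sawtooth_trend(sim$design)
  b0 <- inject_bias_trend(sim$matrix, trend, 0, seed = 1)
  expect_identical(b0$values, sim$matrix$values)
  b <- inject_bias_trend(sim$matrix, trend, 1.5, seed = 1)
  expect_identical(is.na(b$values), is.na(sim$matrix$values))
  # the injected trend dominates the residual eigentrends
  f <- fit_peptide_anova(b, sim$design, sim$pmap)
  comp <- rowSums(is.na(f$residuals)) == 0
  ev <- compute_eigentrends(f$residuals[comp, ])
  expect_gt(abs(cor(ev$trends[, 1], trend)), 0.95)
  expect_error(inject_bias_trend(sim$matrix, trend[-1], 1, 1),
               "length")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_groups = 1), "two groups")
  expect_error(sim_config(samples_per_group = 1), "two samples")
  expect_error(sim_config(censor_quantile = 1), "censor_quantile")
  expect_error(sim_config(error_sd = -1), "non-negative")
  expect_error(sim_config(pi_mcar = 1.2), "probabilities")
})
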