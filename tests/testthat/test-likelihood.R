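test_that("cell log-likelihood matches its closed forms", {
  # missing cell, censoring disabled: only the MCAR channel remains
  p <- missingness_params(0.3, -Inf)
  expect_equal(cell_loglik(NA, 0, 1, p), log(0.3), tolerance = 1e-12)
  # missing cell at mu = cutoff with no MCAR: Phi(0) = 1/2
  p0 <- missingness_params(0, 2)
  expect_equal(cell_loglik(NA, 2, 1, p0), log(0.5), tolerance = 1e-12)
  # frozen high-precision value
  p1 <- missingness_params(0.1, -1)
  expect_equal(cell_loglik(NA, 0, 1, p1), -1.4155595, tolerance = 1e-4)
  # observed cell
  expect_equal(cell_loglik(1.2, 1, 0.5, p1),
               log(0.9) + dnorm(1.2, 1, 0.5, log = TRUE),
               tolerance = 1e-12)
  expect_warning(cell_loglik(1, 0, 1, missingness_params(1, 0)),
                 "impossible")
  expect_error(cell_loglik(1, 0, -1, p1), "positive")
})

test_that("observed and missing probabilities integrate to one (pi = 0)", {
  p <- missingness_params(0, -0.4)
  for (mu in c(-1, 0, 1.3)) {
    dens <- function(y) exp(cell_loglik(y, mu, 0.8, p))
    p_obs <- integrate(Vectorize(dens), p$cutoff, Inf,
                       rel.tol = 1e-10)$value
    p_missing <- exp(cell_loglik(NA, mu, 0.8, p))
    expect_equal(p_obs + p_missing, 1, tolerance = 1e-6)
  }
})

test_that("analytic likelihood gradient matches numerical differentiation", {
  set.seed(30)
  J <- 3; n <- 4
  y <- matrix(rnorm(J * 2 * n, 20), J)
  y[sample(length(y), 7)] <- NA
  grp <- rep(1:2, each = n)
  theta <- c(20, 0.3, -0.2, 0.5, log(c(0.4, 0.6, 0.5)))
  for (pi in c(0, 0.2)) {
    g_an <- lcmsprep:::protein_nll_grad(theta, y, grp, J, 2, pi, 19)
    g_num <- pracma::grad(lcmsprep:::protein_nll, theta, y = y,
                          grp_idx = grp, J = J, K = 2, pi = pi, cc = 19)
    expect_equal(g_an, g_num, tolerance = 1e-6)
  }
})

test_that("complete-data fit reproduces constrained least squares", {
  set.seed(31)
  for (J in c(1, 3)) {
    m <- sim_protein(J, n = 5, diff = 0.8, seed = 31 + J)
    d <- mk_design(5)
    fml <- fit_protein_ml(m, d, missingness_params(0, -Inf))
    fls <- fit_peptide_anova(m, d, mk_map(m, rep("P1", J)))
    expect_equal(unname(fml$protein_mean),
                 unname(fls$protein_mean["P1"]), tolerance = 1e-6)
    expect_equal(unname(fml$peptide_offset),
                 unname(fls$peptide_offset), tolerance = 1e-6)
    expect_equal(unname(fml$treat_effect),
                 unname(fls$treat_effect["P1", ]), tolerance = 1e-6)
  }
})

test_that("censored-likelihood optimizer recovers a known optimum", {
  # with censoring, compare the gradient-based optimum against an
  # independent derivative-free search from a different start
  set.seed(32)
  m <- sim_protein(2, n = 10, diff = 1, seed = 32)
  cc <- quantile(m$values, 0.3)
  v <- m$values; v[v < cc] <- NA
  sub <- mk_matrix(v)
  d <- mk_design(10)
  pars <- missingness_params(0.05, cc)
  fit <- fit_protein_ml(sub, d, pars)
  expect_true(fit$converged)
  nm <- optim(fit$theta * 0 + c(rep(19, 1), 0, 0, rep(log(1), 2)),
              lcmsprep:::protein_nll, y = v,
              grp_idx = rep(1:2, each = 10), J = 2, K = 2,
              pi = 0.05, cc = cc,
              method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(-fit$loglik, nm$value + 1e-4)
})

test_that("protein fits recover group differences under heavy censoring", {
  # 2 peptides x 2 groups x 25 samples each, ~30% left-censored at known c
  n_rep <- 60
  est <- se <- numeric(n_rep)
  truth <- 1
  for (r in seq_len(n_rep)) {
    set.seed(400 + r)
    m <- sim_protein(2, n = 25, diff = truth, sd = 0.6, seed = 400 + r)
    cc <- quantile(m$values, 0.3)
    v <- m$values; v[v < cc] <- NA
    d <- mk_design(25)
    fit <- fit_protein_ml(mk_matrix(v), d, missingness_params(0, cc))
    w <- lcmsprep:::wald_from_fit(fit)
    est[r] <- w$estimate; se[r] <- w$se
  }
  bias <- mean(est) - truth
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(bias), 2 * mc_se + 0.01)
  expect_lt(mean(abs(est - truth)), 3 * mean(se, na.rm = TRUE))
})

test_that("degenerate proteins raise identifiability errors", {
  d <- mk_design(3)
  allmiss <- mk_matrix(matrix(NA_real_, 2, 6))
  expect_error(fit_protein_ml(allmiss, d, missingness_params(0.1, 10)),
               "non-identifiable")
  v <- matrix(rnorm(6, 20), 1)
  v[, 4:6] <- NA
  expect_error(fit_protein_ml(mk_matrix(v), d,
                              missingness_params(0.1, 10)),
               "group 'b' has no observed value")
})

test_that("missingness parameters are estimated from the matrix", {
  expect_equal(estimate_missingness_params(mk_matrix(matrix(rnorm(20), 4))),
               missingness_params(0, -Inf))
  # only high-abundance peptides missing: pure MCAR at known rate
  set.seed(33)
  v <- matrix(rnorm(400 * 20, rep(c(25, 15), each = 200), 0.5), 400, 20)
  top <- which(rowMeans(v) > 20)
  idx <- cbind(sample(top, 200, replace = TRUE), sample(20, 200, TRUE))
  v[idx] <- NA
  p <- estimate_missingness_params(mk_matrix(v))
  expect_equal(p$pi_mcar, mean(is.na(v[rowMeans(v, na.rm = TRUE) >=
    quantile(rowMeans(v, na.rm = TRUE), 0.75), ])), tolerance = 1e-12)
  expect_lt(abs(p$pi_mcar - 0.05), 0.02)
  v2 <- matrix(rnorm(40, 20), 4)
  v2[, 1] <- NA
  expect_error(estimate_missingness_params(mk_matrix(v2)),
               "sample 's1' has no observed")
})
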