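test_that("information content matches the closed-form two-group value", {
  # single peptide, n per group, residuals constructed so sigma-hat = s
  # exactly; the profiled information for the difference is n/(2 s^2)
  for (n in c(4, 8)) {
    s <- 0.7
    y <- matrix(20 + rep(c(0, 1), each = n) + rep(c(-s, s), n), 1)
    d <- mk_design(n)
    fit <- fit_protein_ml(mk_matrix(y), d, missingness_params(0, -Inf))
    expect_equal(unname(fit$resid_sd), s, tolerance = 1e-10)
    expect_equal(information_content(fit), n / (2 * s^2),
                 tolerance = 1e-8)
  }
  # the n in {4, 8} pair doubles n and, per the closed form, the value
})

test_that("information is zero when a group is never observed", {
  v <- matrix(rnorm(12, 20), 2)
  v[, 4:6] <- NA
  d <- mk_design(3)
  sub <- mk_matrix(v)
  g <- greedy_select_peptides(sub, d, missingness_params(0.1, 15))
  expect_true(g$filtered)
  expect_equal(g$info_content, 0)
  expect_length(g$selected, 0)
})

test_that("deleting an observation cannot add information at fixed parameters", {
  # information ordering is a fixed-parameter statement: at re-estimated
  # sigma-hats, deleting an outlying cell can shrink sigma and raise the
  # apparent information, so the comparison is made at the full-data fit
  set.seed(40)
  m <- sim_protein(2, n = 4, diff = 0.5, seed = 40)
  d <- mk_design(4)
  p <- missingness_params(0.1, quantile(m$values, 0.2))
  fit <- fit_protein_ml(m, d, p)
  full <- information_content(fit)
  info_at <- function(v) {
    im <- pracma::hessian(lcmsprep:::protein_nll, fit$theta, y = v,
                          grp_idx = rep(1:2, each = 4), J = 2, K = 2,
                          pi = p$pi_mcar, cc = p$cutoff)
    f2 <- fit; f2$info_matrix <- (im + t(im)) / 2
    information_content(f2)
  }
  for (drop in list(c(1, 2), c(2, 7), c(1, 5))) {
    v <- m$values; v[drop[1], drop[2]] <- NA
    expect_lte(info_at(v), full * (1 + 1e-6))
  }
})

test_that("greedy peptide selection matches exhaustive search on small proteins", {
  d <- mk_design(4)
  exhaustive <- function(sub, params) {
    ids <- sub$peptide_ids
    best <- list(info = 0, set = character(0))
    for (k in seq_along(ids)) for (set in utils::combn(ids, k,
                                                       simplify = FALSE)) {
      info <- lcmsprep:::subset_info(sub, d, params, set)
      if (info > best$info + 1e-9) best <- list(info = info, set = set)
    }
    best
  }
  for (seed in 1:4) {
    set.seed(50 + seed)
    J <- sample(2:4, 1)
    sub <- sim_protein(J, n = 4, diff = 0.6, seed = 50 + seed)
    params <- missingness_params(0.1, quantile(sub$values, 0.1))
    g <- greedy_select_peptides(sub, d, params)
    ex <- exhaustive(sub, params)
    expect_equal(g$info_content, ex$info, tolerance = 1e-4)
    expect_setequal(g$selected, ex$set)
  }
  # an all-missing peptide is never selected
  m <- sim_protein(2, n = 4, seed = 60)
  v <- m$values; v[2, ] <- NA
  g <- greedy_select_peptides(mk_matrix(v), d,
                              missingness_params(0.1, 15))
  expect_false("pep2" %in% g$selected)
  expect_false(g$filtered)
})

test_that("missing-cell classification follows the posterior formula", {
  set.seed(41)
  m <- sim_protein(2, n = 4, seed = 41)
  v <- m$values; v[1, 2] <- NA; v[2, 6] <- NA
  sub <- mk_matrix(v)
  d <- mk_design(4)
  # pi = 0: everything censored
  p0 <- missingness_params(0, 25)
  fit <- fit_protein_ml(sub, d, p0)
  cls <- classify_missing(sub, fit, p0)
  expect_equal(cls$posterior_censored, c(1, 1))
  expect_true(all(cls$label == "censored"))
  # cutoff -Inf: everything MCAR
  pI <- missingness_params(0.2, -Inf)
  fitI <- fit_protein_ml(sub, d, pI)
  clsI <- classify_missing(sub, fitI, pI)
  expect_equal(clsI$posterior_censored, c(0, 0))
  expect_true(all(clsI$label == "mcar"))
  # frozen posterior: pi = 0.1, Phi((c - mu)/sigma) = Phi(-1)
  fit1 <- fitI
  fit1$mu[] <- 20
  fit1$resid_sd[] <- 1
  p1 <- missingness_params(0.1, 19)
  cls1 <- classify_missing(sub, fit1, p1)
  expect_equal(cls1$posterior_censored, rep(0.5881210, 2),
               tolerance = 1e-4)
})
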