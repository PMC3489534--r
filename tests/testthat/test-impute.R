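test_that("model-based imputation respects the censoring bound and the seed", {
  sim <- simulate_dataset(sim_preset("main_study", n_proteins = 60L,
                                     seed = 70))
  params <- estimate_missingness_params(sim$matrix)
  imp1 <- model_impute(sim$matrix, sim$design, sim$pmap, params, seed = 7)
  imp2 <- model_impute(sim$matrix, sim$design, sim$pmap, params, seed = 7)
  expect_identical(imp1$values, imp2$values)
  imp3 <- model_impute(sim$matrix, sim$design, sim$pmap, params, seed = 8)
  expect_false(identical(imp1$values, imp3$values))
  # observed cells untouched; censored-labeled cells below the cutoff
  obs <- !is.na(sim$matrix$values)
  expect_identical(imp1$values[obs], sim$matrix$values[obs])
  prot_of <- sim$pmap$protein_id[match(sim$matrix$peptide_ids,
                                       sim$pmap$peptide_id)]
  for (pr in unique(prot_of[rowSums(is.na(sim$matrix$values)) > 0])[1:5]) {
    rows <- prot_of == pr
    sub <- lcmsprep:::subset_peptides(sim$matrix,
                                      sim$matrix$peptide_ids[rows])
    fit <- fit_protein_ml(sub, sim$design, params, optimize = FALSE,
                          info = FALSE)
    cls <- classify_missing(sub, fit, params)
    cen <- cls[cls$label == "censored", ]
    if (nrow(cen))
      expect_true(all(imp1$values[cbind(
        match(cen$peptide_id, imp1$peptide_ids),
        match(cen$sample_id, imp1$sample_ids))] <= params$cutoff))
  }
})

test_that("truncated-normal imputation has the closed-form tail mean", {
  n <- 1e5
  draws <- with(list(), {
    set.seed(71)
    lcmsprep:::rtrunc_below(n, 0, 1, 0)
  })
  expect_true(all(draws <= 0))
  expect_equal(mean(draws), -sqrt(2 / pi), tolerance = 0.01)
})

test_that("cells in unfittable proteins are reported as skipped", {
  # protein with one group never observed cannot be fit
  v <- matrix(rnorm(12, 20), 2)
  v[, 4:6] <- NA
  m <- mk_matrix(v)
  d <- mk_design(3)
  imp <- model_impute(m, d, mk_map(m, c("P1", "P1")),
                      missingness_params(0.1, 15), seed = 1)
  expect_equal(n_missing(imp), 6L)
  expect_equal(nrow(attr(imp, "skipped")), 6L)
})

test_that("naive imputation methods fill with their stated values", {
  v <- matrix(c(2, NA, 5,
                4, 7, NA,
                6, 9, 1), 3, byrow = TRUE)
  m <- mk_matrix(v)
  rm_ <- impute_naive(m, "row_mean")
  expect_equal(rm_$values[1, 2], 3.5)          # mean of {2, 5}
  expect_equal(rm_$values[2, 3], 5.5)
  mo <- impute_naive(m, "min_observed")
  expect_equal(mo$values[1, 2], 1)             # global minimum
  expect_equal(mo$values[2, 3], 1)
  rmin <- impute_naive(m, "row_min")
  expect_equal(rmin$values[1, 2], 2)           # per-peptide minimum
  expect_equal(rmin$values[2, 3], 4)
  expect_equal(n_missing(rm_), 0L)
})

test_that("normal-draw imputation samples the stated distribution", {
  set.seed(72)
  v <- matrix(rnorm(12, 20, 2), 1)
  v_na <- cbind(v, NA)
  m <- mk_matrix(v_na, samples = sprintf("s%d", 1:13))
  draws <- vapply(1:2000, function(i)
    impute_naive(m, "normal_draw", seed = i)$values[1, 13], numeric(1))
  expect_lt(abs(mean(draws) - mean(v)), 3 * sd(v) / sqrt(2000))
  expect_equal(sd(draws), sd(v), tolerance = 0.2)
  # group-wise variant uses group means
  d <- mk_design(3)
  vg <- matrix(c(10, 10.2, 9.8, 20, 20.2, NA), 1)
  mg <- mk_matrix(vg, samples = d$sample_id)
  gdraws <- vapply(1:500, function(i)
    impute_naive(mg, "group_normal_draw", seed = i,
                 design = d)$values[1, 6], numeric(1))
  expect_equal(mean(gdraws), 20.1, tolerance = 0.1)
  # error paths name the offending peptide
  expect_error(impute_naive(mk_matrix(matrix(c(1, NA, NA, NA), 1,
                                             dimnames = NULL)),
                            "normal_draw"),
               "pep1.*1 observed")
  expect_error(impute_naive(mg, "group_normal_draw"), "design")
})
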