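test_that("abundance matrix enforces its invariants", {
  expect_error(mk_matrix(matrix(1:4, 2), peptides = c("p", "p")),
               "duplicate peptide")
  expect_error(mk_matrix(matrix(1:4, 2), samples = c("s", "s")),
               "duplicate sample")
  expect_error(mk_matrix(matrix(c(1, Inf, 2, 3), 2)), "finite")
  m <- mk_matrix(matrix(c(1, 2, NA, 4), 2))
  expect_equal(n_missing(m), 1L)
  expect_equal(dim(m), c(2L, 2L))
})

test_that("reading a table sets the missing mask and preserves order", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tsA\tsB",
               "PEP1\t1.5\t2.5",
               "PEP2\t\t4.0",
               "PEP3\tNA\t0.25"), f)
  m <- read_abundance_table(f)
  expect_equal(m$peptide_ids, c("PEP1", "PEP2", "PEP3"))
  expect_equal(m$sample_ids, c("sA", "sB"))
  expect_equal(which(is.na(m$values)), c(2L, 3L))   # column-major positions
  expect_equal(m$values[1, ], c(sA = 1.5, sB = 2.5))
})

test_that("malformed tables are rejected with informative errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tsA\tsB", "PEP1\t1\t2", "PEP1\t3\t4"), f)
  expect_error(read_abundance_table(f), "duplicate peptide id: 'PEP1'")
  writeLines(c("peptide_id\tsA\tsB", "PEP1\t1\t2\t9"), f)
  expect_error(read_abundance_table(f), "ragged row")
  writeLines(c("peptide_id\tsA\tsB", "PEP1\tabc\t2"), f)
  expect_error(read_abundance_table(f), "'abc'.*PEP1.*sA")
})

test_that("write/read round trip is the identity on values, mask and ids", {
  set.seed(42)
  v <- matrix(rnorm(30, 20), 6, 5)
  v[sample(30, 7)] <- NA
  m <- mk_matrix(v)
  for (dialect in c("tsv", "csv")) {
    f <- tempfile()
    write_abundance_table(m, f, dialect)
    m2 <- read_abundance_table(f, dialect, log_base = 2)
    expect_equal(m2$values, m$values, tolerance = 1e-12)
    expect_identical(is.na(m2$values), is.na(m$values))
    expect_identical(m2$peptide_ids, m$peptide_ids)
    expect_identical(m2$sample_ids, m$sample_ids)
  }
})

test_that("design and protein map files round trip", {
  d <- study_design(c("s1", "s2", "s3", "s4"), c("a", "a", "b", "b"),
                    batch = c(1, 2, 1, 2))
  f <- tempfile()
  write_study_design(d, f)
  d2 <- read_study_design(f)
  expect_equal(d2$sample_id, d$sample_id)
  expect_equal(as.character(d2$group), as.character(d$group))
  expect_equal(as.character(d2$batch), as.character(d$batch))
  pm <- protein_map(c("p1", "p2"), c("A", "A"))
  write_protein_map(pm, f)
  expect_equal(read_protein_map(f)$protein_id, c("A", "A"))
  expect_error(protein_map(c("p1", "p1"), c("A", "B")), "more than one")
})

test_that("log transform acts on non-missing cells only and is invertible", {
  m <- mk_matrix(matrix(c(4, NA, 8, 1024), 2), log_base = "raw")
  lt <- log_transform(m, 2)
  expect_equal(lt$values[1, 1], 2)
  expect_true(is.na(lt$values[2, 1]))
  expect_equal(lt$log_base, 2)
  back <- 2^lt$values
  expect_equal(back[!is.na(back)], m$values[!is.na(m$values)],
               tolerance = 1e-10)
  expect_error(log_transform(lt, 2), "already")
  expect_error(log_transform(mk_matrix(matrix(c(0, 1), 1),
                                       log_base = "raw")),
               "non-positive")
})

test_that("complete_rows keeps exactly the fully observed peptides", {
  v <- matrix(rnorm(25), 5)
  v[2, 3] <- NA; v[4, 1] <- NA
  m <- mk_matrix(v)
  cr <- complete_rows(m)
  expect_equal(cr$peptide_ids, m$peptide_ids[c(1, 3, 5)])
  expect_equal(n_missing(cr), 0L)
  full <- mk_matrix(matrix(rnorm(4), 2))
  expect_equal(complete_rows(full)$values, full$values)
  allmiss <- mk_matrix(matrix(c(NA, 1, 2, NA), 2))
  expect_error(complete_rows(allmiss), "SVD")
})
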