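test_that("partition function handles the hand-countable cases", {
  expect_identical(partition_function("AAAA"), 1)
  # GAAAC: empty structure + the single G1:C5 pair (weight 1)
  expect_equal(partition_function("GAAAC", fold_model(pair_weight = 1)), 2)
  expect_equal(partition_function("GAAAC", fold_model(pair_weight = 2)), 3)
  expect_equal(partition_function("A"), 1)
  expect_error(partition_function("ACGN"), "invalid residue")
})

test_that("pair probabilities match hand arithmetic on tiny ensembles", {
  m <- base_pair_probabilities("GAAAC", fold_model(pair_weight = 1))
  expect_equal(bpp_at(m, 1, 5), 0.5)
  expect_equal(nrow(m), 1L)
  m0 <- base_pair_probabilities("AAAA")
  expect_equal(nrow(m0), 0L)
  expect_equal(bpp_matrix(m0), matrix(0, 4, 4))
})

test_that("inside-outside agrees with exhaustive enumeration on random draws", {
  set.seed(31)
  for (r in 1:60) {
    L <- sample(6:14, 1)
    s <- random_rna(L)
    model <- random_fold_model()
    ens <- enumerate_structures(s, model)
    Z_oracle <- attr(ens, "Z")
    expect_equal(partition_function(s, model), Z_oracle,
                 tolerance = 1e-9)
    P_dp <- bpp_matrix(base_pair_probabilities(s, model))
    P_oracle <- bpp_matrix(ensemble_probabilities(ens))
    expect_lt(max(abs(P_dp - P_oracle)), 1e-9)
  }
})

test_that("rescaled recursions agree with the raw ones", {
  set.seed(32)
  s <- random_rna(80)
  model <- fold_model(pair_weight = c(AU = 0.8, GC = 2, GU = 0.4), stacking = 1.5)
  raw <- bpp_matrix(base_pair_probabilities(s, model, rescale_above = 300))
  scaled <- bpp_matrix(base_pair_probabilities(s, model, rescale_above = 10))
  expect_lt(max(abs(raw - scaled)), 1e-9)
  expect_equal(partition_function(s, model, log = TRUE, rescale_above = 10),
               partition_function(s, model, log = TRUE, rescale_above = 300),
               tolerance = 1e-9)
})

test_that("every folded matrix satisfies the row-sum and loop-constraint invariants", {
  set.seed(33)
  for (r in 1:10) {
    L <- sample(15:40, 1)
    model <- random_fold_model()
    m <- base_pair_probabilities(random_rna(L), model)
    P <- bpp_matrix(m)
    expect_lte(max(rowSums(P)), 1 + 1e-9)
    expect_true(all(P >= 0))
    if (nrow(m)) expect_true(all(m$j - m$i > model$min_loop))
  }
})

test_that("Z is monotone in the pair weights and collapses as weights vanish", {
  set.seed(34)
  s <- random_rna(25)
  for (w in c(0.5, 1, 2)) {
    z1 <- partition_function(s, fold_model(pair_weight = w))
    z2 <- partition_function(s, fold_model(pair_weight = 2.5 * w))
    expect_gte(z2, z1)
  }
  z_tiny <- partition_function(s, fold_model(pair_weight = 1e-12))
  expect_equal(z_tiny, 1, tolerance = 1e-9)
  m_tiny <- base_pair_probabilities(s, fold_model(pair_weight = 1e-12))
  if (nrow(m_tiny)) expect_lt(max(m_tiny$p), 1e-9)
})

test_that("enumeration matches an independent structure count and refuses long input", {
  model <- fold_model(pair_weight = 1)
  ens <- enumerate_structures("GGAAACC", model)
  expect_equal(nrow(ens), count_structures("GGAAACC", model))
  expect_equal(attr(ens, "Z"), nrow(ens)) # unit weights: Z = count
  expect_equal(nrow(enumerate_structures("GAAAC", model)), 2L)
  expect_equal(nrow(enumerate_structures("AAAA", model)), 1L)
  set.seed(35)
  for (r in 1:10) {
    s <- random_rna(sample(8:13, 1))
    expect_equal(nrow(enumerate_structures(s, model)), count_structures(s, model))
  }
  expect_error(enumerate_structures(random_rna(21)), "cap")
})

test_that("bpp TSV files round-trip and report format errors with line numbers", {
  m <- random_bpp(20, n_entries = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bpp(m, path)
  back <- read_bpp(path)
  expect_equal(bpp_length(back), 20L)
  expect_equal(bpp_matrix(back), bpp_matrix(m), tolerance = 1e-12)

  # zero matrix -> header-only file
  z <- bpp(data.frame(i = integer(), j = integer(), p = numeric()), 5)
  write_bpp(z, path)
  expect_false(any(!grepl("^#", readLines(path))))
  expect_equal(nrow(read_bpp(path)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# length=10", "5\t3\t0.2"), bad)
  expect_error(read_bpp(bad), "line 2.*i < j")
  writeLines(c("# length=10", "1\t5\t0.2", "2\t6\t1.7"), bad)
  expect_error(read_bpp(bad), "line 3.*\\[0, 1\\]")
  writeLines(c("# length=4", "1\t5\t0.2"), bad)
  expect_error(read_bpp(bad), "exceeds declared length")
  writeLines("1\t5\t0.2", bad)
  expect_error(read_bpp(bad), "length")
})

test_that("the Vienna ubox dialect squares the stored value", {
  path <- withr::local_tempfile(fileext = ".ps")
  writeLines(c(
    "%!PS-Adobe-3.0 EPSF-3.0",
    "/sequence (GGGAAACCC\\", ") def",
    "%data starts here",
    "1 9 0.7071 ubox",
    "2 8 0.9 ubox",
    "2 8 0.5 lbox"
  ), path)
  m <- read_bpp(path, dialect = "vienna_ubox")
  expect_equal(bpp_length(m), 9L)
  expect_equal(bpp_at(m, 1, 9), 0.7071^2)
  expect_equal(bpp_at(m, 2, 8), 0.81)
  expect_equal(nrow(m), 2L) # lbox lines ignored
  # explicit length overrides when no sequence block exists
  path2 <- withr::local_tempfile(fileext = ".ps")
  writeLines("1 5 0.5 ubox", path2)
  expect_error(read_bpp(path2, dialect = "vienna_ubox"), "length")
  expect_equal(bpp_at(read_bpp(path2, dialect = "vienna_ubox", length = 6), 1, 5), 0.25)
})

test_that("bpp objects enforce their invariants and symmetrize access", {
  expect_error(bpp(data.frame(i = 3, j = 2, p = 0.5), 5), "i >= j")
  expect_error(bpp(data.frame(i = 1, j = 2, p = 1.5), 5), "outside")
  expect_error(bpp(data.frame(i = c(1, 2), j = c(3, 3), p = c(0.8, 0.9)), 5),
               "row-sum")
  m <- bpp(data.frame(i = 1, j = 5, p = 0.5), 5)
  expect_equal(bpp_at(m, 5, 1), bpp_at(m, 1, 5))
  expect_equal(bpp_at(m, 2, 4), 0)
})
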