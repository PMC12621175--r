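test_that("standardization strips stereo/isotopes and keeps the largest fragment", {
  expect_equal(standardize("C/C=C/C")$canonical_smiles, "CC=CC")
  expect_equal(standardize("[13CH4]")$canonical_smiles, "C")
  expect_equal(standardize("CCO.Cl")$canonical_smiles, "CCO")
  expect_equal(standardize("CC(=O)[O-].[Na+]")$canonical_smiles, "CC(=O)[O-]")
  # bulk mode flags, strict mode raises
  rec <- suppressMessages(standardize(c("CCO", "not_a_smiles"), strict = FALSE))
  expect_equal(rec$is_valid, c(TRUE, FALSE))
  expect_true(is.na(rec$canonical_smiles[2]))
  expect_error(standardize("not_a_smiles"), "invalid")
  expect_error(standardize(""), "non-empty")
})

test_that("standardization is idempotent", {
  raw <- c("C/C=C\\C", "c1ccccc1C(=O)O.[Na+]", "N[C@@H](C)C(=O)O",
           "[2H]OC1CCCCC1", "CCO.CCN", "O=S(C)(=O)c1ccccc1")
  once <- standardize(raw, strict = FALSE)
  twice <- standardize(once$canonical_smiles, strict = FALSE)
  expect_identical(once$canonical_smiles, twice$canonical_smiles)
})

test_that("corpus building deduplicates canonical forms and filters length", {
  rec <- standardize(c("CCO", "OCC", "CCN"), strict = FALSE)
  corpus <- build_corpus(rec)
  expect_length(corpus, 2)
  expect_setequal(unname(corpus), c("CCO", "CCN"))
  # stable first-occurrence order
  expect_equal(unname(corpus[1]), "CCO")
  # dedup conservation: size equals the number of distinct canonical forms
  raw <- c("CCO", "OCC", "C(C)O", "CCN", "NCC", "c1ccccc1", "C1=CC=CC=C1")
  rec2 <- standardize(raw, strict = FALSE)
  expect_length(build_corpus(rec2),
                length(unique(rec2$canonical_smiles)))
  # a 141-character molecule is excluded, which empties this corpus
  long <- strrep("C", 141)
  expect_error(build_corpus(standardize(long)), "empty corpus")
  expect_error(build_corpus(data.frame(canonical_smiles = character(0),
                                       source_id = character(0),
                                       is_valid = logical(0))),
               "empty corpus")
})

test_that("Morgan fingerprints are deterministic 2048-bit radius-2 vectors", {
  a1 <- morgan_fp("c1ccccc1")
  a2 <- morgan_fp("c1ccccc1")
  expect_identical(a1, a2)
  expect_equal(a1$nbits, 2048L)
  expect_equal(a1$radius, 2L)
  b <- morgan_fp("C1CCCCC1")
  expect_gt(length(a1$bits), 0)
  expect_gt(length(b$bits), 0)
  expect_false(identical(a1$bits, b$bits))
  expect_error(morgan_fp("not_a_smiles"), "invalid")
})

test_that("Tanimoto similarity: identity, symmetry, disjointness, degenerate input", {
  fa <- morgan_fp("CCO")
  fb <- morgan_fp("c1ccc(Cl)cc1")
  expect_equal(tanimoto(fa, fa), 1.0)
  expect_equal(tanimoto(fa, fb), tanimoto(fb, fa))
  disjoint_a <- structure(list(bits = c(1L, 5L), nbits = 2048L, radius = 2L),
                          class = "morgan_fp")
  disjoint_b <- structure(list(bits = c(2L, 9L), nbits = 2048L, radius = 2L),
                          class = "morgan_fp")
  expect_equal(tanimoto(disjoint_a, disjoint_b), 0)
  zero <- structure(list(bits = integer(0), nbits = 2048L, radius = 2L),
                    class = "morgan_fp")
  expect_error(tanimoto(zero, zero), "all-zero")
})

test_that("nearest neighbour equals exhaustive search over a toy set", {
  set <- c(m1 = "CCO", m2 = "CCN", m3 = "c1ccccc1", m4 = "CCCO",
           m5 = "CC(=O)O")
  query <- "CCCCO"
  res <- nearest_neighbor_sim(query, set)
  qfp <- morgan_fp(query)
  brute <- vapply(set, function(s) tanimoto(qfp, morgan_fp(s)), numeric(1))
  expect_equal(res$similarity, max(brute))
  expect_equal(res$reference_id, names(which.max(brute)))
  # query inside the set finds itself with similarity 1
  self <- nearest_neighbor_sim("CCO", set)
  expect_equal(self$similarity, 1.0)
  expect_equal(self$reference_id, "m1")
  # singleton reference set
  single <- nearest_neighbor_sim("CCO", c(only = "CCN"))
  expect_equal(single$similarity, tanimoto(morgan_fp("CCO"), morgan_fp("CCN")))
  expect_error(nearest_neighbor_sim("CCO", character(0)), "empty")
})

test_that(".smi and CSV corpora round-trip through the readers", {
  corpus <- c(a = "CCO", b = "c1ccccc1")
  smi <- tempfile(fileext = ".smi")
  write_smi(corpus, smi)
  back <- read_smi(smi)
  expect_equal(back$smiles, unname(corpus))
  expect_equal(back$id, names(corpus))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(SMILES = c("CCO", "CCN"), name = c("x", "y")),
            csv, row.names = FALSE)
  df <- read_smiles_csv(csv, smiles_col = "SMILES", id_col = "name")
  expect_equal(df$smiles, c("CCO", "CCN"))
  expect_equal(df$id, c("x", "y"))
  expect_error(read_smiles_csv(csv, smiles_col = "smi"), "not found")
})
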