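test_that("frequency ranking merges canonical forms and orders by count", {
  tab <- frequency_rank(c("CCO", "CCO", "CCO", "OCC", "OCC", "CCN"))
  expect_equal(tab$smiles, c("CCO", "CCN"))
  expect_equal(tab$frequency, c(5L, 1L))
  expect_equal(tab$freq_rank, c(1L, 2L))
  expect_equal(attr(tab, "n_invalid"), 0L)
  # a single unique sample
  one <- frequency_rank("CCO")
  expect_equal(one$frequency, 1L)
  expect_equal(one$freq_rank, 1L)
  # invalid draws are dropped and counted; an all-invalid multiset errors
  mixed <- suppressMessages(frequency_rank(c("CCO", "xx", "yy")))
  expect_equal(attr(mixed, "n_invalid"), 2L)
  expect_error(suppressMessages(frequency_rank("not_a_smiles")),
               "all sampled")
  expect_error(frequency_rank(character(0)), "empty")
})

test_that("frequency ranking conserves counts, breaks ties reproducibly, flags novelty", {
  set.seed(31)
  pool <- c("CCO", "CCN", "CCC", "c1ccccc1", "CCOC")
  draws <- sample(pool, 200, replace = TRUE)
  tab <- frequency_rank(draws, reference_corpora = list(c("CCO", "CCC")))
  expect_equal(sum(tab$frequency), length(draws))       # conservation
  expect_identical(tab, frequency_rank(draws,
                                       reference_corpora = list(c("CCO", "CCC"))))
  expect_equal(tab$novel[match(c("CCO", "CCC"), tab$smiles)], c(FALSE, FALSE))
  expect_true(all(tab$novel[!tab$smiles %in% c("CCO", "CCC")]))
  # equal frequencies -> lexicographic canonical SMILES order
  ties <- frequency_rank(c("CCO", "CCN"))
  expect_equal(ties$smiles, c("CCN", "CCO"))
})

test_that("similarity prioritization keeps the top-n most template-like designs", {
  templates <- c(t1 = "c1ccc(Cl)cc1", t2 = "CCOC(=O)C")
  designs <- c("c1ccc(Cl)cc1",           # identical to a template
               "c1ccc(Br)cc1", "CCOC(=O)CC", "CCCCCCCC", "CC(C)(C)C",
               "c1ccncc1", "CCO", "CCOC(C)=O", "ClCCl", "C1CC1")
  tab <- data.frame(smiles = standardize(designs, strict = FALSE)$canonical_smiles,
                    stringsAsFactors = FALSE)
  out3 <- similarity_prioritize(tab, templates, top_n = 3)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$nn_similarity[1], 1.0)
  expect_equal(out3$sim_rank, 1:3)
  # oracle: exhaustive nearest-neighbour similarities, sorted
  all_sims <- vapply(tab$smiles, function(s) {
    max(vapply(templates, function(t)
      tanimoto(morgan_fp(s), morgan_fp(t)), numeric(1)))
  }, numeric(1))
  expect_equal(out3$nn_similarity,
               unname(sort(all_sims, decreasing = TRUE)[1:3]))
  # top_n beyond the table keeps everything, ordered by similarity
  outAll <- similarity_prioritize(tab, templates, top_n = 100)
  expect_equal(nrow(outAll), nrow(tab))
  expect_equal(outAll$nn_similarity,
               unname(sort(all_sims, decreasing = TRUE)))
  expect_error(similarity_prioritize(tab, templates, top_n = 0), "positive")
  expect_error(similarity_prioritize(tab, character(0)), "empty")
})

test_that("docking aggregation is a sign-consistent geometric mean", {
  expect_equal(aggregate_dock(-14.0, -15.1), -sqrt(14.0 * 15.1))
  expect_equal(round(aggregate_dock(-14.0, -15.1), 2), -14.54)
  expect_equal(aggregate_dock(-7.5, -7.5), -7.5)        # idempotence
  expect_error(aggregate_dock(-14.0, 2.0), "mixed-sign")
  # the aggregate lies between the two magnitudes
  set.seed(8)
  a <- -runif(20, 1, 20); b <- -runif(20, 1, 20)
  g <- aggregate_dock(a, b)
  expect_true(all(g >= -pmax(abs(a), abs(b)) - 1e-12))
  expect_true(all(g <= -pmin(abs(a), abs(b)) + 1e-12))
})

test_that("the docking adapter degrades gracefully without an engine", {
  cfg <- docking_config(engine = "no_such_engine_on_path")
  expect_message(res <- dock_adapter(c("CCO", "CCN"), cfg), "unavailable")
  expect_true(all(is.na(res$dock_alpha)))
  expect_true(all(is.na(res$dock_aggregate)))
  expect_true(is.na(attr(res, "engine")))
  # frequency/similarity ranking is unaffected by missing docking columns
  tab <- frequency_rank(c("CCO", "CCO", "CCN"))
  tab2 <- tab
  tab2$dock_aggregate <- res$dock_aggregate[match(tab2$smiles, res$smiles)]
  expect_identical(tab2$freq_rank, tab$freq_rank)
  expect_error(redock_cocrystal("r.pdb", "l.sdf", cfg), "not found")
})

test_that("rank tables serialize as TSV", {
  tab <- frequency_rank(c("CCO", "CCO", "CCN"))
  f <- tempfile(fileext = ".tsv")
  write_rank_table(tab, f)
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$smiles, tab$smiles)
  expect_equal(back$frequency, tab$frequency)
})
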