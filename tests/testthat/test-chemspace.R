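make_fp_panel <- function(n, seed = 1) {
  fams <- default_families()
  recs <- rbind(enumerate_family(fams[[1]], ceiling(n / 2), seed = seed),
                enumerate_family(fams[[2]], floor(n / 2), seed = seed + 1))
  list(fps = morgan_fp(recs$canonical_smiles), labels = recs$family,
       smiles = recs$canonical_smiles)
}

test_that("truncated SVD returns the requested number of components", {
  set.seed(2)
  m <- matrix(rbinom(40 * 64, 1, 0.2), 40, 64)
  s <- truncated_svd(m, 10)
  expect_equal(dim(s), c(40, 10))
  # full-rank reconstruction sanity: scores carry the singular values
  sv <- svd(m)
  expect_equal(abs(s[, 1]), abs(sv$u[, 1] * sv$d[1]), tolerance = 1e-8)
})

test_that("t-SNE embedding has the right shape, is finite and seeded", {
  panel <- make_fp_panel(60)
  cfg <- embedding_config(svd_dims = 20, perplexity = 10, seed = 5)
  emb <- embed_tsne(panel$fps, panel$labels, cfg)
  expect_equal(dim(emb), c(60, 4))
  expect_true(all(is.finite(emb$x)))
  expect_true(all(is.finite(emb$y)))
  expect_equal(emb$group, panel$labels)
  # determinism under the seed
  emb2 <- embed_tsne(panel$fps, panel$labels, cfg)
  expect_identical(emb[, c("x", "y")], emb2[, c("x", "y")])
  # perplexity must be below the number of points
  expect_error(embed_tsne(panel$fps[1:8],
                          config = embedding_config(perplexity = 10)),
               "perplexity")
})

test_that("duplicated molecules land on near-identical coordinates", {
  panel <- make_fp_panel(50)
  fps <- c(panel$fps, panel$fps[1])     # duplicate the first molecule
  emb <- embed_tsne(fps, config = embedding_config(svd_dims = 20,
                                                   perplexity = 8, seed = 3))
  co <- as.matrix(emb[, c("x", "y")])
  d_dup <- sqrt(sum((co[1, ] - co[51, ])^2))
  alld <- as.vector(dist(co))
  expect_lt(d_dup, quantile(alld, 0.01))
})

test_that("virtual screening consensus matches a brute-force oracle", {
  fams <- default_families()
  lib <- enumerate_family(fams[[4]], 18, seed = 3)$canonical_smiles
  spikes <- enumerate_family(fams[[5]], 2, seed = 4)$canonical_smiles
  queries <- enumerate_family(fams[[4]], 2, seed = 9)$canonical_smiles
  res <- virtual_screen(lib, spikes, queries, retained_n = 10)
  # oracle: full similarity matrix, per-query ranks, imputed mean ranks
  all_smi <- c(lib, spikes)
  oracle_ranks <- sapply(seq_along(queries), function(qi) {
    sims <- vapply(all_smi, function(s)
      tanimoto(morgan_fp(queries[qi]), morgan_fp(s)), numeric(1))
    ord <- order(-sims, method = "radix")
    r <- rep(11, length(all_smi))
    r[ord[1:10]] <- 1:10
    r
  })
  expect_equal(res$per_query_ranks, t(oracle_ranks))
  oracle_mean <- rowMeans(oracle_ranks)
  ord <- order(oracle_mean, seq_along(oracle_mean))
  expect_equal(res$consensus$mean_rank, unname(oracle_mean[ord]))
  expect_equal(res$consensus$smiles, all_smi[ord])
})

test_that("a spike identical to a query tops every list and the consensus", {
  fams <- default_families()
  lib <- enumerate_family(fams[[4]], 15, seed = 3)$canonical_smiles
  query <- enumerate_family(fams[[5]], 1, seed = 5)$canonical_smiles
  res <- virtual_screen(lib, spikes = query, queries = query,
                        retained_n = 10)
  spike_col <- length(lib) + 1L
  expect_equal(res$per_query_ranks[1, spike_col], 1)
  expect_equal(res$spikes$consensus_rank[1], 1)
  expect_equal(res$consensus$id[1], "spike1")
})

test_that("consensus ranking is invariant to library input order", {
  fams <- default_families()
  lib <- enumerate_family(fams[[4]], 20, seed = 3)$canonical_smiles
  queries <- enumerate_family(fams[[4]], 2, seed = 9)$canonical_smiles
  # restrict to a tie-free sub-library so the insertion-order tie-break
  # cannot mask the invariance
  sims <- sapply(queries, function(q) {
    qf <- morgan_fp(q)
    vapply(lib, function(s) tanimoto(qf, morgan_fp(s)), numeric(1))
  })
  keep <- !duplicated(sims[, 1]) & !duplicated(sims[, 2])
  lib <- lib[keep][1:min(12, sum(keep))]
  r1 <- virtual_screen(lib, character(0), queries, retained_n = 12)
  perm <- rev(seq_along(lib))
  r2 <- virtual_screen(lib[perm], character(0), queries, retained_n = 12)
  m1 <- setNames(r1$consensus$mean_rank, r1$consensus$smiles)
  m2 <- setNames(r2$consensus$mean_rank, r2$consensus$smiles)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m1))])
  expect_error(virtual_screen(character(0), character(0), queries), "empty")
  expect_error(virtual_screen(lib, character(0), character(0)), "quer")
})
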