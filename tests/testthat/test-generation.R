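test_that("beam search equals exhaustive enumeration on a toy model", {
  model <- toy_cpt_model()
  for (k in c(2L, 5L, 1000L)) {
    cfg <- generation_config(beam_width = k, max_len = 6)
    bs <- beam_search(model, cfg)
    oracle <- enumerate_sequences(model, max_len = 6)
    keep <- seq_len(min(k, length(oracle$sequences)))
    expect_equal(attr(bs, "sequences"), oracle$sequences[keep],
                 info = paste("k =", k))
    expect_equal(bs$score, oracle$scores[keep], tolerance = 1e-12)
  }
})

test_that("beam width 1 reduces to greedy argmax decoding", {
  model <- toy_cpt_model()
  bs <- beam_search(model, generation_config(beam_width = 1, max_len = 6))
  # greedy path: argmax at each step, independently recomputed
  prefix <- 1L
  greedy <- integer(0)
  repeat {
    p <- model$cond_fn(prefix)
    p[1] <- 0
    if (length(greedy) == 0L) p[3] <- 0
    nxt <- which.max(p) - 1L
    greedy <- c(greedy, nxt)
    if (nxt == 2L || length(greedy) >= 6) break
    prefix <- c(prefix, nxt)
  }
  expect_equal(attr(bs, "sequences")[[1]], greedy)
})

test_that("beam scores are non-increasing and complete", {
  model <- toy_cpt_model()
  bs <- beam_search(model, generation_config(beam_width = 8, max_len = 6))
  expect_true(all(diff(bs$score) <= 1e-12))
  expect_true(all(bs$score <= 0))
  seqs <- attr(bs, "sequences")
  ends <- vapply(seqs, function(s) s[length(s)] == 2L || length(s) == 6L,
                 logical(1))
  expect_true(all(ends))
})

test_that("the tempered softmax matches its closed form", {
  q <- softmax_temperature(c(0, log(2)), temperature = 0.2)
  expect_equal(q, c(1 / 33, 32 / 33), tolerance = 1e-12)
  # T = 1 recovers the plain softmax
  z <- c(0.3, -1.2, 2.0)
  expect_equal(softmax_temperature(z, 1), exp(z) / sum(exp(z)))
  # the argmax is preserved for every positive temperature
  for (T in c(0.01, 0.2, 1, 5, 50)) {
    expect_equal(which.max(softmax_temperature(z, T)), which.max(z))
  }
  expect_error(softmax_temperature(z, 0))
})

test_that("temperature sampling follows the tempered distribution", {
  # model that emits one token then END: first-token frequencies should
  # follow softmax(log p / T); at T = 1 that is p itself
  p <- c(0, 0, 0, 0.5, 0.2, 0.3)
  model <- table_lm(6L, function(prefix) {
    if (length(prefix) == 1L) p else c(0, 0, 1, 0, 0, 0)
  })
  vocab <- structure(list(tokens = c("<PAD>", "^", "$", "C", "N", "O"),
                          size = 6L), class = "clm_vocab")
  draws <- temperature_sample(model, generation_config(
    n_samples = 10000, temperature = 1, seed = 42), vocab = vocab)
  counts <- table(factor(draws, levels = c("C", "N", "O")))
  gof <- chisq.test(as.vector(counts), p = p[4:6])
  expect_gt(gof$p.value, 0.001)
  # near-zero temperature concentrates on the argmax
  cold <- temperature_sample(model, generation_config(
    n_samples = 2000, temperature = 1e-6, seed = 7), vocab = vocab)
  expect_gte(mean(cold == "C"), 0.999)
})

test_that("sampling is reproducible under a fixed seed", {
  ck <- shared_pretrained()[[length(shared_pretrained())]]
  cfg <- generation_config(n_samples = 50, temperature = 0.5, seed = 123)
  s1 <- temperature_sample(ck, cfg)
  s2 <- temperature_sample(ck, cfg)
  expect_identical(s1, s2)
  cfg$seed <- 124L
  expect_false(identical(s1, temperature_sample(ck, cfg)))
})

test_that("epoch selection scores checkpoints by design similarity", {
  # a model that memorized the reference molecule scores aggregate 1.0
  mol <- "CCOc1ccccc1"
  v <- fit_vocabulary(mol)
  spec <- model_spec(v$size, recurrent_units = c(24, 16), dropout = 0)
  ck <- pretrain(rep(mol, 32), spec,
                 train_config(learning_rate = 5e-3, epochs = 150, seed = 4,
                              dropout = 0, plateau_patience = 1000),
                 vocab = v, randomize_each_epoch = FALSE)
  memorized <- ck[[length(ck)]]
  sel <- select_epochs(list(memorized), c(mol),
                       generation_config(beam_width = 3), band = c(0.9, 1))
  expect_equal(sel$table$mean_nn_sim, 1.0)
  expect_equal(sel$selected, memorized$epoch)
  # an untrained checkpoint scores strictly below a trained one
  s <- shared_study()
  vocab <- shared_vocab()
  spec2 <- model_spec(vocab$size, recurrent_units = c(64, 48, 32))
  untrained <- checkpoint(spec2, init_weights(spec2, seed = 1), vocab,
                          epoch = 0L)
  trained <- shared_finetuned()$ft2
  trained <- trained[[length(trained)]]
  sel2 <- suppressWarnings(
    select_epochs(list(untrained, trained), unname(s$finetune2),
                  generation_config(beam_width = 10), band = c(0, 1)))
  tab <- sel2$table
  expect_gt(tab$mean_nn_sim[2], tab$mean_nn_sim[1])
})
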