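# helper to build arbitrary layer plans for parameter-count checks
raw_spec <- function(layers, vocab_size, units = integer(0)) {
  structure(list(layers = layers, vocab_size = as.integer(vocab_size),
                 recurrent_units = as.integer(units), dropout = 0),
            class = "clm_model_spec")
}

test_that("parameter counting matches the closed forms on toy plans", {
  # BatchNorm + LSTM(2) + BatchNorm + Dense(3) on a 3-wide input: 77
  toy <- raw_spec(list(list(type = "batchnorm"),
                       list(type = "lstm", units = 2L),
                       list(type = "batchnorm"),
                       list(type = "dense", units = 3L)), 3, 2)
  expect_identical(count_parameters(toy), 77L)
  # a bias-and-weight-only dense net on width-1 input: 2 parameters
  dense_only <- raw_spec(list(list(type = "dense", units = 1L)), 1)
  expect_identical(count_parameters(dense_only), 2L)
  # closed forms (4f per BatchNorm incl. moving stats, 4u(d+u+1) per LSTM,
  # (d+1)v for Dense) reproduce the instantiated count for random plans
  set.seed(5)
  for (i in 1:5) {
    units <- sample(2:9, sample(1:3, 1))
    v <- sample(3:12, 1)
    spec <- model_spec(v, recurrent_units = units)
    d <- v
    expected <- 4 * v                       # input BatchNorm
    for (u in units) {
      expected <- expected + 4 * u * (d + u + 1)
      d <- u
    }
    expected <- expected + 4 * d + (d + 1) * v
    expect_identical(count_parameters(spec), as.integer(expected))
  }
})

test_that("backpropagation gradients match finite differences", {
  spec <- raw_spec(list(list(type = "batchnorm"),
                        list(type = "lstm", units = 5L),
                        list(type = "lstm", units = 4L),
                        list(type = "batchnorm"),
                        list(type = "dense", units = 6L)), 6, c(5, 4))
  w <- init_weights(spec, seed = 3)
  X <- rbind(c(1L, 4L, 5L, 3L, 2L, 0L),
             c(1L, 5L, 5L, 2L, 0L, 0L))
  lay <- clmdesign:::.cpp_layers(spec)
  res <- clmdesign:::.cpp_clm_loss_grads(lay, w, X, 6L)
  expect_equal(res$ntok, 7)
  eps <- 1e-6
  set.seed(11)
  for (l in seq_along(w)) {
    for (nm in setdiff(names(w[[l]]), c("rmean", "rvar"))) {
      v <- w[[l]][[nm]]
      for (i in sample(length(v), min(3, length(v)))) {
        wp <- w; wp[[l]][[nm]][i] <- v[i] + eps
        wm <- w; wm[[l]][[nm]][i] <- v[i] - eps
        num <- (clmdesign:::.cpp_clm_loss_grads(lay, wp, X, 6L)$loss -
                  clmdesign:::.cpp_clm_loss_grads(lay, wm, X, 6L)$loss) /
          (2 * eps)
        expect_equal(res$grads[[l]][[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("next-token outputs are valid probability distributions", {
  v <- fit_vocabulary(c("CCO", "CCN", "c1ccccc1"))
  spec <- model_spec(v$size, recurrent_units = c(8, 6), dropout = 0)
  ck <- checkpoint(spec, init_weights(spec, seed = 2), v)
  st <- lm_step(ck, lm_init_state(ck, 3L), c(1L, 1L, 1L))
  probs <- exp(st$logp)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # stepping is deterministic
  st2 <- lm_step(ck, lm_init_state(ck, 3L), c(1L, 1L, 1L))
  expect_identical(st$logits, st2$logits)
})

test_that("a one-molecule corpus is memorized and decoded by greedy beam", {
  mol <- "CCOc1ccccc1"
  v <- fit_vocabulary(mol)
  spec <- model_spec(v$size, recurrent_units = c(24, 16), dropout = 0)
  ck <- pretrain(rep(mol, 32), spec,
                 train_config(learning_rate = 5e-3, epochs = 150, seed = 4,
                              dropout = 0, plateau_patience = 1000),
                 vocab = v, randomize_each_epoch = FALSE)
  losses <- vapply(ck, function(c) c$training_loss, numeric(1))
  expect_lt(losses[length(losses)], 0.05)       # loss approaches zero
  bs <- beam_search(ck[[length(ck)]], generation_config(beam_width = 1))
  expect_equal(bs$smiles[1], mol)
})

test_that("training loss decreases over epochs on a synthetic corpus", {
  ck <- shared_pretrained()
  losses <- vapply(ck, function(c) c$training_loss, numeric(1))
  expect_lt(losses[5], losses[1])
  expect_lt(losses[length(losses)], losses[1])
})

test_that("temperature samples from the pretrained model are mostly valid SMILES", {
  ck <- shared_pretrained()
  smp <- temperature_sample(ck[[length(ck)]],
                            generation_config(n_samples = 200,
                                              temperature = 0.2, seed = 11))
  std <- suppressMessages(standardize(smp, strict = FALSE))
  expect_gte(mean(std$is_valid), 0.8)
})

test_that("frozen LSTM layers keep bit-identical weights across fine-tuning", {
  s <- shared_study()
  ft <- shared_finetuned()
  pre <- ft$pre
  base <- pre[[length(pre)]]$weights
  w1 <- ft$ft1[[length(ft$ft1)]]$weights
  # stage 1: first LSTM (layer 2 of the plan) frozen, second trained
  expect_identical(w1[[2]], base[[2]])
  expect_false(identical(w1[[3]], base[[3]]))
  # stage 2: first and second LSTM frozen
  w2 <- ft$ft2[[length(ft$ft2)]]$weights
  expect_identical(w2[[2]], w1[[2]])
  expect_identical(w2[[3]], w1[[3]])
  expect_false(identical(w2[[4]], w1[[4]]))
  expect_error(
    fine_tune(pre[[length(pre)]], unname(s$finetune2),
              train_config(epochs = 1, frozen_recurrent = 7L)),
    "out of range")
})

test_that("the plateau schedule matches a hand simulation", {
  # constant losses: first epoch 'improves' over Inf, then three stagnant
  # epochs trigger the first halving -> the rate drops from epoch 5 on
  lr <- plateau_schedule(rep(2, 8), lr0 = 1e-4, factor = 0.5, patience = 3,
                         min_lr = 5e-5)
  expect_equal(lr, c(1e-4, 1e-4, 1e-4, 1e-4, 5e-5, 5e-5, 5e-5, 5e-5))
  # strictly improving losses never reduce the rate
  expect_equal(plateau_schedule(seq(2, 1, length.out = 6), 1e-4),
               rep(1e-4, 6))
  # the floor is respected
  lr2 <- plateau_schedule(rep(1, 20), lr0 = 1e-4, factor = 0.5,
                          patience = 1, min_lr = 5e-5)
  expect_true(all(lr2 >= 5e-5))
  expect_equal(lr2[length(lr2)], 5e-5)
  # mixed trace, simulated by hand: improvement resets the wait counter
  losses <- c(3, 2.5, 2.6, 2.6, 2.4, 2.4, 2.4, 2.4)
  expect_equal(plateau_schedule(losses, 1e-3, 0.5, 2, 1e-5),
               c(1e-3, 1e-3, 1e-3, 1e-3, 5e-4, 5e-4, 5e-4, 2.5e-4))
})

test_that("augmentation emits distinct variants that canonicalize home", {
  expect_identical(augment("C", fold = 10, seed = 1)[[1]], "C")
  tol <- augment("Cc1ccccc1", fold = 10, seed = 3)[[1]]
  expect_gte(length(tol), 1)
  expect_lte(length(tol), 10)
  expect_false(any(duplicated(tol)))
  std <- standardize(tol, strict = FALSE)
  expect_true(all(std$canonical_smiles == "Cc1ccccc1"))
  # deterministic under the seed
  expect_identical(augment("Cc1ccccc1", fold = 10, seed = 3)[[1]], tol)
  expect_error(augment("not_a_smiles"), "invalid")
})

test_that("checkpoints persist and reload with identical behaviour", {
  v <- fit_vocabulary(c("CCO", "CCN"))
  spec <- model_spec(v$size, recurrent_units = c(6, 4))
  ck <- checkpoint(spec, init_weights(spec, seed = 9), v, epoch = 3L,
                   training_loss = 1.23, stage = "test")
  dir <- tempfile()
  save_checkpoint(ck, dir)
  expect_true(file.exists(file.path(dir, "epoch_003.rds")))
  expect_true(file.exists(file.path(dir, "epoch_003.json")))
  back <- load_checkpoint(file.path(dir, "epoch_003.rds"))
  s1 <- lm_step(ck, lm_init_state(ck, 1L), 1L)
  s2 <- lm_step(back, lm_init_state(back, 1L), 1L)
  expect_identical(s1$logits, s2$logits)
})
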