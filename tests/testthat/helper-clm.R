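# Shared fixtures: built once per test run and reused across test files.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Design SMILES reconstructed from the synthesis section of the study this
# pipeline re-implements, plus the named reference LXR ligands with
# literature structures (a partial, synthetic reconstruction of the
# fine-tuning tables, which are not redistributed here).
design_smiles <- function() {
  c(design1 = "CCN(C(=O)c1ccccc1)c1ccc(C(O)(C(F)(F)F)C(F)(F)F)cc1",
    design2 = "CS(=O)(=O)c1cccc(N2CCN(c3ccc(Cl)c(C(F)(F)F)c3)CC2)c1",
    design3 = paste0("CS(=O)(=O)c1cccc(-c2ccc(CN(Cc3cccc(C(F)(F)F)c3Cl)",
                     "CC(c3ccccc3)c3ccccc3)cc2)c1"))
}

reference_panel <- function() {
  c(T0901317 = "OC(c1ccc(N(CC(F)(F)F)S(=O)(=O)c2ccccc2)cc1)(C(F)(F)F)C(F)(F)F",
    GW3965 = paste0("OC(=O)Cc1cccc(OCCCN(Cc2cccc(C(F)(F)F)c2Cl)",
                    "CC(c2ccccc2)c2ccccc2)c1"))
}

# desk-scale synthetic study used by the training fixtures
shared_study <- function() .memo("study", function() {
  make_study(600, 60, 8, seed = 7)
})

shared_vocab <- function() .memo("vocab", function() {
  s <- shared_study()
  fit_vocabulary(c(s$pretrain, s$finetune1, s$finetune2),
                 extra_tokens = c("-", "4", "5"))
})

# base model pretrained on the canonical synthetic corpus: a stand-in for
# the large-corpus base CLM, used for validity/decoding properties
shared_pretrained <- function() .memo("pretrained", function() {
  s <- shared_study()
  vocab <- shared_vocab()
  spec <- model_spec(vocab$size, recurrent_units = c(64, 48, 32),
                     dropout = 0.2)
  pretrain(unname(s$pretrain), spec,
           train_config(learning_rate = 1e-3, epochs = 25, seed = 1,
                        dropout = 0.2),
           vocab = vocab, randomize_each_epoch = FALSE)
})

# transfer-learning chain: augmented pretraining (order-robust syntax)
# followed by the two fine-tuning stages with layer freezing
shared_finetuned <- function() .memo("finetuned", function() {
  s <- shared_study()
  vocab <- shared_vocab()
  train <- augment_corpus(unname(s$pretrain), fold = 4, seed = 99,
                          vocab = vocab)
  spec <- model_spec(vocab$size, recurrent_units = c(64, 48, 32),
                     dropout = 0.2)
  pre <- pretrain(train, spec,
                  train_config(learning_rate = 1e-3, epochs = 20, seed = 1,
                               dropout = 0.2),
                  vocab = vocab, randomize_each_epoch = FALSE)
  ft1 <- fine_tune(pre[[length(pre)]], unname(s$finetune1),
                   train_config(epochs = 12, frozen_recurrent = 1L,
                                seed = 2, dropout = 0.2))
  ft2 <- fine_tune(ft1[[length(ft1)]], unname(s$finetune2),
                   train_config(epochs = 12, frozen_recurrent = c(1L, 2L),
                                seed = 3, dropout = 0.2))
  list(pre = pre, ft1 = ft1, ft2 = ft2)
})

# mean nearest-neighbour Tanimoto of the valid members of `smiles` to a
# reference fingerprint list (independent of select_epochs internals)
mean_nn_similarity <- function(smiles, reference) {
  std <- suppressMessages(standardize(smiles, strict = FALSE))
  valid <- std$canonical_smiles[std$is_valid]
  if (length(valid) == 0) return(0)
  fps <- morgan_fp(valid)
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  rfp <- morgan_fp(unname(reference))
  if (inherits(rfp, "morgan_fp")) rfp <- list(rfp)
  sims <- vapply(fps, function(f) {
    max(vapply(rfp, function(r) tanimoto(f, r), numeric(1)))
  }, numeric(1))
  mean(sims)
}

# Exhaustive enumeration oracle for beam search on a table_lm: enumerates
# every complete sequence (END-terminated or truncated at max_len) with its
# cumulative log-probability, independently of the decoder implementation.
enumerate_sequences <- function(model, max_len) {
  V <- model$vocab_size
  out <- list()
  recurse <- function(prefix, logp, depth) {
    p <- model$cond_fn(c(1L, prefix))
    for (v in seq_len(V) - 1L) {
      if (v == 0L || p[v + 1] <= 0) next            # PAD excluded
      if (v == 2L && depth == 0L) next              # no empty molecule
      lp <- logp + log(p[v + 1])
      if (v == 2L) {
        out[[length(out) + 1L]] <<- list(seq = c(prefix, v), logp = lp)
      } else if (depth + 1L < max_len) {
        recurse(c(prefix, v), lp, depth + 1L)
      } else {
        out[[length(out) + 1L]] <<- list(seq = c(prefix, v), logp = lp)
      }
    }
  }
  recurse(integer(0), 0, 0L)
  scores <- vapply(out, `[[`, numeric(1), "logp")
  keys <- vapply(out, function(x)
    paste(sprintf("%04d", x$seq), collapse = ""), character(1))
  ord <- order(-scores, keys, method = "radix")
  list(sequences = lapply(out[ord], `[[`, "seq"), scores = scores[ord])
}

# small deterministic conditional-probability model over
# vocab = PAD START END a b (ids 0..4)
toy_cpt_model <- function() {
  table_lm(5L, function(prefix) {
    last <- prefix[length(prefix)]
    n <- length(prefix) - 1L   # generated tokens so far
    if (n == 0L) {
      c(0, 0, 0, 0.7, 0.3)                     # first: a or b
    } else if (last == 3L) {
      c(0, 0, 0.5, 0.2, 0.3)                   # after a
    } else {
      c(0, 0, 0.25, 0.45, 0.3)                 # after b
    }
  })
}
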