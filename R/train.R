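#' Training configuration
#'
#' Defaults mirror the fine-tuning recipe of the study: Adam with learning
#' rate 1e-4 (pretraining uses 1e-3), batch size 8, 20 epochs, learning-rate
#' reduction on plateau (factor 0.5, patience 3, floor 5e-5), dropout 0.4 on
#' every LSTM layer, and 10-fold randomized-SMILES augmentation.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size sequences per gradient step.
#' @param epochs number of training epochs (one checkpoint each).
#' @param plateau_factor multiplicative learning-rate reduction.
#' @param plateau_patience epochs without improvement before reducing.
#' @param min_lr learning-rate floor.
#' @param frozen_recurrent indices (1-based, network order) of LSTM layers
#'   whose weights are frozen.
#' @param augment_fold randomized-SMILES variants per molecule (fine-tuning).
#' @param dropout dropout fraction on LSTM inputs.
#' @param max_len maximum SMILES length (characters) for encoding.
#' @param seed master seed for shuffling, dropout and augmentation.
#' @return list of class `clm_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8, epochs = 20,
                         plateau_factor = 0.5, plateau_patience = 3,
                         min_lr = 5e-5, frozen_recurrent = integer(0),
                         augment_fold = 10, dropout = 0.4, max_len = 140,
                         seed = 1) {
  stopifnot(learning_rate > 0, min_lr <= learning_rate, batch_size >= 1,
            epochs >= 1, plateau_factor > 0, plateau_factor <= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, frozen_recurrent = as.integer(frozen_recurrent),
                 augment_fold = as.integer(augment_fold), dropout = dropout,
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "clm_train_config")
}

#' Learning-rate plateau schedule
#'
#' Pure reimplementation of reduce-on-plateau monitoring of the training
#' loss: an epoch "improves" when its loss is strictly below the best seen;
#' after `patience` consecutive non-improving epochs the rate is multiplied
#' by `factor`, never below `min_lr`.
#'
#' @param losses numeric vector of per-epoch training losses.
#' @param lr0 initial learning rate.
#' @param factor,patience,min_lr schedule parameters.
#' @return numeric vector: the learning rate in force *during* each epoch.
#' @export
plateau_schedule <- function(losses, lr0, factor = 0.5, patience = 3,
                             min_lr = 5e-5) {
  lr <- lr0
  best <- Inf
  wait <- 0L
  out <- numeric(length(losses))
  for (e in seq_along(losses)) {
    out[e] <- lr
    if (losses[e] < best) {
      best <- losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, min_lr)
        wait <- 0L
      }
    }
  }
  out
}

# are all tokens of each string covered by the vocabulary?
.covered <- function(strings, vocab) {
  vapply(strings, function(s) {
    all(smiles_tokenize(s) %in% vocab$tokens)
  }, logical(1), USE.NAMES = FALSE)
}

# encode a set of training strings, re-randomizing atom order each epoch
# when requested; variants outside the vocabulary fall back to their
# canonical input form
.epoch_matrix <- function(corpus, vocab, config, epoch, randomize) {
  strs <- corpus
  if (randomize) {
    strs <- vapply(augment(corpus, fold = 1,
                           seed = config$seed * 1000L + epoch),
                   `[[`, character(1), 1)
    bad <- !.covered(strs, vocab)
    strs[bad] <- corpus[bad]
  }
  maxlen <- max(config$max_len, max(nchar(strs)))
  X <- .encode_corpus(strs, vocab, maxlen)
  X[, seq_len(max(which(colSums(X != 0) > 0))), drop = FALSE]
}

# shared epoch loop for pretraining and fine-tuning
.train_loop <- function(weights, spec, vocab, train_set, config,
                        frozen_layers, stage, randomize_each_epoch = FALSE,
                        checkpoint_dir = NULL, verbose = FALSE) {
  adam <- list()
  lr <- config$learning_rate
  best <- Inf
  wait <- 0L
  ckpts <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    X <- .epoch_matrix(train_set, vocab, config, epoch, randomize_each_epoch)
    perm <- with_seed(config$seed * 1000L + epoch, sample.int(nrow(X)))
    res <- .cpp_clm_epoch(.cpp_layers(spec), weights, adam,
                          X[perm, , drop = FALSE], vocab$size, lr,
                          config$batch_size, config$dropout,
                          as.integer(frozen_layers),
                          config$seed * 1000L + epoch, TRUE)
    weights <- res$weights
    adam <- res$adam
    loss <- res$loss
    ck <- checkpoint(spec, weights, vocab, epoch = epoch,
                     training_loss = loss, stage = stage)
    ck$learning_rate <- lr
    ckpts[[epoch]] <- ck
    if (!is.null(checkpoint_dir)) save_checkpoint(ck, checkpoint_dir)
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d loss %.4f lr %.2e",
                      stage, epoch, config$epochs, loss, lr))
    }
    # reduce-on-plateau on the training loss
    if (loss < best) {
      best <- loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- max(lr * config$plateau_factor, config$min_lr)
        wait <- 0L
      }
    }
  }
  ckpts
}

.check_coverage <- function(corpus, vocab) {
  bad <- vapply(corpus, function(s) {
    tryCatch({
      .token_ids(smiles_tokenize(s), vocab)
      FALSE
    }, error = function(e) TRUE)
  }, logical(1))
  if (any(bad)) {
    stop("corpus molecules contain tokens outside the vocabulary: ",
         paste(utils::head(corpus[bad], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Pretrain the language model on a corpus
#'
#' Teacher-forced next-token training with masked categorical cross-entropy
#' and Adam; one checkpoint is kept per epoch.
#'
#' @param corpus character vector of canonical SMILES.
#' @param spec a `clm_model_spec`.
#' @param config a `clm_train_config` (pretraining default learning rate is
#'   1e-3).
#' @param vocab optional `clm_vocab`; fitted on the corpus when `NULL`.
#' @param randomize_each_epoch present each molecule as a freshly
#'   randomized-atom-order SMILES every epoch (online augmentation), so the
#'   base model learns order-robust syntax, as large-corpus base models do.
#'   Variants with tokens outside the vocabulary fall back to the canonical
#'   form.
#' @param checkpoint_dir optional directory to persist every epoch.
#' @param verbose print per-epoch losses.
#' @return list of `clm_checkpoint` objects, one per epoch.
#' @export
pretrain <- function(corpus, spec, config = train_config(learning_rate = 1e-3),
                     vocab = NULL, randomize_each_epoch = TRUE,
                     checkpoint_dir = NULL, verbose = FALSE) {
  if (is.null(vocab)) vocab <- fit_vocabulary(corpus)
  .check_coverage(corpus, vocab)
  if (spec$vocab_size != vocab$size) {
    stop("model output width (", spec$vocab_size,
         ") does not match vocabulary size (", vocab$size, ")")
  }
  weights <- init_weights(spec, seed = config$seed)
  .train_loop(weights, spec, vocab, corpus, config, integer(0), "pretrain",
              randomize_each_epoch = randomize_each_epoch,
              checkpoint_dir = checkpoint_dir, verbose = verbose)
}

#' Fine-tune from a checkpoint with optional layer freezing
#'
#' Continues training from a checkpoint on a task-specific corpus after
#' `augment_fold`-fold randomized-SMILES augmentation. Layers listed in
#' `config$frozen_recurrent` (1 = first LSTM in network order) keep their
#' weights bit-identical.
#'
#' @param ckpt a `clm_checkpoint` to start from.
#' @param corpus fine-tuning corpus (canonical SMILES).
#' @param config a `clm_train_config`.
#' @param checkpoint_dir optional directory to persist every epoch.
#' @param verbose print per-epoch losses.
#' @return list of `clm_checkpoint` objects, one per epoch.
#' @export
fine_tune <- function(ckpt, corpus, config = train_config(),
                      checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(ckpt, "clm_checkpoint"))
  vocab <- ckpt$vocab
  spec <- ckpt$spec
  bad <- !.covered(corpus, vocab)
  if (any(bad)) {
    stop("fine-tuning molecules outside the model vocabulary: ",
         paste(utils::head(corpus[bad], 5), collapse = ", "))
  }
  train_set <- corpus
  if (config$augment_fold > 1) {
    aug <- augment(corpus, fold = config$augment_fold, seed = config$seed)
    # a randomized variant may use tokens the vocabulary lacks (e.g. an
    # extra ring-closure digit); such variants revert to the canonical form
    train_set <- unlist(lapply(seq_along(aug), function(i) {
      v <- aug[[i]]
      v[!.covered(v, vocab)] <- corpus[i]
      v
    }), use.names = FALSE)
  }
  rec <- .recurrent_positions(spec)
  if (length(config$frozen_recurrent) &&
      any(!config$frozen_recurrent %in% seq_along(rec))) {
    stop("frozen_recurrent indices out of range")
  }
  frozen_layers <- rec[config$frozen_recurrent]
  .train_loop(ckpt$weights, spec, vocab, train_set, config, frozen_layers,
              paste0(ckpt$stage, "+ft"), randomize_each_epoch = FALSE,
              checkpoint_dir = checkpoint_dir, verbose = verbose)
}

#' Build an augmented training corpus
#'
#' Canonical SMILES plus `fold` randomized-atom-order variants per
#' molecule, deduplicated; variants with tokens outside `vocab` (when
#' given) are dropped. Used to give the base model order-robust syntax
#' before fine-tuning on augmented task corpora.
#'
#' @param corpus character vector of canonical SMILES.
#' @param fold randomized variants per molecule.
#' @param seed RNG seed.
#' @param vocab optional `clm_vocab` used to filter uncovered variants.
#' @return character vector of training strings.
#' @export
augment_corpus <- function(corpus, fold = 4, seed = 1, vocab = NULL) {
  corpus <- unname(corpus)
  if (fold < 1) return(corpus)
  aug <- unlist(augment(corpus, fold = fold, seed = seed), use.names = FALSE)
  out <- unique(c(corpus, aug))
  if (!is.null(vocab)) out <- out[.covered(out, vocab)]
  out
}

#' Randomized-SMILES augmentation
#'
#' Emits up to `fold` distinct randomized-atom-order SMILES per molecule;
#' every variant canonicalizes back to the input's canonical form.
#'
#' @param smiles character vector of valid SMILES.
#' @param fold maximum number of variants per molecule.
#' @param seed RNG seed (deterministic output).
#' @return list (per input molecule) of character vectors.
#' @export
augment <- function(smiles, fold = 10, seed = 1) {
  stopifnot(is.character(smiles), fold >= 1)
  out <- .rdkit_run("augment", smiles, args = c(fold, seed))
  if (any(out == "NA")) {
    stop("invalid molecule(s): ",
         paste(utils::head(smiles[out == "NA"], 5), collapse = ", "))
  }
  strsplit(out, "\t", fixed = TRUE)
}
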