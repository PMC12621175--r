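#' Generation configuration
#'
#' @param beam_width beam search width `k`.
#' @param temperature softmax temperature `T` for sampling.
#' @param n_samples number of strings drawn by temperature sampling.
#' @param max_len maximum generated SMILES length (tokens after START).
#' @param seed RNG seed for sampling.
#' @return list of class `clm_generation_config`.
#' @export
generation_config <- function(beam_width = 50, temperature = 0.2,
                              n_samples = 2000, max_len = 140, seed = 1) {
  stopifnot(beam_width >= 1, temperature > 0, max_len >= 1, n_samples >= 1)
  structure(list(beam_width = as.integer(beam_width),
                 temperature = temperature,
                 n_samples = as.integer(n_samples),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "clm_generation_config")
}

# ---- sequence-model step interface ------------------------------------
# A "language model" is anything implementing lm_init_state / lm_step /
# lm_reindex_state. Checkpoints use the compiled network; toy models with
# explicit conditional probability tables plug into the same decoders.

#' @export
lm_vocab_size <- function(model) UseMethod("lm_vocab_size")

#' Initialize decoder state for a batch of sequences
#' @param model a sequence model (e.g. `clm_checkpoint`).
#' @param n batch size.
#' @export
lm_init_state <- function(model, n) UseMethod("lm_init_state")

#' Advance the model one token and return next-token log-probabilities
#' @param model a sequence model.
#' @param state decoder state.
#' @param tokens integer vector (0-based ids) of the tokens just consumed.
#' @return list with `logp` (n x vocab matrix of log-probabilities),
#'   `logits` (unnormalized), and the new `state`.
#' @export
lm_step <- function(model, state, tokens) UseMethod("lm_step")

#' Subset/reorder decoder state rows
#' @param model a sequence model.
#' @param state decoder state.
#' @param idx row indices to keep (with repetition allowed).
#' @export
lm_reindex_state <- function(model, state, idx) UseMethod("lm_reindex_state")

#' @export
lm_vocab_size.clm_checkpoint <- function(model) model$vocab$size

#' @export
lm_init_state.clm_checkpoint <- function(model, n) {
  lapply(.recurrent_positions(model$spec), function(p) {
    u <- model$spec$layers[[p]]$units
    list(h = matrix(0, n, u), c = matrix(0, n, u))
  })
}

#' @export
lm_step.clm_checkpoint <- function(model, state, tokens) {
  res <- .cpp_clm_step(.cpp_layers(model$spec), model$weights, state,
                       as.integer(tokens), model$vocab$size)
  logits <- res$logits
  lse <- apply(logits, 1, function(z) {
    m <- max(z)
    m + log(sum(exp(z - m)))
  })
  list(logp = logits - lse, logits = logits, state = res$state)
}

#' @export
lm_reindex_state.clm_checkpoint <- function(model, state, idx) {
  lapply(state, function(s) list(h = s$h[idx, , drop = FALSE],
                                 c = s$c[idx, , drop = FALSE]))
}

#' Toy sequence model with an explicit conditional distribution
#'
#' For testing decoders against exhaustive enumeration: `cond_fn(prefix)`
#' receives the 0-based token-id prefix (starting with START = 1) and must
#' return a probability vector over the vocabulary.
#'
#' @param vocab_size vocabulary width.
#' @param cond_fn conditional distribution function.
#' @return object of class `table_lm`.
#' @export
table_lm <- function(vocab_size, cond_fn) {
  structure(list(vocab_size = as.integer(vocab_size), cond_fn = cond_fn),
            class = "table_lm")
}

#' @export
lm_vocab_size.table_lm <- function(model) model$vocab_size

#' @export
lm_init_state.table_lm <- function(model, n) {
  lapply(seq_len(n), function(i) integer(0))
}

#' @export
lm_step.table_lm <- function(model, state, tokens) {
  state <- lapply(seq_along(state), function(i) c(state[[i]], tokens[i]))
  p <- do.call(rbind, lapply(state, model$cond_fn))
  list(logp = log(p), logits = log(p), state = state)
}

#' @export
lm_reindex_state.table_lm <- function(model, state, idx) state[idx]

# lexicographic order key for token sequences (deterministic tie-break)
.seq_key <- function(seqs) {
  vapply(seqs, function(s) paste(sprintf("%04d", s), collapse = ""),
         character(1))
}

#' Beam-search decoding
#'
#' Keeps the `k` highest-scoring partial sequences per step, scored by
#' cumulative log-probability without length normalization. Decoding is
#' deterministic; ties are broken lexicographically by token indices.
#' PAD is never expanded and END is disallowed as the first token.
#'
#' @param model a sequence model (checkpoint or toy model).
#' @param config a `clm_generation_config` (`beam_width`, `max_len` used).
#' @param vocab optional `clm_vocab` used to decode SMILES strings.
#' @return data.frame with columns `smiles` (empty strings when no vocab is
#'   supplied), `score`, and `length`; token sequences (without START) in
#'   `attr(, "sequences")`. Ordered by descending score.
#' @export
beam_search <- function(model, config = generation_config(),
                        vocab = NULL) {
  k <- config$beam_width
  V <- lm_vocab_size(model)
  if (inherits(model, "clm_checkpoint") && is.null(vocab)) vocab <- model$vocab
  active_seq <- list(integer(0))          # tokens after START
  active_score <- 0
  state <- lm_init_state(model, 1L)
  last_tok <- 1L                           # START
  done_seq <- list()
  done_score <- numeric(0)

  for (t in seq_len(config$max_len)) {
    st <- lm_step(model, state, last_tok)
    logp <- st$logp
    logp[, 1] <- -Inf                      # PAD never generated
    if (t == 1L) logp[, 3] <- -Inf         # END: no empty molecules
    cand_score <- active_score + logp      # n_active x V
    n_active <- length(active_seq)
    cs <- as.vector(t(cand_score))         # row-major: (parent i, token v)
    parent <- rep(seq_len(n_active), each = V)
    tok <- rep.int(seq_len(V) - 1L, n_active)
    keep <- is.finite(cs)
    cs <- cs[keep]; parent <- parent[keep]; tok <- tok[keep]
    cand_seqs <- lapply(seq_along(cs), function(j)
      c(active_seq[[parent[j]]], tok[j]))
    # END children join the completed pool (best k kept there)
    fin <- tok == 2L
    done_seq <- c(done_seq, cand_seqs[fin])
    done_score <- c(done_score, cs[fin])
    dord <- utils::head(order(-done_score, .seq_key(done_seq),
                              method = "radix"), k)
    done_seq <- done_seq[dord]
    done_score <- done_score[dord]
    # the beam itself holds the top-k *partial* sequences
    open_idx <- which(!fin)
    if (length(open_idx) == 0) {
      active_seq <- list(); active_score <- numeric(0); break
    }
    aord <- utils::head(order(-cs[open_idx], .seq_key(cand_seqs[open_idx]),
                              method = "radix"), k)
    sel <- open_idx[aord]
    active_seq <- cand_seqs[sel]
    active_score <- cs[sel]
    state <- lm_reindex_state(model, st$state, parent[sel])
    last_tok <- tok[sel]
    # no surviving partial can outscore the k-th completed hypothesis
    if (length(done_score) == k && max(active_score) < min(done_score)) {
      active_seq <- list(); active_score <- numeric(0); break
    }
  }
  # hypotheses still active at max_len count as complete (truncation)
  done_seq <- c(done_seq, active_seq)
  done_score <- c(done_score, active_score)
  ord <- utils::head(order(-done_score, .seq_key(done_seq), method = "radix"), k)
  done_seq <- done_seq[ord]
  done_score <- done_score[ord]
  smiles <- if (!is.null(vocab)) {
    vapply(done_seq, decode_indices, character(1), vocab = vocab)
  } else {
    rep("", length(done_seq))
  }
  res <- data.frame(smiles = smiles, score = done_score,
                    length = vapply(done_seq, length, integer(1)),
                    stringsAsFactors = FALSE)
  attr(res, "sequences") <- done_seq
  res
}

#' Tempered softmax
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`; `T = 1` recovers the plain
#' softmax and `T -> 0` concentrates on the arg-max (which is preserved for
#' every `T > 0`).
#'
#' @param logits numeric vector (or matrix, row-wise) of model outputs.
#' @param temperature positive temperature `T`.
#' @return probabilities with the same shape as `logits`.
#' @export
softmax_temperature <- function(logits, temperature = 1) {
  stopifnot(temperature > 0)
  f <- function(z) {
    z <- z / temperature
    z <- z - max(z[is.finite(z)])
    e <- exp(z)
    e / sum(e)
  }
  if (is.matrix(logits)) t(apply(logits, 1, f)) else f(logits)
}

# vectorized categorical draw, one per row of a probability matrix
.draw_rows <- function(prob) {
  cum <- t(apply(prob, 1, cumsum))
  u <- runif(nrow(prob)) * cum[, ncol(cum)]
  max.col(cum >= u, ties.method = "first")
}

#' Temperature sampling of SMILES
#'
#' Draws `n_samples` strings token-by-token from the tempered softmax of
#' the model logits. Strings are truncated at `max_len` tokens; invalid
#' SMILES are retained (filtering happens during prioritization).
#'
#' @param model a sequence model (typically a `clm_checkpoint`).
#' @param config a `clm_generation_config`.
#' @param vocab optional `clm_vocab` (taken from the checkpoint if absent).
#' @param batch number of chains advanced simultaneously.
#' @return character vector of `n_samples` SMILES strings (possibly
#'   invalid); the draw index is the element order.
#' @export
temperature_sample <- function(model, config = generation_config(),
                               vocab = NULL, batch = 256L) {
  if (inherits(model, "clm_checkpoint") && is.null(vocab)) vocab <- model$vocab
  if (is.null(vocab)) stop("a vocabulary is required to decode samples")
  n <- config$n_samples
  out <- character(0)
  with_seed(config$seed, {
    remaining <- n
    while (remaining > 0) {
      B <- min(batch, remaining)
      seqs <- matrix(0L, B, config$max_len)
      state <- lm_init_state(model, B)
      tok <- rep(1L, B)  # START
      alive <- rep(TRUE, B)
      for (t in seq_len(config$max_len)) {
        st <- lm_step(model, state, tok)
        state <- st$state
        prob <- softmax_temperature(st$logits, config$temperature)
        prob[, 1] <- 0                    # PAD
        if (t == 1L) prob[, 3] <- 0       # no empty molecule
        draw <- .draw_rows(prob) - 1L
        draw[!alive] <- 2L                # finished chains idle on END
        seqs[, t] <- draw
        alive <- alive & draw != 2L
        tok <- draw
        if (!any(alive)) break
      }
      out <- c(out, apply(seqs, 1, decode_indices, vocab = vocab))
      remaining <- remaining - B
    }
  })
  out
}

#' Select fine-tuning epochs by beam-search similarity to a reference set
#'
#' For every checkpoint, decodes `beam_width` representative molecules by
#' beam search, keeps the chemically valid ones, and scores the checkpoint
#' by the mean nearest-neighbor Tanimoto similarity of its designs to the
#' reference corpus. Checkpoints whose aggregate falls inside `band` are
#' selected for sampling.
#'
#' @param checkpoints list of `clm_checkpoint` objects (one per epoch).
#' @param reference reference corpus (e.g. fine-tuning set II).
#' @param config a `clm_generation_config` (beam width).
#' @param band inclusive acceptance band for the aggregate similarity.
#' @return list with `table` (epoch, n_valid, mean_nn_sim, selected) and
#'   `selected` (epoch indices).
#' @export
select_epochs <- function(checkpoints, reference,
                          config = generation_config(), band = c(0.3, 0.9)) {
  if (length(checkpoints) == 0) stop("no checkpoints supplied")
  if (length(reference) == 0) stop("reference corpus is empty")
  ref_fp <- morgan_fp(unname(reference))
  if (inherits(ref_fp, "morgan_fp")) ref_fp <- list(ref_fp)
  rows <- lapply(checkpoints, function(ck) {
    bs <- beam_search(ck, config)
    smi <- unique(bs$smiles[nzchar(bs$smiles)])
    agg <- 0
    n_valid <- 0L
    if (length(smi)) {
      std <- standardize(smi, strict = FALSE)
      valid <- std$canonical_smiles[std$is_valid]
      n_valid <- length(valid)
      if (n_valid > 0) {
        fps <- morgan_fp(valid)
        if (inherits(fps, "morgan_fp")) fps <- list(fps)
        sims <- .tanimoto_matrix(fps, ref_fp)
        agg <- mean(apply(sims, 1, max))
      }
    }
    if (n_valid == 0L) {
      warning("epoch ", ck$epoch, ": no valid beam designs; aggregate 0")
    }
    data.frame(epoch = ck$epoch, n_valid = n_valid, mean_nn_sim = agg)
  })
  tab <- do.call(rbind, rows)
  tab$selected <- tab$mean_nn_sim >= band[1] & tab$mean_nn_sim <= band[2]
  list(table = tab, selected = tab$epoch[tab$selected])
}
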