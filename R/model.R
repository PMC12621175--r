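#' Define the language-model architecture
#'
#' The default layer plan is the six-layer network used for the full-scale
#' task: input BatchNormalization, three stacked LSTM layers (1024, 512,
#' 256 units), BatchNormalization, and a Dense output of vocabulary width.
#' Inputs are one-hot encoded tokens, so the input feature width equals the
#' vocabulary size.
#'
#' @param vocab_size width of the one-hot input and of the Dense output.
#' @param recurrent_units integer vector of LSTM layer widths.
#' @param dropout dropout fraction applied to the inputs of every LSTM
#'   layer during training.
#' @return an object of class `clm_model_spec`.
#' @export
model_spec <- function(vocab_size, recurrent_units = c(1024, 512, 256),
                       dropout = 0.4) {
  stopifnot(vocab_size >= 1, length(recurrent_units) >= 1,
            all(recurrent_units >= 1), dropout >= 0, dropout < 1)
  layers <- c(
    list(list(type = "batchnorm")),
    lapply(as.integer(recurrent_units),
           function(u) list(type = "lstm", units = u)),
    list(list(type = "batchnorm")),
    list(list(type = "dense", units = as.integer(vocab_size)))
  )
  structure(list(layers = layers, vocab_size = as.integer(vocab_size),
                 recurrent_units = as.integer(recurrent_units),
                 dropout = dropout),
            class = "clm_model_spec")
}

#' @export
print.clm_model_spec <- function(x, ...) {
  cat("<clm_model_spec>", length(x$layers), "layers, vocab", x$vocab_size,
      "\n  LSTM units:", paste(x$recurrent_units, collapse = "/"),
      "\n  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

# positions (1-based) of the LSTM layers in the layer plan
.recurrent_positions <- function(spec) {
  which(vapply(spec$layers, function(l) l$type == "lstm", logical(1)))
}

# feature widths entering each layer
.layer_dims <- function(spec) {
  d <- spec$vocab_size
  dims <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    out <- switch(l$type, batchnorm = d, lstm = l$units, dense = l$units)
    dims[[i]] <- c(d_in = d, d_out = out)
    d <- out
  }
  dims
}

# Glorot-uniform matrix
.glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# random orthogonal matrix (QR of a Gaussian)
.orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q * sign(diag(q))[col(q)]
}

#' Initialize model weights
#'
#' LSTM input kernels are Glorot-uniform, recurrent kernels orthogonal,
#' biases zero except the forget gate (initialized to 1); BatchNorm starts
#' at the identity transform with zero-mean/unit-variance moving statistics.
#'
#' @param spec a `clm_model_spec`.
#' @param seed integer RNG seed.
#' @return list of per-layer weight lists (the order of `spec$layers`).
#' @export
init_weights <- function(spec, seed = 1) {
  dims <- .layer_dims(spec)
  with_seed(seed, {
    lapply(seq_along(spec$layers), function(i) {
      l <- spec$layers[[i]]
      d <- dims[[i]][["d_in"]]
      if (l$type == "batchnorm") {
        list(gamma = rep(1, d), beta = rep(0, d),
             rmean = rep(0, d), rvar = rep(1, d))
      } else if (l$type == "lstm") {
        u <- l$units
        b <- rep(0, 4 * u)
        b[(u + 1):(2 * u)] <- 1  # forget-gate bias
        list(W = .glorot(4 * u, d),
             U = do.call(rbind, replicate(4, .orthogonal(u), simplify = FALSE)),
             b = b)
      } else {
        list(W = .glorot(l$units, d), b = rep(0, l$units))
      }
    })
  })
}

#' Count model parameters
#'
#' Instantiates the network and sums the sizes of every parameter tensor,
#' including the non-trainable BatchNorm moving statistics.
#'
#' @param spec a `clm_model_spec`.
#' @return integer total parameter count.
#' @export
count_parameters <- function(spec) {
  w <- init_weights(spec, seed = 1)
  sum(vapply(w, function(layer) sum(vapply(layer, length, integer(1))),
             integer(1)))
}

.cpp_layers <- function(spec) {
  lapply(spec$layers, function(l) {
    if (is.null(l$units)) list(type = l$type) else
      list(type = l$type, units = l$units)
  })
}

#' Construct a model checkpoint
#'
#' @param spec a `clm_model_spec`.
#' @param weights per-layer weight list.
#' @param vocab the training `clm_vocab`.
#' @param epoch training epoch the weights come from.
#' @param training_loss mean per-token cross-entropy at that epoch.
#' @param stage label of the training stage.
#' @return an object of class `clm_checkpoint`.
#' @export
checkpoint <- function(spec, weights, vocab, epoch = 0L,
                       training_loss = NA_real_, stage = "init") {
  structure(list(spec = spec, weights = weights, vocab = vocab,
                 epoch = as.integer(epoch), training_loss = training_loss,
                 stage = stage),
            class = "clm_checkpoint")
}

#' @export
print.clm_checkpoint <- function(x, ...) {
  cat(sprintf("<clm_checkpoint> stage %s epoch %d loss %.4f vocab %d\n",
              x$stage, x$epoch, x$training_loss, x$vocab$size))
  invisible(x)
}

#' Save / load a checkpoint (weights file plus JSON metadata)
#'
#' @param ckpt a `clm_checkpoint`.
#' @param dir checkpoint directory (one file pair per epoch).
#' @export
save_checkpoint <- function(ckpt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sprintf("epoch_%03d", ckpt$epoch))
  saveRDS(ckpt, paste0(base, ".rds"))
  meta <- list(epoch = ckpt$epoch, stage = ckpt$stage,
               training_loss = ckpt$training_loss,
               vocab_hash = unname(.hash_obj(ckpt$vocab$tokens)),
               n_parameters = count_parameters(ckpt$spec))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  invisible(base)
}

#' @rdname save_checkpoint
#' @param path path to an `epoch_xxx.rds` file.
#' @export
load_checkpoint <- function(path) readRDS(path)

.hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}
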