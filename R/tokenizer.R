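#' Tokenize a SMILES string
#'
#' Greedy character-level tokenization in which two-character halogens
#' (`Cl`, `Br`), bracket atoms (`[...]`) and two-digit ring closures
#' (`%nn`) are kept atomic. The scheme is prefix-free under greedy longest
#' match, so `detokenize(smiles_tokenize(s)) == s`.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr("\\[[^\\]]*\\]|Cl|Br|%[0-9]{2}|.", smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stop("tokenization failed to cover: ", smiles)
  }
  toks
}

#' @rdname smiles_tokenize
#' @param tokens character vector of tokens.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = "")

.SPECIALS <- c(PAD = "<PAD>", START = "^", END = "$")

#' Fit a token vocabulary on a corpus
#'
#' The vocabulary is the sorted set of distinct tokens in the corpus plus
#' the special symbols, with `PAD` fixed at index 0 followed by `START` and
#' `END`. Refitting on the same corpus is deterministic.
#'
#' @param corpus character vector of SMILES.
#' @param specials character vector of special tokens (PAD, START, END).
#' @param extra_tokens additional tokens to reserve (e.g. ring-closure
#'   digits that only appear in randomized-SMILES augmentation variants).
#' @return an object of class `clm_vocab` with elements `tokens` (ordered)
#'   and `size`.
#' @export
fit_vocabulary <- function(corpus, specials = .SPECIALS,
                           extra_tokens = character(0)) {
  if (length(corpus) == 0) stop("cannot fit a vocabulary on an empty corpus")
  toks <- sort(unique(c(unlist(lapply(corpus, smiles_tokenize)),
                        extra_tokens)))
  if (any(toks %in% specials)) stop("corpus tokens collide with specials")
  tokens <- c(unname(specials), toks)
  structure(list(tokens = tokens, size = length(tokens)), class = "clm_vocab")
}

#' @export
print.clm_vocab <- function(x, ...) {
  cat("<clm_vocab> size", x$size, "\n")
  invisible(x)
}

# 0-based token ids; PAD = 0, START = 1, END = 2.
.token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab$tokens)
  if (anyNA(ids)) {
    stop("token(s) not in vocabulary: ",
         paste(unique(tokens[is.na(ids)]), collapse = ", "))
  }
  ids - 1L
}

#' Encode a SMILES string as a token-index sequence
#'
#' @param smiles a single SMILES string.
#' @param vocab a `clm_vocab`.
#' @param pad_to optionally right-pad with PAD (index 0) to this length.
#' @return integer vector of 0-based indices beginning with START and ending
#'   with END.
#' @export
encode_smiles <- function(smiles, vocab, pad_to = NULL) {
  ids <- c(1L, .token_ids(smiles_tokenize(smiles), vocab), 2L)
  if (!is.null(pad_to)) {
    if (length(ids) > pad_to) stop("sequence longer than pad_to")
    ids <- c(ids, rep(0L, pad_to - length(ids)))
  }
  ids
}

#' Decode a token-index sequence back to SMILES
#'
#' PAD and START are dropped; decoding stops at the first END.
#'
#' @param ids integer vector of 0-based indices.
#' @param vocab a `clm_vocab`.
#' @return SMILES string.
#' @export
decode_indices <- function(ids, vocab) {
  end <- which(ids == 2L)
  if (length(end)) ids <- ids[seq_len(end[1] - 1L)]
  ids <- ids[ids > 2L]
  detokenize(vocab$tokens[ids + 1L])
}

# Encode a corpus into a right-padded integer matrix (n x max_len + 2).
.encode_corpus <- function(corpus, vocab, max_len = 140) {
  width <- max_len + 2L
  rows <- lapply(corpus, encode_smiles, vocab = vocab, pad_to = width)
  do.call(rbind, rows)
}

#' Serialize / restore a vocabulary as JSON
#' @param vocab a `clm_vocab`.
#' @param path JSON file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(list(tokens = tokens, size = length(tokens)), class = "clm_vocab")
}
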