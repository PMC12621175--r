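#' Embedding configuration
#'
#' @param svd_dims number of truncated-SVD components kept before t-SNE.
#' @param perplexity t-SNE perplexity (must be below the point count).
#' @param metric `"jaccard_svd"` computes Jaccard distances on the
#'   SVD-reduced vectors binarized at 0; `"jaccard_raw"` uses the raw
#'   2048-bit fingerprints.
#' @param seed RNG seed for the embedding initialization.
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(svd_dims = 50, perplexity = 30,
                             metric = c("jaccard_svd", "jaccard_raw"),
                             seed = 1) {
  structure(list(svd_dims = as.integer(svd_dims), perplexity = perplexity,
                 metric = match.arg(metric), seed = as.integer(seed)),
            class = "embedding_config")
}

#' Truncated SVD scores of a matrix
#'
#' Uncentred singular value decomposition; returns the first `d` left
#' singular vectors scaled by their singular values.
#'
#' @param m numeric matrix (rows = molecules).
#' @param d number of components.
#' @return matrix with `min(d, rank)` columns.
#' @export
truncated_svd <- function(m, d = 50) {
  d <- min(d, nrow(m) - 1L, ncol(m))
  s <- svd(m, nu = d, nv = 0)
  s$u %*% diag(s$d[seq_len(d)], d, d)
}

# pairwise Jaccard distance between rows of a binary matrix
.jaccard_dist <- function(B) {
  inter <- tcrossprod(B)
  p <- rowSums(B)
  un <- outer(p, p, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  diag(d) <- 0
  d
}

#' t-SNE chemical-space embedding of fingerprints
#'
#' Fingerprints are reduced with truncated SVD, pairwise Jaccard distances
#' are computed (after sign-binarization of the reduced vectors, or on the
#' raw bits), and an exact t-SNE projects the set to two dimensions.
#' Deterministic under the configured seed.
#'
#' @param fingerprints list of `morgan_fp` objects (or a binary matrix).
#' @param labels optional grouping labels carried into the output.
#' @param config an `embedding_config`.
#' @return data.frame with columns `id`, `x`, `y`, `group`.
#' @export
embed_tsne <- function(fingerprints, labels = NULL,
                       config = embedding_config()) {
  M <- if (is.matrix(fingerprints)) fingerprints else .fp_matrix(fingerprints)
  n <- nrow(M)
  if (n <= config$perplexity) {
    stop("need more points (", n, ") than the perplexity (",
         config$perplexity, ")")
  }
  B <- if (config$metric == "jaccard_svd") {
    truncated_svd(M, config$svd_dims) > 0
  } else {
    M > 0
  }
  D <- .jaccard_dist(B * 1)
  Y <- .tsne_from_dist(D, perplexity = config$perplexity, seed = config$seed)
  data.frame(id = seq_len(n), x = Y[, 1], y = Y[, 2],
             group = if (is.null(labels)) NA_character_ else as.character(labels),
             stringsAsFactors = FALSE)
}

#' Spiked virtual-screening simulation
#'
#' Appends the spike molecules to the library, scores every library member
#' against each query by Tanimoto similarity, keeps the `retained_n` most
#' similar per query, and forms a consensus by averaging ranks across
#' queries (members absent from a query's top list are imputed rank
#' `retained_n + 1`). Ties in similarity are broken by library insertion
#' order.
#'
#' @param library_corpus character vector of library SMILES.
#' @param spikes character vector of spiked-in designs.
#' @param queries character vector of query molecules (e.g. a fine-tuning
#'   set).
#' @param retained_n per-query list length.
#' @return list of class `screen_result`: `consensus` (data.frame `id`,
#'   `smiles`, `mean_rank`, `consensus_rank`), `per_query_ranks` (matrix of
#'   imputed ranks, queries x library), `top_lists`, and `spikes`
#'   (consensus rows of the spiked designs).
#' @export
virtual_screen <- function(library_corpus, spikes, queries,
                           retained_n = 1000) {
  if (length(library_corpus) == 0) stop("empty screening library")
  if (length(queries) == 0) stop("no query molecules")
  lib <- c(unname(library_corpus), unname(spikes))
  ids <- c(paste0("lib", seq_along(library_corpus)),
           paste0("spike", seq_along(spikes)))
  lfp <- morgan_fp(lib)
  if (inherits(lfp, "morgan_fp")) lfp <- list(lfp)
  qfp <- morgan_fp(unname(queries))
  if (inherits(qfp, "morgan_fp")) qfp <- list(qfp)
  S <- .tanimoto_matrix(qfp, lfp)     # queries x library
  nq <- nrow(S)
  nlib <- ncol(S)
  ranks <- matrix(retained_n + 1, nq, nlib)
  top_lists <- vector("list", nq)
  for (q in seq_len(nq)) {
    ord <- order(-S[q, ], method = "radix")   # stable: insertion order ties
    top <- utils::head(ord, retained_n)
    ranks[q, top] <- seq_along(top)
    top_lists[[q]] <- ids[top]
  }
  mean_rank <- colMeans(ranks)
  ord <- order(mean_rank, seq_len(nlib), method = "radix")
  consensus <- data.frame(id = ids[ord], smiles = lib[ord],
                          mean_rank = mean_rank[ord],
                          consensus_rank = seq_len(nlib),
                          stringsAsFactors = FALSE)
  spike_rows <- consensus[grepl("^spike", consensus$id), , drop = FALSE]
  structure(list(consensus = consensus, per_query_ranks = ranks,
                 top_lists = top_lists, retained_n = retained_n,
                 spikes = spike_rows),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", nrow(x$consensus), "library members,",
      length(x$top_lists), "queries, top", x$retained_n, "retained\n")
  if (nrow(x$spikes)) {
    cat("spike consensus ranks:",
        paste(x$spikes$id, x$spikes$consensus_rank, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}
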