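#' Standardize raw SMILES into canonical molecule records
#'
#' Applies the corpus cleanup used throughout the pipeline: isotopic labels
#' are cleared, stereo descriptors are stripped, only the fragment with the
#' most heavy atoms is kept (ties broken by the lexicographically smallest
#' canonical SMILES), and the result is emitted as canonical SMILES.
#'
#' @param raw_smiles character vector of SMILES strings.
#' @param source_id optional character vector of identifiers (recycled names).
#' @param strict if `TRUE`, an unparseable SMILES raises an error; if `FALSE`
#'   (bulk mode) it is flagged via `is_valid = FALSE` and reported with a
#'   message. Defaults to strict for a single input, bulk otherwise.
#' @return a data.frame of molecule records with columns `raw_smiles`,
#'   `canonical_smiles`, `source_id`, `is_valid`.
#' @examples
#' \dontrun{
#' standardize("C/C=C/C")$canonical_smiles  # "CC=CC"
#' standardize("CCO.Cl")$canonical_smiles   # "CCO"
#' }
#' @export
standardize <- function(raw_smiles, source_id = NULL,
                        strict = length(raw_smiles) == 1L) {
  stopifnot(is.character(raw_smiles), length(raw_smiles) >= 1L)
  if (any(!nzchar(raw_smiles))) stop("raw_smiles must be non-empty text")
  if (is.null(source_id)) source_id <- paste0("mol", seq_along(raw_smiles))
  out <- .rdkit_run("standardize", raw_smiles)
  parts <- strsplit(out, "\t", fixed = TRUE)
  valid <- vapply(parts, function(p) identical(p[[1]], "1"), logical(1))
  canonical <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                      character(1))
  canonical[!valid] <- NA_character_
  if (any(!valid)) {
    if (strict) {
      stop("invalid SMILES: ",
           paste(utils::head(raw_smiles[!valid], 5), collapse = ", "))
    }
    message(sum(!valid), " invalid SMILES flagged during standardization")
  }
  data.frame(raw_smiles = raw_smiles, canonical_smiles = canonical,
             source_id = as.character(source_id), is_valid = valid,
             stringsAsFactors = FALSE)
}

#' Build a deduplicated SMILES corpus
#'
#' Filters standardized molecule records to valid, length-admissible
#' canonical SMILES and removes duplicates, keeping the first occurrence.
#'
#' @param records data.frame from [standardize()], or a character vector of
#'   canonical SMILES.
#' @param max_len maximum admitted canonical SMILES length (characters).
#' @return named character vector of canonical SMILES (names = source ids).
#' @export
build_corpus <- function(records, max_len = 140) {
  if (is.character(records)) {
    records <- data.frame(canonical_smiles = records,
                          source_id = if (is.null(names(records)))
                            paste0("mol", seq_along(records)) else names(records),
                          is_valid = TRUE, stringsAsFactors = FALSE)
  }
  keep <- records$is_valid & !is.na(records$canonical_smiles) &
    nchar(records$canonical_smiles) <= max_len
  smi <- records$canonical_smiles[keep]
  ids <- records$source_id[keep]
  first <- !duplicated(smi)
  corpus <- stats::setNames(smi[first], ids[first])
  if (length(corpus) == 0) stop("empty corpus: no valid molecules retained")
  corpus
}

#' Read a .smi file (one SMILES per line, optional whitespace-separated id)
#' @param path file path.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][[2]] else paste0("mol", i),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Read SMILES from a CSV file with a named SMILES column
#' @param path file path.
#' @param smiles_col name of the column holding SMILES.
#' @param id_col optional name of an identifier column.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles", id_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("column '", smiles_col, "' not found in ", path)
  }
  id <- if (!is.null(id_col) && id_col %in% names(df)) as.character(df[[id_col]])
  else paste0("mol", seq_len(nrow(df)))
  data.frame(smiles = df[[smiles_col]], id = id, stringsAsFactors = FALSE)
}

#' Write a corpus to a .smi file
#' @param corpus named character vector of SMILES.
#' @param path output file path.
#' @export
write_smi <- function(corpus, path) {
  ids <- names(corpus)
  lines <- if (is.null(ids)) as.character(corpus) else paste(corpus, ids)
  writeLines(lines, path)
  invisible(path)
}

#' Morgan fingerprints (radius 2, 2048 bits)
#'
#' @param smiles character vector of (ideally canonical) SMILES.
#' @param radius circular neighbourhood radius.
#' @param nbits folded fingerprint length.
#' @return for a single input a `morgan_fp` object; otherwise a list of
#'   `morgan_fp` objects (`NULL` for unparseable SMILES).
#' @export
morgan_fp <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(is.character(smiles))
  out <- .rdkit_run("fp", smiles, args = c(radius, nbits))
  fps <- lapply(out, function(line) {
    if (identical(line, "NA")) return(NULL)
    bits <- if (nzchar(line)) as.integer(strsplit(line, " ", fixed = TRUE)[[1]]) + 1L
    else integer(0)
    structure(list(bits = bits, nbits = as.integer(nbits),
                   radius = as.integer(radius)), class = "morgan_fp")
  })
  if (length(smiles) == 1L) {
    if (is.null(fps[[1]])) stop("invalid molecule: ", smiles)
    return(fps[[1]])
  }
  fps
}

# Dense logical matrix (n x nbits) from a list of fingerprints.
.fp_matrix <- function(fps) {
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  nbits <- fps[[1]]$nbits
  m <- matrix(0, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits] <- 1
  m
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b `morgan_fp` objects of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "morgan_fp"), inherits(b, "morgan_fp"))
  if (a$nbits != b$nbits) stop("fingerprint lengths differ")
  if (length(a$bits) == 0 && length(b$bits) == 0) {
    stop("Tanimoto undefined for two all-zero fingerprints")
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (length(a$bits) + length(b$bits) - inter)
}

# All pairwise Tanimoto similarities between two fingerprint lists.
.tanimoto_matrix <- function(fps_a, fps_b) {
  A <- .fp_matrix(fps_a); B <- .fp_matrix(fps_b)
  inter <- A %*% t(B)
  pa <- rowSums(A); pb <- rowSums(B)
  un <- outer(pa, pb, "+") - inter
  s <- inter / un
  s[un == 0] <- NaN
  s
}

#' Nearest-neighbor Tanimoto similarity against a reference set
#'
#' @param query a SMILES string or `morgan_fp`.
#' @param reference_set corpus (character vector of SMILES) or list of
#'   `morgan_fp` objects; names/ids are carried into the result.
#' @return list with `similarity`, `reference_id`, and `index` (arg-max,
#'   ties broken by first occurrence).
#' @export
nearest_neighbor_sim <- function(query, reference_set) {
  if (length(reference_set) == 0) stop("reference set is empty")
  qfp <- if (inherits(query, "morgan_fp")) query else morgan_fp(query)
  if (is.character(reference_set)) {
    ids <- if (is.null(names(reference_set)))
      as.character(reference_set) else names(reference_set)
    rfp <- morgan_fp(reference_set)
    if (length(reference_set) == 1L) rfp <- list(rfp)
  } else {
    rfp <- reference_set
    ids <- if (is.null(names(rfp))) as.character(seq_along(rfp)) else names(rfp)
  }
  sims <- .tanimoto_matrix(list(qfp), rfp)[1, ]
  idx <- which.max(sims)  # first occurrence wins ties
  list(similarity = sims[[idx]], reference_id = ids[[idx]], index = idx)
}
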