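# Subprocess bridge to the RDKit helper script. All chemistry primitives
# (canonicalization, Morgan fingerprints, randomized-SMILES augmentation)
# are batched through a single python call per request.

.backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "clmdesign")
  if (!nzchar(p)) stop("chem_backend.py not found in installed package")
  p
}

#' Is the RDKit chemistry backend available?
#'
#' The package delegates SMILES canonicalization, Morgan fingerprints and
#' augmentation to RDKit through the `python` interpreter on the PATH.
#'
#' @return `TRUE` if `python` can import rdkit.
#' @export
rdkit_available <- function() {
  if (!is.null(.clm_env$rdkit_ok)) return(.clm_env$rdkit_ok)
  py <- Sys.which("python")
  ok <- nzchar(py) && {
    st <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                   stdout = FALSE, stderr = FALSE))
    identical(st, 0L)
  }
  .clm_env$rdkit_ok <- ok
  ok
}

.clm_env <- new.env(parent = emptyenv())

.rdkit_run <- function(task, lines, args = character()) {
  if (!rdkit_available()) {
    stop("the RDKit backend is unavailable: `python` with rdkit is required")
  }
  if (length(lines) == 0) return(character(0))
  fin <- tempfile("clm_in_"); fout <- tempfile("clm_out_")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(lines, fin)
  status <- system2(Sys.which("python"), c(.backend_script(), task, args),
                    stdin = fin, stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("RDKit backend call '", task, "' failed")
  out <- readLines(fout)
  if (length(out) != length(lines)) {
    stop("RDKit backend returned ", length(out), " lines for ",
         length(lines), " inputs")
  }
  out
}
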