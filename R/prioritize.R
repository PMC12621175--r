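#' Rank sampled designs by sampling frequency
#'
#' Invalid SMILES are dropped (their count is reported as an attribute),
#' valid ones are canonicalized and grouped, and designs are ranked by
#' descending frequency with ties broken by lexicographic canonical SMILES.
#' Designs present in any reference corpus are flagged as non-novel.
#'
#' @param samples character multiset of sampled SMILES.
#' @param reference_corpora optional list of corpora (character vectors of
#'   canonical SMILES) used to flag non-novel designs.
#' @return data.frame with columns `smiles`, `frequency`, `freq_rank`,
#'   `novel`; `attr(, "n_invalid")` counts dropped draws.
#' @export
frequency_rank <- function(samples, reference_corpora = NULL) {
  if (length(samples) == 0) stop("empty sample multiset")
  std <- standardize(samples, strict = FALSE)
  valid <- std$canonical_smiles[std$is_valid]
  n_invalid <- sum(!std$is_valid)
  if (length(valid) == 0) stop("all sampled SMILES are invalid")
  counts <- table(valid)
  tab <- data.frame(smiles = names(counts),
                    frequency = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$smiles, method = "radix"), ,
             drop = FALSE]
  tab$freq_rank <- seq_len(nrow(tab))
  known <- unique(unlist(reference_corpora, use.names = FALSE))
  tab$novel <- !(tab$smiles %in% known)
  rownames(tab) <- NULL
  attr(tab, "n_invalid") <- n_invalid
  tab
}

#' Keep the designs most similar to a template set
#'
#' Annotates each design with its nearest-neighbor Tanimoto similarity to
#' the template set and retains the `top_n` most similar designs.
#'
#' @param rank_table data.frame from [frequency_rank()] (or any table with
#'   a `smiles` column of canonical SMILES).
#' @param template_set template corpus (character vector of SMILES).
#' @param top_n number of designs to retain.
#' @return the retained rows, ordered by descending `nn_similarity`, with
#'   columns `nn_similarity`, `nn_template` and `sim_rank` added.
#' @export
similarity_prioritize <- function(rank_table, template_set, top_n = 1000) {
  if (top_n <= 0) stop("top_n must be positive")
  if (length(template_set) == 0) stop("template set is empty")
  fps <- morgan_fp(rank_table$smiles)
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  tfp <- morgan_fp(unname(template_set))
  if (inherits(tfp, "morgan_fp")) tfp <- list(tfp)
  sims <- .tanimoto_matrix(fps, tfp)
  ids <- if (is.null(names(template_set))) as.character(template_set)
  else names(template_set)
  rank_table$nn_similarity <- apply(sims, 1, max)
  rank_table$nn_template <- ids[apply(sims, 1, which.max)]
  ord <- order(-rank_table$nn_similarity, method = "radix")  # stable
  out <- utils::head(rank_table[ord, , drop = FALSE], top_n)
  out$sim_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Aggregate two per-target docking scores
#'
#' The combined score is the geometric mean of the two affinities. Both
#' scores must share a sign; for the usual negative affinities the result
#' is the negated geometric mean of their magnitudes, so better (more
#' negative) inputs give a better (more negative) aggregate.
#'
#' @param score_alpha,score_beta docking scores (engine affinity units).
#' @return aggregated score (vectorized).
#' @export
aggregate_dock <- function(score_alpha, score_beta) {
  mixed <- sign(score_alpha) * sign(score_beta) < 0
  if (any(mixed, na.rm = TRUE)) {
    stop("aggregate undefined for mixed-sign docking scores")
  }
  sign(score_alpha) * sqrt(abs(score_alpha) * abs(score_beta))
}

#' Docking configuration
#'
#' @param receptor_files named character vector of two prepared receptor
#'   structures (PDB/PDBQT), e.g. `c(alpha = ..., beta = ...)`.
#' @param ref_ligands named character vector of the cocrystallized ligand
#'   files used to autobox the grid (same names as `receptor_files`).
#' @param receptor_ids structure identifiers for reporting.
#' @param autobox_size padding added around the reference ligand box.
#' @param exhaustiveness search exhaustiveness of the engine.
#' @param repeats number of redocking repeats.
#' @param engine name or path of the docking engine binary.
#' @return list of class `docking_config`.
#' @export
docking_config <- function(receptor_files = NULL, ref_ligands = NULL,
                           receptor_ids = c("3IPQ", "5JY3"),
                           autobox_size = 8, exhaustiveness = 16,
                           repeats = 5, engine = "smina") {
  stopifnot(exhaustiveness >= 1, repeats >= 1)
  structure(list(receptor_files = receptor_files, ref_ligands = ref_ligands,
                 receptor_ids = receptor_ids, autobox_size = autobox_size,
                 exhaustiveness = as.integer(exhaustiveness),
                 repeats = as.integer(repeats), engine = engine),
            class = "docking_config")
}

.find_engine <- function(config) {
  p <- Sys.which(config$engine)
  if (nzchar(p)) p else NULL
}

# Prepare a ligand SDF (3D coordinates, hydrogens) with obabel.
.prepare_ligand <- function(smiles, out_sdf) {
  ob <- Sys.which("obabel")
  if (!nzchar(ob)) return(FALSE)
  st <- suppressWarnings(system2(ob, c(paste0("-:", shQuote(smiles)),
                                       "-osdf", "-O", out_sdf,
                                       "--gen3d", "-h"),
                                 stdout = FALSE, stderr = FALSE))
  identical(st, 0L) && file.exists(out_sdf)
}

# Parse the best-pose affinity from engine stdout (Vina-format table).
.parse_affinity <- function(lines) {
  hits <- regmatches(lines, regexpr("^\\s*1\\s+(-?[0-9.]+)", lines))
  if (!length(hits)) return(NA_real_)
  as.numeric(strsplit(trimws(hits[[1]]), "\\s+")[[1]][2])
}

.run_engine <- function(engine, receptor, ligand, ref_ligand, config,
                        seed = NULL, out_pose = NULL) {
  args <- c("-r", receptor, "-l", ligand,
            "--autobox_ligand", ref_ligand,
            "--autobox_add", config$autobox_size,
            "--exhaustiveness", config$exhaustiveness)
  if (!is.null(seed)) args <- c(args, "--seed", seed)
  if (!is.null(out_pose)) args <- c(args, "-o", out_pose)
  out <- tryCatch(suppressWarnings(
    system2(engine, args, stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  .parse_affinity(out)
}

#' Dock designs against both receptor structures
#'
#' Thin adapter around an external docking engine (the engine's scoring
#' function is not re-implemented). Each design is embedded in 3D,
#' docked into both receptors with the configured autobox and
#' exhaustiveness, and the two best-pose affinities are combined with
#' [aggregate_dock()]. When the engine (or obabel) is unavailable, the
#' docking columns are `NA` and the rest of the pipeline is unaffected.
#'
#' @param smiles character vector of design SMILES.
#' @param config a `docking_config`.
#' @return data.frame with columns `smiles`, `dock_alpha`, `dock_beta`,
#'   `dock_aggregate`; `attr(, "engine")` records the engine used (or NA).
#' @export
dock_adapter <- function(smiles, config = docking_config()) {
  out <- data.frame(smiles = smiles, dock_alpha = NA_real_,
                    dock_beta = NA_real_, dock_aggregate = NA_real_,
                    stringsAsFactors = FALSE)
  engine <- .find_engine(config)
  if (is.null(engine) || is.null(config$receptor_files)) {
    message("docking engine '", config$engine,
            "' or receptors unavailable; docking scores left empty")
    attr(out, "engine") <- NA_character_
    return(out)
  }
  for (i in seq_along(smiles)) {
    lig <- tempfile(fileext = ".sdf")
    if (!.prepare_ligand(smiles[i], lig)) next
    sc <- vapply(seq_along(config$receptor_files), function(j) {
      .run_engine(engine, config$receptor_files[[j]], lig,
                  config$ref_ligands[[j]], config)
    }, numeric(1))
    unlink(lig)
    out$dock_alpha[i] <- sc[1]
    out$dock_beta[i] <- sc[2]
    if (!anyNA(sc)) out$dock_aggregate[i] <- aggregate_dock(sc[1], sc[2])
  }
  attr(out, "engine") <- engine
  out
}

#' Redock a cocrystallized ligand to validate the docking setup
#'
#' Repeats the docking of a crystal structure's own ligand and reports the
#' mean and standard deviation of the best-pose score and of the
#' symmetry-aware heavy-atom RMSD to the crystal pose (via `obrms`).
#'
#' @param receptor_file prepared receptor structure.
#' @param ligand_file the cocrystallized ligand (also the autobox
#'   reference and the RMSD reference pose).
#' @param config a `docking_config` (`repeats` controls the repeats).
#' @return list with `score_mean`, `score_sd`, `rmsd_mean`, `rmsd_sd`.
#' @export
redock_cocrystal <- function(receptor_file, ligand_file,
                             config = docking_config()) {
  engine <- .find_engine(config)
  if (is.null(engine)) stop("docking engine '", config$engine, "' not found")
  scores <- rmsds <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    pose <- tempfile(fileext = ".sdf")
    scores[r] <- .run_engine(engine, receptor_file, ligand_file, ligand_file,
                             config, seed = r, out_pose = pose)
    obrms <- Sys.which("obrms")
    rmsds[r] <- if (nzchar(obrms) && file.exists(pose)) {
      txt <- suppressWarnings(system2(obrms, c("-f", ligand_file, pose),
                                      stdout = TRUE, stderr = FALSE))
      suppressWarnings(as.numeric(sub(".*\\s", "", txt[1])))
    } else NA_real_
    unlink(pose)
  }
  list(score_mean = mean(scores), score_sd = stats::sd(scores),
       rmsd_mean = mean(rmsds), rmsd_sd = stats::sd(rmsds))
}

#' Write a rank table as TSV
#' @param tab a rank table data.frame.
#' @param path output file.
#' @export
write_rank_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
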