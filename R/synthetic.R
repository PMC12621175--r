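# Synthetic scaffold-family corpora. Each family is a drug-like core with
# substitution sites; enumerated products give a large diverse pretraining
# corpus, a mid-size target-focused fine-tuning set drawn from a few
# families, and a small template subset sharing scaffolds across families
# -- the statistical structure the transfer-learning pipeline assumes.

#' Define a scaffold family
#'
#' @param family_id label for the family.
#' @param core SMILES template with substitution sites written as
#'   placeholders `{R1}`, `{R2}`, ...
#' @param substituents named list (`R1`, `R2`, ...) of fragment SMILES
#'   pools, written so that textual substitution yields valid SMILES.
#' @return object of class `scaffold_family`.
#' @export
scaffold_family <- function(family_id, core, substituents) {
  sites <- regmatches(core, gregexpr("\\{R[0-9]+\\}", core))[[1]]
  if (length(sites) < 1) stop("core must contain at least one {Rk} site")
  keys <- gsub("[{}]", "", sites)
  if (!setequal(keys, names(substituents))) {
    stop("substituent pools must be named after the core sites: ",
         paste(keys, collapse = ", "))
  }
  structure(list(family_id = family_id, core = core,
                 substituents = substituents[keys]),
            class = "scaffold_family")
}

#' @export
print.scaffold_family <- function(x, ...) {
  cat("<scaffold_family>", x$family_id, "-", length(x$substituents),
      "site(s), capacity", prod(lengths(x$substituents)), "\n")
  invisible(x)
}

.family_product <- function(family, idx) {
  s <- family$core
  for (k in seq_along(idx)) {
    s <- sub(paste0("{", names(family$substituents)[k], "}"),
             family$substituents[[k]][idx[k]], s, fixed = TRUE)
  }
  s
}

#' Enumerate distinct molecules from a scaffold family
#'
#' Draws random substituent combinations, canonicalizes the products and
#' returns `n` distinct valid molecules, deterministically under `seed`.
#'
#' @param family a `scaffold_family`.
#' @param n number of distinct products required.
#' @param seed RNG seed.
#' @return data.frame of molecule records with a `family` column.
#' @export
enumerate_family <- function(family, n, seed = 1) {
  capacity <- prod(lengths(family$substituents))
  if (n == 0) {
    return(data.frame(raw_smiles = character(0),
                      canonical_smiles = character(0),
                      source_id = character(0), is_valid = logical(0),
                      family = character(0), stringsAsFactors = FALSE))
  }
  if (n > capacity) {
    stop("family '", family$family_id, "' can yield at most ", capacity,
         " products; ", n, " requested")
  }
  grid <- as.matrix(expand.grid(lapply(lengths(family$substituents),
                                       seq_len)))
  smiles <- apply(grid, 1, function(idx) .family_product(family, idx))
  std <- standardize(smiles, strict = FALSE)
  distinct <- !duplicated(std$canonical_smiles) & std$is_valid &
    nchar(std$canonical_smiles) <= 140
  pool <- std$canonical_smiles[distinct]
  if (n > length(pool)) {
    stop("family '", family$family_id, "' yields only ", length(pool),
         " distinct valid products; ", n, " requested")
  }
  pick <- with_seed(seed, sample(pool, n))
  data.frame(raw_smiles = pick, canonical_smiles = pick,
             source_id = paste0(family$family_id, "_", seq_len(n)),
             is_valid = TRUE, family = family$family_id,
             stringsAsFactors = FALSE)
}

#' Built-in scaffold families
#'
#' Eight families built from drug-like cores echoing nuclear-receptor
#' ligand chemotypes (hexafluoropropanol aryl amides, diaryl piperazines,
#' biaryl sulfone benzylamines, oxyacetic acids, sulfonamides, ureas), so
#' the token statistics of the synthetic corpora resemble the real task.
#'
#' @return named list of `scaffold_family` objects.
#' @export
default_families <- function() {
  aryl <- c("F", "Cl", "Br", "C", "CC", "CCC", "OC", "OCC", "O", "N",
            "N(C)C", "C#N", "CO", "CCO", "C(F)(F)F", "OC(F)(F)F",
            "S(C)(=O)=O", "C(=O)N", "C(=O)OC", "C(C)C", "CC(C)C", "CCCC",
            "OC(C)C", "CCN")
  alkyl <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "CCO", "CCCO",
             "CCOC", "C(C)CC", "CCN(C)C", "CC(C)(C)C", "CCCCC", "CCC(C)C",
             "CCCN(C)C", "CC(F)(F)F")
  fams <- list(
    scaffold_family("hfip_amide",
      "OC(C(F)(F)F)(C(F)(F)F)c1ccc(N({R1})C(=O)c2ccc({R2})cc2)cc1",
      list(R1 = alkyl, R2 = aryl)),
    scaffold_family("aryl_piperazine",
      "O=S(C)(=O)c1cccc(N2CCN(c3ccc({R1})c({R2})c3)CC2)c1",
      list(R1 = aryl, R2 = aryl)),
    scaffold_family("sulfone_benzylamine",
      "CS(=O)(=O)c1cccc(-c2ccc(CN({R1})Cc3ccc({R2})cc3)cc2)c1",
      list(R1 = alkyl, R2 = aryl)),
    scaffold_family("amide_piperidine",
      "O=C(N1CCC({R1})CC1)c1ccc({R2})cc1",
      list(R1 = alkyl, R2 = aryl)),
    scaffold_family("oxyacetic_acid",
      "OC(=O)Cc1ccc(OCCN({R1})Cc2ccc({R2})cc2)cc1",
      list(R1 = alkyl, R2 = aryl)),
    scaffold_family("cf3_sulfonamide",
      "FC(F)(F)c1ccc(N({R1})S(=O)(=O)c2ccc({R2})cc2)cc1",
      list(R1 = alkyl, R2 = aryl)),
    scaffold_family("diaryl_urea",
      "O=C(Nc1ccc({R1})cc1)Nc1ccc({R2})cc1",
      list(R1 = aryl, R2 = aryl)),
    scaffold_family("benzyl_sulfonamide",
      "O=S(=O)(Cc1ccc({R1})cc1)Nc1ccc({R2})cc1",
      list(R1 = aryl, R2 = aryl))
  )
  stats::setNames(fams, vapply(fams, `[[`, character(1), "family_id"))
}

#' Generate a synthetic transfer-learning study
#'
#' Produces three corpora with the structure the pipeline assumes: a large
#' diverse pretraining corpus drawn from all families, a mid-size
#' target-focused fine-tuning set I drawn from three families, and a small
#' template set II sampled from set I across at least two families. The
#' template set is excluded from the pretraining corpus.
#'
#' @param n_pretrain,n_finetune1,n_finetune2 corpus sizes.
#' @param seed single study seed controlling all randomness.
#' @param families named list of `scaffold_family` objects.
#' @param finetune_families family ids used for the fine-tuning sets.
#' @return object of class `synthetic_study` with elements `pretrain`,
#'   `finetune1`, `finetune2` (named character vectors of canonical
#'   SMILES), `manifest` (id, smiles, family, split) and `seed`.
#' @export
make_study <- function(n_pretrain = 2000, n_finetune1 = 120,
                       n_finetune2 = 10, seed = 7,
                       families = default_families(),
                       finetune_families = c("hfip_amide",
                                             "aryl_piperazine",
                                             "sulfone_benzylamine")) {
  stopifnot(n_finetune2 <= n_finetune1, length(finetune_families) >= 2,
            all(finetune_families %in% names(families)))
  nf <- length(families)
  # fine-tuning set I: equal shares over its families
  share1 <- diff(round(seq(0, n_finetune1, length.out =
                             length(finetune_families) + 1)))
  ft1 <- do.call(rbind, lapply(seq_along(finetune_families), function(i) {
    enumerate_family(families[[finetune_families[i]]], share1[i],
                     seed = seed * 100L + i)
  }))
  if (nrow(ft1) < n_finetune2) stop("infeasible sizes: set II exceeds set I")
  # set II: stratified over the fine-tuning families (>= 2 represented)
  ft2_idx <- with_seed(seed + 1L, {
    by_fam <- split(seq_len(nrow(ft1)), ft1$family)
    share2 <- diff(round(seq(0, n_finetune2, length.out =
                               length(by_fam) + 1)))
    unlist(lapply(seq_along(by_fam), function(i)
      sample(by_fam[[i]], min(share2[i], length(by_fam[[i]])))))
  })
  ft2_idx <- utils::head(ft2_idx, n_finetune2)
  ft2 <- ft1[ft2_idx, , drop = FALSE]
  if (length(unique(ft2$family)) < 2) {
    stop("set II could not span two families; increase n_finetune2")
  }
  # pretraining corpus: equal shares over all families, templates excluded
  sharep <- diff(round(seq(0, n_pretrain, length.out = nf + 1)))
  pre <- do.call(rbind, lapply(seq_len(nf), function(i) {
    rec <- enumerate_family(families[[i]], sharep[i] + n_finetune2,
                            seed = seed * 100L + 50L + i)
    rec <- rec[!(rec$canonical_smiles %in% ft2$canonical_smiles), ,
               drop = FALSE]
    utils::head(rec, sharep[i])
  }))
  if (nrow(pre) < n_pretrain) stop("infeasible sizes: family capacity too small")
  manifest <- rbind(
    data.frame(id = paste0("pre_", seq_len(nrow(pre))),
               smiles = pre$canonical_smiles, family = pre$family,
               split = "pretrain", stringsAsFactors = FALSE),
    data.frame(id = paste0("ft1_", seq_len(nrow(ft1))),
               smiles = ft1$canonical_smiles, family = ft1$family,
               split = "finetune1", stringsAsFactors = FALSE),
    data.frame(id = paste0("ft2_", seq_len(nrow(ft2))),
               smiles = ft2$canonical_smiles, family = ft2$family,
               split = "finetune2", stringsAsFactors = FALSE))
  structure(list(
    pretrain = stats::setNames(pre$canonical_smiles,
                               paste0("pre_", seq_len(nrow(pre)))),
    finetune1 = stats::setNames(ft1$canonical_smiles,
                                paste0("ft1_", seq_len(nrow(ft1)))),
    finetune2 = stats::setNames(ft2$canonical_smiles,
                                paste0("ft2_", seq_len(nrow(ft2)))),
    manifest = manifest, seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> pretrain", length(x$pretrain), "/ set I",
      length(x$finetune1), "/ set II", length(x$finetune2),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write a study to .smi files plus a TSV manifest
#' @param study a `synthetic_study`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_smi(study$pretrain, file.path(dir, "pretrain.smi"))
  write_smi(study$finetune1, file.path(dir, "finetune1.smi"))
  write_smi(study$finetune2, file.path(dir, "finetune2.smi"))
  utils::write.table(study$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
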