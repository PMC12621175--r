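#' Pipeline run configuration
#'
#' Bundles the per-stage configurations. The two-stage fine-tuning is data:
#' `finetune_stages` is a list of stages, each naming its corpus and the
#' recurrent layers to freeze, so single-stage (or n-stage) variants are
#' expressible without code changes. The serialized configuration plus the
#' seed fully determine every non-docking output.
#'
#' @param workspace directory for all artifacts.
#' @param seed master seed.
#' @param study_sizes sizes of the synthetic study
#'   (pretrain, set I, set II).
#' @param recurrent_units LSTM widths of the model used for the run.
#' @param pretrain_epochs pretraining epochs.
#' @param pretrain_augment_fold randomized variants per molecule added to
#'   the pretraining corpus (canonical forms always included).
#' @param dropout dropout fraction for the run; desk-scale models are far
#'   smaller than the full-scale network, so the default is milder than
#'   the full-scale 0.4.
#' @param finetune_stages list of stages, each
#'   `list(corpus = "finetune1"|"finetune2", frozen_recurrent = ...)`.
#' @param finetune_epochs epochs per fine-tuning stage.
#' @param generation a `clm_generation_config`.
#' @param epoch_band acceptance band for [select_epochs()].
#' @param top_n designs retained by similarity prioritization.
#' @param docking optional `docking_config` (NULL disables docking).
#' @param do_tsne,do_vscreen toggle the chemical-space stages.
#' @return list of class `clm_run_config`.
#' @export
run_config <- function(workspace = tempfile("clm_run_"), seed = 7,
                       study_sizes = c(2000, 120, 10),
                       recurrent_units = c(64, 48, 32),
                       pretrain_epochs = 25,
                       pretrain_augment_fold = 4,
                       dropout = 0.2,
                       finetune_stages = list(
                         list(corpus = "finetune1", frozen_recurrent = 1L),
                         list(corpus = "finetune2", frozen_recurrent = c(1L, 2L))),
                       finetune_epochs = 20,
                       generation = generation_config(),
                       epoch_band = c(0.3, 0.9),
                       top_n = 1000,
                       docking = NULL,
                       do_tsne = TRUE, do_vscreen = TRUE) {
  structure(list(workspace = workspace, seed = as.integer(seed),
                 study_sizes = study_sizes,
                 recurrent_units = recurrent_units,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_augment_fold = as.integer(pretrain_augment_fold),
                 dropout = dropout,
                 finetune_stages = finetune_stages,
                 finetune_epochs = as.integer(finetune_epochs),
                 generation = generation, epoch_band = epoch_band,
                 top_n = as.integer(top_n), docking = docking,
                 do_tsne = do_tsne, do_vscreen = do_vscreen),
            class = "clm_run_config")
}

.log_stage <- function(ws, stage, info = list()) {
  line <- jsonlite::toJSON(c(list(stage = stage,
                                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                             info), auto_unbox = TRUE)
  cat(line, "\n", file = file.path(ws, "log.jsonl"), append = TRUE)
}

# Run `compute` unless the stage marker exists with a matching config hash
# (re-entrancy: interrupted runs resume from completed stages).
.stage <- function(ws, name, config_hash, compute) {
  marker <- file.path(ws, paste0(".stage_", name, ".json"))
  if (file.exists(marker)) {
    meta <- jsonlite::read_json(marker)
    if (identical(meta$hash, config_hash)) {
      return(invisible(FALSE))
    }
  }
  compute()
  jsonlite::write_json(list(hash = config_hash), marker, auto_unbox = TRUE)
  .log_stage(ws, name, list(hash = config_hash))
  invisible(TRUE)
}

#' Run the design pipeline end-to-end
#'
#' Executes: synthetic data -> standardization -> vocabulary -> pretraining
#' -> staged fine-tuning -> epoch selection -> temperature sampling ->
#' frequency and similarity ranking (docking optional) -> chemical-space
#' reports. Every stage logs to `log.jsonl` and persists its artifacts in
#' the workspace; rerunning with the same configuration reuses completed
#' stages.
#'
#' @param config a `clm_run_config`.
#' @param verbose print progress.
#' @return list with the main artifacts (study, epoch table, rank table,
#'   file paths).
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  ws <- config$workspace
  dir.create(ws, recursive = TRUE, showWarnings = FALSE)
  chash <- .hash_obj(config[setdiff(names(config), "workspace")])

  say <- function(...) if (verbose) message("[pipeline] ", ...)
  fail <- function(stage, e, hint) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "\n  hint: ", hint, call. = FALSE)
  }

  # -- synthetic data ----------------------------------------------------
  study_file <- file.path(ws, "data")
  .stage(ws, "simulate_data", chash, function() {
    say("generating synthetic study")
    tryCatch({
      study <- make_study(config$study_sizes[1], config$study_sizes[2],
                          config$study_sizes[3], seed = config$seed)
      write_study(study, study_file)
    }, error = function(e) fail("simulate_data", e,
                                "check study sizes against family capacity"))
  })
  study <- list(
    pretrain = with(read_smi(file.path(study_file, "pretrain.smi")),
                    stats::setNames(smiles, id)),
    finetune1 = with(read_smi(file.path(study_file, "finetune1.smi")),
                     stats::setNames(smiles, id)),
    finetune2 = with(read_smi(file.path(study_file, "finetune2.smi")),
                     stats::setNames(smiles, id)))

  # -- corpus + vocabulary ----------------------------------------------
  corpora <- lapply(study, build_corpus)
  vocab_file <- file.path(ws, "vocab.json")
  .stage(ws, "vocabulary", chash, function() {
    say("fitting vocabulary")
    # reserve tokens that appear only in randomized augmentation variants
    vocab <- fit_vocabulary(unlist(corpora, use.names = FALSE),
                            extra_tokens = c("-", "4", "5"))
    write_vocabulary(vocab, vocab_file)
  })
  vocab <- read_vocabulary(vocab_file)
  spec <- model_spec(vocab$size, recurrent_units = config$recurrent_units,
                     dropout = config$dropout)

  # -- pretraining -------------------------------------------------------
  pre_dir <- file.path(ws, "checkpoints", "pretrain")
  .stage(ws, "pretrain", chash, function() {
    say("pretraining ", config$pretrain_epochs, " epochs")
    train <- augment_corpus(corpora$pretrain,
                            fold = config$pretrain_augment_fold,
                            seed = config$seed + 99L, vocab = vocab)
    tryCatch(
      pretrain(train, spec,
               train_config(learning_rate = 1e-3,
                            epochs = config$pretrain_epochs,
                            dropout = config$dropout,
                            seed = config$seed),
               vocab = vocab, randomize_each_epoch = FALSE,
               checkpoint_dir = pre_dir, verbose = verbose),
      error = function(e) fail("pretrain", e,
                               "inspect the corpus/vocabulary coverage"))
  })
  last_ckpt <- function(dir) {
    files <- sort(list.files(dir, pattern = "^epoch_[0-9]+\\.rds$",
                             full.names = TRUE))
    load_checkpoint(files[length(files)])
  }

  # -- staged fine-tuning ------------------------------------------------
  ck <- last_ckpt(pre_dir)
  ft_dirs <- character(0)
  for (s in seq_along(config$finetune_stages)) {
    stg <- config$finetune_stages[[s]]
    ft_dir <- file.path(ws, "checkpoints", paste0("finetune", s))
    ft_dirs <- c(ft_dirs, ft_dir)
    .stage(ws, paste0("finetune", s), chash, function() {
      say("fine-tuning stage ", s, " on ", stg$corpus)
      tryCatch(
        fine_tune(ck, corpora[[stg$corpus]],
                  train_config(epochs = config$finetune_epochs,
                               frozen_recurrent = stg$frozen_recurrent,
                               dropout = config$dropout,
                               seed = config$seed + s),
                  checkpoint_dir = ft_dir, verbose = verbose),
        error = function(e) fail(paste0("finetune", s), e,
                                 "check vocabulary coverage of the corpus"))
    })
    ck <- last_ckpt(ft_dir)
  }

  # -- epoch selection ---------------------------------------------------
  final_dir <- ft_dirs[length(ft_dirs)]
  epoch_file <- file.path(ws, "epoch_scores.tsv")
  .stage(ws, "select_epochs", chash, function() {
    say("selecting epochs by beam-search similarity")
    files <- sort(list.files(final_dir, pattern = "\\.rds$", full.names = TRUE))
    ckpts <- lapply(files, load_checkpoint)
    sel <- select_epochs(ckpts, corpora$finetune2, config$generation,
                         band = config$epoch_band)
    utils::write.table(sel$table, epoch_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  epoch_table <- utils::read.table(epoch_file, header = TRUE, sep = "\t")
  selected <- epoch_table$epoch[epoch_table$selected]
  if (length(selected) == 0) {
    say("no epoch inside the acceptance band; sampling from the last epoch")
    selected <- max(epoch_table$epoch)
  }

  # -- temperature sampling (pooled across selected epochs) --------------
  samples_file <- file.path(ws, "samples.smi")
  .stage(ws, "sample", chash, function() {
    say("sampling ", config$generation$n_samples, " SMILES from ",
        length(selected), " epoch(s)")
    per <- diff(round(seq(0, config$generation$n_samples,
                          length.out = length(selected) + 1)))
    draws <- unlist(lapply(seq_along(selected), function(i) {
      ckpt <- load_checkpoint(file.path(
        final_dir, sprintf("epoch_%03d.rds", selected[i])))
      cfg <- config$generation
      cfg$n_samples <- per[i]
      cfg$seed <- config$generation$seed + i
      temperature_sample(ckpt, cfg)
    }), use.names = FALSE)
    writeLines(draws, samples_file)
  })
  draws <- readLines(samples_file)

  # -- ranking -----------------------------------------------------------
  rank_file <- file.path(ws, "rank_table.tsv")
  .stage(ws, "rank", chash, function() {
    say("ranking designs")
    tab <- tryCatch(
      frequency_rank(draws, reference_corpora = corpora),
      error = function(e) fail("rank", e,
                               "all samples invalid; train longer or raise T"))
    tab <- similarity_prioritize(tab, corpora$finetune2,
                                 top_n = config$top_n)
    if (!is.null(config$docking)) {
      dk <- dock_adapter(tab$smiles, config$docking)
      tab$dock_alpha <- dk$dock_alpha
      tab$dock_beta <- dk$dock_beta
      tab$dock_aggregate <- dk$dock_aggregate
    }
    write_rank_table(tab, rank_file)
  })
  rank_table <- utils::read.table(rank_file, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)

  # -- chemical-space reports -------------------------------------------
  tsne_file <- file.path(ws, "tsne.tsv")
  if (config$do_tsne) {
    .stage(ws, "tsne", chash, function() {
      say("embedding chemical space")
      top <- utils::head(rank_table$smiles, 50)
      sets <- list(pretrain = utils::head(corpora$pretrain, 150),
                   set_I = corpora$finetune1,
                   set_II = corpora$finetune2,
                   designs = top)
      smi <- unlist(sets, use.names = FALSE)
      grp <- rep(names(sets), lengths(sets))
      emb <- embed_tsne(morgan_fp(smi), grp,
                        embedding_config(seed = config$seed,
                                         perplexity = min(30, floor(length(smi) / 4))))
      utils::write.table(emb, tsne_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  vscreen_file <- file.path(ws, "vscreen.tsv")
  if (config$do_vscreen) {
    .stage(ws, "vscreen", chash, function() {
      say("virtual-screening simulation")
      spikes <- utils::head(rank_table$smiles[rank_table$novel], 3)
      scr <- virtual_screen(corpora$pretrain, spikes, corpora$finetune1,
                            retained_n = min(config$top_n,
                                             length(corpora$pretrain)))
      utils::write.table(scr$consensus, vscreen_file, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  say("done")
  list(workspace = ws, study = study, vocab = vocab,
       epoch_table = epoch_table, selected_epochs = selected,
       rank_table = rank_table,
       files = list(samples = samples_file, ranks = rank_file,
                    epochs = epoch_file,
                    tsne = if (config$do_tsne) tsne_file else NULL,
                    vscreen = if (config$do_vscreen) vscreen_file else NULL))
}
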