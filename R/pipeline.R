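#' Assemble a run configuration
#'
#' One nested configuration object for [run_pipeline()]: the synthetic-data
#' description, model architecture, per-stage training settings, and
#' sampler. The global seed fans out deterministically to per-stage seeds
#' (`seed + 1000 * stage_index`), so any stage can be re-run independently
#' and reproduce its outputs bitwise on one device.
#'
#' @param model [model_config()] for the run.
#' @param synth [synthetic_config()] describing the corpus.
#' @param pretrain,pair_finetune,dev_finetune [train_config()]s per stage.
#' @param sampler [sampler_config()] for generation.
#' @param n_unpaired,n_paired,n_generate Corpus and generation sizes.
#' @param seed Global seed.
#' @return An `fv_run_config` list.
#' @export
run_config <- function(model = model_config(),
                       synth = synthetic_config(),
                       pretrain = train_config(),
                       pair_finetune = train_config(peak_lr = 1e-5, epochs = 3L,
                                                    batch_size = 256L,
                                                    grad_accum_steps = 1L),
                       dev_finetune = train_config(peak_lr = 1e-5, epochs = 2L,
                                                   batch_size = 256L,
                                                   grad_accum_steps = 1L),
                       sampler = sampler_config(),
                       n_unpaired = 2000L, n_paired = 1000L,
                       n_generate = 500L, seed = 0L) {
  structure(list(model = model, synth = synth, pretrain = pretrain,
                 pair_finetune = pair_finetune, dev_finetune = dev_finetune,
                 sampler = sampler, n_unpaired = as.integer(n_unpaired),
                 n_paired = as.integer(n_paired),
                 n_generate = as.integer(n_generate), seed = as.integer(seed)),
            class = "fv_run_config")
}

stage_seed <- function(config, stage_index) config$seed + 1000L * stage_index

#' Run the staged training/generation/evaluation pipeline
#'
#' Executes an ordered subset of `pretrain` (unpaired corpus),
#' `pair-finetune`, `dev-finetune`, `generate`, and `evaluate`. The
#' three-step training mirrors the published recipe: pretrain on unpaired
#' chains, finetune on paired sequences, then finetune on the developable
#' subset. Each stage writes its checkpoint (plus JSON metadata) and any
#' tabular outputs under `out_dir`, along with the resolved configuration
#' (`run_config.yaml`), so every output directory is self-describing and
#' re-execution reproduces it. Later stages resume from the checkpoints of
#' earlier ones; requesting a finetune without its prerequisite checkpoint
#' is an ordered-stage error.
#'
#' @param stages Character vector, ordered subset of
#'   `c("pretrain", "pair-finetune", "dev-finetune", "generate",
#'   "evaluate")`.
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(stages, config = run_config(),
                         out_dir = tempfile("fvgen_run_"), quiet = FALSE) {
  all_stages <- c("pretrain", "pair-finetune", "dev-finetune", "generate",
                  "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.unsorted(match(stages, all_stages))) {
    stop("stages must be given in pipeline order", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  paths <- list(out_dir = out_dir)
  ckpt <- function(stage) file.path(out_dir, paste0(stage, ".ckpt.rds"))
  germ <- config$synth$germlines

  if ("pretrain" %in% stages) {
    synth <- config$synth; synth$seed <- stage_seed(config, 1L)
    rep_ <- sample_repertoire(synth, config$n_unpaired)
    unpaired <- tibble::tibble(
      seq = c(rep_$heavy, rep_$light),
      split = rep(rep_$split, 2L))
    model <- init_model(config$model, seed = config$seed)
    tc <- config$pretrain; tc$seed <- stage_seed(config, 1L)
    model <- train_lm(model, unpaired, tc, quiet = quiet)
    model$meta$stage <- "pretrained"
    save_checkpoint(model, ckpt("pretrain"))
    paths$pretrain <- ckpt("pretrain")
  }
  if ("pair-finetune" %in% stages) {
    if (!file.exists(ckpt("pretrain"))) {
      stop("ordered-stage error: pair-finetune requires the pretrain ",
           "checkpoint", call. = FALSE)
    }
    model <- load_checkpoint(ckpt("pretrain"))
    synth <- config$synth; synth$seed <- stage_seed(config, 2L)
    paired <- sample_repertoire(synth, config$n_paired)
    tc <- config$pair_finetune; tc$seed <- stage_seed(config, 2L)
    model <- finetune(model, paired, tc, stage = "paired", quiet = quiet)
    save_checkpoint(model, ckpt("pair-finetune"))
    readr::write_csv(paired[, c("id", "heavy", "light", "split")],
                     file.path(out_dir, "paired_corpus.csv"))
    paths$pair_finetune <- ckpt("pair-finetune")
  }
  if ("dev-finetune" %in% stages) {
    if (!file.exists(ckpt("pair-finetune"))) {
      stop("ordered-stage error: dev-finetune requires the pair-finetune ",
           "checkpoint", call. = FALSE)
    }
    model <- load_checkpoint(ckpt("pair-finetune"))
    paired <- readr::read_csv(file.path(out_dir, "paired_corpus.csv"),
                              show_col_types = FALSE)
    flags <- sample_flags(paired$id, seed = stage_seed(config, 3L))
    dev <- filter_developable(paired, flags)
    tc <- config$dev_finetune; tc$seed <- stage_seed(config, 3L)
    model <- finetune_developable(model, dev, tc, quiet = quiet)
    save_checkpoint(model, ckpt("dev-finetune"))
    paths$dev_finetune <- ckpt("dev-finetune")
  }
  if ("generate" %in% stages) {
    last <- rev(intersect(c("pretrain", "pair-finetune", "dev-finetune"),
                          basename(sub("\\.ckpt\\.rds$", "",
                                       list.files(out_dir, "ckpt.rds$")))))
    if (length(last) == 0L) {
      stop("ordered-stage error: generate requires a trained checkpoint",
           call. = FALSE)
    }
    model <- load_checkpoint(ckpt(last[1]))
    sc <- config$sampler; sc$seed <- stage_seed(config, 4L)
    gen <- generate_pairs(model, config$n_generate, sc, germ)
    out <- gen[gen$kept, c("heavy", "light", "log_likelihood", "boundary",
                           "split_score")]
    out$id <- sprintf("gen%05d", seq_len(nrow(out)))
    write_paired_sequences(out, file.path(out_dir, "generated.fasta"))
    readr::write_csv(out[, c("id", "heavy", "light", "log_likelihood",
                             "boundary", "split_score")],
                     file.path(out_dir, "generated.csv"))
    paths$generated <- file.path(out_dir, "generated.csv")
  }
  if ("evaluate" %in% stages) {
    gp <- file.path(out_dir, "generated.csv")
    pc <- file.path(out_dir, "paired_corpus.csv")
    if (!file.exists(gp) || !file.exists(pc)) {
      stop("ordered-stage error: evaluate requires generated.csv and ",
           "paired_corpus.csv", call. = FALSE)
    }
    last <- intersect(c("dev-finetune", "pair-finetune", "pretrain"),
                      basename(sub("\\.ckpt\\.rds$", "",
                                   list.files(out_dir, "ckpt.rds$"))))
    model <- load_checkpoint(ckpt(last[1]))
    gen <- readr::read_csv(gp, show_col_types = FALSE)
    paired <- readr::read_csv(pc, show_col_types = FALSE)
    ref <- paired[paired$split == "validation", , drop = FALSE]
    if (nrow(ref) < 2L) ref <- paired
    met <- repertoire_metrics(model, gen, ref, germ,
                              seed = stage_seed(config, 5L))
    readr::write_csv(generics::tidy(met), file.path(out_dir, "metrics.csv"))
    paths$metrics <- file.path(out_dir, "metrics.csv")
  }
  invisible(paths)
}

#' Write / read a run configuration as YAML
#'
#' Lossless round-trip of the scalar fields of an [run_config()] (germline
#' pools are re-expanded from [synthetic_germlines()] unless a `germlines`
#' block is present).
#'
#' @param config An `fv_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    if (!is.null(x$germlines)) {
      x$germlines <- as.list(x$germlines[, c("name", "chain", "seq")])
    }
    x
  }
  obj <- lapply(unclass(config), function(x) {
    if (is.list(x)) strip(x) else x
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  synth_args <- obj$synth
  if (!is.null(synth_args$germlines)) {
    gl <- tibble::as_tibble(synth_args$germlines)
    full <- synthetic_germlines()
    synth_args$germlines <- if (all(gl$name %in% full$name)) {
      full[match(gl$name, full$name), ]
    } else gl
  }
  synth_args$pairing_rule <- unlist(synth_args$pairing_rule)
  synth_args$cdr3_length_distribution <- unlist(synth_args$cdr3_length_distribution)
  run_config(
    model = do.call(model_config, obj$model),
    synth = do.call(synthetic_config, synth_args),
    pretrain = do.call(train_config, obj$pretrain),
    pair_finetune = do.call(train_config, obj$pair_finetune),
    dev_finetune = do.call(train_config, obj$dev_finetune),
    sampler = do.call(sampler_config, obj$sampler),
    n_unpaired = obj$n_unpaired, n_paired = obj$n_paired,
    n_generate = obj$n_generate, seed = obj$seed
  )
}
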