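#' Training configuration
#'
#' Hyperparameters for autoregressive training. The published stages used
#' Adam with a cosine learning-rate schedule: pretraining at peak learning
#' rate 1e-4 with batch size 512 and 4 gradient-accumulation steps for 20
#' epochs; paired finetuning at 1e-5 / batch 256 for 3 epochs; developable
#' finetuning at the same settings for 2 epochs. Warmup is not part of the
#' published recipe; the default here is 1% of total steps, with
#' `min_lr = 0.1 * peak_lr`.
#'
#' @param peak_lr Peak learning rate.
#' @param epochs Training epochs.
#' @param batch_size Sequences per optimizer micro-batch.
#' @param grad_accum_steps Micro-batches accumulated per optimizer update
#'   (effective batch = `batch_size * grad_accum_steps`).
#' @param min_lr Floor of the cosine decay (default `0.1 * peak_lr`).
#' @param warmup_frac Fraction of total steps used for linear warmup.
#' @param seed Seed controlling shuffling and direction augmentation.
#' @param max_stream_length Streams longer than this are rejected.
#' @param validation_metric Either `"loss"` or `"pair_gap"`; with
#'   `"pair_gap"`, early stopping tracks the true-vs-randomly-paired
#'   validation likelihood gap and stops when it stops improving.
#' @param adam_beta1,adam_beta2,adam_eps Adam moments (no weight decay).
#' @return An `fv_train_config` list.
#' @export
train_config <- function(peak_lr = 1e-4, epochs = 20L, batch_size = 512L,
                         grad_accum_steps = 4L, min_lr = 0.1 * peak_lr,
                         warmup_frac = 0.01, seed = 0L,
                         max_stream_length = 1024L,
                         validation_metric = c("loss", "pair_gap"),
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(peak_lr >= 0, epochs >= 0, batch_size >= 1, grad_accum_steps >= 1,
            min_lr >= 0, min_lr <= peak_lr, warmup_frac >= 0, warmup_frac < 1)
  structure(list(
    peak_lr = peak_lr, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    grad_accum_steps = as.integer(grad_accum_steps),
    min_lr = min_lr, warmup_frac = warmup_frac, seed = as.integer(seed),
    max_stream_length = as.integer(max_stream_length),
    validation_metric = match.arg(validation_metric),
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps
  ), class = "fv_train_config")
}

#' Cosine learning-rate schedule with linear warmup
#'
#' Linear warmup from 0 to `peak_lr` over the warmup steps, then cosine
#' decay `min_lr + (peak_lr - min_lr) * (1 + cos(pi * progress)) / 2` down
#' to `min_lr` at `total_steps`.
#'
#' @param step Current optimizer step (0-based).
#' @param total_steps Total optimizer steps in the run.
#' @param config An [train_config()].
#' @return Learning rate for the step.
#' @export
cosine_lr <- function(step, total_steps, config) {
  if (any(step > total_steps)) {
    stop("step exceeds total_steps", call. = FALSE)
  }
  warmup <- floor(config$warmup_frac * total_steps)
  ifelse(step < warmup & warmup > 0,
         config$peak_lr * step / warmup,
         {
           prog <- if (total_steps > warmup) (step - warmup) / (total_steps - warmup) else 1
           config$min_lr + (config$peak_lr - config$min_lr) * (1 + cos(pi * prog)) / 2
         })
}

#' Bidirectional direction augmentation
#'
#' Encodes each corpus item forward or reverse with probability 1/2,
#' independently; called afresh every epoch so each sequence is seen in both
#' directions over training.
#'
#' @param items Tibble of corpus items: paired rows (`heavy`, `light`) or
#'   single-chain rows (`seq`).
#' @param vocab An [fv_vocabulary()].
#' @param max_positions Longest allowed stream.
#' @param forced Optional `"forward"`/`"reverse"` to disable randomness.
#' @return List of [fv_stream()]s. Uses the current RNG state; seed at the
#'   call site for reproducibility.
#' @export
direction_augment <- function(items, vocab = fv_vocabulary(),
                              max_positions = 1024L, forced = NULL) {
  n <- nrow(items)
  dirs <- if (is.null(forced)) {
    ifelse(stats::runif(n) < 0.5, "forward", "reverse")
  } else rep(forced, n)
  if (!is.null(items[["heavy"]])) {
    purrr::pmap(list(items$heavy, items$light, dirs),
                function(h, l, d) encode_pair(h, l, d, vocab, max_positions))
  } else {
    purrr::map2(items$seq, dirs,
                function(s, d) encode_chain(s, d, vocab, max_positions))
  }
}

#' Train an autoregressive model
#'
#' Minimizes mean next-token cross-entropy (sentinels predicted, padding
#' excluded) with Adam under the cosine schedule, drawing each sequence in a
#' random direction every epoch. Deterministic for a fixed seed on one
#' device.
#'
#' `finetune()` is the same mechanics with all parameters trainable (no
#' freezing) — used for the unpaired-to-paired and paired-to-developable
#' stages; it tags the checkpoint metadata with the stage name.
#'
#' @param model An `fv_model` (initialized or previously trained).
#' @param corpus Tibble of training items (`heavy`+`light` columns, or `seq`
#'   for the unpaired stage). An optional `split` column restricts training
#'   to `split == "train"` and monitors `split == "validation"`.
#' @param config An [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `fv_model`; per-epoch loss history is appended to
#'   `model$meta$history` (a tibble with epoch, mean train loss, validation
#'   loss, the true-vs-randomly-paired validation likelihood gap when
#'   `validation_metric = "pair_gap"`, and learning rate). With
#'   `"pair_gap"`, training stops early once that gap stops improving.
#' @export
train_lm <- function(model, corpus, config = train_config(), quiet = FALSE) {
  stopifnot(inherits(model, "fv_model"), inherits(config, "fv_train_config"))
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    stop("corpus must be a non-empty data frame", call. = FALSE)
  }
  has_split <- !is.null(corpus[["split"]])
  train_items <- if (has_split) corpus[corpus$split == "train", , drop = FALSE] else corpus
  val_items <- if (has_split) corpus[corpus$split == "validation", , drop = FALSE] else corpus[0, ]
  if (nrow(train_items) == 0L) stop("no training items in corpus", call. = FALSE)
  if (config$epochs == 0L) return(model)

  maxlen <- min(config$max_stream_length, model$config$max_positions)
  n <- nrow(train_items)
  steps_per_epoch <- ceiling(n / config$batch_size / config$grad_accum_steps)
  total_steps <- steps_per_epoch * config$epochs
  opt <- adam_init(model$w)
  history <- list()
  val_streams <- if (nrow(val_items) > 0) {
    with_seed(config$seed + 1L,
              direction_augment(val_items, model$vocab, maxlen, forced = "forward"))
  }
  track_gap <- config$validation_metric == "pair_gap" &&
    !is.null(val_streams) && !is.null(val_items[["heavy"]]) &&
    nrow(val_items) >= 2L
  gap_shuffled <- if (track_gap) {
    with_seed(config$seed + 2L,
              direction_augment(random_pairing_control(val_items,
                                                       seed = config$seed + 3L),
                                model$vocab, maxlen, forced = "forward"))
  }
  best_gap <- -Inf
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      streams <- direction_augment(train_items[ord, , drop = FALSE],
                                   model$vocab, maxlen)
      micro <- split(seq_len(n),
                     ceiling(seq_len(n) / config$batch_size))
      acc <- NULL; acc_k <- 0L; acc_ntok <- 0
      epoch_loss <- 0; epoch_ntok <- 0
      lr_last <- NA_real_
      for (mi in seq_along(micro)) {
        mb <- micro[[mi]]
        ba <- streams_to_batch(streams[mb])
        res <- model_grad_fast(model, ba$tokens, ba$lens)
        ntok <- sum(ba$lens - 1L)
        epoch_loss <- epoch_loss + res$loss * ntok
        epoch_ntok <- epoch_ntok + ntok
        # token-weighted accumulation: the effective batch's mean-loss
        # gradient, so (batch 2b, accum 1) == (batch b, accum 2) exactly
        scaled <- map_params(res$grads, res$grads, function(g, .) g * ntok)
        acc <- if (is.null(acc)) scaled else map_params(acc, scaled, `+`)
        acc_k <- acc_k + 1L
        acc_ntok <- acc_ntok + ntok
        if (acc_k == config$grad_accum_steps || mi == length(micro)) {
          tot <- acc_ntok
          grads <- map_params(acc, acc, function(a, .) a / tot)
          lr <- cosine_lr(step, total_steps, config)
          upd <- adam_step(model$w, grads, opt, lr, config)
          model$w <- upd$w; opt <- upd$opt
          step <- step + 1L
          lr_last <- lr
          acc <- NULL; acc_k <- 0L; acc_ntok <- 0
        }
      }
      val_loss <- NA_real_
      pair_gap <- NA_real_
      if (!is.null(val_streams)) {
        vb <- streams_to_batch(val_streams)
        val_loss <- model_loss(model, vb$tokens, vb$lens)
        if (track_gap) {
          true_ll <- mean(sequence_log_likelihood(model, val_streams))
          shuf_ll <- mean(sequence_log_likelihood(model, gap_shuffled))
          pair_gap <- true_ll - shuf_ll
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss / epoch_ntok,
        val_loss = val_loss, pair_gap = pair_gap, lr = lr_last)
      if (!quiet) {
        message(sprintf("epoch %d/%d  train loss %.4f%s%s", epoch, config$epochs,
                        epoch_loss / epoch_ntok,
                        if (!is.na(val_loss)) sprintf("  val loss %.4f", val_loss) else "",
                        if (!is.na(pair_gap)) sprintf("  pair gap %.4f", pair_gap) else ""))
      }
      # stop the stage once the true-vs-randomly-paired validation
      # likelihood gap stops improving (minimum-epochs stopping rule)
      if (track_gap && !is.na(pair_gap)) {
        if (pair_gap <= best_gap) break
        best_gap <- pair_gap
      }
    }
  })
  model$meta$epochs_trained <- model$meta$epochs_trained + length(history)
  model$meta$history <- dplyr::bind_rows(model$meta$history, history)
  if (identical(model$meta$stage, "initialized")) model$meta$stage <- "trained"
  model
}

#' @rdname train_lm
#' @param stage Stage label recorded in checkpoint metadata (for example
#'   `"paired"` or `"developable"`).
#' @export
finetune <- function(model, corpus, config = train_config(peak_lr = 1e-5,
                                                          epochs = 3L,
                                                          batch_size = 256L,
                                                          grad_accum_steps = 1L),
                     stage = "finetuned", quiet = FALSE) {
  model <- train_lm(model, corpus, config, quiet = quiet)
  model$meta$stage <- stage
  model
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(w) {
  z <- empty_grads(w)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(w, grads, opt, lr, config) {
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  opt$t <- opt$t + 1L
  opt$m <- map_params(opt$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  opt$v <- map_params(opt$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  mhat <- map_params(opt$m, opt$m, function(m, .) m / bc1)
  vhat <- map_params(opt$v, opt$v, function(v, .) v / bc2)
  upd <- map_params(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(w = map_params(w, upd, `-`), opt = opt)
}
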