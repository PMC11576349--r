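# Shared fixtures. Everything is generated in code; toy models and corpora
# are kept small enough that the whole suite runs on one CPU.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2L, n_heads = 2L, d_model = 16L, d_ff = 32L,
         vocab_size = 26L, max_positions = 96L), list(...))
  do.call(model_config, args)
}

# short Fv-like pairs: truncated germline prefixes with a few substitutions,
# so streams stay ~50-70 tokens and toy training is fast
toy_pairs <- function(n_distinct = 5L, chain_len = 28L, n_mut = 2L,
                      seed = 42L) {
  g <- synthetic_germlines()
  gh <- g$seq[g$chain == "VH"]
  gl <- g$seq[g$chain == "VL"]
  set.seed(seed)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    ch[pos] <- vapply(pos, function(p) sample(setdiff(AA_STANDARD, ch[p]), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  tibble::tibble(
    heavy = vapply(seq_len(n_distinct), function(i)
      mut(substr(gh[(i - 1L) %% length(gh) + 1L], 1, chain_len), n_mut),
      character(1)),
    light = vapply(seq_len(n_distinct), function(i)
      mut(substr(gl[(i - 1L) %% length(gl) + 1L], 1, chain_len), n_mut),
      character(1))
  )
}

toy_corpus <- function(n_distinct = 5L, n_copies = 40L, ...) {
  base <- toy_pairs(n_distinct, ...)
  base[rep(seq_len(n_distinct), n_copies), , drop = FALSE]
}

# a tiny model overfit on a handful of short pairs; trained lazily once per
# test run and reused across files
.toy_env <- new.env(parent = emptyenv())

toy_trained_model <- function() {
  if (is.null(.toy_env$model)) {
    corpus <- toy_corpus(n_distinct = 5L, n_copies = 40L, seed = 42L)
    model <- init_model(tiny_config(), seed = 11L)
    cfgt <- train_config(peak_lr = 5e-3, epochs = 25L, batch_size = 10L,
                         grad_accum_steps = 1L, seed = 13L,
                         max_stream_length = 96L)
    .toy_env$model <- suppressMessages(train_lm(model, corpus, cfgt,
                                                quiet = TRUE))
    .toy_env$corpus <- corpus
  }
  .toy_env$model
}

toy_trained_corpus <- function() {
  invisible(toy_trained_model())
  .toy_env$corpus
}

random_chain <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

# brute-force Needleman-Wunsch (match +1 / mismatch -1 / gap -2): the
# independent oracle for alignment scores
nw_oracle <- function(s, g) {
  s <- utf8ToInt(s); g <- utf8ToInt(g)
  n <- length(s); m <- length(g)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -2 * (0:n); F[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    F[i + 1, j + 1] <- max(F[i, j] + ifelse(s[i] == g[j], 1, -1),
                           F[i, j + 1] - 2, F[i + 1, j] - 2)
  }
  F[n + 1, m + 1]
}
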