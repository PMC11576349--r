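test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- model_config(n_layers = 2L, n_heads = 2L, d_model = 8L, d_ff = 16L,
                      vocab_size = 26L, max_positions = 16L)
  m <- init_model(cfg, seed = 42)
  set.seed(7)
  tokens <- rbind(c(2L, sample(4:23, 6, TRUE), 3L, 1L, 1L),
                  c(2L, sample(4:23, 8, TRUE), 3L))
  lens <- c(8L, 10L)
  gr <- fvgen:::model_grad(m, tokens, lens)
  eps <- 1e-6
  fd <- function(mutate, read) {
    m2 <- mutate(m, +eps); up <- fvgen:::model_loss(m2, tokens, lens)
    m2 <- mutate(m, -eps); dn <- fvgen:::model_loss(m2, tokens, lens)
    c(fd = (up - dn) / (2 * eps), an = read(gr$grads))
  }
  checks <- list(
    fd(function(m, e) { m$w$tok_emb[5, 3] <- m$w$tok_emb[5, 3] + e; m },
       function(g) g$tok_emb[5, 3]),
    fd(function(m, e) { m$w$pos_emb[2, 4] <- m$w$pos_emb[2, 4] + e; m },
       function(g) g$pos_emb[2, 4]),
    fd(function(m, e) { m$w$layers[[1]]$w_qkv[3, 20] <- m$w$layers[[1]]$w_qkv[3, 20] + e; m },
       function(g) g$layers[[1]]$w_qkv[3, 20]),
    fd(function(m, e) { m$w$layers[[2]]$w_o[4, 2] <- m$w$layers[[2]]$w_o[4, 2] + e; m },
       function(g) g$layers[[2]]$w_o[4, 2]),
    fd(function(m, e) { m$w$layers[[1]]$w_f1[6, 11] <- m$w$layers[[1]]$w_f1[6, 11] + e; m },
       function(g) g$layers[[1]]$w_f1[6, 11]),
    fd(function(m, e) { m$w$layers[[2]]$ln1_g[3] <- m$w$layers[[2]]$ln1_g[3] + e; m },
       function(g) g$layers[[2]]$ln1_g[3]),
    fd(function(m, e) { m$w$lnf_b[2] <- m$w$lnf_b[2] + e; m },
       function(g) g$lnf_b[2]),
    fd(function(m, e) { m$w$layers[[2]]$w_f2[10, 5] <- m$w$layers[[2]]$w_f2[10, 5] + e; m },
       function(g) g$layers[[2]]$w_f2[10, 5])
  )
  for (ch in checks) {
    expect_equal(ch[["an"]], ch[["fd"]],
                 tolerance = max(1e-4, 1e-5 / max(abs(ch[["fd"]]), 1e-8)))
  }
})

test_that("cosine schedule hits its endpoints and midpoint", {
  cfg <- train_config(peak_lr = 1e-3, min_lr = 0, warmup_frac = 0.1)
  expect_equal(cosine_lr(10, 100, cfg), 1e-3)           # end of warmup
  expect_equal(cosine_lr(100, 100, cfg), 0)             # end of decay
  expect_equal(cosine_lr(55, 100, cfg), 5e-4)           # midpoint of decay
  expect_equal(cosine_lr(5, 100, cfg), 5e-4)            # mid-warmup
  expect_error(cosine_lr(101, 100, cfg), "exceeds")
  cfg2 <- train_config(peak_lr = 1e-3, min_lr = 1e-4, warmup_frac = 0)
  expect_equal(cosine_lr(0, 10, cfg2), 1e-3)
  expect_equal(cosine_lr(10, 10, cfg2), 1e-4)
})

test_that("direction augmentation is balanced, seeded, and forceable", {
  items <- toy_pairs(2L)[c(1, 2, 1, 2), ]
  items <- items[rep(1:4, 2500), ]                      # 10,000 items
  set.seed(1)
  streams <- direction_augment(items, max_positions = 96L)
  dirs <- vapply(streams, function(s) s$direction, character(1))
  expect_gte(mean(dirs == "forward"), 0.47)
  expect_lte(mean(dirs == "forward"), 0.53)
  set.seed(9); a <- direction_augment(items[1:50, ], max_positions = 96L)
  set.seed(9); b <- direction_augment(items[1:50, ], max_positions = 96L)
  expect_identical(a, b)
  f <- direction_augment(items[1:20, ], max_positions = 96L,
                         forced = "forward")
  expect_true(all(vapply(f, function(s) s$direction, character(1)) ==
                    "forward"))
})

test_that("zero epochs and zero learning rate leave the model unchanged", {
  m <- init_model(tiny_config(), seed = 2)
  corpus <- toy_pairs(3L)
  cfg0 <- train_config(epochs = 0L, seed = 1)
  expect_identical(train_lm(m, corpus, cfg0), m)
  cfg_lr0 <- train_config(peak_lr = 0, min_lr = 0, epochs = 2L,
                          batch_size = 4L, grad_accum_steps = 1L, seed = 1)
  m2 <- suppressMessages(finetune(m, corpus, cfg_lr0, quiet = TRUE))
  expect_equal(m2$w, m$w, tolerance = 1e-15)
})

test_that("gradient accumulation reproduces the large-batch trajectory", {
  m <- init_model(tiny_config(), seed = 6)
  corpus <- toy_pairs(8L)
  base <- train_config(peak_lr = 1e-3, epochs = 2L, batch_size = 8L,
                       grad_accum_steps = 1L, seed = 4, warmup_frac = 0)
  acc <- train_config(peak_lr = 1e-3, epochs = 2L, batch_size = 4L,
                      grad_accum_steps = 2L, seed = 4, warmup_frac = 0)
  m_base <- suppressMessages(train_lm(m, corpus, base, quiet = TRUE))
  m_acc <- suppressMessages(train_lm(m, corpus, acc, quiet = TRUE))
  fa <- unlist(fvgen:::flatten_params(m_base$w))
  fb <- unlist(fvgen:::flatten_params(m_acc$w))
  expect_lt(max(abs(fa - fb)) / max(abs(fa)), 1e-5)
})

test_that("every parameter tensor receives gradient on a nontrivial batch", {
  m <- init_model(tiny_config(), seed = 3)
  set.seed(2)
  tokens <- rbind(c(2L, sample(4:23, 10, TRUE), 3L),
                  c(2L, sample(4:23, 10, TRUE), 3L))
  gr <- fvgen:::model_grad(m, tokens, c(12L, 12L))
  flat <- fvgen:::flatten_params(gr$grads)
  nonzero <- vapply(flat, function(x) any(x != 0), logical(1))
  expect_true(all(nonzero))
})

test_that("a tiny model overfits a small distinct-pair corpus", {
  m <- toy_trained_model()
  h <- tidy(m)
  expect_lt(h$train_loss[nrow(h)], 0.25 * h$train_loss[1])
})

test_that("training is reproducible end to end for a fixed seed", {
  corpus <- toy_corpus(n_distinct = 3L, n_copies = 4L)
  cfgt <- train_config(peak_lr = 2e-3, epochs = 2L, batch_size = 6L,
                       grad_accum_steps = 1L, seed = 8)
  m1 <- suppressMessages(train_lm(init_model(tiny_config(), seed = 1),
                                  corpus, cfgt, quiet = TRUE))
  m2 <- suppressMessages(train_lm(init_model(tiny_config(), seed = 1),
                                  corpus, cfgt, quiet = TRUE))
  expect_identical(m1$w, m2$w)
  expect_identical(m1$meta$history, m2$meta$history)
})

test_that("paired finetuning after unpaired pretraining lowers paired validation loss and separates true from shuffled pairings", {
  # staged toy run: unpaired chains first, then paired sequences with a
  # family pairing rule; the criterion mirrors validating by the
  # true-vs-randomly-paired likelihood gap
  g <- synthetic_germlines()
  synth <- synthetic_config(seed = 55L, pairing_adherence = 1)
  rep_ <- sample_repertoire(synth, 60L)
  short <- tibble::tibble(heavy = substr(rep_$heavy, 1, 30),
                          light = substr(rep_$light, 1, 30),
                          split = rep_$split)
  unpaired <- tibble::tibble(seq = c(short$heavy, short$light),
                             split = rep(short$split, 2))
  m <- init_model(tiny_config(), seed = 9)
  m <- suppressMessages(train_lm(
    m, unpaired, train_config(peak_lr = 3e-3, epochs = 4L, batch_size = 30L,
                              grad_accum_steps = 1L, seed = 2), quiet = TRUE))
  val <- short[short$split == "validation", ]
  if (nrow(val) < 4L) val <- short[1:6, ]
  val_streams <- purrr::map2(val$heavy, val$light, encode_pair,
                             direction = "forward", vocab = m$vocab)
  vb <- fvgen:::streams_to_batch(val_streams)
  pre_loss <- fvgen:::model_loss(m, vb$tokens, vb$lens)
  m2 <- suppressMessages(finetune(
    m, short, train_config(peak_lr = 2e-3, epochs = 6L, batch_size = 30L,
                           grad_accum_steps = 1L, seed = 3),
    stage = "paired", quiet = TRUE))
  post_loss <- fvgen:::model_loss(m2, vb$tokens, vb$lens)
  expect_lt(post_loss, pre_loss)
  # held-out true pairs beat the same chains randomly re-paired
  true_ll <- mean(sequence_log_likelihood(m2, val_streams))
  shuf <- random_pairing_control(val, seed = 12)
  shuf_streams <- purrr::map2(shuf$heavy, shuf$light, encode_pair,
                              direction = "forward", vocab = m2$vocab)
  expect_gt(true_ll, mean(sequence_log_likelihood(m2, shuf_streams)))
})

test_that("pair-gap validation tracking stops when the gap stops improving", {
  synth <- synthetic_config(seed = 61L, pairing_adherence = 1)
  rep_ <- sample_repertoire(synth, 50L)
  corpus <- tibble::tibble(heavy = substr(rep_$heavy, 1, 25),
                           light = substr(rep_$light, 1, 25),
                           split = rep(c("train", "validation"),
                                       c(40L, 10L)))
  m <- init_model(tiny_config(), seed = 3L)
  cfgt <- train_config(peak_lr = 3e-3, epochs = 8L, batch_size = 8L,
                       grad_accum_steps = 1L, seed = 2L,
                       validation_metric = "pair_gap")
  m2 <- suppressMessages(train_lm(m, corpus, cfgt, quiet = TRUE))
  h <- tidy(m2)
  expect_true("pair_gap" %in% names(h))
  expect_true(all(is.finite(h$pair_gap)))
  expect_lte(nrow(h), 8L)
  expect_equal(m2$meta$epochs_trained, nrow(h))
  # stopped runs end on a non-improving gap
  if (nrow(h) < 8L) {
    expect_lte(h$pair_gap[nrow(h)], max(h$pair_gap[-nrow(h)]))
  }
})
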