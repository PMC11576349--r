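test_that("the full-scale configuration has exactly 17,349,888 parameters", {
  expect_identical(count_parameters(model_config()), 17349888L)
})

test_that("closed-form parameter count equals tensor enumeration", {
  cfg <- tiny_config(n_layers = 1L, n_heads = 2L, d_model = 8L, d_ff = 16L,
                     vocab_size = 26L, max_positions = 32L)
  m <- init_model(cfg, seed = 1)
  expect_identical(count_parameters(cfg),
                   fvgen:::count_parameters_enumerated(m))
  set.seed(99)
  for (i in 1:20) {
    h <- sample(c(1L, 2L, 4L), 1)
    cfg <- model_config(
      n_layers = sample(1:3, 1), n_heads = h,
      d_model = h * 2L * sample(1:6, 1), d_ff = sample(c(8L, 16L, 40L), 1),
      vocab_size = sample(24:30, 1), max_positions = sample(16:64, 1),
      tie_embeddings = sample(c(TRUE, FALSE), 1),
      use_learned_positions = sample(c(TRUE, FALSE), 1))
    m <- init_model(cfg, seed = i)
    expect_identical(count_parameters(cfg),
                     fvgen:::count_parameters_enumerated(m))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(n_heads = 5L, d_model = 768L), "divisible")
  expect_error(model_config(vocab_size = 20L), "at least 24")
})

test_that("initialization is seed-deterministic and causal", {
  cfg <- tiny_config()
  expect_identical(init_model(cfg, seed = 7)$w, init_model(cfg, seed = 7)$w)
  expect_false(identical(init_model(cfg, seed = 7)$w,
                         init_model(cfg, seed = 8)$w))
  m <- init_model(cfg, seed = 7)
  # perturbing tokens after position t never changes logits at position t
  base <- c(2L, 5L, 9L, 12L, 17L, 3L)
  fw1 <- fvgen:::model_forward(m, matrix(base, 1), 6L)$logits
  for (t in 2:5) {
    alt <- base
    alt[(t + 1):6] <- sample(4:23, 6 - t, replace = TRUE)
    fw2 <- fvgen:::model_forward(m, matrix(alt, 1), 6L)$logits
    expect_equal(fw1[1:t, ], fw2[1:t, ], tolerance = 1e-12)
  }
})

test_that("softmax rows are proper distributions at every position", {
  m <- init_model(tiny_config(), seed = 3)
  fw <- fvgen:::model_forward(m, matrix(c(2L, 8L, 15L, 21L, 3L), 1), 5L)
  p <- exp(fvgen:::log_softmax_rows(fw$logits))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("a zero-embedding model is uniform: closed-form likelihood and perplexity", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 1)
  m$w$tok_emb[] <- 0   # tied output projection -> all logits zero -> uniform
  V <- cfg$vocab_size
  probs <- exp(fvgen:::log_softmax_rows(
    fvgen:::model_forward(m, matrix(c(2L, 5L, 6L, 3L), 1), 4L)$logits))
  expect_equal(probs, matrix(1 / V, 4, V), tolerance = 1e-12)
  for (n in c(2L, 5L, 9L)) {
    s <- fv_stream(c(2L, rep(5L, n - 2L), 3L), "forward")
    expect_equal(sequence_log_likelihood(m, s), (n - 1) * log(1 / V),
                 tolerance = 1e-10)
    expect_equal(perplexity(m, s), V, tolerance = 1e-8)
  }
})

test_that("sequence likelihood matches the position-wise chain-rule oracle", {
  m <- toy_trained_model()
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    toks <- c(2L, sample(4:23, n - 2L, replace = TRUE), 3L)
    ll <- sequence_log_likelihood(m, fv_stream(toks, "forward"))
    oracle <- 0
    for (t in 2:n) {
      lg <- next_token_logits(m, toks[1:(t - 1)])
      oracle <- oracle + (lg[toks[t]] - log(sum(exp(lg - max(lg)))) - max(lg))
    }
    expect_equal(ll, oracle, tolerance = 1e-10)
    expect_lt(ll, 0)
    # appending tokens never increases total log-likelihood
    ll_ext <- sequence_log_likelihood(m, fv_stream(c(toks, 5L), "forward"))
    expect_lte(ll_ext, ll)
    # perplexity identity
    expect_equal(perplexity(m, fv_stream(toks, "forward")),
                 exp(-ll / (n - 1)), tolerance = 1e-12)
  }
})

test_that("prefix scoring rejects empty and overlong prefixes", {
  m <- init_model(tiny_config(max_positions = 8L), seed = 2)
  expect_error(next_token_logits(m, integer(0)), "non-empty")
  expect_error(next_token_logits(m, rep(5L, 9L)), "max_positions")
  expect_equal(next_token_logits(m, c(2L, 5L)),
               next_token_logits(m, c(2L, 5L)))
})

test_that("a trained model assigns lower perplexity to training sequences than to shuffled ones", {
  m <- toy_trained_model()
  corpus <- toy_trained_corpus()
  pairs <- unique(corpus)
  streams <- purrr::map2(pairs$heavy, pairs$light, encode_pair,
                         direction = "forward", vocab = m$vocab)
  set.seed(4)
  shuffled <- lapply(streams, function(s) {
    interior <- s$tokens[-c(1, length(s$tokens))]
    fv_stream(c(s$tokens[1], sample(interior), s$tokens[length(s$tokens)]),
              "forward")
  })
  expect_lt(mean(perplexity(m, streams)), mean(perplexity(m, shuffled)))
})

test_that("checkpoints round-trip bitwise", {
  m <- init_model(tiny_config(), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_identical(load_checkpoint(path), m)
  expect_true(file.exists(paste0(path, ".meta.json")))
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("embeddings are deterministic, pooled to d_model, and identical for identical input", {
  m <- toy_trained_model()
  pairs <- toy_pairs(3L)
  emb <- embed_sequences(m, pairs[c(1, 1, 2, 3), ])
  expect_equal(ncol(emb), m$config$d_model)
  expect_equal(emb[1, ], emb[2, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(emb[1, ], emb[3, ])))
  expect_equal(emb, embed_sequences(m, pairs[c(1, 1, 2, 3), ]))
})
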