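test_that("nucleus filter keeps the minimal prefix and renormalizes", {
  expect_equal(nucleus_filter(c(0.5, 0.3, 0.15, 0.05), 0.8),
               c(0.625, 0.375, 0, 0))
  p <- c(0.1, 0.4, 0.2, 0.3)
  expect_equal(nucleus_filter(p, 1.0), p)
  # top_p <= max(probs): one-hot on the argmax
  expect_equal(nucleus_filter(p, 0.3), c(0, 1, 0, 0))
  # ties broken by token index
  expect_equal(nucleus_filter(c(0.25, 0.25, 0.25, 0.25), 0.5),
               c(0.5, 0.5, 0, 0))
  expect_error(nucleus_filter(p, 0), "positive")
  expect_error(nucleus_filter(c(0.5, 0.2), 0.9), "sum to 1")
  # output is always a distribution with minimal support
  set.seed(2)
  for (i in 1:25) {
    q <- stats::runif(8); q <- q / sum(q)
    tp <- stats::runif(1, 0.05, 1)
    out <- nucleus_filter(q, tp)
    expect_equal(sum(out), 1)
    kept <- which(out > 0)
    expect_gte(sum(q[kept]), tp - 1e-12)
    # removing the smallest kept token would drop below top_p
    if (length(kept) > 1) {
      drop <- kept[which.min(q[kept])]
      expect_lt(sum(q[setdiff(kept, drop)]), tp)
    }
  }
})

test_that("empirical next-token frequencies match the analytic temperature+nucleus transform", {
  logits <- c(1.0, 0.2, -0.6)     # hand-set 3-token toy model
  temperature <- 1.2; top_p <- 0.95
  target <- fvgen:::transform_logits(logits, temperature, top_p)
  n <- 10000L
  set.seed(123)
  draws <- replicate(n, sample_next_token(logits, temperature, top_p))
  freq <- tabulate(draws, nbins = 3) / n
  for (k in 1:3) {
    se <- sqrt(target[k] * (1 - target[k]) / n)
    expect_lt(abs(freq[k] - target[k]), 3 * se + 1e-12)
  }
  # goodness of fit at alpha = 0.01
  expect_gt(stats::chisq.test(tabulate(draws, 3), p = target)$p.value, 0.01)
})

test_that("sampling is seeded-deterministic and greedy mode is the argmax limit", {
  m <- toy_trained_model()
  sc <- sampler_config(max_new_tokens = 80L, seed = 31L)
  r1 <- sample_streams(m, 6L, sc)
  r2 <- sample_streams(m, 6L, sc)
  expect_identical(r1$stream, r2$stream)
  g1 <- sample_streams(m, 2L, sampler_config(greedy = TRUE, seed = 1L,
                                             max_new_tokens = 80L),
                       direction = "forward")
  g2 <- sample_streams(m, 2L, sampler_config(greedy = TRUE, seed = 2L,
                                             max_new_tokens = 80L),
                       direction = "forward")
  expect_identical(g1$stream[[1]]$tokens, g2$stream[[1]]$tokens)
})

test_that("reported generation likelihoods equal full-forward recomputation", {
  m <- toy_trained_model()
  res <- sample_streams(m, 6L, sampler_config(max_new_tokens = 80L,
                                              seed = 17L))
  ok <- which(!res$truncated)
  expect_gte(length(ok), 1L)
  recomputed <- sequence_log_likelihood(m, res$stream[ok])
  expect_equal(res$log_likelihood[ok], recomputed, tolerance = 1e-8)
})

test_that("likelihood filter discards exactly the floor(fraction*n) lowest", {
  streams <- lapply(seq_len(20), function(i)
    fv_stream(c(2L, rep(5L, 10), 3L), "forward"))
  res <- tibble::tibble(stream = streams,
                        log_likelihood = -seq(1, 20))
  out <- likelihood_filter(res, 0.05)
  expect_equal(sum(!out$kept), 1L)
  expect_false(out$kept[20])                     # the minimum
  expect_equal(out$log_likelihood, res$log_likelihood)  # order preserved
  out19 <- likelihood_filter(res[1:19, ], 0.05)  # floor(0.95) = 0
  expect_true(all(out19$kept))
  out0 <- likelihood_filter(res, 0)
  expect_true(all(out0$kept))
  # length normalization changes the ranking when lengths differ
  res$stream[[20]] <- fv_stream(c(2L, rep(5L, 100), 3L), "forward")
  raw <- likelihood_filter(res, 0.05, length_normalize = FALSE)
  norm <- likelihood_filter(res, 0.05, length_normalize = TRUE)
  expect_false(raw$kept[20])
  expect_true(norm$kept[20])
})

test_that("generate_pairs validates n and produces internally consistent results", {
  m <- toy_trained_model()
  expect_error(generate_pairs(m, 0), "at least 1")
  g <- synthetic_germlines()
  short_germ <- g
  short_germ$seq <- substr(g$seq, 1, 28)
  res <- generate_pairs(m, 12L,
                        sampler_config(temperature = 0.8,
                                       max_new_tokens = 80L, seed = 3L),
                        germlines = short_germ, retry_factor = 8)
  expect_equal(nrow(res), 12L)
  expect_true(all(nchar(res$heavy) > 0))
  expect_true(all(nchar(res$light) > 0))
  expect_identical(paste0(res$heavy, res$light),
                   vapply(res$stream, decode_stream, character(1),
                          vocab = m$vocab))
  recomputed <- sequence_log_likelihood(m, res$stream)
  expect_equal(res$log_likelihood, recomputed, tolerance = 1e-8)
})

test_that("complete_chain preserves the given chain verbatim in both directions", {
  m <- toy_trained_model()
  corpus <- toy_trained_corpus()
  sc <- sampler_config(greedy = TRUE, max_new_tokens = 60L, seed = 2L)
  r <- complete_chain(m, corpus$heavy[1], "VH", sc)
  expect_identical(r$heavy, corpus$heavy[1])
  r2 <- complete_chain(m, corpus$light[1], "VL", sc)
  expect_identical(r2$light, corpus$light[1])
  # greedy completion from a fixed model is deterministic
  r3 <- complete_chain(m, corpus$light[1], "VL", sc)
  expect_identical(r2$heavy, r3$heavy)
  # reverse-direction round trip: the completed stream decodes to heavy+light
  if (!r2$truncated) {
    s <- encode_pair(r2$heavy, r2$light, "reverse", m$vocab)
    expect_identical(decode_stream(s, m$vocab), paste0(r2$heavy, r2$light))
  }
})

test_that("an overfit model regenerates its training pairs", {
  m <- toy_trained_model()
  corpus <- unique(toy_trained_corpus())
  res <- sample_streams(m, 20L, sampler_config(temperature = 0.6,
                                               max_new_tokens = 70L,
                                               seed = 5L),
                        direction = "forward")
  decoded <- vapply(res$stream[!res$truncated], function(s)
    tryCatch(decode_stream(s, m$vocab), error = function(e) ""),
    character(1))
  train_concat <- paste0(corpus$heavy, corpus$light)
  expect_gte(mean(decoded %in% train_concat), 0.5)
})
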