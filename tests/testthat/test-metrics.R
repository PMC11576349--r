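test_that("nearest-neighbour cosine diversity matches the brute-force oracle", {
  expect_equal(nn_cosine_diversity(rbind(c(1, 0), c(1, 0), c(1, 0))), 0)
  expect_equal(nn_cosine_diversity(rbind(c(1, 0), c(0, 1))), 1)
  expect_error(nn_cosine_diversity(matrix(1, 1, 3)), "at least 2")
  set.seed(14)
  X <- matrix(rnorm(200 * 6), 200)
  oracle <- mean(vapply(seq_len(200), function(i) {
    min(vapply(setdiff(seq_len(200), i), function(j) {
      1 - sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(nn_cosine_diversity(X), oracle, tolerance = 1e-12)
})

test_that("simulated repertoires recover the target mutation correlation; random pairing destroys it", {
  g <- synthetic_germlines()
  rep_ <- sample_repertoire(synthetic_config(seed = 606L), 2000L)
  r <- vhvl_mutation_correlation(rep_, g)
  expect_gt(r, 0.44 - 0.06)  # alignment recovery adds slight attenuation
  expect_lt(r, 0.56 + 0.02)
  ctrl <- vhvl_mutation_correlation(random_pairing_control(rep_, seed = 2L), g)
  expect_lt(abs(ctrl), 0.05)
  # degenerate margins raise
  flat <- tibble::tibble(heavy = rep(g$seq[g$chain == "VH"][1], 3),
                         light = rep(g$seq[g$chain == "VL"][1], 3))
  expect_error(vhvl_mutation_correlation(flat, g), "zero variance")
})

test_that("random pairing control conserves chains, is seeded, and is uniform", {
  pairs <- toy_pairs(5L)
  ctrl <- random_pairing_control(pairs, seed = 7L)
  expect_identical(sort(ctrl$light), sort(pairs$light))
  expect_identical(ctrl$heavy, pairs$heavy)
  expect_identical(random_pairing_control(pairs, seed = 7L), ctrl)
  counts <- matrix(0, 5, 5)
  for (s in 1:1000) {
    perm <- match(random_pairing_control(pairs, seed = s)$light, pairs$light)
    counts[cbind(seq_len(5), perm)] <- counts[cbind(seq_len(5), perm)] + 1
  }
  expect_true(all(abs(counts / 1000 - 0.2) <= 0.04))
})

test_that("Mann-Whitney comparison agrees with exhaustive enumeration and detects shifts", {
  # exhaustive U-statistic null for n = 4 vs 4, no ties
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(2.8, 6.1, 4.4, 7.3)
  pool <- c(a, b)
  combs <- utils::combn(8, 4)
  u_obs <- sum(vapply(a, function(x) sum(x > b), numeric(1)))
  u_all <- apply(combs, 2, function(ix) {
    aa <- pool[ix]; bb <- pool[-ix]
    sum(vapply(aa, function(x) sum(x > bb), numeric(1)))
  })
  p_exact <- mean(abs(u_all - 8) >= abs(u_obs - 8))  # symmetric two-sided
  expect_equal(compare_distributions(a, b), p_exact, tolerance = 1e-12)
  # identical samples: p = 1 within tolerance
  x <- c(1, 2, 3, 4, 5)
  expect_gt(compare_distributions(x, x), 0.99)
  # a 2-sigma shift at n = 200 is overwhelmingly detected
  set.seed(3)
  expect_lt(compare_distributions(rnorm(200), rnorm(200, 2)), 1e-3)
  expect_error(compare_distributions(rep(1, 4), rep(1, 4)), "degenerate")
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("pairing discrimination is exact under a rigged scorer", {
  g <- synthetic_germlines()
  rep_ <- sample_repertoire(synthetic_config(seed = 42L), 80L)
  truth <- stats::setNames(seq_len(80L), rep_$light)
  rigged <- function(heavy, light) {
    # true pairings (matching row index) get the top score
    ifelse(match(heavy, rep_$heavy) == match(light, rep_$light) &
             !is.na(match(light, rep_$light)), 1e6, stats::runif(length(heavy)))
  }
  pd <- pairing_discrimination(NULL, rep_, g, n_decoys = 20L, tolerance = 30L,
                               n_cases = 40L, score_fn = rigged, seed = 5L)
  expect_equal(pd$frac_top1, 1)
  expect_equal(pd$frac_above_random_mean, 1)
  expect_equal(pd$frac_top8, 1)
})

test_that("constant-score discrimination reproduces the uniform-rank null", {
  g <- synthetic_germlines()
  # 5000 replicate cases built from 120 distinct light chains
  rep_ <- sample_repertoire(synthetic_config(seed = 9L), 120L)
  big <- rep_[rep(seq_len(120L), length.out = 5000L), ]
  pd <- pairing_discrimination(NULL, big, g, n_decoys = 50L,
                               tolerance = 1000L, n_cases = Inf,
                               score_fn = function(h, l) rep(0, length(h)),
                               seed = 77L)
  n <- pd$n_cases
  expect_equal(n, 5000L)
  p1 <- 1 / 51; p8 <- 8 / 51
  expect_lt(abs(pd$frac_top1 - p1), 3 * sqrt(p1 * (1 - p1) / n))
  expect_lt(abs(pd$frac_top8 - p8), 3 * sqrt(p8 * (1 - p8) / n))
  expect_lte(pd$frac_top1, pd$frac_top8)
})

test_that("discrimination skips VHs without enough mutation-matched decoys", {
  g <- synthetic_germlines()
  rep_ <- sample_repertoire(synthetic_config(seed = 3L), 30L)
  # tolerance 0 leaves some VL counts without 20 matched partners
  pd <- tryCatch(
    pairing_discrimination(NULL, rep_, g, n_decoys = 20L, tolerance = 0L,
                           score_fn = function(h, l) stats::runif(length(h)),
                           seed = 1L),
    error = function(e) e)
  if (inherits(pd, "error")) {
    expect_match(conditionMessage(pd), "decoy")
  } else {
    expect_gt(pd$n_skipped, 0L)
  }
})

test_that("zero-shot correlation recovers affine identities and rejects degenerate inputs", {
  m <- toy_trained_model()
  pairs <- toy_pairs(8L, seed = 91L)
  streams <- purrr::map2(pairs$heavy, pairs$light, encode_pair,
                         direction = "forward", vocab = m$vocab)
  ppl <- perplexity(m, streams)
  data <- tibble::tibble(heavy = pairs$heavy, light = pairs$light,
                         fitness = -ppl)
  expect_equal(zero_shot_correlation(m, data), -1, tolerance = 1e-10)
  data$fitness <- rep(1, 8)
  expect_error(zero_shot_correlation(m, data), "zero variance")
  expect_error(zero_shot_correlation(m, data[1:2, ]), "at least 3")
})

test_that("zero-shot correlation is near zero for permuted fitness", {
  # independence null: permuting fitness against sequences kills the signal
  m <- toy_trained_model()
  cfg <- synthetic_config(seed = 31L, fitness_noise_sd = 0)
  fd <- sample_fitness_dataset(cfg, 500L)
  fd$heavy <- substr(fd$heavy, 1, 30)   # short chains keep scoring fast
  fd$light <- substr(fd$light, 1, 30)
  set.seed(99)
  fd$fitness <- sample(fd$fitness)
  expect_lt(abs(zero_shot_correlation(m, fd)), 0.1)
})

test_that("metric panel is invariant to input ordering and self-aware", {
  m <- toy_trained_model()
  set.seed(8)
  gen <- toy_pairs(10L, seed = 51L)
  ref <- toy_pairs(10L, seed = 52L)
  met <- repertoire_metrics(m, gen, ref, synthetic_germlines(), seed = 1L)
  perm <- sample(nrow(gen))
  met2 <- repertoire_metrics(m, gen[perm, ], ref, synthetic_germlines(),
                             seed = 1L)
  expect_equal(met$mean_vh_nn_hamming, met2$mean_vh_nn_hamming)
  expect_equal(met$diversity, met2$diversity, tolerance = 1e-10)
  # reference scored against itself: self excluded, so distances > 0 for
  # distinct sequences
  expect_gt(met$reference_vh_nn_hamming, 0)
})

test_that("embeddings place clones closer than different-germline pairs", {
  m <- toy_trained_model()
  corpus <- unique(toy_trained_corpus())
  set.seed(5)
  n <- 40L; ok <- 0L
  cosd <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (i in seq_len(n)) {
    k <- sample(5, 1); j <- sample(setdiff(1:5, k), 1)
    ch <- strsplit(corpus$heavy[k], "")[[1]]
    p <- sample(seq_along(ch), 1)
    ch[p] <- sample(setdiff(AA_STANDARD, ch[p]), 1)
    emb <- embed_sequences(m, tibble::tibble(
      heavy = c(corpus$heavy[k], paste(ch, collapse = ""), corpus$heavy[j]),
      light = c(corpus$light[k], corpus$light[k], corpus$light[j])))
    if (cosd(emb[1, ], emb[2, ]) < cosd(emb[1, ], emb[3, ])) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.9)
})
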