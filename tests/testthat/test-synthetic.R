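test_that("the gamma-shape mapping hits target correlations in simulation", {
  for (rho in c(0.3, 0.5, 0.7)) {
    mu <- 6
    a <- gamma_shape_for_rho(rho, mu, mu)
    # closed form for equal means: rho = mu / (a + mu)
    expect_equal(mu / (a + mu), rho, tolerance = 1e-10)
    set.seed(round(100 * rho))
    G <- rgamma(20000, shape = a, rate = a)
    nh <- rpois(20000, mu * G); nl <- rpois(20000, mu * G)
    expect_equal(cor(nh, nl), rho, tolerance = 0.03)
  }
  expect_equal(gamma_shape_for_rho(0, 5, 5), Inf)
  expect_error(gamma_shape_for_rho(-0.2, 5, 5), "rho")
  expect_error(synthetic_config(mutation_correlation = -0.3), "negative")
})

test_that("simulator calibration: correlation, adherence, and CDR3 deltas", {
  cfg <- synthetic_config(seed = 11L)
  rep_ <- sample_repertoire(cfg, 2000L)
  r <- cor(rep_$vh_mutations, rep_$vl_mutations)
  expect_gte(r, 0.44)
  expect_lte(r, 0.56)
  # adherence: preferred family with prob pi, else uniform over 4
  expect_lt(abs(mean(rep_$family_pair_respected) - (0.9 + 0.1 / 4)), 0.025)
  # CDR3 delta histogram matches its distribution at n = 2000
  emp <- as.numeric(table(factor(rep_$vh_cdr3_delta, levels = -2:2)) / 2000)
  expect_true(all(abs(emp - c(0.05, 0.15, 0.6, 0.15, 0.05)) < 0.03))
})

test_that("degenerate settings behave exactly", {
  g <- synthetic_germlines()
  r0 <- sample_repertoire(synthetic_config(mutation_rate_mean = 0,
                                           cdr3_length_distribution = c("0" = 1),
                                           seed = 4L), 40L)
  expect_true(all(r0$vh_mutations == 0))
  expect_true(all(r0$vl_mutations == 0))
  expect_true(all(mapply(function(h, nm) h == g$seq[g$name == nm],
                         r0$heavy, r0$vh_germline)))
  r1 <- sample_repertoire(synthetic_config(pairing_adherence = 1, seed = 5L),
                          40L)
  expect_true(all(r1$family_pair_respected))
  rule <- synthetic_config()$pairing_rule
  expect_identical(unname(rule[r1$vh_germline]), r1$vl_germline)
})

test_that("identical seeds give identical corpora and truth reconstructs the pair", {
  cfg <- synthetic_config(seed = 21L)
  a <- sample_repertoire(cfg, 30L)
  b <- sample_repertoire(cfg, 30L)
  expect_identical(a, b)
  g <- synthetic_germlines()
  for (i in seq_len(30L)) {
    gh <- g[g$name == a$vh_germline[i], ]
    # rebuild: germline with its CDR3 replaced by the recorded CDR3, then
    # the recorded substitutions applied
    chars <- strsplit(gh$seq, "")[[1]]
    rebuilt <- c(chars[seq_len(gh$cdr3_start)],
                 strsplit(a$vh_cdr3_seq[[i]], "")[[1]],
                 chars[(gh$cdr3_end + 1L):length(chars)])
    # recorded substitutions are positions on the post-CDR3-edit sequence,
    # but CDR3-internal substitutions are already part of vh_cdr3_seq only
    # if they landed there after the edit; apply all recorded ones
    rebuilt[a$vh_sub_pos[[i]]] <- a$vh_sub_new[[i]]
    expect_identical(paste(rebuilt, collapse = ""), a$heavy[i])
    gl <- g[g$name == a$vl_germline[i], ]
    lchars <- strsplit(gl$seq, "")[[1]]
    lchars[a$vl_sub_pos[[i]]] <- a$vl_sub_new[[i]]
    expect_identical(paste(lchars, collapse = ""), a$light[i])
  }
})

test_that("fitness datasets carry the designed signal and attenuate under noise", {
  cfg0 <- synthetic_config(seed = 8L, fitness_noise_sd = 0)
  fd0 <- sample_fitness_dataset(cfg0, 300L)
  rep0 <- sample_repertoire(cfg0, 300L)
  load0 <- rep0$vh_mutations + rep0$vl_mutations + abs(rep0$vh_cdr3_delta)
  expect_equal(cor(fd0$fitness, load0), -1)
  # noise sd equal to the load sd attenuates |r| to ~ 1/sqrt(2)
  cfg1 <- synthetic_config(seed = 8L)
  rep1 <- sample_repertoire(cfg1, 1000L)
  load1 <- rep1$vh_mutations + rep1$vl_mutations + abs(rep1$vh_cdr3_delta)
  cfg1$fitness_noise_sd <- sd(load1)
  fd1 <- sample_fitness_dataset(cfg1, 1000L)
  expect_equal(abs(cor(fd1$fitness, load1)), 1 / sqrt(2), tolerance = 0.04)
  expect_error(sample_fitness_dataset(cfg1, 2L), "at least 3")
})
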