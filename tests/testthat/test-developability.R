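ann_row <- function(heavy, light, ivs) {
  # ivs: named list like list(vh_cdr1 = c(0, 8), ...)
  out <- tibble::tibble(heavy = heavy, light = light)
  for (nm in names(ivs)) {
    out[[paste0(nm, "_start")]] <- ivs[[nm]][1]
    out[[paste0(nm, "_end")]] <- ivs[[nm]][2]
  }
  out
}

test_that("total CDR length sums the six intervals", {
  h <- random_chain(60, seed = 1); l <- random_chain(50)
  pairs <- ann_row(h, l, list(
    vh_cdr1 = c(0, 8), vh_cdr2 = c(10, 17), vh_cdr3 = c(20, 30),
    vl_cdr1 = c(0, 6), vl_cdr2 = c(10, 13), vl_cdr3 = c(20, 29)))
  expect_equal(total_cdr_length(pairs), 8L + 7L + 10L + 6L + 3L + 9L)
  # empty CDR3 contributes zero
  pairs2 <- pairs; pairs2$vh_cdr3_end <- pairs2$vh_cdr3_start
  expect_equal(total_cdr_length(pairs2), 43L - 10L)
  # out-of-bounds annotation errors
  pairs3 <- pairs; pairs3$vl_cdr3_end <- nchar(l) + 5L
  expect_error(total_cdr_length(pairs3), "annotation error")
})

test_that("CDR-length flag boundaries are inclusive and ordered", {
  expect_equal(flag_total_cdr_length(40, c(40, 60), 3), "green")
  expect_equal(flag_total_cdr_length(60, c(40, 60), 3), "green")
  expect_equal(flag_total_cdr_length(63, c(40, 60), 3), "amber")
  expect_equal(flag_total_cdr_length(37, c(40, 60), 3), "amber")
  expect_equal(flag_total_cdr_length(64, c(40, 60), 3), "red")
  expect_equal(flag_total_cdr_length(c(50, 62, 70), c(40, 60), 3),
               c("green", "amber", "red"))
  expect_error(flag_total_cdr_length(50, c(60, 40), 3), "lo <= hi")
})

test_that("annotation transfer recovers simulated CDR intervals", {
  g <- synthetic_germlines()
  rep_ <- sample_repertoire(synthetic_config(seed = 71L), 40L)
  ann <- annotate_cdrs(rep_[, c("heavy", "light")], g)
  for (col in c("vh_cdr1_start", "vh_cdr1_end", "vh_cdr2_start",
                "vh_cdr2_end", "vh_cdr3_start", "vh_cdr3_end",
                "vl_cdr1_start", "vl_cdr1_end", "vl_cdr3_end")) {
    expect_gte(mean(ann[[col]] == rep_[[col]]), 0.9)
  }
  # the transferred total reflects the simulated CDR3 length change
  tot_truth <- total_cdr_length(rep_)
  tot_ann <- total_cdr_length(ann)
  expect_gte(mean(tot_ann == tot_truth), 0.85)
})

test_that("developable filtering applies the all-green structural policy", {
  corpus <- tibble::tibble(id = sprintf("ab%02d", 1:10),
                           heavy = "EVQ", light = "DIQ",
                           split = rep(c("train", "validation"), 5))
  flags <- tibble::tibble(
    id = corpus$id,
    psh = c(rep("green", 6), rep("amber", 4)),
    ppc = rep("green", 10),
    pnc = c(rep("green", 4), "amber", rep("green", 5)),
    sfvcsp = rep("green", 10))
  out <- filter_developable(corpus, flags)
  expect_equal(nrow(out), 5L)                      # rows 1-4 and 6 all green
  expect_identical(out$id, corpus$id[c(1:4, 6)])
  expect_identical(out$split, corpus$split[c(1:4, 6)])  # labels preserved
  # amber on one structural metric excludes
  expect_false("ab05" %in% out$id)
  # identity policy keeps everything
  out_all <- filter_developable(corpus, flags, policy = function(r) TRUE)
  expect_equal(nrow(out_all), 10L)
  # idempotent and order-preserving
  out2 <- filter_developable(out, flags)
  expect_identical(out2$id, out$id)
  # missing flags are dropped and counted
  out3 <- filter_developable(corpus, flags[1:6, ])
  expect_equal(attr(out3, "n_missing_flags"), 4L)
})

test_that("developable finetuning keeps architecture and changes only weights", {
  m <- toy_trained_model()
  corpus <- toy_trained_corpus()[1:20, ]
  corpus$id <- sprintf("t%02d", 1:20)
  m2 <- suppressMessages(finetune_developable(
    m, corpus, train_config(peak_lr = 1e-4, epochs = 1L, batch_size = 20L,
                            grad_accum_steps = 1L, seed = 3L), quiet = TRUE))
  expect_identical(m2$config, m$config)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(m2$meta$stage, "developable")
  expect_false(identical(m2$w, m$w))
})
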