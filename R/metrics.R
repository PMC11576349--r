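#' Nearest-neighbour cosine diversity
#'
#' For each row vector, the cosine distance (1 - cosine similarity) to its
#' nearest neighbour among the other rows; returns the mean. Zero means
#' all items identical; higher means more diverse.
#'
#' @param vectors Numeric matrix, one embedding per row (>= 2 rows).
#' @return Mean nearest-neighbour cosine distance.
#' @export
nn_cosine_diversity <- function(vectors) {
  if (!is.matrix(vectors) || nrow(vectors) < 2L) {
    stop("need at least 2 vectors", call. = FALSE)
  }
  mean(nn_cosine_distances(vectors))
}

nn_cosine_distances <- function(vectors) {
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm vector has no cosine distance", call. = FALSE)
  X <- vectors / nrm
  S <- tcrossprod(X)
  diag(S) <- -Inf
  1 - apply(S, 1L, max)
}

#' VH-VL mutation-rate correlation
#'
#' Pearson correlation between per-pair VH and VL mutation counts away
#' from germline — the somatic-hypermutation coupling signal that natural
#' paired repertoires show and randomly re-paired chains destroy.
#'
#' @param pairs Tibble with `heavy` and `light` columns (>= 3 rows).
#' @param germlines Germline reference tibble.
#' @return Pearson r.
#' @export
vhvl_mutation_correlation <- function(pairs, germlines) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  ch <- mutation_count(pairs$heavy, germlines, "VH")$count
  cl <- mutation_count(pairs$light, germlines, "VL")$count
  if (stats::sd(ch) == 0 || stats::sd(cl) == 0) {
    stop("undefined correlation: zero variance in mutation counts", call. = FALSE)
  }
  stats::cor(ch, cl)
}

#' Random-pairing control
#'
#' Uniformly permutes the light chains against fixed heavy chains
#' (self-pairing allowed), destroying any VH-VL coupling while conserving
#' both chain multisets. Seeded.
#'
#' @param pairs Tibble with `heavy` and `light` columns (>= 2 rows).
#' @param seed Integer seed.
#' @return The tibble with its `light` column permuted.
#' @export
random_pairing_control <- function(pairs, seed = 0L) {
  if (nrow(pairs) < 2L) stop("need at least 2 pairs", call. = FALSE)
  perm <- with_seed(seed, sample.int(nrow(pairs)))
  pairs$light <- pairs$light[perm]
  pairs
}

#' Mann-Whitney U comparison of two metric samples
#'
#' Two-sided Mann-Whitney U test; exact when both samples are small and
#' untied, normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The p-value.
#' @export
compare_distributions <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    stop("degenerate samples: all values identical", call. = FALSE)
  }
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, correct = TRUE)$p.value
  )
}

#' Pairing-likelihood discrimination
#'
#' For each evaluated VH, scores the true VH-VL pair against `n_decoys`
#' pairings with decoy VLs whose germline mutation counts lie within
#' `tolerance` of the true VL's count (controlling for mutation rate), and
#' reports: the fraction of cases where the true pair scores above the
#' decoy mean; the fraction where it ranks first of `n_decoys + 1`; and
#' the fraction where it ranks in the top 8. Ranks break ties at random.
#' VHs with fewer than `n_decoys` eligible decoys are skipped and counted.
#'
#' @param model A trained `fv_model` (ignored when `score_fn` is given).
#' @param pairs Tibble with `heavy` and `light` columns of true pairs.
#' @param germlines Germline reference for mutation counting.
#' @param n_decoys Decoys per VH (published protocol: 50).
#' @param tolerance Mutation-count window for decoy eligibility (+/-).
#' @param n_cases Maximum VH cases to evaluate (sampled without
#'   replacement); `Inf` evaluates all.
#' @param score_fn Scoring function `function(heavy, light) -> numeric`
#'   (vectorized); defaults to the model's raw sequence log-likelihood of
#'   the forward stream.
#' @param seed Integer seed (decoy draws, tie-breaks, case subsampling).
#' @return An `fv_pairing_result`: list with `frac_above_random_mean`,
#'   `frac_top1`, `frac_top8`, `n_cases`, `n_skipped`, `n_decoys`,
#'   `tolerance`, and the per-case tibble `cases`.
#' @export
pairing_discrimination <- function(model = NULL, pairs, germlines,
                                   n_decoys = 50L, tolerance = 2L,
                                   n_cases = Inf, score_fn = NULL,
                                   seed = 0L) {
  n <- nrow(pairs)
  if (n < n_decoys + 1L) {
    stop("need more pairs than decoys", call. = FALSE)
  }
  if (is.null(score_fn)) {
    stopifnot(inherits(model, "fv_model"))
    score_fn <- function(heavy, light) {
      streams <- purrr::map2(heavy, light, encode_pair, direction = "forward",
                             vocab = model$vocab,
                             max_positions = model$config$max_positions)
      sequence_log_likelihood(model, streams)
    }
  }
  vl_counts <- mutation_count(pairs$light, germlines, "VL")$count
  with_seed(seed, {
    cases <- seq_len(n)
    if (is.finite(n_cases) && n_cases < n) {
      cases <- sort(sample.int(n, n_cases))
    }
    picks <- vector("list", length(cases))
    eligible_ok <- logical(length(cases))
    for (j in seq_along(cases)) {
      i <- cases[j]
      elig <- which(abs(vl_counts - vl_counts[i]) <= tolerance)
      elig <- setdiff(elig, i)
      if (length(elig) >= n_decoys) {
        picks[[j]] <- if (length(elig) == n_decoys) elig
                      else sample(elig, n_decoys)
        eligible_ok[j] <- TRUE
      }
    }
    n_skipped <- sum(!eligible_ok)
    cases <- cases[eligible_ok]
    picks <- picks[eligible_ok]
    if (length(cases) == 0L) {
      stop("no VH has enough mutation-matched decoy VLs", call. = FALSE)
    }
    # one batched scoring call over all (true + decoy) pairings
    hv <- rep(pairs$heavy[cases], each = n_decoys + 1L)
    lt <- character(length(hv))
    idx <- 1L
    for (j in seq_along(cases)) {
      lt[idx] <- pairs$light[cases[j]]
      lt[idx + seq_len(n_decoys)] <- pairs$light[picks[[j]]]
      idx <- idx + n_decoys + 1L
    }
    sc <- score_fn(hv, lt)
    per <- matrix(sc, nrow = n_decoys + 1L)   # col = case; row 1 = true pair
    above <- per[1, ] > colMeans(per[-1, , drop = FALSE])
    ranks <- vapply(seq_len(ncol(per)), function(j) {
      r <- rank(-per[, j], ties.method = "random")
      r[1]
    }, numeric(1))
    res <- list(
      frac_above_random_mean = mean(above),
      frac_top1 = mean(ranks == 1),
      frac_top8 = mean(ranks <= 8),
      n_cases = length(cases), n_skipped = n_skipped,
      n_decoys = as.integer(n_decoys), tolerance = as.integer(tolerance),
      cases = tibble::tibble(case = cases, true_score = per[1, ],
                             decoy_mean = colMeans(per[-1, , drop = FALSE]),
                             rank = as.integer(ranks))
    )
    class(res) <- "fv_pairing_result"
    res
  })
}

#' @export
print.fv_pairing_result <- function(x, ...) {
  cat("<fv_pairing_result> ", x$n_cases, " VH cases (", x$n_skipped,
      " skipped), ", x$n_decoys, " decoys, tolerance +/-", x$tolerance, "\n",
      sprintf("  true > decoy mean: %.1f%%   top-1: %.1f%%   top-8: %.1f%%\n",
              100 * x$frac_above_random_mean, 100 * x$frac_top1,
              100 * x$frac_top8), sep = "")
  invisible(x)
}

#' Zero-shot perplexity-fitness correlation
#'
#' Pearson correlation between each record's forward-stream perplexity
#' under the model and its measured fitness. Reported with its natural
#' sign: negative r means lower perplexity associates with higher fitness.
#'
#' @param model A trained `fv_model`.
#' @param data Fitness tibble: `heavy`, `light`, `fitness` (>= 3 rows,
#'   finite fitness).
#' @return Pearson r.
#' @export
zero_shot_correlation <- function(model, data) {
  if (nrow(data) < 3L) stop("need at least 3 records", call. = FALSE)
  if (!all(is.finite(data$fitness))) stop("fitness must be finite", call. = FALSE)
  streams <- purrr::map2(data$heavy, data$light, encode_pair,
                         direction = "forward", vocab = model$vocab,
                         max_positions = model$config$max_positions)
  ppl <- perplexity(model, streams)
  if (stats::sd(ppl) == 0 || stats::sd(data$fitness) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(ppl, data$fitness)
}

#' Repertoire metric panel
#'
#' The standard evaluation panel for a generated set against a reference
#' set: mean nearest-neighbour VH and VL Hamming distances to the
#' reference, embedding cosine diversity, VH-VL mutation-count correlation
#' with its random-pairing control, and Mann-Whitney p-values comparing
#' the generated and reference per-sequence metric distributions.
#'
#' @param model Trained `fv_model` used for embeddings.
#' @param generated,reference Tibbles with `heavy` and `light` columns.
#' @param germlines Germline reference tibble.
#' @param seed Seed for the random-pairing control.
#' @return An `fv_metrics` object (list) with fields
#'   `mean_vh_nn_hamming`, `mean_vl_nn_hamming`, `diversity`,
#'   `vhvl_mutation_correlation`, `random_pairing_correlation`,
#'   `comparison_p_values` (named list), and per-sequence detail tibbles.
#' @export
repertoire_metrics <- function(model, generated, reference,
                               germlines = synthetic_germlines(), seed = 0L) {
  vh_g <- nn_hamming(generated$heavy, reference$heavy)
  vl_g <- nn_hamming(generated$light, reference$light)
  vh_r <- nn_hamming(reference$heavy, reference$heavy)   # self excluded
  vl_r <- nn_hamming(reference$light, reference$light)
  emb_g <- embed_sequences(model, generated)
  emb_r <- embed_sequences(model, reference)
  div_g <- nn_cosine_distances(emb_g)
  div_r <- nn_cosine_distances(emb_r)
  rr <- vhvl_mutation_correlation(generated, germlines)
  rctrl <- vhvl_mutation_correlation(
    random_pairing_control(generated, seed = seed), germlines)
  res <- list(
    mean_vh_nn_hamming = vh_g$mean,
    mean_vl_nn_hamming = vl_g$mean,
    diversity = mean(div_g),
    vhvl_mutation_correlation = rr,
    random_pairing_correlation = rctrl,
    reference_vh_nn_hamming = vh_r$mean,
    reference_vl_nn_hamming = vl_r$mean,
    reference_diversity = mean(div_r),
    comparison_p_values = list(
      vh_nn_hamming = compare_distributions(vh_g$distances, vh_r$distances),
      vl_nn_hamming = compare_distributions(vl_g$distances, vl_r$distances),
      diversity = compare_distributions(div_g, div_r)
    ),
    detail = tibble::tibble(
      set = rep(c("generated", "reference"),
                c(nrow(generated), nrow(reference))),
      vh_nn_hamming = c(vh_g$distances, vh_r$distances),
      vl_nn_hamming = c(vl_g$distances, vl_r$distances),
      nn_cosine = c(div_g, div_r)
    )
  )
  class(res) <- "fv_metrics"
  res
}

#' @export
print.fv_metrics <- function(x, ...) {
  cat("<fv_metrics>\n")
  cat(sprintf("  mean VH NN Hamming: %.2f (reference %.2f, p=%.3g)\n",
              x$mean_vh_nn_hamming, x$reference_vh_nn_hamming,
              x$comparison_p_values$vh_nn_hamming))
  cat(sprintf("  mean VL NN Hamming: %.2f (reference %.2f, p=%.3g)\n",
              x$mean_vl_nn_hamming, x$reference_vl_nn_hamming,
              x$comparison_p_values$vl_nn_hamming))
  cat(sprintf("  diversity (NN cosine): %.3f (reference %.3f, p=%.3g)\n",
              x$diversity, x$reference_diversity,
              x$comparison_p_values$diversity))
  cat(sprintf("  VH-VL mutation correlation: %.3f (random pairing %.3f)\n",
              x$vhvl_mutation_correlation, x$random_pairing_correlation))
  invisible(x)
}
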