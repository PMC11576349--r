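#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a repertoire metric panel
#'
#' @param x An `fv_metrics` from [repertoire_metrics()].
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `generated`,
#'   `reference`, `p_value` (Mann-Whitney, where applicable).
#' @export
tidy.fv_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("vh_nn_hamming", "vl_nn_hamming", "diversity",
               "vhvl_mutation_correlation", "random_pairing_correlation"),
    generated = c(x$mean_vh_nn_hamming, x$mean_vl_nn_hamming, x$diversity,
                  x$vhvl_mutation_correlation, x$random_pairing_correlation),
    reference = c(x$reference_vh_nn_hamming, x$reference_vl_nn_hamming,
                  x$reference_diversity, NA, NA),
    p_value = c(x$comparison_p_values$vh_nn_hamming,
                x$comparison_p_values$vl_nn_hamming,
                x$comparison_p_values$diversity, NA, NA)
  )
}

#' @rdname tidy.fv_metrics
#' @export
glance.fv_metrics <- function(x, ...) {
  tibble::tibble(
    mean_vh_nn_hamming = x$mean_vh_nn_hamming,
    mean_vl_nn_hamming = x$mean_vl_nn_hamming,
    diversity = x$diversity,
    vhvl_mutation_correlation = x$vhvl_mutation_correlation,
    random_pairing_correlation = x$random_pairing_correlation
  )
}

#' @rdname tidy.fv_metrics
#' @param object An `fv_metrics`.
#' @export
autoplot.fv_metrics <- function(object, ...) {
  det <- tidyr::pivot_longer(object$detail, -"set",
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(det, ggplot2::aes(x = .data$set, y = .data$value,
                                    fill = .data$set)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-sequence repertoire metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Tidy a pairing-discrimination result
#'
#' @param x An `fv_pairing_result` from [pairing_discrimination()].
#' @param ... Unused.
#' @return Per-case tibble (`case`, `true_score`, `decoy_mean`, `rank`).
#' @export
tidy.fv_pairing_result <- function(x, ...) x$cases

#' @rdname tidy.fv_pairing_result
#' @export
glance.fv_pairing_result <- function(x, ...) {
  tibble::tibble(
    frac_above_random_mean = x$frac_above_random_mean,
    frac_top1 = x$frac_top1,
    frac_top8 = x$frac_top8,
    n_cases = x$n_cases, n_skipped = x$n_skipped,
    n_decoys = x$n_decoys, tolerance = x$tolerance
  )
}

#' @rdname tidy.fv_pairing_result
#' @param object An `fv_pairing_result`.
#' @export
autoplot.fv_pairing_result <- function(object, ...) {
  ggplot2::ggplot(object$cases, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_hline(yintercept = object$n_cases / (object$n_decoys + 1),
                        linetype = "dashed") +
    ggplot2::labs(x = "rank of true pairing",
                  y = "VH cases",
                  title = "True-pairing rank among mutation-matched decoys",
                  subtitle = "dashed: uniform null") +
    ggplot2::theme_minimal()
}

#' Tidy / inspect a fitted model
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row
#' summary; `autoplot()` the loss curve.
#'
#' @param x An `fv_model`.
#' @param ... Unused.
#' @export
tidy.fv_model <- function(x, ...) {
  h <- x$meta$history
  if (is.null(h)) tibble::tibble(epoch = integer(), train_loss = numeric(),
                                 val_loss = numeric(), lr = numeric())
  else tibble::as_tibble(h)
}

#' @rdname tidy.fv_model
#' @export
glance.fv_model <- function(x, ...) {
  h <- tidy.fv_model(x)
  tibble::tibble(
    stage = x$meta$stage,
    n_parameters = count_parameters(x$config),
    epochs_trained = x$meta$epochs_trained,
    final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
    final_val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_
  )
}

#' @rdname tidy.fv_model
#' @param object An `fv_model`.
#' @export
autoplot.fv_model <- function(object, ...) {
  h <- tidy.fv_model(object)
  h$run <- cumsum(c(TRUE, diff(h$epoch) <= 0))  # separate training stages
  h <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  h <- h[!is.na(h$loss), , drop = FALSE]
  h$step <- seq_len(nrow(h))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set,
                                  group = interaction(.data$run, .data$set))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss",
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Compare total-CDR-length distributions before and after biasing
#'
#' Density plot of total CDR lengths for two generated sets (for example
#' before and after developability-biased finetuning), with the
#' Mann-Whitney p-value in the subtitle.
#'
#' @param before,after Integer vectors of total CDR lengths.
#' @return A ggplot.
#' @export
plot_cdr_length_shift <- function(before, after) {
  df <- tibble::tibble(
    set = rep(c("before", "after"), c(length(before), length(after))),
    total_cdr_length = c(before, after))
  p <- compare_distributions(after, before, alternative = "less")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_cdr_length,
                                   fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(title = "Total CDR length of generated antibodies",
                  subtitle = sprintf("one-sided Mann-Whitney p = %.2g", p),
                  x = "total CDR length (6 loops)", y = "density") +
    ggplot2::theme_minimal()
}
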