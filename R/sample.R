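#' Sampler configuration
#'
#' Controlled sampling parameters. The published operating point is
#' temperature 1.2, top-p 0.95, and discarding the bottom 5% of generated
#' sequences by model likelihood; the developability-biased variant raises
#' the temperature to 1.25 to maintain diversity.
#'
#' @param temperature Softmax temperature (> 0). `greedy = TRUE` replaces
#'   sampling by argmax (the temperature-to-zero limit).
#' @param top_p Nucleus mass in (0, 1].
#' @param discard_fraction Fraction of generated sequences discarded by
#'   likelihood, in \[0, 1).
#' @param max_new_tokens Generation cap per stream (default 260 covers
#'   VH+VL Fv lengths with margin).
#' @param seed Integer seed for the categorical draws.
#' @param greedy Argmax decoding instead of sampling.
#' @param length_normalize Use per-token (length-normalized) log-likelihood
#'   for the discard filter (default) rather than the raw sum.
#' @return An `fv_sampler_config` list.
#' @export
sampler_config <- function(temperature = 1.2, top_p = 0.95,
                           discard_fraction = 0.05, max_new_tokens = 260L,
                           seed = 0L, greedy = FALSE, length_normalize = TRUE) {
  stopifnot(temperature > 0, top_p > 0, top_p <= 1,
            discard_fraction >= 0, discard_fraction < 1, max_new_tokens >= 1)
  structure(list(temperature = temperature, top_p = top_p,
                 discard_fraction = discard_fraction,
                 max_new_tokens = as.integer(max_new_tokens),
                 seed = as.integer(seed), greedy = isTRUE(greedy),
                 length_normalize = isTRUE(length_normalize)),
            class = "fv_sampler_config")
}

#' Nucleus (top-p) filter
#'
#' Keeps the smallest set of highest-probability tokens whose cumulative
#' mass reaches `top_p`, zeroes the rest, and renormalizes. Ties are broken
#' by token index (lower index enters the nucleus first).
#'
#' @param probs Probability vector (sums to 1 within tolerance).
#' @param top_p Nucleus mass in (0, 1].
#' @return Filtered, renormalized probability vector.
#' @examples
#' nucleus_filter(c(0.5, 0.3, 0.15, 0.05), 0.8)  # c(0.625, 0.375, 0, 0)
#' @export
nucleus_filter <- function(probs, top_p) {
  if (top_p <= 0) stop("top_p must be positive", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-6) {
    stop("probs must sum to 1", call. = FALSE)
  }
  ord <- order(probs, seq_along(probs), decreasing = c(TRUE, FALSE),
               method = "radix")
  cum <- cumsum(probs[ord])
  k <- which(cum >= top_p - 1e-12)[1]
  if (is.na(k)) k <- length(probs)
  keep <- ord[seq_len(k)]
  out <- numeric(length(probs))
  out[keep] <- probs[keep]
  out / sum(out)
}

# temperature + nucleus transform of a logit vector -> probability vector
transform_logits <- function(logits, temperature, top_p) {
  z <- logits / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  nucleus_filter(p, top_p)
}

#' Draw the next token
#'
#' Applies temperature scaling (before nucleus truncation), the nucleus
#' filter, and a categorical draw from the current RNG state. With
#' `greedy = TRUE`, returns the argmax (first index on ties).
#'
#' @param logits Numeric logit vector.
#' @param temperature,top_p As in [sampler_config()].
#' @param greedy Argmax instead of sampling.
#' @return Integer token id.
#' @export
sample_next_token <- function(logits, temperature = 1.2, top_p = 0.95,
                              greedy = FALSE) {
  if (greedy) return(which.max(logits))
  p <- transform_logits(logits, temperature, top_p)
  sample.int(length(p), 1L, prob = p)
}

# ---- KV-cached batched generation -------------------------------------------

# Incremental decoding of a batch of prompts. All heavy state lives in
# per-dimension B x Lmax cache matrices so each step is a handful of
# vectorized ops. Returns token matrix (prompt + continuation), lengths,
# a truncation flag, and the raw (untempered) log-likelihood accumulated
# over the *generated* positions plus prompt positions after the first.
decode_batch <- function(model, prompts, max_new_tokens, temperature, top_p,
                         greedy, stop_token, alt_stop_token = NULL) {
  cfg <- model$config; w <- model$w
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  half <- dh / 2L
  B <- length(prompts)
  plen <- vapply(prompts, length, integer(1))
  Lmax <- min(cfg$max_positions, max(plen) + max_new_tokens)
  rot <- rotary_tables(Lmax, dh, cfg$rotary_base)
  nl <- cfg$n_layers
  Kc <- replicate(nl, lapply(seq_len(d), function(i) matrix(0, B, Lmax)),
                  simplify = FALSE)
  Vc <- replicate(nl, lapply(seq_len(d), function(i) matrix(0, B, Lmax)),
                  simplify = FALSE)
  tokens <- matrix(1L, B, Lmax)
  for (b in seq_len(B)) tokens[b, seq_len(plen[b])] <- prompts[[b]]
  done <- rep(FALSE, B)
  lens <- plen
  loglik <- numeric(B)
  scale <- 1 / sqrt(dh)
  E_out <- if (cfg$tie_embeddings) w$tok_emb else w$out_emb
  i1g <- lapply(seq_len(H), function(h) (h - 1L) * dh + 2L * seq_len(half) - 1L)
  i2g <- lapply(i1g, function(i) i + 1L)
  hcg <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  logits <- NULL
  t_ <- 0L
  wrong_terminal <- rep(FALSE, B)
  repeat {
    t_ <- t_ + 1L
    if (t_ > Lmax) break
    cur <- tokens[, t_]
    X <- w$tok_emb[cur, , drop = FALSE]
    if (cfg$use_learned_positions) {
      X <- X + rep(w$pos_emb[t_, ], each = B)
    }
    cosr <- rot$cos[t_, ]; sinr <- rot$sin[t_, ]
    COS <- rep(cosr, each = B); SIN <- rep(sinr, each = B)
    for (l in seq_len(nl)) {
      ly <- w$layers[[l]]
      a1 <- ln_fwd(X, ly$ln1_g, ly$ln1_b)$y
      QKV <- add_bias(a1 %*% ly$w_qkv, ly$b_qkv)
      Q <- QKV[, 1:d, drop = FALSE]
      K <- QKV[, (d + 1):(2 * d), drop = FALSE]
      Vv <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
      for (h in seq_len(H)) {
        i1 <- i1g[[h]]; i2 <- i2g[[h]]
        q1 <- Q[, i1, drop = FALSE]; q2 <- Q[, i2, drop = FALSE]
        Q[, i1] <- q1 * COS - q2 * SIN; Q[, i2] <- q1 * SIN + q2 * COS
        k1 <- K[, i1, drop = FALSE]; k2 <- K[, i2, drop = FALSE]
        K[, i1] <- k1 * COS - k2 * SIN; K[, i2] <- k1 * SIN + k2 * COS
      }
      for (i in seq_len(d)) {
        Kc[[l]][[i]][, t_] <- K[, i]
        Vc[[l]][[i]][, t_] <- Vv[, i]
      }
      CTX <- matrix(0, B, d)
      for (h in seq_len(H)) {
        hc <- hcg[[h]]
        S <- matrix(0, B, t_)
        for (i in hc) S <- S + Q[, i] * Kc[[l]][[i]][, seq_len(t_), drop = FALSE]
        S <- S * scale
        S <- S - max(S)
        P <- exp(S)
        P <- P / rowSums(P)
        for (i in hc) CTX[, i] <- rowSums(P * Vc[[l]][[i]][, seq_len(t_), drop = FALSE])
      }
      X <- X + add_bias(CTX %*% ly$w_o, ly$b_o)
      a2 <- ln_fwd(X, ly$ln2_g, ly$ln2_b)$y
      X <- X + add_bias(gelu_fwd(add_bias(a2 %*% ly$w_f1, ly$b_f1)) %*% ly$w_f2,
                        ly$b_f2)
    }
    hf <- ln_fwd(X, w$lnf_g, w$lnf_b)$y
    logits <- tcrossprod(hf, E_out)   # B x V: next-token logits at position t_
    lp <- log_softmax_rows(logits)
    # accumulate likelihood of known prompt tokens at position t_+1
    known <- which(!done & plen > t_)
    if (length(known)) {
      nxt <- tokens[cbind(known, t_ + 1L)]
      loglik[known] <- loglik[known] + lp[cbind(known, nxt)]
    }
    # sample for sequences whose prompt is exhausted and that are not done
    active <- which(!done & plen <= t_)
    if (length(active)) {
      if (t_ + 1L > Lmax) { lens[active] <- t_; break }
      if (greedy) {
        draws <- apply(logits[active, , drop = FALSE], 1L, which.max)
      } else {
        la <- logits[active, , drop = FALSE]
        draws <- integer(length(active))
        for (jj in seq_along(active)) {
          p <- transform_logits(la[jj, ], temperature, top_p)
          draws[jj] <- sample.int(length(p), 1L, prob = p)
        }
      }
      tokens[cbind(active, t_ + 1L)] <- draws
      loglik[active] <- loglik[active] + lp[cbind(active, draws)]
      lens[active] <- t_ + 1L
      # any sentinel ends the stream; ending on the wrong one makes the
      # stream malformed and is flagged below, not silently accepted
      terminal <- draws == stop_token |
        (!is.null(alt_stop_token) & draws %in% alt_stop_token)
      fin <- active[terminal | (t_ + 1L - plen[active]) >= max_new_tokens]
      done[fin] <- TRUE
    }
    if (all(done)) break
  }
  for (b in seq_len(B)) {
    last <- tokens[b, lens[b]]
    wrong_terminal[b] <- done[b] && last != stop_token &&
      !is.null(alt_stop_token) && last %in% alt_stop_token
  }
  # truncated covers both failure modes: never terminated, or terminated
  # on the direction-inappropriate sentinel (malformed stream)
  list(tokens = tokens, lens = lens, loglik = loglik,
       truncated = !done | wrong_terminal)
}

#' Sample token streams from the model
#'
#' Iteratively applies temperature scaling, the nucleus filter, and a
#' categorical draw until the closing sentinel or `max_new_tokens`.
#' Generation is batched with a key/value cache; streams that never emit
#' the closing sentinel are flagged `truncated`, not raised.
#'
#' @param model A trained `fv_model`.
#' @param n Number of streams (ignored when `prompts` given).
#' @param config An [sampler_config()].
#' @param prompts Optional list of integer token prefixes, each beginning
#'   with a sentinel. Default: the forward start sentinel for all `n`.
#' @param direction Direction tag for unprompted sampling: `"forward"`,
#'   `"reverse"`, or `"both"` (50/50).
#' @param chunk_size Streams decoded per cache batch.
#' @return Tibble: `stream` (list of [fv_stream()]), `log_likelihood` (raw,
#'   under the untempered model), `truncated`.
#' @export
sample_streams <- function(model, n = 1L, config = sampler_config(),
                           prompts = NULL, direction = "both",
                           chunk_size = 500L) {
  vocab <- model$vocab
  bos <- vocab_bos(vocab); eos <- vocab_eos(vocab)
  with_seed(config$seed, {
    if (is.null(prompts)) {
      dirs <- switch(direction,
                     forward = rep("forward", n),
                     reverse = rep("reverse", n),
                     both = sample(c("forward", "reverse"), n, replace = TRUE))
      prompts <- lapply(dirs, function(d) if (d == "forward") bos else eos)
    } else {
      dirs <- vapply(prompts, function(p) {
        if (p[1] == bos) "forward"
        else if (p[1] == eos) "reverse"
        else stop("prompt must begin with a sentinel", call. = FALSE)
      }, character(1))
      n <- length(prompts)
    }
    out <- vector("list", n)
    ll <- numeric(n); trunc <- logical(n)
    idx <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
    for (ix in idx) {
      # decode forward-direction and reverse-direction prompts separately
      for (dd in unique(dirs[ix])) {
        sel <- ix[dirs[ix] == dd]
        dec <- decode_batch(model, prompts[sel], config$max_new_tokens,
                            config$temperature, config$top_p, config$greedy,
                            stop_token = if (dd == "forward") eos else bos,
                            alt_stop_token = if (dd == "forward") bos else eos)
        for (j in seq_along(sel)) {
          out[[sel[j]]] <- fv_stream(dec$tokens[j, seq_len(dec$lens[j])], dd)
        }
        ll[sel] <- dec$loglik
        trunc[sel] <- dec$truncated
      }
    }
    tibble::tibble(stream = out, log_likelihood = ll, truncated = trunc)
  })
}

#' Likelihood-based discard filter
#'
#' Ranks results by length-normalized log-likelihood (or the raw sum when
#' `length_normalize = FALSE`) and marks the lowest
#' `floor(discard_fraction * n)` as `kept = FALSE`. Input order is
#' preserved.
#'
#' @param results Tibble with `log_likelihood` and `stream` columns (as
#'   from [sample_streams()] or [generate_pairs()]).
#' @param discard_fraction Fraction in \[0, 1).
#' @param length_normalize Rank by per-token likelihood (default).
#' @return `results` with a logical `kept` column.
#' @export
likelihood_filter <- function(results, discard_fraction = 0.05,
                              length_normalize = TRUE) {
  n <- nrow(results)
  if (n == 0L) stop("results must be non-empty", call. = FALSE)
  score <- results$log_likelihood
  if (length_normalize) {
    len <- vapply(results$stream, function(s) length(s$tokens), integer(1))
    score <- score / (len - 1L)
  }
  k <- floor(discard_fraction * n)
  kept <- rep(TRUE, n)
  if (k > 0) kept[order(score)[seq_len(k)]] <- FALSE
  results$kept <- kept
  results
}

#' Generate paired sequences
#'
#' Samples streams from a start sentinel, decodes them, recovers the
#' VH/VL boundary with the germline-anchored splitter, and applies the
#' likelihood discard filter. Unsplittable or truncated streams are
#' resampled up to `retry_factor * n` total draws and counted in the
#' `n_resampled` attribute; exceeding the cap raises a generation-quality
#' error.
#'
#' @param model A trained `fv_model`.
#' @param n Number of paired sequences requested (>= 1).
#' @param config An [sampler_config()].
#' @param germlines Germline reference tibble for boundary recovery.
#' @param direction `"forward"`, `"reverse"` or `"both"` (default).
#' @param retry_factor Resampling cap as a multiple of `n`.
#' @return Tibble: `heavy`, `light`, `log_likelihood`, `kept`, `boundary`,
#'   `split_score`, `stream` (list column), with attribute `n_resampled`.
#' @export
generate_pairs <- function(model, n, config = sampler_config(),
                           germlines = synthetic_germlines(),
                           direction = "both", retry_factor = 3) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  budget <- ceiling(retry_factor * n)
  got <- list(); drawn <- 0L; attempt <- 0L
  need <- n
  seed <- config$seed
  while (need > 0L) {
    if (drawn + need > budget) {
      stop("generation-quality error: exceeded resampling cap (",
           budget, " draws) with ", n - need, "/", n, " well-formed pairs; ",
           "drawn=", drawn, call. = FALSE)
    }
    cfg_i <- config; cfg_i$seed <- seed + attempt
    res <- sample_streams(model, need, cfg_i, direction = direction)
    drawn <- drawn + need
    attempt <- attempt + 1L
    res <- res[!res$truncated, , drop = FALSE]
    if (nrow(res) > 0L) {
      dec <- lapply(res$stream, function(s) {
        seq <- tryCatch(decode_stream(s, model$vocab), error = function(e) NULL)
        if (is.null(seq) || nchar(seq) < 2L) return(NULL)
        sp <- tryCatch(split_pair(seq, germlines), error = function(e) NULL)
        sp
      })
      ok <- !vapply(dec, is.null, logical(1))
      if (any(ok)) {
        keep <- res[ok, , drop = FALSE]
        sp <- dec[ok]
        got[[length(got) + 1L]] <- tibble::tibble(
          heavy = vapply(sp, `[[`, character(1), "heavy"),
          light = vapply(sp, `[[`, character(1), "light"),
          log_likelihood = keep$log_likelihood,
          boundary = vapply(sp, `[[`, integer(1), "boundary"),
          split_score = vapply(sp, function(x) as.numeric(x$score), numeric(1)),
          stream = keep$stream
        )
        need <- n - sum(vapply(got, nrow, integer(1)))
      }
    }
  }
  out <- dplyr::bind_rows(got)
  out <- out[seq_len(n), , drop = FALSE]
  out <- likelihood_filter(out, config$discard_fraction, config$length_normalize)
  out <- out[, c("heavy", "light", "log_likelihood", "kept", "boundary",
                 "split_score", "stream")]
  attr(out, "n_resampled") <- drawn - n
  out
}

#' Complete the partner chain of a given VH or VL
#'
#' Given a heavy chain, prompts the model with the forward prefix
#' `1 + heavy` and samples the light-chain continuation; given a light
#' chain, prompts with the reverse prefix `2 + reversed light` and samples
#' the reversed heavy continuation, then un-reverses. The given chain is
#' returned verbatim in the result.
#'
#' @param model A trained `fv_model`.
#' @param seq Residue string of the given chain.
#' @param chain_type `"VH"` or `"VL"`.
#' @param config An [sampler_config()].
#' @return A list: `heavy`, `light`, `log_likelihood`, `truncated`
#'   (`TRUE` if the closing sentinel was never emitted — flagged, not
#'   raised).
#' @export
complete_chain <- function(model, seq, chain_type = c("VH", "VL"),
                           config = sampler_config()) {
  chain_type <- match.arg(chain_type)
  validate_chain(seq, chain_type, max_x_fraction = 1)
  vocab <- model$vocab
  res_ids <- residue_ids(seq, vocab)
  prompt <- if (chain_type == "VH") {
    c(vocab_bos(vocab), res_ids)
  } else {
    c(vocab_eos(vocab), rev(res_ids))
  }
  res <- sample_streams(model, config = config, prompts = list(prompt))
  stream <- res$stream[[1]]
  # continuation tokens after the prompt, up to (not including) the closing
  # sentinel; a non-residue token before the closing sentinel marks the
  # completion as incomplete rather than raising
  cont <- stream$tokens[-seq_along(prompt)]
  closing <- if (chain_type == "VH") vocab_eos(vocab) else vocab_bos(vocab)
  rid <- attr(vocab, "residue_ids")
  stopidx <- which(!(cont %in% rid))
  complete <- length(stopidx) > 0 && cont[stopidx[1]] == closing
  run <- if (length(stopidx)) cont[seq_len(stopidx[1] - 1L)] else cont
  partner <- paste(vocab_tokens(vocab, run), collapse = "")
  if (chain_type == "VH") {
    heavy <- seq
    light <- partner
  } else {
    light <- seq
    heavy <- paste(rev(strsplit(partner, "")[[1]]), collapse = "")
  }
  list(heavy = heavy, light = light,
       log_likelihood = res$log_likelihood[1],
       truncated = res$truncated[1] || !complete)
}
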