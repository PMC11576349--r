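#' Model configuration
#'
#' Architecture hyperparameters of the decoder-only autoregressive
#' transformer. The full-scale default mirrors the published paired-antibody
#' configuration: 3 attention layers, 12 heads, embedding size 768,
#' feed-forward size 2048, vocabulary 26, tied input/output embeddings, a
#' learned absolute-position table of 1024 retained alongside rotary
#' attention — an accounting that yields exactly 17,349,888 trainable
#' parameters (see [count_parameters()]). The vocabulary composition,
#' embedding tying and position-table retention are not published; these
#' defaults are reverse-engineered to match the printed parameter total and
#' are documented as such.
#'
#' @param n_layers,n_heads,d_model,d_ff Transformer shape. `d_model` must be
#'   divisible by `n_heads`.
#' @param vocab_size Token vocabulary size (at least 24).
#' @param max_positions Longest token stream the model accepts (sentinels
#'   included); also the size of the learned position table.
#' @param tie_embeddings Share the input embedding matrix with the output
#'   projection (no output bias).
#' @param use_learned_positions Keep a learned absolute position table in
#'   addition to rotary query/key rotation.
#' @param rotary_base Rotary frequency base; rotation spans the full head
#'   dimension of every layer.
#' @return An `fv_config` list.
#' @examples
#' count_parameters(model_config())  # 17349888
#' @export
model_config <- function(n_layers = 3L, n_heads = 12L, d_model = 768L,
                         d_ff = 2048L, vocab_size = 26L, max_positions = 1024L,
                         tie_embeddings = TRUE, use_learned_positions = TRUE,
                         rotary_base = 10000) {
  if (d_model %% n_heads != 0L) {
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads, ")",
         call. = FALSE)
  }
  if (vocab_size < 24L) stop("vocab_size must be at least 24", call. = FALSE)
  if ((d_model / n_heads) %% 2L != 0L) {
    stop("head dimension must be even for rotary pairing", call. = FALSE)
  }
  structure(list(
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    d_model = as.integer(d_model), d_ff = as.integer(d_ff),
    vocab_size = as.integer(vocab_size),
    max_positions = as.integer(max_positions),
    tie_embeddings = isTRUE(tie_embeddings),
    use_learned_positions = isTRUE(use_learned_positions),
    rotary_base = rotary_base
  ), class = "fv_config")
}

#' Closed-form trainable parameter count
#'
#' Per layer: `4 d^2 + 2 d f + 9 d + f` (query/key/value and output
#' projections with biases, two layer norms, two feed-forward matrices with
#' biases); plus token embeddings `V d` (doubled if untied), the learned
#' position table `P d` if retained, and the final layer norm `2 d`.
#' The default configuration gives 17,349,888.
#'
#' @param config An [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  d <- config$d_model; f <- config$d_ff
  per_layer <- 4 * d^2 + 2 * d * f + 9 * d + f
  total <- config$n_layers * per_layer +
    config$vocab_size * d +
    (if (config$tie_embeddings) 0 else config$vocab_size * d) +
    (if (config$use_learned_positions) config$max_positions * d else 0) +
    2 * d
  as.integer(total)
}

# enumerate every parameter tensor's length (two-route check for the closed form)
count_parameters_enumerated <- function(model) {
  sum(vapply(flatten_params(model$w), length, integer(1)))
}

#' Initialize a model
#'
#' Deterministic (seeded) GPT-2-style initialization: weights from
#' N(0, 0.02^2) with residual output projections scaled by
#' `1/sqrt(2 n_layers)`, zero biases, unit layer-norm gains. Causal masking
#' is enforced in the forward pass, so logits at position t depend only on
#' tokens at positions <= t.
#'
#' @param config An [model_config()].
#' @param seed Integer seed; identical config + seed gives bitwise-identical
#'   parameters.
#' @param vocab The [fv_vocabulary()] the model is bound to; its size must
#'   equal `config$vocab_size`.
#' @return An `fv_model`: list with `config`, `w` (weights), `vocab`, `meta`.
#' @export
init_model <- function(config, seed = 0L, vocab = fv_vocabulary(config$vocab_size)) {
  stopifnot(inherits(config, "fv_config"))
  if (length(vocab) != config$vocab_size) {
    stop("vocabulary size does not match config$vocab_size", call. = FALSE)
  }
  d <- config$d_model; f <- config$d_ff; V <- config$vocab_size
  w <- with_seed(seed, {
    rn <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    resid_sd <- 0.02 / sqrt(2 * config$n_layers)
    w <- list(
      tok_emb = rn(V, d),
      layers = lapply(seq_len(config$n_layers), function(l) list(
        ln1_g = rep(1, d), ln1_b = rep(0, d),
        w_qkv = rn(d, 3 * d), b_qkv = rep(0, 3 * d),
        w_o = rn(d, d, resid_sd), b_o = rep(0, d),
        ln2_g = rep(1, d), ln2_b = rep(0, d),
        w_f1 = rn(d, f), b_f1 = rep(0, f),
        w_f2 = rn(f, d, resid_sd), b_f2 = rep(0, d)
      )),
      lnf_g = rep(1, d), lnf_b = rep(0, d)
    )
    if (config$use_learned_positions) w$pos_emb <- rn(config$max_positions, d, 0.01)
    if (!config$tie_embeddings) w$out_emb <- rn(V, d)
    w
  })
  structure(list(config = config, w = w, vocab = vocab,
                 meta = list(seed = as.integer(seed), stage = "initialized",
                             epochs_trained = 0L)),
            class = "fv_model")
}

#' @export
print.fv_model <- function(x, ...) {
  cfg <- x$config
  cat("<fv_model> ", cfg$n_layers, " layers, ", cfg$n_heads, " heads, d_model ",
      cfg$d_model, ", d_ff ", cfg$d_ff, ", ", count_parameters(cfg),
      " parameters; stage: ", x$meta$stage, "\n", sep = "")
  invisible(x)
}

# ---- numeric building blocks ------------------------------------------------

LN_EPS <- 1e-5

add_bias <- function(X, b) X + rep(b, each = nrow(X))

ln_fwd <- function(X, g, b) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  rstd <- 1 / sqrt(.rowMeans(xc * xc, n, d) + LN_EPS)
  xhat <- xc * rstd
  list(y = add_bias(xhat * rep(g, each = n), b), xhat = xhat, rstd = rstd)
}

# tanh-approximation GELU (the GPT-2 convention); gelu_tanh() returns the
# cached tanh term so the backward pass reuses it
GELU_C <- sqrt(2 / pi)
gelu_tanh <- function(X) tanh(GELU_C * (X + 0.044715 * X^3))
gelu_fwd <- function(X, t = gelu_tanh(X)) 0.5 * X * (1 + t)
gelu_grad <- function(X, t = gelu_tanh(X)) {
  0.5 * (1 + t) + 0.5 * X * (1 - t * t) * GELU_C * (1 + 3 * 0.044715 * X^2)
}

# rotary cos/sin tables for positions 0..(L-1); dh = head dim (even)
rotary_tables <- function(L, dh, base) {
  half <- dh / 2L
  theta <- base^(-(2 * (seq_len(half) - 1)) / dh)
  ang <- outer(0:(L - 1), theta)           # L x half
  list(cos = cos(ang), sin = sin(ang))
}

# apply rotary rotation to Q or K laid out as N x d_model (heads contiguous).
# COS/SIN are N x half matrices (already expanded to row positions).
# sign = +1 forward rotation, -1 for the transpose (backward).
rope_apply <- function(X, n_heads, dh, COS, SIN, sign = 1) {
  half <- dh / 2L
  out <- X
  for (h in seq_len(n_heads)) {
    off <- (h - 1L) * dh
    i1 <- off + 2L * seq_len(half) - 1L     # odd slots of the head
    i2 <- i1 + 1L
    x1 <- X[, i1, drop = FALSE]; x2 <- X[, i2, drop = FALSE]
    if (sign > 0) {
      out[, i1] <- x1 * COS - x2 * SIN
      out[, i2] <- x1 * SIN + x2 * COS
    } else {
      out[, i1] <- x1 * COS + x2 * SIN
      out[, i2] <- -x1 * SIN + x2 * COS
    }
  }
  out
}

# ---- batched forward pass ---------------------------------------------------

# tokens: B x L integer matrix (padded); lens: true stream lengths.
# Returns activations needed for loss/backward when keep_cache = TRUE.
# Row layout of activation matrices: row (b-1)*L + t  <-> sequence b, position t.
model_forward <- function(model, tokens, lens, keep_cache = FALSE) {
  cfg <- model$config; w <- model$w
  B <- nrow(tokens); L <- ncol(tokens)
  if (L > cfg$max_positions) {
    stop("stream length ", L, " exceeds max_positions ", cfg$max_positions,
         call. = FALSE)
  }
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  N <- B * L
  tokv <- as.integer(t(tokens))            # row-order (b-1)*L + t
  posv <- rep.int(seq_len(L), B)
  X <- w$tok_emb[tokv, , drop = FALSE]
  if (cfg$use_learned_positions) X <- X + w$pos_emb[posv, , drop = FALSE]
  rot <- rotary_tables(L, dh, cfg$rotary_base)
  COS <- rot$cos[posv, , drop = FALSE]
  SIN <- rot$sin[posv, , drop = FALSE]
  scale <- 1 / sqrt(dh)
  cache <- if (keep_cache) list(tokv = tokv, posv = posv, COS = COS, SIN = SIN,
                                layers = vector("list", cfg$n_layers))
  rowsb <- lapply(seq_len(B), function(b) ((b - 1L) * L + 1L):(b * L))
  neg_mask <- matrix(0, L, L)              # additive causal mask
  neg_mask[upper.tri(neg_mask)] <- -Inf
  for (l in seq_len(cfg$n_layers)) {
    ly <- w$layers[[l]]
    a1 <- ln_fwd(X, ly$ln1_g, ly$ln1_b)
    QKV <- add_bias(a1$y %*% ly$w_qkv, ly$b_qkv)
    Q <- rope_apply(QKV[, 1:d, drop = FALSE], H, dh, COS, SIN)
    K <- rope_apply(QKV[, (d + 1):(2 * d), drop = FALSE], H, dh, COS, SIN)
    Vv <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
    CTX <- matrix(0, N, d)
    Pc <- if (keep_cache) vector("list", B)
    for (b in seq_len(B)) {
      rows <- rowsb[[b]]
      Ph <- if (keep_cache) vector("list", H)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        q <- Q[rows, hc, drop = FALSE]
        k <- K[rows, hc, drop = FALSE]
        S <- tcrossprod(q, k) * scale + neg_mask
        S <- S - max(S)                    # global shift; scores are bounded
        P <- exp(S)
        P <- P / .rowSums(P, L, L)
        CTX[rows, hc] <- P %*% Vv[rows, hc, drop = FALSE]
        if (keep_cache) Ph[[h]] <- P
      }
      if (keep_cache) Pc[[b]] <- Ph
    }
    att_out <- add_bias(CTX %*% ly$w_o, ly$b_o)
    X1 <- X + att_out
    a2 <- ln_fwd(X1, ly$ln2_g, ly$ln2_b)
    H1 <- add_bias(a2$y %*% ly$w_f1, ly$b_f1)
    gt <- gelu_tanh(H1)
    Hg <- gelu_fwd(H1, gt)
    X <- X1 + add_bias(Hg %*% ly$w_f2, ly$b_f2)
    if (keep_cache) {
      cache$layers[[l]] <- list(a1 = a1, QKV = QKV, Q = Q, K = K, V = Vv,
                                P = Pc, CTX = CTX, X1 = X1, a2 = a2,
                                H1 = H1, Hg = Hg, gt = gt)
    }
  }
  af <- ln_fwd(X, w$lnf_g, w$lnf_b)
  E_out <- if (cfg$tie_embeddings) w$tok_emb else w$out_emb
  logits <- tcrossprod(af$y, E_out)        # N x V
  if (keep_cache) {
    cache$X_final <- X; cache$af <- af
  }
  list(logits = logits, hidden = af$y, cache = cache, B = B, L = L)
}

# stable log-softmax over rows (V is small, this is cheap)
log_softmax_rows <- function(logits) {
  mx <- do.call(pmax, as.data.frame(logits))
  sh <- logits - mx
  sh - log(rowSums(exp(sh)))
}

# ---- user-facing scoring ----------------------------------------------------

streams_to_batch <- function(streams) {
  lens <- vapply(streams, function(s) length(s$tokens), integer(1))
  L <- max(lens)
  tokens <- matrix(1L, length(streams), L)   # pad id = 1
  for (i in seq_along(streams)) tokens[i, seq_len(lens[i])] <- streams[[i]]$tokens
  list(tokens = tokens, lens = lens)
}

#' Next-token logits for a prefix
#'
#' @param model An `fv_model`.
#' @param prefix Integer token ids (a stream prefix beginning with a
#'   sentinel), length 1 to `max_positions`.
#' @return Numeric vector of length `vocab_size`: unnormalized logits for
#'   the next token.
#' @export
next_token_logits <- function(model, prefix) {
  prefix <- as.integer(prefix)
  if (length(prefix) < 1L) stop("prefix must be non-empty", call. = FALSE)
  if (length(prefix) > model$config$max_positions) {
    stop("prefix longer than max_positions", call. = FALSE)
  }
  fw <- model_forward(model, matrix(prefix, nrow = 1L), length(prefix))
  as.numeric(fw$logits[length(prefix), ])
}

#' Sequence log-likelihood and perplexity
#'
#' `sequence_log_likelihood()` returns, for each stream, the sum over
#' positions 2..n of the log-probability of the observed token given its
#' predecessors (always <= 0). `perplexity()` is
#' `exp(-log_likelihood / (n - 1))`, the exponential of the mean per-token
#' negative log-likelihood (always >= 1).
#'
#' @param model An `fv_model`.
#' @param streams One [fv_stream()] or a list of them.
#' @param chunk_size Streams scored per forward batch.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference
#'   implementation); the two agree to numerical precision.
#' @export
sequence_log_likelihood <- function(model, streams, chunk_size = 256L,
                                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(streams, "fv_stream")) streams <- list(streams)
  for (s in streams) {
    if (!inherits(s, "fv_stream") || length(s$tokens) < 2L) {
      stop("each stream must be a well-formed fv_stream of length >= 2",
           call. = FALSE)
    }
  }
  lens_all <- vapply(streams, function(s) length(s$tokens), integer(1))
  if (any(lens_all > model$config$max_positions)) {
    stop("stream length exceeds max_positions", call. = FALSE)
  }
  out <- numeric(length(streams))
  idx <- split(seq_along(streams), ceiling(seq_along(streams) / chunk_size))
  for (ix in idx) {
    ba <- streams_to_batch(streams[ix])
    if (engine == "cpp") {
      out[ix] <- .cpp_loglik(model$w, ba$tokens, ba$lens,
                             model$config$n_heads, model$config$rotary_base)
    } else {
      fw <- model_forward(model, ba$tokens, ba$lens)
      lp <- log_softmax_rows(fw$logits)
      L <- ncol(ba$tokens)
      for (j in seq_along(ix)) {
        n <- ba$lens[j]
        rows <- (j - 1L) * L + seq_len(n - 1L)
        targets <- ba$tokens[j, 2:n]
        out[ix[j]] <- sum(lp[cbind(rows, targets)])
      }
    }
  }
  out
}

#' @rdname sequence_log_likelihood
#' @export
perplexity <- function(model, streams, chunk_size = 256L) {
  if (inherits(streams, "fv_stream")) streams <- list(streams)
  ll <- sequence_log_likelihood(model, streams, chunk_size)
  n <- vapply(streams, function(s) length(s$tokens), integer(1))
  exp(-ll / (n - 1))
}

#' Fixed-length sequence embeddings
#'
#' One vector per paired sequence: the mean over (non-padding) positions of
#' the final-layer hidden states of the forward stream. Used by the cosine
#' diversity metric; pluggable, so an external encoder can be substituted.
#'
#' @param model A trained `fv_model`.
#' @param pairs Tibble with `heavy` and `light` columns (or a list of
#'   [fv_stream()]s).
#' @param chunk_size Sequences per forward batch.
#' @param engine `"cpp"` (default) or `"r"` (reference path).
#' @return Numeric matrix, `nrow(pairs)` x `d_model`.
#' @export
embed_sequences <- function(model, pairs, chunk_size = 256L,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  streams <- if (is.data.frame(pairs)) {
    purrr::map2(pairs$heavy, pairs$light, encode_pair,
                direction = "forward", vocab = model$vocab,
                max_positions = model$config$max_positions)
  } else pairs
  out <- matrix(NA_real_, length(streams), model$config$d_model)
  idx <- split(seq_along(streams), ceiling(seq_along(streams) / chunk_size))
  for (ix in idx) {
    ba <- streams_to_batch(streams[ix])
    if (engine == "cpp") {
      out[ix, ] <- .cpp_hidden_means(model$w, ba$tokens, ba$lens,
                                     model$config$n_heads,
                                     model$config$rotary_base)
    } else {
      fw <- model_forward(model, ba$tokens, ba$lens)
      L <- ncol(ba$tokens)
      for (j in seq_along(ix)) {
        rows <- (j - 1L) * L + seq_len(ba$lens[j])
        out[ix[j], ] <- colMeans(fw$hidden[rows, , drop = FALSE])
      }
    }
  }
  out
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is an `.rds` file holding config, weights, vocabulary and
#' training metadata, plus a human-readable JSON sidecar
#' (`<path>.meta.json`). Save then load round-trips bitwise.
#'
#' @param model An `fv_model`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the `fv_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fv_model"))
  saveRDS(model, path)
  meta <- c(model$meta, model$config[c("n_layers", "n_heads", "d_model", "d_ff",
                                       "vocab_size", "max_positions")],
            list(n_parameters = count_parameters(model$config)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fv_model")) stop("not an fv_model checkpoint", call. = FALSE)
  model
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
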