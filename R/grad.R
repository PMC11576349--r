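# Loss and analytic gradients for the decoder transformer.
#
# The loss is mean next-token cross-entropy over all non-padding target
# positions: both sentinels are predicted targets (the end sentinel is the
# stop signal and must be learned); padding is excluded. Gradients are
# derived by hand and verified against finite differences in the test
# suite.

# Forward + loss only (no gradients); used for validation monitoring.
model_loss <- function(model, tokens, lens) {
  ll <- .cpp_loglik(model$w, tokens, as.integer(lens),
                    model$config$n_heads, model$config$rotary_base)
  -sum(ll) / sum(lens - 1L)
}

# reference-path loss through the pure-R forward (used by tests)
model_loss_r <- function(model, tokens, lens) {
  fw <- model_forward(model, tokens, lens)
  ce_from_logits(fw$logits, tokens, lens)$loss
}

# compiled fused forward/backward; the pure-R model_grad below is the
# reference implementation the test suite checks it against
model_grad_fast <- function(model, tokens, lens) {
  res <- .cpp_grad(model$w, tokens, as.integer(lens), model$config$n_heads,
                   model$config$rotary_base)
  res$grads <- match_shapes(res$grads, model$w)
  res
}

# arma vectors come back as n x 1 matrices; restore the weight shapes so
# optimizer updates preserve the parameter structure exactly
match_shapes <- function(g, w) {
  if (is.list(w)) {
    for (nm in seq_along(w)) {
      key <- names(w)[nm]
      gi <- if (!is.null(key) && nzchar(key)) key else nm
      g[[gi]] <- match_shapes(g[[gi]], w[[nm]])
    }
    g
  } else if (!is.matrix(w) && is.matrix(g)) {
    as.numeric(g)
  } else g
}

ce_from_logits <- function(logits, tokens, lens) {
  B <- nrow(tokens); L <- ncol(tokens)
  lp <- log_softmax_rows(logits)
  rows <- integer(0); targets <- integer(0)
  for (b in seq_len(B)) {
    n <- lens[b]
    rows <- c(rows, (b - 1L) * L + seq_len(n - 1L))
    targets <- c(targets, tokens[b, 2:n])
  }
  loss <- -mean(lp[cbind(rows, targets)])
  list(loss = loss, rows = rows, targets = targets, lp = lp)
}

# Full forward/backward. Returns list(loss, grads) with grads shaped like
# model$w.
model_grad <- function(model, tokens, lens) {
  cfg <- model$config; w <- model$w
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  fw <- model_forward(model, tokens, lens, keep_cache = TRUE)
  ca <- fw$cache
  B <- fw$B; L <- fw$L; N <- B * L
  ce <- ce_from_logits(fw$logits, tokens, lens)
  nval <- length(ce$rows)

  # dlogits = (softmax - onehot) / nval on target rows, 0 elsewhere
  dlogits <- matrix(0, N, cfg$vocab_size)
  P <- exp(ce$lp[ce$rows, , drop = FALSE])
  P[cbind(seq_len(nval), ce$targets)] <-
    P[cbind(seq_len(nval), ce$targets)] - 1
  dlogits[ce$rows, ] <- P / nval

  E_out <- if (cfg$tie_embeddings) w$tok_emb else w$out_emb
  g <- empty_grads(w)
  dHf <- dlogits %*% E_out
  dE_out <- crossprod(dlogits, ca$af$y)     # V x d
  if (cfg$tie_embeddings) g$tok_emb <- g$tok_emb + dE_out
  else g$out_emb <- g$out_emb + dE_out

  lnb <- ln_bwd(dHf, ca$af, w$lnf_g)
  g$lnf_g <- lnb$dg; g$lnf_b <- lnb$db
  dX <- lnb$dx

  scale <- 1 / sqrt(dh)
  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- w$layers[[l]]; cl <- ca$layers[[l]]
    gl <- g$layers[[l]]
    # FFN block: X = X1 + (gelu(LN2(X1) W1 + b1)) W2 + b2
    dY2 <- dX
    gl$w_f2 <- crossprod(cl$Hg, dY2)
    gl$b_f2 <- colSums(dY2)
    dHg <- dY2 %*% t(ly$w_f2)
    dH1 <- dHg * gelu_grad(cl$H1, cl$gt)
    gl$w_f1 <- crossprod(cl$a2$y, dH1)
    gl$b_f1 <- colSums(dH1)
    dA2 <- dH1 %*% t(ly$w_f1)
    lnb <- ln_bwd(dA2, cl$a2, ly$ln2_g)
    gl$ln2_g <- lnb$dg; gl$ln2_b <- lnb$db
    dX1 <- dX + lnb$dx                      # residual + LN path
    # attention block: X1 = X + (CTX W_o + b_o)
    dAtt <- dX1
    gl$w_o <- crossprod(cl$CTX, dAtt)
    gl$b_o <- colSums(dAtt)
    dCTX <- dAtt %*% t(ly$w_o)
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        Pm <- cl$P[[b]][[h]]
        dctx <- dCTX[rows, hc, drop = FALSE]
        v <- cl$V[rows, hc, drop = FALSE]
        dP <- tcrossprod(dctx, v)
        dV[rows, hc] <- crossprod(Pm, dctx)
        dS <- Pm * (dP - rowSums(dP * Pm))
        q <- cl$Q[rows, hc, drop = FALSE]
        k <- cl$K[rows, hc, drop = FALSE]
        dQ[rows, hc] <- (dS %*% k) * scale
        dK[rows, hc] <- crossprod(dS, q) * scale
      }
    }
    # undo rotary (transpose rotation) on dQ, dK
    dQ <- rope_apply(dQ, H, dh, ca$COS, ca$SIN, sign = -1)
    dK <- rope_apply(dK, H, dh, ca$COS, ca$SIN, sign = -1)
    dQKV <- cbind(dQ, dK, dV)
    gl$w_qkv <- crossprod(cl$a1$y, dQKV)
    gl$b_qkv <- colSums(dQKV)
    dA1 <- dQKV %*% t(ly$w_qkv)
    lnb <- ln_bwd(dA1, cl$a1, ly$ln1_g)
    gl$ln1_g <- lnb$dg; gl$ln1_b <- lnb$db
    dX <- dX1 + lnb$dx
    g$layers[[l]] <- gl
  }
  # embeddings: aggregate dX rows by token id / position id
  agg <- rowsum(dX, group = ca$tokv)
  ids <- as.integer(rownames(agg))
  g$tok_emb[ids, ] <- g$tok_emb[ids, , drop = FALSE] + agg
  if (cfg$use_learned_positions) {
    aggp <- rowsum(dX, group = ca$posv)
    idsp <- as.integer(rownames(aggp))
    g$pos_emb[idsp, ] <- g$pos_emb[idsp, , drop = FALSE] + aggp
  }
  list(loss = ce$loss, grads = g)
}

# layer-norm backward; fwd is the list returned by ln_fwd
ln_bwd <- function(dy, fwd, g) {
  n <- nrow(dy)
  G <- rep(g, each = n)
  dxhat <- dy * G
  dg <- colSums(dy * fwd$xhat)
  db <- colSums(dy)
  m1 <- .rowMeans(dxhat, n, ncol(dy))
  m2 <- .rowMeans(dxhat * fwd$xhat, n, ncol(dy))
  dx <- fwd$rstd * (dxhat - m1 - fwd$xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

empty_grads <- function(w) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  zero_like(w)
}

# flatten nested weight/grad lists to a flat named list of arrays (stable order)
flatten_params <- function(w, prefix = "") {
  out <- list()
  for (nm in names(w)) {
    x <- w[[nm]]
    key <- paste0(prefix, nm)
    if (nm == "layers") {
      for (l in seq_along(x)) {
        out <- c(out, flatten_params(x[[l]], sprintf("%slayers%02d.", prefix, l)))
      }
    } else {
      out[[key]] <- x
    }
  }
  out
}

# apply a binary op elementwise over two same-shaped nested lists
# (indexes by position so unnamed lists — e.g. the per-layer list — are
# traversed too)
map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      out[[i]] <- map_params(a[[i]], bi, f)
    }
    out
  } else f(a, b)
}
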