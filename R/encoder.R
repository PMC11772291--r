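# Small trainable transformer encoder with hand-written backpropagation.
#
# The encoder is a pre-norm transformer (embedding + positional embedding,
# n_layers of multi-head self-attention and a ReLU feed-forward block with
# residual connections, final layer norm). It is deliberately desk-scale:
# the package's pre-training and fine-tuning objectives are studied on a
# configurable 2-layer/64-dim encoder trained from scratch, and any
# checkpoint implementing this interface can be plugged in.

#' Configure the encoder
#'
#' @param vocab_size vocabulary size (token ids are 1-based).
#' @param hidden_dim model width; must be divisible by \code{n_heads}.
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads.
#' @param max_len maximum sequence length (positional table size).
#' @param dropout dropout rate in [0, 1); the perturbation used both for
#'   regularisation and for the two stochastic passes of R-drop.
#' @param ffn_dim feed-forward inner width.
#' @param seed initialisation seed.
#' @return object of class \code{encoder_config}.
#' @export
encoder_config <- function(vocab_size, hidden_dim = 64L, n_layers = 2L,
                           n_heads = 2L, max_len = 128L, dropout = 0.1,
                           ffn_dim = 2L * hidden_dim, seed = 1L) {
  if (hidden_dim %% n_heads != 0L) {
    stopf("hidden_dim (%d) must be divisible by n_heads (%d)",
          hidden_dim, n_heads)
  }
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(vocab_size = as.integer(vocab_size),
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 max_len = as.integer(max_len),
                 dropout = dropout,
                 ffn_dim = as.integer(ffn_dim),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

rnorm_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Initialise encoder parameters
#'
#' Embeddings and projection weights are drawn N(0, 0.02^2); layer norms
#' start at identity. Label-token embeddings (the reserved \code{<B-...>} /
#' \code{<I-...>} vocabulary block used by entity MLM) are initialised to the
#' mean embedding of the tokens making up the label name, when those tokens
#' exist in the vocabulary, so the inserted labels start semantically close
#' to their names.
#'
#' @param cfg an [encoder_config()].
#' @param vocab an optional [build_vocab()] vocabulary used for label-token
#'   initialisation.
#' @return named list of parameter matrices/vectors.
#' @export
init_encoder_params <- function(cfg, vocab = NULL) {
  with_seed(cfg$seed, {
    d <- cfg$hidden_dim; f <- cfg$ffn_dim
    p <- list(
      tok_emb = rnorm_mat(cfg$vocab_size, d),
      pos_emb = rnorm_mat(cfg$max_len, d),
      ln_f_g = rep(1, d), ln_f_b = rep(0, d),
      lm_b = rep(0, cfg$vocab_size)
    )
    for (l in seq_len(cfg$n_layers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(pre, nm)]] <- rnorm_mat(d, d)
      }
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- rnorm_mat(d, f)
      p[[paste0(pre, "b1")]] <- rep(0, f)
      p[[paste0(pre, "W2")]] <- rnorm_mat(f, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    if (!is.null(vocab)) {
      p$tok_emb <- init_label_token_embeddings(p$tok_emb, vocab)
    }
    p
  })
}

# Mean-of-constituents initialisation for label-token embeddings, e.g.
# <B-disease_location> from the embeddings of "disease" and "location".
init_label_token_embeddings <- function(tok_emb, vocab) {
  for (id in vocab$label_ids) {
    surf <- vocab$tokens[id]                      # e.g. "<B-diagnosis>"
    name <- sub("^<[BI]-(.*)>$", "\\1", surf)
    words <- strsplit(name, "_", fixed = TRUE)[[1L]]
    wids <- match(words, vocab$tokens)
    wids <- wids[!is.na(wids)]
    if (length(wids)) {
      tok_emb[id, ] <- colMeans(tok_emb[wids, , drop = FALSE])
    }
  }
  tok_emb
}

# Layer norm ------------------------------------------------------------

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, sd = sd)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

drop_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - rate), nrow(x), ncol(x)) /
    (1 - rate)
  list(y = x * mask, mask = mask)
}

#' Encoder forward pass
#'
#' @param params parameter list from [init_encoder_params()].
#' @param cfg the [encoder_config()].
#' @param ids integer token ids (1-based), length <= \code{max_len}.
#' @param train enable dropout (draws from the current RNG stream).
#' @param input_override optional n x d matrix replacing the embedding lookup
#'   (used by section fusion in `embed` mode).
#' @return list with \code{H} (n x d final representations) and \code{cache}
#'   for [encoder_backward()].
#' @export
encoder_forward <- function(params, cfg, ids, train = FALSE,
                            input_override = NULL) {
  n <- length(ids)
  if (n == 0L) stopf("empty input sequence")
  if (n > cfg$max_len) stopf("sequence length %d exceeds max_len %d",
                             n, cfg$max_len)
  if (any(ids < 1L | ids > cfg$vocab_size)) stopf("token id out of vocabulary")
  d <- cfg$hidden_dim
  dh <- d %/% cfg$n_heads
  X <- if (is.null(input_override)) {
    params$tok_emb[ids, , drop = FALSE]
  } else {
    input_override
  }
  X <- X + params$pos_emb[seq_len(n), , drop = FALSE]
  cache <- list(ids = ids, n = n, layers = vector("list", cfg$n_layers),
                used_override = !is.null(input_override))
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("l", l, "_")
    lc <- list(X = X)
    ln1 <- ln_fwd(X, params[[paste0(pre, "ln1_g")]],
                  params[[paste0(pre, "ln1_b")]])
    A <- ln1$y
    Q <- A %*% params[[paste0(pre, "Wq")]] +
      rep(params[[paste0(pre, "bq")]], each = n)
    K <- A %*% params[[paste0(pre, "Wk")]] +
      rep(params[[paste0(pre, "bk")]], each = n)
    V <- A %*% params[[paste0(pre, "Wv")]] +
      rep(params[[paste0(pre, "bv")]], each = n)
    O <- matrix(0, n, d)
    Ph <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) /
        sqrt(dh)
      P <- softmax_rows(S)
      Ph[[h]] <- P
      O[, idx] <- P %*% V[, idx, drop = FALSE]
    }
    attn <- O %*% params[[paste0(pre, "Wo")]] +
      rep(params[[paste0(pre, "bo")]], each = n)
    dr1 <- drop_fwd(attn, cfg$dropout, train)
    X2 <- X + dr1$y
    ln2 <- ln_fwd(X2, params[[paste0(pre, "ln2_g")]],
                  params[[paste0(pre, "ln2_b")]])
    B <- ln2$y
    Z1 <- B %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = n)
    H1 <- pmax(Z1, 0)
    FF <- H1 %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = n)
    dr2 <- drop_fwd(FF, cfg$dropout, train)
    X3 <- X2 + dr2$y
    lc$ln1 <- ln1; lc$A <- A; lc$Q <- Q; lc$K <- K; lc$V <- V
    lc$Ph <- Ph; lc$O <- O; lc$dr1 <- dr1; lc$X2 <- X2; lc$ln2 <- ln2
    lc$B <- B; lc$H1 <- H1; lc$dr2 <- dr2
    cache$layers[[l]] <- lc
    X <- X3
  }
  lnf <- ln_fwd(X, params$ln_f_g, params$ln_f_b)
  cache$X_last <- X
  cache$lnf <- lnf
  list(H = lnf$y, cache = cache)
}

#' Encoder backward pass
#'
#' Accumulates gradients for all encoder parameters given the gradient of the
#' loss with respect to the final representations.
#'
#' @param params parameter list.
#' @param cfg the [encoder_config()].
#' @param cache forward cache from [encoder_forward()].
#' @param dH gradient at the output representations (n x d).
#' @return list with \code{grads} (named like \code{params}) and \code{dX0}
#'   (gradient at the embedding-sum input, for fusion layers).
#' @export
encoder_backward <- function(params, cfg, cache, dH) {
  n <- cache$n
  d <- cfg$hidden_dim
  dh <- d %/% cfg$n_heads
  g <- list()
  lb <- ln_bwd(dH, cache$lnf, params$ln_f_g)
  g$ln_f_g <- lb$dg; g$ln_f_b <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    # FFN block
    dFFdrop <- dX
    dFF <- if (is.null(lc$dr2$mask)) dFFdrop else dFFdrop * lc$dr2$mask
    g[[paste0(pre, "W2")]] <- crossprod(lc$H1, dFF)
    g[[paste0(pre, "b2")]] <- colSums(dFF)
    dH1 <- tcrossprod(dFF, params[[paste0(pre, "W2")]])
    dZ1 <- dH1 * (lc$H1 > 0)
    g[[paste0(pre, "W1")]] <- crossprod(lc$B, dZ1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dB <- tcrossprod(dZ1, params[[paste0(pre, "W1")]])
    lb2 <- ln_bwd(dB, lc$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX2 <- dX + lb2$dx
    # attention block
    dattn_drop <- dX2
    dattn <- if (is.null(lc$dr1$mask)) dattn_drop else
      dattn_drop * lc$dr1$mask
    g[[paste0(pre, "Wo")]] <- crossprod(lc$O, dattn)
    g[[paste0(pre, "bo")]] <- colSums(dattn)
    dO <- tcrossprod(dattn, params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      P <- lc$Ph[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dP <- tcrossprod(dOh, lc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dS <- dS / sqrt(dh)
      dQ[, idx] <- dS %*% lc$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, lc$Q[, idx, drop = FALSE])
    }
    g[[paste0(pre, "Wq")]] <- crossprod(lc$A, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(lc$A, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(lc$A, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dA <- tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "Wv")]])
    lb1 <- ln_bwd(dA, lc$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX2 + lb1$dx
  }
  # dX is the gradient at the embedding sum (token/override + positional)
  g$pos_emb <- matrix(0, cfg$max_len, d)
  g$pos_emb[seq_len(n), ] <- dX
  g$tok_emb <- matrix(0, cfg$vocab_size, d)
  if (!cache$used_override) {
    agg <- rowsum(dX, group = cache$ids)
    g$tok_emb[as.integer(rownames(agg)), ] <- agg
  }
  list(grads = g, dX0 = dX)
}

# Gradient accumulation: a + b elementwise over shared names.
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    gr <- grads[[nm]]
    if (weight_decay > 0) gr <- gr + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Linear warmup then constant decay to zero over the step budget.
lr_schedule <- function(step, total_steps, base_lr, warmup_ratio = 0.1) {
  warm <- max(1, floor(total_steps * warmup_ratio))
  if (step <= warm) return(base_lr * step / warm)
  base_lr * max(0.05, 1 - (step - warm) / max(1, total_steps - warm))
}

# Parameter fingerprint used to assert teacher immutability.
params_hash <- function(params) {
  v <- unlist(params[sort(names(params))], use.names = FALSE)
  paste(format(sum(v), digits = 17), format(sum(v * v), digits = 17),
        format(sum(abs(v)), digits = 17))
}
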