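# Bidirectional transformer encoder with three pretraining heads
# (masked-token recovery, physicochemical regression, in vitro panel
# classification) and the dual-pass (corrupted + clean) training loop.
#
# The encoder is a standard pre-norm transformer: token + learned position
# embeddings with layer norm, L blocks of multi-head self-attention and a
# GELU feed-forward, each wrapped in residual connections, and a final
# layer norm. The pooled molecule representation is the first-position
# (begin-marker) output passed through a learned tanh pooling layer; mean
# pooling over non-pad positions is available in the config.

.PAD_ID <- 1L
.BEGIN_ID <- 2L
.END_ID <- 3L
.MASK_ID <- 4L
.UNK_ID <- 5L

#' Encoder configuration
#'
#' @param layers number of transformer blocks (default 12).
#' @param n_heads attention heads (default 12); must divide `hidden`.
#' @param hidden hidden size (default 768).
#' @param ffn_mult feed-forward width multiplier (default 4).
#' @param max_length maximum token sequence length (default 128).
#' @param vocab_size vocabulary size V.
#' @param n_physchem number of physicochemical descriptor targets.
#' @param n_invitro number of in vitro tasks (0 disables the head).
#' @param head_hidden hidden width of the physchem/invitro heads
#'   (default = `hidden`).
#' @param pooling `"first"` (default) or `"mean"`.
#' @param heads character vector of enabled heads, subset of
#'   `c("mask", "physchem", "invitro")`.
#' @param seed integer seed for weight initialization.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(layers = 12L, n_heads = 12L, hidden = 768L,
                           ffn_mult = 4L, max_length = 128L,
                           vocab_size, n_physchem = 0L, n_invitro = 0L,
                           head_hidden = NULL,
                           pooling = c("first", "mean"),
                           heads = c("mask", "physchem", "invitro"),
                           seed = 1L) {
  pooling <- match.arg(pooling)
  if (hidden %% n_heads != 0) stop("hidden size must be divisible by n_heads")
  if (!length(heads)) stop("at least one head must be enabled")
  heads <- match.arg(heads, several.ok = TRUE)
  if ("invitro" %in% heads && n_invitro == 0L) {
    heads <- setdiff(heads, "invitro")
  }
  structure(list(
    layers = as.integer(layers), n_heads = as.integer(n_heads),
    hidden = as.integer(hidden), ffn_mult = as.integer(ffn_mult),
    max_length = as.integer(max_length), vocab_size = as.integer(vocab_size),
    n_physchem = as.integer(n_physchem), n_invitro = as.integer(n_invitro),
    head_hidden = as.integer(head_hidden %||% hidden),
    pooling = pooling, heads = heads, seed = as.integer(seed)
  ), class = "encoder_config")
}

#' Desk-test encoder preset (2 layers, 4 heads, 64 hidden)
#' @inheritParams encoder_config
#' @param ... passed through to [encoder_config()].
#' @export
encoder_config_tiny <- function(vocab_size, n_physchem = 0L, n_invitro = 0L,
                                head_hidden = 64L, ffn_mult = 2L, ...) {
  encoder_config(layers = 2L, n_heads = 4L, hidden = 64L,
                 ffn_mult = ffn_mult, vocab_size = vocab_size,
                 n_physchem = n_physchem, n_invitro = n_invitro,
                 head_hidden = head_hidden, ...)
}

# one transformer block's parameters
.init_layer <- function(H, F) {
  list(
    ln1_g = rep(1, H), ln1_b = rep(0, H),
    Wq = .init_mat(H, H), bq = rep(0, H),
    Wk = .init_mat(H, H), bk = rep(0, H),
    Wv = .init_mat(H, H), bv = rep(0, H),
    Wo = .init_mat(H, H), bo = rep(0, H),
    ln2_g = rep(1, H), ln2_b = rep(0, H),
    W1 = .init_mat(H, F), b1 = rep(0, F),
    W2 = .init_mat(F, H), b2 = rep(0, H)
  )
}

#' Initialize encoder + head parameters
#' @param cfg an [encoder_config()].
#' @return nested parameter list.
#' @export
init_params <- function(cfg) {
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(cfg$seed)
  H <- cfg$hidden
  F <- H * cfg$ffn_mult
  hh <- cfg$head_hidden
  p <- list(
    tok_emb = .init_mat(cfg$vocab_size, H),
    pos_emb = .init_mat(cfg$max_length, H),
    emb_ln_g = rep(1, H), emb_ln_b = rep(0, H),
    layers = lapply(seq_len(cfg$layers), function(i) .init_layer(H, F)),
    final_ln_g = rep(1, H), final_ln_b = rep(0, H),
    pool_W = .init_mat(H, H), pool_b = rep(0, H)
  )
  if ("physchem" %in% cfg$heads) {
    p$pc_W1 <- .init_mat(H, hh); p$pc_b1 <- rep(0, hh)
    p$pc_W2 <- .init_mat(hh, cfg$n_physchem); p$pc_b2 <- rep(0, cfg$n_physchem)
  }
  if ("invitro" %in% cfg$heads) {
    p$iv_W1 <- .init_mat(H, hh); p$iv_b1 <- rep(0, hh)
    p$iv_W2 <- .init_mat(hh, cfg$n_invitro); p$iv_b2 <- rep(0, cfg$n_invitro)
  }
  if ("mask" %in% cfg$heads) {
    p$mh_W1 <- .init_mat(H, H); p$mh_b1 <- rep(0, H)
    p$mh_ln_g <- rep(1, H); p$mh_ln_b <- rep(0, H)
    p$mh_layer <- .init_layer(H, F)
    p$mh_Wv <- .init_mat(H, cfg$vocab_size)
    p$mh_bv <- rep(0, cfg$vocab_size)
  }
  p
}

# ---- transformer block --------------------------------------------------

# X: (B*T) x H flat activations, sequence-major (rows (b-1)*T + 1:T);
# keymask: B x T logical, TRUE = real (non-pad) token
# dispatch: compiled fast path with a pure-R reference (.tf_layer_*_r)
.tf_layer_fwd <- function(X, p, B, T, nh, keymask) {
  .tf_layer_fwd_cpp(X, p, as.integer(B), as.integer(T), as.integer(nh),
                    matrix(as.integer(keymask), nrow(keymask)))
}

.tf_layer_bwd <- function(dY, p, cache) {
  r <- .tf_layer_bwd_cpp(dY, p, cache)
  r$grads <- lapply(r$grads, function(x)
    if (is.matrix(x) && nrow(x) == 1L) drop(x) else x)
  r
}

.tf_layer_fwd_r <- function(X, p, B, T, nh, keymask) {
  H <- ncol(X)
  dh <- H %/% nh
  l1 <- ln_fwd(X, p$ln1_g, p$ln1_b)
  Q <- dense_fwd(l1$y, p$Wq, p$bq)
  K <- dense_fwd(l1$y, p$Wk, p$bk)
  V <- dense_fwd(l1$y, p$Wv, p$bv)
  O <- matrix(0, nrow(X), H)
  Plist <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    km <- keymask[b, ]
    Pb <- vector("list", nh)
    for (a in seq_len(nh)) {
      cols <- ((a - 1L) * dh + 1L):(a * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dh)
      if (!all(km)) S[, !km] <- -1e9
      P <- softmax_rows(S)
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      Pb[[a]] <- P
    }
    Plist[[b]] <- Pb
  }
  att <- dense_fwd(O, p$Wo, p$bo)
  X1 <- X + att
  l2 <- ln_fwd(X1, p$ln2_g, p$ln2_b)
  F1 <- dense_fwd(l2$y, p$W1, p$b1)
  gl <- gelu_fwd(F1)
  A <- gl$y
  F2 <- dense_fwd(A, p$W2, p$b2)
  X2 <- X1 + F2
  list(y = X2,
       cache = list(l1 = l1, l2 = l2, Q = Q, K = K, V = V, O = O,
                    P = Plist, F1 = F1, A = A, pn = gl$pn,
                    B = B, T = T, nh = nh))
}

.tf_layer_bwd_r <- function(dY, p, cache) {
  B <- cache$B; T <- cache$T; nh <- cache$nh
  H <- ncol(dY)
  dh <- H %/% nh
  g <- list()
  # FFN
  d2 <- dense_bwd(dY, cache$A, p$W2)
  g$W2 <- d2$dW; g$b2 <- d2$db
  dF1 <- d2$dx * gelu_grad_cached(cache$F1, cache$pn)
  d1 <- dense_bwd(dF1, cache$l2$y, p$W1)
  g$W1 <- d1$dW; g$b1 <- d1$db
  l2b <- ln_bwd(d1$dx, cache$l2$cache)
  g$ln2_g <- l2b$dg; g$ln2_b <- l2b$db
  dX1 <- dY + l2b$dx
  # attention output projection
  do_ <- dense_bwd(dX1, cache$O, p$Wo)
  g$Wo <- do_$dW; g$bo <- do_$db
  dO <- do_$dx
  dQ <- matrix(0, nrow(dY), H)
  dK <- matrix(0, nrow(dY), H)
  dV <- matrix(0, nrow(dY), H)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (a in seq_len(nh)) {
      cols <- ((a - 1L) * dh + 1L):(a * dh)
      P <- cache$P[[b]][[a]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) /
        sqrt(dh)
    }
  }
  dq <- dense_bwd(dQ, cache$l1$y, p$Wq)
  dk <- dense_bwd(dK, cache$l1$y, p$Wk)
  dv <- dense_bwd(dV, cache$l1$y, p$Wv)
  g$Wq <- dq$dW; g$bq <- dq$db
  g$Wk <- dk$dW; g$bk <- dk$db
  g$Wv <- dv$dW; g$bv <- dv$db
  l1b <- ln_bwd(dq$dx + dk$dx + dv$dx, cache$l1$cache)
  g$ln1_g <- l1b$dg; g$ln1_b <- l1b$db
  dX <- dX1 + l1b$dx
  list(dx = dX, grads = g[names(p)])
}

# ---- encoder forward / backward ----------------------------------------

# ids: B x T integer matrix (padded with .PAD_ID)
.encoder_fwd <- function(params, cfg, ids) {
  B <- nrow(ids); T <- ncol(ids)
  keymask <- ids != .PAD_ID
  ids_flat <- as.vector(t(ids))
  pos_flat <- rep(seq_len(T), B)
  E <- params$tok_emb[ids_flat, , drop = FALSE] +
    params$pos_emb[pos_flat, , drop = FALSE]
  eln <- ln_fwd(E, params$emb_ln_g, params$emb_ln_b)
  X <- eln$y
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    r <- .tf_layer_fwd(X, params$layers[[l]], B, T, cfg$n_heads, keymask)
    X <- r$y
    caches[[l]] <- r$cache
  }
  fln <- ln_fwd(X, params$final_ln_g, params$final_ln_b)
  seq_out <- fln$y
  if (cfg$pooling == "first") {
    pooled_in <- seq_out[(seq_len(B) - 1L) * T + 1L, , drop = FALSE]
  } else {
    pooled_in <- t(vapply(seq_len(B), function(b) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      colMeans(seq_out[rows[keymask[b, ]], , drop = FALSE])
    }, numeric(cfg$hidden)))
  }
  pre_pool <- dense_fwd(pooled_in, params$pool_W, params$pool_b)
  pooled <- tanh(pre_pool)
  list(seq = seq_out, pooled = pooled,
       cache = list(ids_flat = ids_flat, pos_flat = pos_flat,
                    eln = eln, layers = caches, fln = fln,
                    keymask = keymask, pooled_in = pooled_in,
                    pooled = pooled, B = B, T = T))
}

# dseq: gradient wrt the final sequence output ((B*T) x H or NULL);
# dpooled: gradient wrt the pooled output (B x H or NULL)
.encoder_bwd <- function(dseq, dpooled, params, cfg, cache) {
  B <- cache$B; T <- cache$T
  H <- cfg$hidden
  g <- list()
  if (is.null(dseq)) dseq <- matrix(0, B * T, H)
  if (!is.null(dpooled)) {
    dpre <- dpooled * (1 - cache$pooled^2)
    dp <- dense_bwd(dpre, cache$pooled_in, params$pool_W)
    g$pool_W <- dp$dW; g$pool_b <- dp$db
    if (cfg$pooling == "first") {
      first_rows <- (seq_len(B) - 1L) * T + 1L
      dseq[first_rows, ] <- dseq[first_rows, ] + dp$dx
    } else {
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * T + 1L):(b * T)
        real <- rows[cache$keymask[b, ]]
        dseq[real, ] <- dseq[real, ] +
          matrix(dp$dx[b, ] / length(real), length(real), H, byrow = TRUE)
      }
    }
  } else {
    g$pool_W <- params$pool_W * 0; g$pool_b <- params$pool_b * 0
  }
  flb <- ln_bwd(dseq, cache$fln$cache)
  g$final_ln_g <- flb$dg; g$final_ln_b <- flb$db
  dX <- flb$dx
  g$layers <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    r <- .tf_layer_bwd(dX, params$layers[[l]], cache$layers[[l]])
    dX <- r$dx
    g$layers[[l]] <- r$grads
  }
  elb <- ln_bwd(dX, cache$eln$cache)
  g$emb_ln_g <- elb$dg; g$emb_ln_b <- elb$db
  dE <- elb$dx
  dtok <- matrix(0, cfg$vocab_size, H)
  agg <- rowsum(dE, cache$ids_flat)
  dtok[as.integer(rownames(agg)), ] <- agg
  g$tok_emb <- dtok
  dpos <- matrix(0, cfg$max_length, H)
  aggp <- rowsum(dE, cache$pos_flat)
  dpos[as.integer(rownames(aggp)), ] <- aggp
  g$pos_emb <- dpos
  g
}

# ---- heads --------------------------------------------------------------

.physchem_fwd <- function(params, pooled) {
  h <- dense_fwd(pooled, params$pc_W1, params$pc_b1)
  a <- relu(h)
  y <- dense_fwd(a, params$pc_W2, params$pc_b2)
  list(y = y, cache = list(h = h, a = a, pooled = pooled))
}

.physchem_bwd <- function(dy, params, cache) {
  d2 <- dense_bwd(dy, cache$a, params$pc_W2)
  da <- d2$dx * (cache$h > 0)
  d1 <- dense_bwd(da, cache$pooled, params$pc_W1)
  list(dpooled = d1$dx,
       grads = list(pc_W1 = d1$dW, pc_b1 = d1$db,
                    pc_W2 = d2$dW, pc_b2 = d2$db))
}

.invitro_fwd <- function(params, pooled) {
  h <- dense_fwd(pooled, params$iv_W1, params$iv_b1)
  a <- relu(h)
  f <- dense_fwd(a, params$iv_W2, params$iv_b2)
  list(f = f, cache = list(h = h, a = a, pooled = pooled))
}

.invitro_bwd <- function(df, params, cache) {
  d2 <- dense_bwd(df, cache$a, params$iv_W2)
  da <- d2$dx * (cache$h > 0)
  d1 <- dense_bwd(da, cache$pooled, params$iv_W1)
  list(dpooled = d1$dx,
       grads = list(iv_W1 = d1$dW, iv_b1 = d1$db,
                    iv_W2 = d2$dW, iv_b2 = d2$db))
}

# masking head: linear -> GELU -> LayerNorm -> one encoder block -> vocab
.mask_head_fwd <- function(params, cfg, seq_out, B, T, keymask) {
  z <- dense_fwd(seq_out, params$mh_W1, params$mh_b1)
  gl <- gelu_fwd(z)
  a <- gl$y
  l <- ln_fwd(a, params$mh_ln_g, params$mh_ln_b)
  blk <- .tf_layer_fwd(l$y, params$mh_layer, B, T, cfg$n_heads, keymask)
  logits <- dense_fwd(blk$y, params$mh_Wv, params$mh_bv)
  list(logits = logits,
       cache = list(z = z, pn = gl$pn, l = l, blk = blk, seq_out = seq_out))
}

.mask_head_bwd <- function(dlogits, params, cache) {
  dv <- dense_bwd(dlogits, cache$blk$y, params$mh_Wv)
  blkb <- .tf_layer_bwd(dv$dx, params$mh_layer, cache$blk$cache)
  lb <- ln_bwd(blkb$dx, cache$l$cache)
  da <- lb$dx * gelu_grad_cached(cache$z, cache$pn)
  d1 <- dense_bwd(da, cache$seq_out, params$mh_W1)
  list(dseq = d1$dx,
       grads = list(mh_W1 = d1$dW, mh_b1 = d1$db,
                    mh_ln_g = lb$dg, mh_ln_b = lb$db,
                    mh_layer = blkb$grads,
                    mh_Wv = dv$dW, mh_bv = dv$db))
}

# ---- corruption ---------------------------------------------------------

#' Corrupt a token batch for masked-token pretraining
#'
#' Each non-special position (pad, begin and end markers are never masked)
#' is independently masked with probability `mask_rate`. By default every
#' selected token is replaced by the mask token; `bert_style = TRUE`
#' switches to the 80/10/10 replace/random/keep policy. Uses the current
#' RNG state, so results are reproducible under `set.seed()`.
#'
#' @param ids integer matrix (batch x positions), padded with the pad id.
#' @param mask_rate masking probability in (0, 1).
#' @param vocab_size vocabulary size (needed for `bert_style` random
#'   replacement).
#' @param bert_style logical, default `FALSE`.
#' @return list with `ids` (corrupted matrix), `mask` (logical matrix of
#'   masked positions), `n_masked`, and `orig` (the input matrix).
#' @export
corrupt_tokens <- function(ids, mask_rate = 0.15, vocab_size = NULL,
                           bert_style = FALSE) {
  stopifnot(mask_rate > 0, mask_rate < 1)
  maskable <- !(ids %in% c(.PAD_ID, .BEGIN_ID, .END_ID))
  dim(maskable) <- dim(ids)
  u <- matrix(stats::runif(length(ids)), nrow(ids), ncol(ids))
  mask <- maskable & (u < mask_rate)
  out <- ids
  if (any(mask)) {
    if (bert_style) {
      r <- matrix(stats::runif(length(ids)), nrow(ids), ncol(ids))
      repl <- mask & (r < 0.8)
      rand <- mask & (r >= 0.8) & (r < 0.9)
      out[repl] <- .MASK_ID
      if (any(rand)) {
        if (is.null(vocab_size)) stop("vocab_size required for bert_style")
        out[rand] <- sample(seq(.UNK_ID + 1L, vocab_size), sum(rand),
                            replace = TRUE)
      }
    } else {
      out[mask] <- .MASK_ID
    }
  }
  list(ids = out, mask = mask, n_masked = sum(mask), orig = ids)
}

# ---- batching -----------------------------------------------------------

#' Collate token sequences into a padded batch matrix
#'
#' @param token_list list of integer token vectors.
#' @param max_length optional cap; a longer sequence raises an error.
#' @return integer matrix (batch x positions), padded with the pad id.
#' @export
collate_batch <- function(token_list, max_length = NULL) {
  T <- max(lengths(token_list))
  if (!is.null(max_length) && T > max_length) {
    stop(sprintf("batch sequence length %d exceeds max_length %d",
                 T, max_length))
  }
  B <- length(token_list)
  ids <- matrix(.PAD_ID, B, T)
  for (b in seq_len(B)) {
    ids[b, seq_along(token_list[[b]])] <- token_list[[b]]
  }
  ids
}

# ---- dual pass ----------------------------------------------------------

#' Dual-pass forward through encoder and heads
#'
#' Processes a batch twice: once with tokens randomly masked (the corrupted
#' pass, feeding the masking head) and once unmodified (the clean pass,
#' feeding the physchem and invitro heads). Uses the current RNG state for
#' the mask draw.
#'
#' @param params parameter list from [init_params()].
#' @param cfg an [encoder_config()].
#' @param token_list list of integer token vectors (one molecule each).
#' @param mask_rate masking probability (default 0.15).
#' @return list with `mask_logits` (positions x V, corrupted pass; `NULL`
#'   if the mask head is disabled), `physchem` (B x D), `invitro` (B x P),
#'   `corruption`, and internal caches.
#' @export
dual_pass <- function(params, cfg, token_list, mask_rate = 0.15) {
  ids <- collate_batch(token_list, cfg$max_length)
  B <- nrow(ids); T <- ncol(ids)
  keymask <- ids != .PAD_ID
  out <- list()
  if ("mask" %in% cfg$heads) {
    corr <- corrupt_tokens(ids, mask_rate, cfg$vocab_size)
    enc_c <- .encoder_fwd(params, cfg, corr$ids)
    mh <- .mask_head_fwd(params, cfg, enc_c$seq, B, T, keymask)
    out$mask_logits <- mh$logits
    out$corruption <- corr
    out$.enc_corr <- enc_c
    out$.mh <- mh
  }
  enc <- .encoder_fwd(params, cfg, ids)
  out$.enc_clean <- enc
  out$pooled <- enc$pooled
  if ("physchem" %in% cfg$heads) {
    pc <- .physchem_fwd(params, enc$pooled)
    out$physchem <- pc$y
    out$.pc <- pc
  }
  if ("invitro" %in% cfg$heads) {
    iv <- .invitro_fwd(params, enc$pooled)
    out$invitro <- iv$f
    out$.iv <- iv
  }
  out$.ids <- ids
  out
}

#' Combined multi-objective pretraining loss
#'
#' Arithmetic mean of the enabled head losses: masked-token cross-entropy
#' on the corrupted pass, physchem MSE and in vitro weighted focal loss
#' (fixed `alpha = 1`, `gamma = 2`) on the clean pass.
#'
#' @param outs output of [dual_pass()].
#' @param targets list with `tokens` (original id matrix), `physchem`
#'   (B x D matrix) and `invitro` (B x P label matrix) as required by the
#'   enabled heads.
#' @param cfg an [encoder_config()].
#' @param invitro_weights per-task positive weights for the in vitro loss
#'   (usually from training-set counts).
#' @return list with `total` and per-head `components`.
#' @export
combined_loss <- function(outs, targets, cfg, invitro_weights = NULL) {
  comps <- c()
  if ("mask" %in% cfg$heads) {
    truth <- as.vector(t(outs$corruption$orig))
    mvec <- as.vector(t(outs$corruption$mask))
    comps["mask"] <- if (any(mvec)) {
      masking_loss(outs$mask_logits, truth, mvec)
    } else NA_real_
  }
  if ("physchem" %in% cfg$heads) {
    comps["physchem"] <- physchem_loss(outs$physchem, targets$physchem)
  }
  if ("invitro" %in% cfg$heads) {
    comps["invitro"] <- weighted_focal_loss(
      targets$invitro, outs$invitro,
      loss_config(alpha = 1, gamma = 2, weights = invitro_weights)
    )
  }
  ok <- !is.na(comps)
  list(total = mean(comps[ok]), components = comps)
}

# one training step: forward, all backward passes, gradient tree
.pretrain_step <- function(params, cfg, token_list, targets,
                           invitro_weights, mask_rate) {
  outs <- dual_pass(params, cfg, token_list, mask_rate)
  loss <- combined_loss(outs, targets, cfg, invitro_weights)
  nh <- sum(!is.na(loss$components))
  grads <- tree_zeros_like(params)

  if ("mask" %in% cfg$heads && outs$corruption$n_masked > 0) {
    truth <- as.vector(t(outs$corruption$orig))
    mvec <- as.vector(t(outs$corruption$mask))
    probs <- softmax_rows(outs$mask_logits[mvec, , drop = FALSE])
    onehot <- matrix(0, nrow(probs), cfg$vocab_size)
    onehot[cbind(seq_len(nrow(probs)), truth[mvec])] <- 1
    dlog <- matrix(0, nrow(outs$mask_logits), cfg$vocab_size)
    dlog[mvec, ] <- (probs - onehot) / sum(mvec) / nh
    mhb <- .mask_head_bwd(dlog, params, outs$.mh$cache)
    encg <- .encoder_bwd(mhb$dseq, NULL, params, cfg, outs$.enc_corr$cache)
    for (nm in names(mhb$grads)) grads[[nm]] <- tree_add(grads[[nm]],
                                                         mhb$grads[[nm]])
    for (nm in names(encg)) grads[[nm]] <- tree_add(grads[[nm]], encg[[nm]])
  }

  dpooled <- NULL
  if ("physchem" %in% cfg$heads) {
    dy <- 2 * (outs$physchem - targets$physchem) /
      nrow(outs$physchem) / nh
    pcb <- .physchem_bwd(dy, params, outs$.pc$cache)
    for (nm in names(pcb$grads)) grads[[nm]] <- tree_add(grads[[nm]],
                                                         pcb$grads[[nm]])
    dpooled <- pcb$dpooled
  }
  if ("invitro" %in% cfg$heads) {
    df <- weighted_focal_grad(
      targets$invitro, outs$invitro,
      loss_config(alpha = 1, gamma = 2, weights = invitro_weights)
    ) / nh
    ivb <- .invitro_bwd(df, params, outs$.iv$cache)
    for (nm in names(ivb$grads)) grads[[nm]] <- tree_add(grads[[nm]],
                                                         ivb$grads[[nm]])
    dpooled <- if (is.null(dpooled)) ivb$dpooled else dpooled + ivb$dpooled
  }
  if (!is.null(dpooled)) {
    encg <- .encoder_bwd(NULL, dpooled, params, cfg, outs$.enc_clean$cache)
    for (nm in names(encg)) grads[[nm]] <- tree_add(grads[[nm]], encg[[nm]])
  }
  list(grads = grads, loss = loss)
}

# ---- pretraining loop ---------------------------------------------------

#' Pretrain the encoder on masking + physchem + in vitro objectives
#'
#' Gradient training with Adam and linear learning-rate warmup. A
#' scaffold-disjoint validation subset must be supplied via `val_idx`; the
#' per-epoch history tracks validation physchem loss, masked-token
#' accuracy, and in vitro macro-AUPR.
#'
#' @param token_list list of integer token vectors (all molecules).
#' @param physchem numeric matrix of normalized descriptor targets
#'   (N x D), or `NULL` if the physchem head is disabled.
#' @param invitro label matrix (N x P, `NA` = unobserved) or `NULL`.
#' @param cfg an [encoder_config()].
#' @param val_idx integer indices of the validation molecules.
#' @param epochs training epochs (default 10).
#' @param batch_size default 32.
#' @param lr Adam learning rate (default 3e-5).
#' @param warmup_frac fraction of total steps with linear warmup
#'   (default 0.01).
#' @param schedule learning-rate schedule after warmup: `"linear_decay"`
#'   (default, linear to zero at the final step, the convention for
#'   BERT-style pretraining) or `"constant"`.
#' @param mask_rate masking probability (default 0.15).
#' @param seed integer seed controlling batch order and mask draws.
#' @param params optional initial parameters (e.g. from a checkpoint);
#'   default fresh initialization from `cfg$seed`.
#' @param verbose print per-epoch progress.
#' @return object of class `vitro_encoder`: list with `params`, `config`,
#'   `history` (one row per epoch) and `invitro_weights`.
#' @export
fit_pretrain <- function(token_list, physchem = NULL, invitro = NULL,
                         cfg, val_idx, epochs = 10L, batch_size = 32L,
                         lr = 3e-5, warmup_frac = 0.01,
                         schedule = c("linear_decay", "constant"),
                         mask_rate = 0.15, seed = 1L, params = NULL,
                         verbose = FALSE) {
  schedule <- match.arg(schedule)
  N <- length(token_list)
  stopifnot(length(val_idx) >= 1L, all(val_idx %in% seq_len(N)))
  train_idx <- setdiff(seq_len(N), val_idx)
  if (is.null(params)) params <- init_params(cfg)

  iv_w <- NULL
  if ("invitro" %in% cfg$heads) {
    stopifnot(!is.null(invitro), ncol(invitro) == cfg$n_invitro)
    cnt <- label_counts(invitro[train_idx, , drop = FALSE])
    iv_w <- suppressWarnings(positive_weights(cnt[, 1], cnt[, 2], alpha = 1))
    iv_w[is.na(iv_w)] <- 1
  }
  if ("physchem" %in% cfg$heads) {
    stopifnot(!is.null(physchem), ncol(physchem) == cfg$n_physchem)
  }

  state <- adam_init(params)
  steps_per_epoch <- ceiling(length(train_idx) / batch_size)
  total_steps <- steps_per_epoch * epochs
  warmup_steps <- max(1, round(warmup_frac * total_steps))
  history <- NULL

  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)

  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    # length bucketing: sort within blocks of 8 batches so padded batch
    # width tracks the longest member, then shuffle batch order
    block <- batch_size * 8L
    for (st in seq(1, length(ord), by = block)) {
      en <- min(st + block - 1L, length(ord))
      seg <- ord[st:en]
      ord[st:en] <- seg[order(lengths(token_list[seg]))]
    }
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    batches <- batches[sample(length(batches))]
    for (s in seq_len(steps_per_epoch)) {
      bidx <- batches[[s]]
      targets <- list(
        physchem = if ("physchem" %in% cfg$heads)
          physchem[bidx, , drop = FALSE] else NULL,
        invitro = if ("invitro" %in% cfg$heads)
          unclass(as.matrix(invitro))[bidx, , drop = FALSE] else NULL
      )
      r <- .pretrain_step(params, cfg, token_list[bidx], targets,
                          iv_w, mask_rate)
      comps <- r$loss$components
      if (all(is.na(comps) & !is.nan(comps))) next  # no masked positions
      if (!is.finite(r$loss$total)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d step %d",
                     ep, s))
      }
      step <- step + 1L
      lr_t <- if (step <= warmup_steps) {
        lr * step / warmup_steps
      } else if (schedule == "linear_decay") {
        lr * (total_steps - step + 1) / (total_steps - warmup_steps)
      } else {
        lr
      }
      upd <- adam_step(params, r$grads, state, lr_t)
      params <- upd$params
      state <- upd$state
    }
    ev <- .pretrain_eval(params, cfg, token_list[val_idx],
                         if (!is.null(physchem))
                           physchem[val_idx, , drop = FALSE] else NULL,
                         if (!is.null(invitro))
                           unclass(as.matrix(invitro))[val_idx, , drop = FALSE]
                         else NULL,
                         iv_w, mask_rate, batch_size)
    history <- rbind(history, data.frame(epoch = ep, t(ev)))
    if (verbose) {
      message(sprintf(
        "epoch %d: train_loss=%.4f val_physchem=%.4f val_mask_acc=%.3f val_invitro_aupr=%.3f",
        ep, r$loss$total, ev["physchem_loss"], ev["mask_accuracy"],
        ev["invitro_aupr"]))
    }
  }
  structure(list(params = params, config = cfg, history = history,
                 invitro_weights = iv_w),
            class = "vitro_encoder")
}

# validation metrics: physchem loss, masked-token accuracy, invitro AUPR
.pretrain_eval <- function(params, cfg, token_list, physchem, invitro,
                           iv_w, mask_rate, batch_size) {
  N <- length(token_list)
  pc_loss <- NA_real_
  acc_num <- 0; acc_den <- 0
  pc_sum <- 0
  iv_logits <- NULL
  nb <- ceiling(N / batch_size)
  for (s in seq_len(nb)) {
    bidx <- ((s - 1L) * batch_size + 1L):min(s * batch_size, N)
    outs <- dual_pass(params, cfg, token_list[bidx], mask_rate)
    if ("mask" %in% cfg$heads && outs$corruption$n_masked > 0) {
      mvec <- as.vector(t(outs$corruption$mask))
      truth <- as.vector(t(outs$corruption$orig))
      pred <- max.col(outs$mask_logits[mvec, , drop = FALSE])
      acc_num <- acc_num + sum(pred == truth[mvec])
      acc_den <- acc_den + sum(mvec)
    }
    if ("physchem" %in% cfg$heads) {
      pc_sum <- pc_sum + physchem_loss(outs$physchem,
                                       physchem[bidx, , drop = FALSE]) *
        length(bidx)
    }
    if ("invitro" %in% cfg$heads) {
      iv_logits <- rbind(iv_logits, outs$invitro)
    }
  }
  iv_aupr <- NA_real_
  if (!is.null(iv_logits) && !is.null(invitro)) {
    auprs <- vapply(seq_len(ncol(invitro)), function(p) {
      y <- invitro[, p]
      obs <- !is.na(y)
      if (sum(y[obs] == 1) >= 1 && sum(y[obs] == 0) >= 1) {
        aupr(y[obs], stats::plogis(iv_logits[obs, p]))
      } else NA_real_
    }, numeric(1))
    iv_aupr <- mean(auprs, na.rm = TRUE)
  }
  c(physchem_loss = if ("physchem" %in% cfg$heads) pc_sum / N else NA_real_,
    mask_accuracy = if (acc_den > 0) acc_num / acc_den else NA_real_,
    invitro_aupr = iv_aupr)
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints are self-describing: the config, vocabulary and any
#' normalization statistics travel with the weights.
#'
#' @param model a `vitro_encoder`.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vitro_encoder"))
  saveRDS(model, path)
}

#' @rdname save_checkpoint
#' @return a `vitro_encoder`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vitro_encoder"))
  model
}
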