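# tiny shared pretraining setup reused across blocks
.enc_setup <- function(n = 60L, n_invitro = 4L, seed = 1L) {
  corpus <- small_corpus(120L)
  idx <- seq_len(n)
  smiles <- corpus$molecules$smiles[idx]
  vocab <- build_vocab(smiles)
  physchem <- normalize_descriptors(
    corpus$descriptors[idx, , drop = FALSE])$values
  list(
    corpus = corpus,
    vocab = vocab,
    toks = encode_smiles(smiles, vocab),
    physchem = physchem,
    invitro = unclass(as.matrix(corpus$invitro))[idx, seq_len(n_invitro),
                                                 drop = FALSE],
    cfg = encoder_config(layers = 1L, n_heads = 2L, hidden = 16L,
                         ffn_mult = 2L, vocab_size = length(vocab),
                         n_physchem = ncol(physchem),
                         n_invitro = n_invitro, head_hidden = 16L,
                         pooling = "mean", seed = seed)
  )
}

test_that("corruption masks at the configured rate and spares specials", {
  s <- .enc_setup()
  ids <- collate_batch(s$toks)
  set.seed(1)
  total <- 0; masked <- 0
  for (i in 1:40) {
    cr <- corrupt_tokens(ids, mask_rate = 0.15)
    specials <- ids %in% c(1L, 2L, 3L)
    expect_true(all(!cr$mask[specials]))
    expect_true(all(cr$ids[cr$mask] == 4L))
    expect_equal(cr$ids[!cr$mask], ids[!cr$mask])
    total <- total + sum(!specials)
    masked <- masked + cr$n_masked
  }
  expect_lt(abs(masked / total - 0.15), 0.01)
  # identical seed, identical mask pattern
  set.seed(9); a <- corrupt_tokens(ids, 0.15)
  set.seed(9); b <- corrupt_tokens(ids, 0.15)
  expect_identical(a$mask, b$mask)
  # a batch of only special tokens is returned unmasked with |m| = 0
  all_special <- matrix(c(2L, 3L, 1L, 1L), 1, 4)
  cr0 <- corrupt_tokens(all_special, 0.15)
  expect_equal(cr0$n_masked, 0L)
  expect_identical(cr0$ids, all_special)
})

test_that("dual pass produces the contracted head shapes", {
  s <- .enc_setup(n = 8L)
  params <- init_params(s$cfg)
  set.seed(2)
  outs <- dual_pass(params, s$cfg, s$toks[1:8], mask_rate = 0.15)
  B <- 8L; T <- max(lengths(s$toks[1:8]))
  expect_equal(dim(outs$mask_logits), c(B * T, length(s$vocab)))
  expect_equal(dim(outs$physchem), c(B, s$cfg$n_physchem))
  expect_equal(dim(outs$invitro), c(B, s$cfg$n_invitro))
  expect_equal(dim(outs$pooled), c(B, s$cfg$hidden))
  # over-long batch is rejected at collation
  expect_error(collate_batch(list(rep(2L, 200)), max_length = 128L),
               "max_length")
})

test_that("clean-pass embeddings do not depend on the mask draw", {
  s <- .enc_setup(n = 8L)
  params <- init_params(s$cfg)
  set.seed(3)
  o1 <- dual_pass(params, s$cfg, s$toks[1:8], mask_rate = 0.4)
  o2 <- dual_pass(params, s$cfg, s$toks[1:8], mask_rate = 0.4)
  expect_false(identical(o1$corruption$mask, o2$corruption$mask))
  expect_identical(o1$pooled, o2$pooled)
  expect_identical(o1$physchem, o2$physchem)
})

test_that("combined loss is the arithmetic mean of enabled heads", {
  # synthetic head outputs with known component losses
  s <- .enc_setup(n = 4L)
  params <- init_params(s$cfg)
  set.seed(4)
  outs <- dual_pass(params, s$cfg, s$toks[1:4], mask_rate = 0.3)
  targets <- list(physchem = s$physchem[1:4, , drop = FALSE],
                  invitro = s$invitro[1:4, , drop = FALSE])
  cl <- combined_loss(outs, targets, s$cfg, invitro_weights = rep(2, 4))
  expect_equal(cl$total, mean(cl$components), tolerance = 1e-12)
  expect_named(cl$components, c("mask", "physchem", "invitro"))
  # the in vitro component is the weighted focal loss at alpha=1, gamma=2
  expect_equal(unname(cl$components["invitro"]),
               weighted_focal_loss(targets$invitro, outs$invitro,
                                   loss_config(1, 2, weights = rep(2, 4))),
               tolerance = 1e-12)
})

test_that("analytic gradients of the full model match finite differences", {
  cfg <- encoder_config(layers = 1L, n_heads = 2L, hidden = 8L,
                        ffn_mult = 2L, max_length = 10L, vocab_size = 12L,
                        n_physchem = 3L, n_invitro = 2L, head_hidden = 8L,
                        seed = 7L)
  params <- init_params(cfg)
  toks <- list(c(2L, 6L, 7L, 8L, 3L), c(2L, 9L, 10L, 6L, 7L, 11L, 3L))
  set.seed(8)
  targets <- list(physchem = matrix(rnorm(6), 2, 3),
                  invitro = matrix(c(1, 0, NA, 1), 2, 2))
  loss_at <- function(p) {
    set.seed(99)
    combined_loss(dual_pass(p, cfg, toks, 0.3), targets, cfg,
                  rep(1.5, 2))$total
  }
  set.seed(99)
  r <- vitroembed:::.pretrain_step(params, cfg, toks, targets,
                                   rep(1.5, 2), 0.3)
  eps <- 1e-5
  leaves <- list(
    list(\(p) p$tok_emb, \(p, v) {p$tok_emb[] <- v; p}, \(g) g$tok_emb),
    list(\(p) p$layers[[1]]$Wq, \(p, v) {p$layers[[1]]$Wq[] <- v; p},
         \(g) g$layers[[1]]$Wq),
    list(\(p) p$layers[[1]]$W1, \(p, v) {p$layers[[1]]$W1[] <- v; p},
         \(g) g$layers[[1]]$W1),
    list(\(p) p$pool_W, \(p, v) {p$pool_W[] <- v; p}, \(g) g$pool_W),
    list(\(p) p$iv_W1, \(p, v) {p$iv_W1[] <- v; p}, \(g) g$iv_W1),
    list(\(p) p$mh_layer$Wv, \(p, v) {p$mh_layer$Wv[] <- v; p},
         \(g) g$mh_layer$Wv)
  )
  set.seed(10)
  for (lf in leaves) {
    v <- lf[[1]](params)
    i <- sample(length(v), 1)
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    fd <- (loss_at(lf[[2]](params, vp)) - loss_at(lf[[2]](params, vm))) /
      (2 * eps)
    an <- lf[[3]](r$grads)[i]
    expect_equal(an, fd, tolerance = 1e-3)
  }
})

test_that("pretraining is seeded, logged per epoch, and detects divergence", {
  s <- .enc_setup(n = 40L)
  val_idx <- 33:40
  fit1 <- fit_pretrain(s$toks[1:40], s$physchem[1:40, ], s$invitro[1:40, ],
                       s$cfg, val_idx, epochs = 2L, batch_size = 16L,
                       lr = 1e-3, seed = 77L)
  fit2 <- fit_pretrain(s$toks[1:40], s$physchem[1:40, ], s$invitro[1:40, ],
                       s$cfg, val_idx, epochs = 2L, batch_size = 16L,
                       lr = 1e-3, seed = 77L)
  expect_equal(nrow(fit1$history), 2L)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  # numerical blow-up aborts with a diagnostic instead of training on NaN
  expect_error(
    fit_pretrain(s$toks[1:40], s$physchem[1:40, ], s$invitro[1:40, ],
                 s$cfg, val_idx, epochs = 2L, batch_size = 16L,
                 lr = 1e160, seed = 77L),
    "diverged|non-finite")
})

test_that("disabling the in vitro head leaves the encoder unchanged", {
  s <- .enc_setup()
  cfg_mp <- encoder_config(layers = 1L, n_heads = 2L, hidden = 16L,
                           ffn_mult = 2L, vocab_size = length(s$vocab),
                           n_physchem = ncol(s$physchem),
                           heads = c("mask", "physchem"),
                           head_hidden = 16L, pooling = "mean", seed = 1L)
  p_full <- init_params(s$cfg)
  p_mp <- init_params(cfg_mp)
  # identical encoder weights from the same init seed; only head params
  # differ (loss composition changes, not the encoder)
  expect_identical(p_full$layers, p_mp$layers)
  expect_identical(p_full$tok_emb, p_mp$tok_emb)
  expect_false("iv_W1" %in% names(p_mp))
  expect_error(encoder_config(vocab_size = 10, heads = character(0)),
               "at least one head")
})

test_that("a tiny model memorizes masked tokens on a small corpus", {
  corpus <- small_corpus(120L)
  smiles <- corpus$molecules$smiles[1:30]
  vocab <- build_vocab(smiles)
  toks <- encode_smiles(smiles, vocab)
  # validation sequences duplicate training molecules: the check is
  # memorization, not generalization
  toks_all <- c(toks, toks[1:20])
  cfg <- encoder_config_tiny(vocab_size = length(vocab), n_physchem = 0L,
                             heads = "mask", pooling = "mean", seed = 3L)
  fit <- fit_pretrain(toks_all, NULL, NULL, cfg, val_idx = 31:50,
                      epochs = 300L, batch_size = 8L, lr = 3e-3,
                      seed = 13L)
  expect_gte(max(fit$history$mask_accuracy), 0.95)
})

test_that("pretraining recovers planted in vitro signal above prevalence", {
  corpus <- small_corpus(300L, seed = 5L, n_invitro = 4L)
  vocab <- build_vocab(corpus$molecules$smiles)
  toks <- encode_smiles(corpus$molecules$smiles, vocab)
  nd <- normalize_descriptors(corpus$descriptors)
  cfg <- encoder_config_tiny(vocab_size = length(vocab),
                             n_physchem = ncol(nd$values), n_invitro = 4L,
                             pooling = "mean", seed = 2L)
  sp <- scaffold_split(corpus$molecules$scaffold_key, K = 5, seed = 2)
  val_idx <- which(sp$fold_id == sp$test_fold)
  fit <- fit_pretrain(toks, nd$values, corpus$invitro, cfg, val_idx,
                      epochs = 10L, batch_size = 32L, lr = 2e-3,
                      seed = 19L)
  prev <- mean(unclass(corpus$invitro)[val_idx, ] == 1, na.rm = TRUE)
  expect_gt(max(fit$history$invitro_aupr), prev)
})

test_that("checkpoints round-trip with their configuration", {
  s <- .enc_setup(n = 20L)
  fit <- fit_pretrain(s$toks[1:20], s$physchem[1:20, ], s$invitro[1:20, ],
                      s$cfg, val_idx = 17:20, epochs = 1L,
                      batch_size = 8L, lr = 1e-3, seed = 5L)
  fit$vocab <- s$vocab
  tmp <- withr::local_tempdir()
  save_checkpoint(fit, file.path(tmp, "m.rds"))
  back <- load_checkpoint(file.path(tmp, "m.rds"))
  expect_identical(back$params, fit$params)
  expect_identical(back$config, fit$config)
})
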