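# small deterministic feature/label setup for head tests
.ds_setup <- function(n = 80L, f = 10L, p = 3L, seed = 31L) {
  set.seed(seed)
  x <- matrix(rnorm(n * f), n, f)
  w <- matrix(rnorm(f * p), f, p)
  logits <- x %*% w
  y <- matrix(as.numeric(logits + rnorm(n * p) > 0.8), n, p)
  y[sample(n * p, n * p * 0.1)] <- NA
  for (j in seq_len(p)) y[1:2, j] <- c(0, 1)
  list(x = x, y = y)
}

test_that("MLP head forward obeys the shape and sigma(0) = 0.5 contracts", {
  d <- .ds_setup()
  head <- fit_mlp(d$x, d$y, epochs = 2L, hidden = 8L, seed = 1L)
  pr <- predict_mlp(head, d$x)
  expect_equal(dim(pr), dim(d$y))
  expect_true(all(pr > 0 & pr < 1))
  # zeroed output layer puts every probability at exactly 0.5
  head0 <- head
  head0$params$W2[] <- 0
  head0$params$b2[] <- 0
  expect_true(all(predict_mlp(head0, d$x) == 0.5))
  # evaluation mode is deterministic (no dropout, running stats)
  expect_identical(predict_mlp(head, d$x), predict_mlp(head, d$x))
  expect_error(predict_mlp(head, d$x[, 1:3]), "width")
})

test_that("the head learns a noiseless separable multitask problem", {
  set.seed(33)
  x <- matrix(rnorm(150 * 10), 150, 10)
  w <- matrix(rnorm(10 * 3), 10, 3)
  y <- matrix(as.numeric(x %*% w > 0.8), 150, 3)   # deterministic labels
  head <- fit_mlp(x, y, loss_config(1, 2), epochs = 80L, hidden = 16L,
                  seed = 2L)
  rep <- compute_metrics(y, predict_mlp(head, x))
  expect_true(all(rep$aupr > 0.95))
})

test_that("early stopping monitors validation AUPR with patience", {
  d <- .ds_setup(n = 120L)
  tr <- 1:90; va <- 91:120
  head <- fit_mlp(d$x[tr, ], d$y[tr, ], epochs = 100L, hidden = 8L,
                  val = list(x = d$x[va, ], y = d$y[va, ]),
                  patience = 5L, seed = 3L)
  expect_true(length(head$val_history) < 100L)
  expect_gte(head$best_epoch, 1L)
})

test_that("downstream protocol holds out the test fold and reports per task", {
  d <- .ds_setup(n = 100L)
  split <- list(fold_id = rep(1:5, each = 20), test_fold = 5L)
  r <- fit_downstream(d$x, d$y, split, grid = data.frame(alpha = 1,
                                                         gamma = 2),
                      hidden = 8L, epochs = 10L, seed = 4L)
  expect_equal(r$test_idx, 81:100)
  expect_equal(nrow(r$report), ncol(d$y))
  expect_equal(r$best$alpha, 1)
  # degenerate one-point grid returns that point without inner CV
  expect_true(all(is.na(r$cv$mean_val_aupr)))
})

test_that("hyperparameter selection never touches the test fold", {
  d <- .ds_setup(n = 100L, seed = 32L)
  split <- list(fold_id = rep(1:5, each = 20), test_fold = 5L)
  grid <- data.frame(alpha = c(0, 1), gamma = c(0, 2))
  r1 <- fit_downstream(d$x, d$y, split, grid = grid, hidden = 8L,
                       epochs = 5L, seed = 5L)
  # scrambling the held-out fold's labels must not change selection
  y2 <- d$y
  y2[81:100, ] <- y2[sample(81:100), ]
  r2 <- fit_downstream(d$x, y2, split, grid = grid, hidden = 8L,
                       epochs = 5L, seed = 5L)
  expect_identical(r1$cv$mean_val_aupr, r2$cv$mean_val_aupr)
  expect_identical(r1$best, r2$best)
})

test_that("downstream refuses splits with no positives outside test", {
  d <- .ds_setup(n = 40L)
  y <- d$y
  y[1:30, ][y[1:30, ] == 1] <- 0   # dev folds all negative
  split <- list(fold_id = rep(1:4, each = 10), test_fold = 4L)
  expect_error(fit_downstream(d$x, y, split), "stratification")
})

test_that("frozen encoder: extraction leaves checkpoint weights untouched", {
  corpus <- small_corpus(120L)
  smiles <- corpus$molecules$smiles[1:30]
  vocab <- build_vocab(smiles)
  toks <- encode_smiles(smiles, vocab)
  cfg <- encoder_config(layers = 1L, n_heads = 2L, hidden = 16L,
                        ffn_mult = 2L, vocab_size = length(vocab),
                        n_physchem = 0L, heads = "mask",
                        head_hidden = 16L, pooling = "mean", seed = 6L)
  model <- fit_pretrain(toks, NULL, NULL, cfg, val_idx = 28:30,
                        epochs = 1L, batch_size = 16L, lr = 1e-3,
                        seed = 7L)
  before <- serialize(model$params, NULL)
  e1 <- extract_embeddings(model, toks)
  e2 <- extract_embeddings(model, toks)
  expect_identical(serialize(model$params, NULL), before)
  expect_identical(e1, e2)                      # deterministic
  expect_equal(ncol(e1), cfg$hidden)            # width = checkpoint hidden
  expect_equal(e1[1, ], e1[1, ])
  # same molecule twice yields identical rows
  e3 <- extract_embeddings(model, toks[c(1, 1)])
  expect_equal(e3[1, ], e3[2, ])
  # molecules beyond max_length are refused by name
  long <- list(rep(6L, cfg$max_length + 1L))
  expect_error(extract_embeddings(model, long), "max_length")
})

test_that("fingerprint baselines share the split protocol and schema", {
  set.seed(41)
  n <- 120L
  fp <- matrix(rbinom(n * 30, 1, 0.3), n, 30)
  # separable task: the label is one observed bit
  y <- cbind(sep = fp[, 7])
  split <- list(fold_id = rep(1:4, each = 30), test_fold = 4L)
  r <- fit_baselines(fp, y, split, mtry_grid = 8L, ntree = 100L,
                     mlp_grid = data.frame(alpha = 0, gamma = 0),
                     epochs = 10L, hidden = 8L, seed = 8L)
  expect_gte(r$rf_report$aupr[1], 0.99)
  expect_identical(names(r$rf_report), names(r$mlp_report))
})
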