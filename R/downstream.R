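# Frozen-encoder embedding extraction, the skip-connected multitask MLP
# head trained with the weighted focal loss family, fingerprint baselines,
# and the cross-validated hyperparameter search.

#' Extract frozen-encoder embeddings
#'
#' Runs the clean (uncorrupted) pass of a pretrained encoder and returns
#' the pooled molecule representations. The encoder weights are never
#' modified (frozen contract) and the result is deterministic given the
#' checkpoint and the canonical SMILES.
#'
#' @param model a `vitro_encoder` (from [fit_pretrain()] or
#'   [load_checkpoint()]).
#' @param token_list list of integer token vectors; or a character vector
#'   of SMILES if the model carries a `vocab`.
#' @param batch_size default 64.
#' @return numeric matrix, molecules x hidden, with attributes `pooling`.
#' @export
extract_embeddings <- function(model, token_list, batch_size = 64L) {
  stopifnot(inherits(model, "vitro_encoder"))
  cfg <- model$config
  if (is.character(token_list)) {
    if (is.null(model$vocab)) stop("model has no vocabulary; pass token ids")
    token_list <- encode_smiles(token_list, model$vocab, cfg$max_length)
  }
  too_long <- which(lengths(token_list) > cfg$max_length)
  if (length(too_long)) {
    stop("molecule(s) exceed max_length: ",
         paste(too_long, collapse = ", "))
  }
  N <- length(token_list)
  out <- matrix(0, N, cfg$hidden)
  nb <- ceiling(N / batch_size)
  for (s in seq_len(nb)) {
    bidx <- ((s - 1L) * batch_size + 1L):min(s * batch_size, N)
    ids <- collate_batch(token_list[bidx], cfg$max_length)
    out[bidx, ] <- .encoder_fwd(model$params, cfg, ids)$pooled
  }
  attr(out, "pooling") <- cfg$pooling
  out
}

# ---- multitask MLP head -------------------------------------------------
# architecture: input -> dense(hidden) -> batchnorm -> ReLU -> dropout ->
# concat skip with input -> dense(P) -> logits

.mlp_init <- function(n_in, hidden, n_tasks, seed) {
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)
  list(
    W1 = .init_mat(n_in, hidden, sd = sqrt(2 / n_in)),
    b1 = rep(0, hidden),
    bn_g = rep(1, hidden), bn_b = rep(0, hidden),
    W2 = .init_mat(n_in + hidden, n_tasks, sd = sqrt(1 / (n_in + hidden))),
    b2 = rep(0, n_tasks)
  )
}

.BN_EPS <- 1e-5

# training forward; returns logits + cache, updates running stats
.mlp_fwd_train <- function(p, x, dropout, run_stats, momentum = 0.1) {
  h <- dense_fwd(x, p$W1, p$b1)
  mu <- colMeans(h)
  v <- colMeans(sweep(h, 2, mu)^2)
  inv <- 1 / sqrt(v + .BN_EPS)
  hhat <- sweep(sweep(h, 2, mu), 2, inv, `*`)
  a <- relu(sweep(sweep(hhat, 2, p$bn_g, `*`), 2, p$bn_b, `+`))
  keep <- if (dropout > 0) {
    matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
  } else 1
  ad <- a * keep
  z <- dense_fwd(cbind(x, ad), p$W2, p$b2)
  run_stats$mean <- (1 - momentum) * run_stats$mean + momentum * mu
  run_stats$var <- (1 - momentum) * run_stats$var + momentum * v
  list(logits = z, run_stats = run_stats,
       cache = list(x = x, h = h, mu = mu, inv = inv, hhat = hhat,
                    a = a, keep = keep, ad = ad))
}

.mlp_bwd <- function(dz, p, cache) {
  n_in <- ncol(cache$x)
  d2 <- dense_bwd(dz, cbind(cache$x, cache$ad), p$W2)
  dx_skip <- d2$dx[, seq_len(n_in), drop = FALSE]
  dad <- d2$dx[, -seq_len(n_in), drop = FALSE]
  da <- dad * cache$keep
  dpre <- da * (cache$a > 0)
  dg <- colSums(dpre * cache$hhat)
  db <- colSums(dpre)
  dhhat <- sweep(dpre, 2, p$bn_g, `*`)
  nb <- nrow(dhhat)
  m1 <- colMeans(dhhat)
  m2 <- colMeans(dhhat * cache$hhat)
  dh <- sweep(dhhat, 2, m1) - sweep(cache$hhat, 2, m2, `*`)
  dh <- sweep(dh, 2, cache$inv, `*`)
  d1 <- dense_bwd(dh, cache$x, p$W1)
  list(grads = list(W1 = d1$dW, b1 = d1$db, bn_g = dg, bn_b = db,
                    W2 = d2$dW, b2 = d2$db))
}

# evaluation forward: running batch-norm stats, no dropout; deterministic
.mlp_fwd_eval <- function(p, x, run_stats) {
  h <- dense_fwd(x, p$W1, p$b1)
  inv <- 1 / sqrt(run_stats$var + .BN_EPS)
  hhat <- sweep(sweep(h, 2, run_stats$mean), 2, inv, `*`)
  a <- relu(sweep(sweep(hhat, 2, p$bn_g, `*`), 2, p$bn_b, `+`))
  dense_fwd(cbind(x, a), p$W2, p$b2)
}

#' Multitask MLP head forward pass (evaluation mode)
#'
#' @param head a fitted `mlp_head`.
#' @param x input matrix (embeddings or fingerprints).
#' @return matrix of per-task probabilities in (0, 1).
#' @export
predict_mlp <- function(head, x) {
  stopifnot(inherits(head, "mlp_head"))
  x <- as.matrix(x)
  if (ncol(x) != head$n_in) {
    stop(sprintf("input width %d does not match head width %d",
                 ncol(x), head$n_in))
  }
  stats::plogis(.mlp_fwd_eval(head$params, x, head$run_stats))
}

#' Train the multitask MLP head
#'
#' Minimizes the weighted focal loss over observed labels with Adam.
#' Optional early stopping monitors macro-AUPR on a validation set.
#'
#' @param x input matrix (N x F): frozen-encoder embeddings or binary
#'   fingerprints.
#' @param y label matrix (N x P, `NA` = unobserved).
#' @param loss_cfg a [loss_config()]; per-task weights default to the
#'   training-set counts of `y`.
#' @param hidden hidden width (default 128).
#' @param dropout dropout rate (default 0.2).
#' @param epochs maximum epochs (default 100).
#' @param batch_size default 32.
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 coefficient applied through the optimizer
#'   (default 0).
#' @param val optional list(x, y) for early stopping.
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed integer seed.
#' @return object of class `mlp_head`.
#' @export
fit_mlp <- function(x, y, loss_cfg = loss_config(), hidden = 128L,
                    dropout = 0.2, epochs = 100L, batch_size = 32L,
                    lr = 1e-3, weight_decay = 0, val = NULL,
                    patience = 10L, seed = 1L) {
  x <- as.matrix(x)
  ym <- unclass(as.matrix(y))
  stopifnot(nrow(x) == nrow(ym))
  if (is.null(loss_cfg$weights)) {
    cnt <- label_counts(ym)
    w <- suppressWarnings(positive_weights(cnt[, 1], cnt[, 2],
                                           loss_cfg$alpha))
    w[is.na(w)] <- 1
    loss_cfg$weights <- w
  }
  p <- .mlp_init(ncol(x), hidden, ncol(ym), seed)
  run_stats <- list(mean = rep(0, hidden), var = rep(1, hidden))
  state <- adam_init(p)
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)
  N <- nrow(x)
  best <- list(score = -Inf, params = p, run_stats = run_stats, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    for (s in seq_len(ceiling(N / batch_size))) {
      bidx <- ord[((s - 1L) * batch_size + 1L):min(s * batch_size, N)]
      yb <- ym[bidx, , drop = FALSE]
      if (all(is.na(yb))) next
      fw <- .mlp_fwd_train(p, x[bidx, , drop = FALSE], dropout, run_stats)
      run_stats <- fw$run_stats
      dz <- weighted_focal_grad(yb, fw$logits, loss_cfg)
      if (any(!is.finite(dz))) stop("training diverged (non-finite gradient)")
      g <- .mlp_bwd(dz, p, fw$cache)$grads
      upd <- adam_step(p, g, state, lr, weight_decay = weight_decay)
      p <- upd$params
      state <- upd$state
    }
    if (!is.null(val)) {
      head_now <- structure(list(params = p, run_stats = run_stats,
                                 n_in = ncol(x)), class = "mlp_head")
      pr <- predict_mlp(head_now, val$x)
      sc <- .macro_aupr(val$y, pr)
      history <- c(history, sc)
      if (sc > best$score + 1e-6) {
        best <- list(score = sc, params = p, run_stats = run_stats,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(val) && is.finite(best$score)) {
    p <- best$params
    run_stats <- best$run_stats
  }
  structure(list(params = p, run_stats = run_stats, n_in = ncol(x),
                 loss_cfg = loss_cfg, hidden = hidden,
                 val_history = history, best_epoch = best$epoch),
            class = "mlp_head")
}

# macro-average AUPR over tasks with both classes observed
.macro_aupr <- function(y, probs) {
  y <- unclass(as.matrix(y))
  vals <- vapply(seq_len(ncol(y)), function(pi) {
    obs <- !is.na(y[, pi])
    if (sum(y[obs, pi] == 1) >= 1 && sum(y[obs, pi] == 0) >= 1) {
      aupr(y[obs, pi], probs[obs, pi])
    } else NA_real_
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Fit the downstream head with cross-validated hyperparameter search
#'
#' Protocol: the designated test fold is held out before any tuning.
#' Candidate settings (the loss parameters alpha/gamma plus regularizers)
#' are scored by K-fold cross-validation on the non-test molecules using
#' macro validation AUPR; the winning setting is retrained on all
#' non-test data and evaluated once on the test fold.
#'
#' @param x input matrix (embeddings or fingerprints).
#' @param y label matrix.
#' @param split a [scaffold_split()] result (or any list with `fold_id`,
#'   `test_fold`).
#' @param grid data.frame of candidate settings with columns among
#'   `alpha`, `gamma`, `dropout`, `weight_decay` (missing columns use the
#'   defaults).
#' @param inner_k inner CV folds (default 5; capped at the number of
#'   non-test folds when using outer folds as inner folds is impossible).
#' @param hidden,epochs,batch_size,lr,patience passed to [fit_mlp()].
#' @param seed integer seed.
#' @return list with `head` (final fitted `mlp_head`), `best` (chosen
#'   row of the grid), `cv` (per-setting mean validation AUPR), and
#'   `report` (per-task test metrics from [compute_metrics()]).
#' @export
fit_downstream <- function(x, y, split, grid = data.frame(alpha = 1,
                                                          gamma = 2),
                           inner_k = 5L, hidden = 128L, epochs = 100L,
                           batch_size = 32L, lr = 1e-3, patience = 10L,
                           seed = 1L) {
  x <- as.matrix(x)
  ym <- unclass(as.matrix(y))
  stopifnot(nrow(x) == nrow(ym), nrow(x) == length(split$fold_id),
            nrow(grid) >= 1)
  test_idx <- which(split$fold_id == split$test_fold)
  dev_idx <- which(split$fold_id != split$test_fold)
  ydev <- ym[dev_idx, , drop = FALSE]
  cnt <- label_counts(ydev)
  if (all(cnt[, "n_pos"] == 0)) {
    stop("no positive labels outside the test fold; review stratification")
  }

  g <- grid
  if (is.null(g$alpha)) g$alpha <- 1
  if (is.null(g$gamma)) g$gamma <- 2
  if (is.null(g$dropout)) g$dropout <- 0.2
  if (is.null(g$weight_decay)) g$weight_decay <- 0

  cv_scores <- rep(NA_real_, nrow(g))
  if (nrow(g) > 1L) {
    old <- .rng_snapshot()
    on.exit(.rng_restore(old), add = TRUE)
    set.seed(seed)
    k <- min(inner_k, length(dev_idx))
    inner_fold <- sample(rep_len(seq_len(k), length(dev_idx)))
    for (gi in seq_len(nrow(g))) {
      scores <- numeric(0)
      for (fi in seq_len(k)) {
        tr <- dev_idx[inner_fold != fi]
        va <- dev_idx[inner_fold == fi]
        vcnt <- label_counts(ym[va, , drop = FALSE])
        if (all(vcnt[, "n_pos"] == 0 | vcnt[, "n_neg"] == 0)) next
        head <- fit_mlp(x[tr, , drop = FALSE], ym[tr, , drop = FALSE],
                        loss_config(g$alpha[gi], g$gamma[gi]),
                        hidden = hidden, dropout = g$dropout[gi],
                        epochs = epochs, batch_size = batch_size, lr = lr,
                        weight_decay = g$weight_decay[gi],
                        val = list(x = x[va, , drop = FALSE],
                                   y = ym[va, , drop = FALSE]),
                        patience = patience, seed = seed + fi)
        scores <- c(scores,
                    .macro_aupr(ym[va, , drop = FALSE],
                                predict_mlp(head, x[va, , drop = FALSE])))
      }
      if (!length(scores)) {
        stop("every inner fold lacked positives for every task; ",
             "review stratification")
      }
      cv_scores[gi] <- mean(scores)
    }
    best_i <- which.max(cv_scores)
  } else {
    best_i <- 1L
  }

  head <- fit_mlp(x[dev_idx, , drop = FALSE], ydev,
                  loss_config(g$alpha[best_i], g$gamma[best_i]),
                  hidden = hidden, dropout = g$dropout[best_i],
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  weight_decay = g$weight_decay[best_i],
                  seed = seed)
  probs <- predict_mlp(head, x[test_idx, , drop = FALSE])
  report <- compute_metrics(ym[test_idx, , drop = FALSE], probs)
  list(head = head, best = g[best_i, , drop = FALSE],
       cv = data.frame(g, mean_val_aupr = cv_scores),
       report = report, test_idx = test_idx)
}

#' Fingerprint baselines: random forest and multitask MLP
#'
#' (a) One random-forest classifier per task, tuned by inner K-fold CV
#' over `mtry` on validation AUPR; (b) the multitask MLP head on the same
#' fingerprints via [fit_downstream()]. Both follow the identical split
#' protocol and produce the same metric schema.
#'
#' @param fp binary fingerprint matrix.
#' @param y label matrix.
#' @param split split object as in [fit_downstream()].
#' @param mtry_grid candidate `mtry` values (default c(32, sqrt(F), F/8)).
#' @param ntree trees per forest (default 200).
#' @param mlp_grid hyperparameter grid for the MLP baseline.
#' @param inner_k inner CV folds for RF tuning (default 3).
#' @param seed integer seed.
#' @param ... passed to [fit_downstream()] for the MLP baseline.
#' @return list with `rf_report`, `mlp_report` (per-task test metrics)
#'   and the fitted models.
#' @export
fit_baselines <- function(fp, y, split, mtry_grid = NULL, ntree = 200L,
                          mlp_grid = data.frame(alpha = 1, gamma = 2),
                          inner_k = 3L, seed = 1L, ...) {
  fp <- as.matrix(fp)
  ym <- unclass(as.matrix(y))
  test_idx <- which(split$fold_id == split$test_fold)
  dev_idx <- which(split$fold_id != split$test_fold)
  if (is.null(mtry_grid)) {
    mtry_grid <- unique(pmax(2L, round(c(sqrt(ncol(fp)), ncol(fp) / 8))))
  }
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)
  k <- min(inner_k, length(dev_idx))
  inner_fold <- sample(rep_len(seq_len(k), length(dev_idx)))

  rf_models <- vector("list", ncol(ym))
  rf_probs <- matrix(NA_real_, length(test_idx), ncol(ym))
  for (p in seq_len(ncol(ym))) {
    obs_dev <- dev_idx[!is.na(ym[dev_idx, p])]
    ydp <- ym[obs_dev, p]
    if (length(unique(ydp)) < 2) next
    best_m <- mtry_grid[1]
    if (length(mtry_grid) > 1) {
      sc <- vapply(mtry_grid, function(m) {
        vals <- numeric(0)
        for (fi in seq_len(k)) {
          tr <- obs_dev[inner_fold[match(obs_dev, dev_idx)] != fi]
          va <- setdiff(obs_dev, tr)
          if (length(unique(ym[tr, p])) < 2 ||
              length(unique(ym[va, p])) < 2) next
          fit <- randomForest::randomForest(
            x = fp[tr, , drop = FALSE], y = factor(ym[tr, p]),
            ntree = ntree, mtry = m)
          pr <- predict(fit, fp[va, , drop = FALSE], type = "prob")[, "1"]
          vals <- c(vals, aupr(ym[va, p], pr))
        }
        if (length(vals)) mean(vals) else NA_real_
      }, numeric(1))
      if (any(is.finite(sc))) best_m <- mtry_grid[which.max(sc)]
    }
    rf_models[[p]] <- randomForest::randomForest(
      x = fp[obs_dev, , drop = FALSE], y = factor(ydp),
      ntree = ntree, mtry = best_m)
    rf_probs[, p] <- predict(rf_models[[p]], fp[test_idx, , drop = FALSE],
                             type = "prob")[, "1"]
  }
  rf_report <- compute_metrics(ym[test_idx, , drop = FALSE], rf_probs)

  mlp <- fit_downstream(fp, ym, split, grid = mlp_grid, seed = seed, ...)
  list(rf_report = rf_report, mlp_report = mlp$report,
       rf_models = rf_models, mlp = mlp)
}

#' Write a metric report as tidy CSV
#'
#' @param report data.frame from [compute_metrics()].
#' @param path output CSV path.
#' @export
write_report_csv <- function(report, path) {
  long <- stats::reshape(
    report[, c("task", "aupr", "roc_auc", "mcc", "pos_ratio")],
    direction = "long", varying = c("aupr", "roc_auc", "mcc", "pos_ratio"),
    v.names = "value", timevar = "metric",
    times = c("aupr", "roc_auc", "mcc", "pos_ratio"), idvar = "task")
  utils::write.csv(long[order(long$task), ], path, row.names = FALSE)
}
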