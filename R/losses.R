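# Imbalance-aware loss family for sparse multitask binary panels.
#
# All losses treat NA labels as unobserved: they contribute zero loss and
# zero gradient, and per-task class counts are taken over observed entries
# only. Log-probabilities are computed through the numerically stable
# log-sigmoid (plogis(..., log.p = TRUE)); probabilities are never clipped.

#' Loss configuration for the weighted focal family
#'
#' @param alpha positive-balancing parameter in \[0, 1\]. At `alpha = 0`
#'   all per-task positive weights are 1; at `alpha = 1` they equal the
#'   negative/positive count ratio.
#' @param gamma focusing parameter, >= 0. `gamma = 0` disables focusing.
#' @param reduction `"mean"` (default; mean over observed entries, so the
#'   magnitude is batch-size invariant) or `"sum"` (the literal double sum).
#' @param weights optional per-task positive weights; if `NULL` they are
#'   derived from label counts via [positive_weights()] at fit time.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0, gamma = 0, reduction = c("mean", "sum"),
                        weights = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0)
  reduction <- match.arg(reduction)
  structure(list(alpha = alpha, gamma = gamma, reduction = reduction,
                 weights = weights),
            class = "loss_config")
}

#' Per-task positive weights
#'
#' Computes `w+ = alpha * (N_neg / N_pos) + (1 - alpha)` per task from
#' observed label counts. Tasks with no observed positives have undefined
#' weights: they get `NA` with a warning and should be excluded from
#' weighting downstream.
#'
#' @param n_pos,n_neg integer vectors of observed positive / negative
#'   counts per task.
#' @param alpha balancing parameter in \[0, 1\].
#' @return numeric vector of weights, one per task.
#' @export
positive_weights <- function(n_pos, n_neg, alpha) {
  stopifnot(length(n_pos) == length(n_neg), alpha >= 0, alpha <= 1)
  w <- alpha * (n_neg / n_pos) + (1 - alpha)
  if (any(n_pos == 0)) {
    warning("tasks with zero observed positives have undefined weights (NA)")
    w[n_pos == 0] <- NA_real_
  }
  w
}

#' Observed class counts per task
#'
#' Counts positive and negative entries per column of a label matrix,
#' ignoring `NA` (unobserved) entries.
#'
#' @param y label matrix with entries in \{0, 1, NA\}.
#' @return integer matrix with columns `n_pos`, `n_neg`, one row per task.
#' @export
label_counts <- function(y) {
  y <- as.matrix(y)
  n_pos <- colSums(y == 1, na.rm = TRUE)
  n_neg <- colSums(y == 0, na.rm = TRUE)
  cbind(n_pos = n_pos, n_neg = n_neg)
}

# resolve per-task weights from a loss_config and a label matrix
.resolve_weights <- function(y, cfg) {
  if (!is.null(cfg$weights)) {
    stopifnot(length(cfg$weights) == ncol(y))
    return(cfg$weights)
  }
  cnt <- label_counts(y)
  w <- suppressWarnings(positive_weights(cnt[, 1], cnt[, 2], cfg$alpha))
  # tasks with no positives in this batch: fall back to the unweighted
  # contribution (their positive term never fires anyway)
  w[is.na(w)] <- 1
  w
}

#' Weighted focal loss
#'
#' The primary training objective for imbalanced multitask binary panels:
#' \deqn{L = \sum_{n,p} w^+_p (1-\sigma(f_{np}))^\gamma y_{np}
#'       (-\log \sigma(f_{np})) +
#'       \sigma(f_{np})^\gamma (1-y_{np}) (-\log(1-\sigma(f_{np})))}
#' over observed entries. Reduces exactly to focal loss when `alpha = 0`,
#' to weighted BCE when `gamma = 0`, and to standard BCE when both are 0.
#'
#' @param y binary label matrix with `NA` for unobserved entries.
#' @param f logit matrix (raw model outputs), same shape as `y`.
#' @param cfg a [loss_config()]; if `cfg$weights` is `NULL`, weights are
#'   derived from the observed counts of `y`.
#' @return scalar loss (non-negative).
#' @export
weighted_focal_loss <- function(y, f, cfg = loss_config()) {
  y <- as.matrix(y); f <- as.matrix(f)
  stopifnot(identical(dim(y), dim(f)))
  if (any(!is.finite(f))) stop("non-finite logits")
  obs <- !is.na(y)
  if (!any(obs)) stop("all labels are missing")
  w <- .resolve_weights(y, cfg)
  s <- stats::plogis(f)
  log_s <- stats::plogis(f, log.p = TRUE)      # log sigma(f)
  log_1ms <- stats::plogis(-f, log.p = TRUE)   # log(1 - sigma(f))
  wmat <- matrix(w, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  pos <- wmat * (1 - s)^cfg$gamma * (-log_s)
  neg <- s^cfg$gamma * (-log_1ms)
  contrib <- ifelse(obs & y == 1, pos, ifelse(obs & y == 0, neg, 0))
  total <- sum(contrib)
  if (cfg$reduction == "mean") total / sum(obs) else total
}

#' Gradient of the weighted focal loss with respect to the logits
#'
#' Analytic per-entry derivative, used by the package's trainers. Missing
#' labels get exactly zero gradient.
#'
#' @inheritParams weighted_focal_loss
#' @return matrix of `dL/df`, same shape as `f`.
#' @export
weighted_focal_grad <- function(y, f, cfg = loss_config()) {
  y <- as.matrix(y); f <- as.matrix(f)
  stopifnot(identical(dim(y), dim(f)))
  obs <- !is.na(y)
  w <- .resolve_weights(y, cfg)
  s <- stats::plogis(f)
  log_s <- stats::plogis(f, log.p = TRUE)
  log_1ms <- stats::plogis(-f, log.p = TRUE)
  g <- cfg$gamma
  wmat <- matrix(w, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  # d/df for y=1:  w [ g s (1-s)^g log s - (1-s)^(g+1) ]
  dpos <- wmat * (g * s * (1 - s)^g * log_s - (1 - s)^(g + 1))
  # d/df for y=0:  s^g [ s - g (1-s) log(1-s) ]
  dneg <- s^g * (s - g * (1 - s) * log_1ms)
  d <- ifelse(obs & y == 1, dpos, ifelse(obs & y == 0, dneg, 0))
  if (cfg$reduction == "mean") d / sum(obs) else d
}

#' Masked-token cross-entropy loss
#'
#' Mean over masked positions of the softmax cross-entropy between
#' predicted token logits and the true tokens. Unmasked positions
#' contribute exactly zero.
#'
#' @param pred_logits numeric matrix, positions x vocabulary.
#' @param true_tokens integer vector of true token indices (1-based).
#' @param mask logical or 0/1 vector marking masked positions.
#' @return scalar loss.
#' @export
masking_loss <- function(pred_logits, true_tokens, mask) {
  pred_logits <- as.matrix(pred_logits)
  mask <- as.logical(mask)
  stopifnot(nrow(pred_logits) == length(true_tokens),
            length(mask) == length(true_tokens))
  if (!any(mask)) stop("no masked positions (|m| = 0)")
  idx <- which(mask)
  z <- pred_logits[idx, , drop = FALSE]
  zmax <- z[cbind(seq_along(idx), max.col(z, ties.method = "first"))]
  lse <- zmax + log(rowSums(exp(z - zmax)))
  truth <- z[cbind(seq_along(idx), true_tokens[idx])]
  mean(lse - truth)
}

#' Physicochemical regression loss
#'
#' Mean over samples of the squared Euclidean norm of the estimation error
#' across descriptor dimensions.
#'
#' @param estimates,targets numeric matrices of equal shape (samples x
#'   descriptors).
#' @return scalar loss.
#' @export
physchem_loss <- function(estimates, targets) {
  estimates <- as.matrix(estimates); targets <- as.matrix(targets)
  if (!identical(dim(estimates), dim(targets))) {
    stop("estimates and targets must have the same shape")
  }
  stopifnot(nrow(estimates) >= 1)
  mean(rowSums((estimates - targets)^2))
}

#' Per-class log-loss diagnostic
#'
#' For each task, the mean negative log-probability over observed positives
#' and, separately, over observed negatives. A wide positive/negative gap
#' diagnoses a network biased toward the majority class. Sides with no
#' observed instances are reported as `NA` (undefined, not zero).
#'
#' @param y binary label matrix with `NA` for unobserved entries.
#' @param f logit matrix aligned with `y`.
#' @return data.frame with columns `task`, `L_pos`, `L_neg`, `n_pos`,
#'   `n_neg`.
#' @export
classwise_logloss <- function(y, f) {
  y <- as.matrix(y); f <- as.matrix(f)
  stopifnot(identical(dim(y), dim(f)))
  log_s <- stats::plogis(f, log.p = TRUE)
  log_1ms <- stats::plogis(-f, log.p = TRUE)
  tasks <- colnames(y)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(y)))
  res <- lapply(seq_len(ncol(y)), function(p) {
    yp <- y[, p]
    pos <- which(!is.na(yp) & yp == 1)
    neg <- which(!is.na(yp) & yp == 0)
    data.frame(
      task = tasks[p],
      L_pos = if (length(pos)) mean(-log_s[pos, p]) else NA_real_,
      L_neg = if (length(neg)) mean(-log_1ms[neg, p]) else NA_real_,
      n_pos = length(pos), n_neg = length(neg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Read/write a loss configuration as YAML
#'
#' @param path YAML file with fields `alpha`, `gamma`, `reduction` and an
#'   optional `per_task_weights` file path (one weight per line).
#' @return a [loss_config()].
#' @export
read_loss_config <- function(path) {
  cf <- yaml::read_yaml(path)
  w <- NULL
  if (!is.null(cf$per_task_weights)) {
    w <- as.numeric(readLines(cf$per_task_weights))
  }
  loss_config(alpha = cf$alpha %||% 0, gamma = cf$gamma %||% 0,
              reduction = cf$reduction %||% "mean", weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
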