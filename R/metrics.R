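# Precision-recall-first evaluation for sparse, imbalanced multitask
# binary panels, plus the diagnostic analyses (imbalance sensitivity and
# the positive/negative log-loss gap).

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over achieved recall levels (the average-
#' precision estimator): scores are swept from high to low and each
#' recall increment is credited with the precision at that threshold.
#' Tied scores are handled as a single threshold. No linear interpolation
#' between PR points is used (which would be optimistically biased).
#'
#' @param labels binary vector (0/1).
#' @param scores numeric score vector, higher = more positive.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) {
    stop("AUPR undefined: need at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # cumulative counts at the end of each tie group
  grp_end <- which(c(diff(sc) != 0, TRUE))
  tp <- cumsum(lab == 1)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator, equivalent to trapezoidal
#' integration of the ROC curve with ties contributing 1/2.
#'
#' @inheritParams aupr
#' @return ROC-AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("ROC-AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Matthews correlation coefficient at a probability threshold
#'
#' @inheritParams aupr
#' @param threshold decision threshold on the scores (default 0.5).
#' @return MCC in \[-1, 1\]; 0 when a marginal is degenerate.
#' @export
mcc <- function(labels, scores, threshold = 0.5) {
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Per-task metric report
#'
#' Computes AUPR, ROC-AUC, MCC (at 0.5), prevalence and class counts per
#' task over observed labels. Tasks with a single observed class are
#' flagged (`defined = FALSE`) and their threshold-free metrics are `NA`.
#'
#' @param y label matrix (`NA` = unobserved).
#' @param probs probability matrix aligned with `y`.
#' @return data.frame with one row per task: `task`, `aupr`, `roc_auc`,
#'   `mcc`, `pos_ratio`, `n_pos`, `n_neg`, `defined`.
#' @export
compute_metrics <- function(y, probs) {
  y <- unclass(as.matrix(y)); probs <- as.matrix(probs)
  stopifnot(identical(dim(y), dim(probs)))
  tasks <- colnames(y)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(y)))
  res <- lapply(seq_len(ncol(y)), function(p) {
    obs <- !is.na(y[, p])
    yy <- y[obs, p]; pp <- probs[obs, p]
    np <- sum(yy == 1); nn <- sum(yy == 0)
    ok <- np >= 1 && nn >= 1
    data.frame(
      task = tasks[p],
      aupr = if (ok) aupr(yy, pp) else NA_real_,
      roc_auc = if (ok) roc_auc(yy, pp) else NA_real_,
      mcc = if (ok) mcc(yy, pp) else NA_real_,
      pos_ratio = if (np + nn > 0) np / (np + nn) else NA_real_,
      n_pos = np, n_neg = nn, defined = ok,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Sensitivity of performance to class imbalance
#'
#' Spearman rank correlation between per-task AUPR and positive ratio,
#' with the fitted least-squares line for a diagnostic scatter plot. A
#' high correlation indicates the model's performance is driven by task
#' prevalence rather than signal.
#'
#' @param report a [compute_metrics()] data.frame (>= 3 defined tasks).
#' @return list with `spearman_rho`, `table` (task, aupr, pos_ratio) and
#'   `line` (intercept, slope of AUPR ~ pos_ratio).
#' @export
imbalance_sensitivity <- function(report) {
  r <- report[report$defined & !is.na(report$aupr), , drop = FALSE]
  if (nrow(r) < 3) stop("need at least 3 tasks with defined AUPR")
  if (stats::sd(r$aupr) == 0) {
    warning("constant AUPR across tasks: correlation undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(r$aupr, r$pos_ratio, method = "spearman")
  }
  fit <- stats::lm(aupr ~ pos_ratio, data = r)
  list(spearman_rho = rho,
       table = r[, c("task", "aupr", "pos_ratio")],
       line = stats::coef(fit))
}

#' Positive/negative log-loss gap report
#'
#' Tabulates the per-task mean log-loss of positive and negative
#' instances (a biased network shows a wide gap: confident on the
#' majority negatives, poor on positives) together with the across-task
#' mean and a 95% covariance-ellipse summary for plotting.
#'
#' @param y label matrix.
#' @param probs probability matrix aligned with `y` (converted to logits
#'   internally).
#' @return list with `per_task` (the [classwise_logloss()] table with a
#'   `gap` column), `mean` (c(L_pos, L_neg)), and `ellipse` (center,
#'   covariance eigenvectors/values scaled to the 95% quantile).
#' @export
logloss_gap_report <- function(y, probs) {
  probs <- as.matrix(probs)
  f <- stats::qlogis(pmin(pmax(probs, 1e-12), 1 - 1e-12))
  tab <- classwise_logloss(y, f)
  tab$gap <- tab$L_pos - tab$L_neg
  ok <- stats::complete.cases(tab[, c("L_pos", "L_neg")])
  ctr <- c(L_pos = mean(tab$L_pos[ok]), L_neg = mean(tab$L_neg[ok]))
  ell <- NULL
  if (sum(ok) >= 3) {
    S <- stats::cov(tab[ok, c("L_pos", "L_neg")])
    eg <- eigen(S, symmetric = TRUE)
    ell <- list(center = ctr, axes = eg$vectors,
                radii = sqrt(pmax(eg$values, 0) *
                               stats::qchisq(0.95, df = 2)))
  }
  list(per_task = tab, mean = ctr, ellipse = ell)
}
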