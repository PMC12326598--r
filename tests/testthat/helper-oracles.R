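# Shared fixtures and independent scalar reference implementations used
# as oracles against the vectorized package code.

.fixture_env <- new.env(parent = emptyenv())

# small planted-signal corpus, built once and reused across test files
small_corpus <- function(n = 120L, seed = 42L, n_invitro = 6L,
                         n_invivo = 3L) {
  key <- sprintf("c%d_%d_%d_%d", n, seed, n_invitro, n_invivo)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(synthetic_spec(
      n_molecules = n, n_invitro = n_invitro, n_invivo = n_invivo,
      seed = seed))
  }
  .fixture_env[[key]]
}

# scalar double-loop reference for the weighted focal loss: a literal
# transcription of the summation, one entry at a time
ref_weighted_focal <- function(y, f, alpha, gamma, weights = NULL,
                               reduction = "mean") {
  cnt <- label_counts(y)
  if (is.null(weights)) {
    weights <- alpha * (cnt[, "n_neg"] / cnt[, "n_pos"]) + (1 - alpha)
    weights[cnt[, "n_pos"] == 0] <- 1
  }
  total <- 0
  nobs <- 0
  for (n in seq_len(nrow(y))) {
    for (p in seq_len(ncol(y))) {
      if (is.na(y[n, p])) next
      nobs <- nobs + 1
      s <- 1 / (1 + exp(-f[n, p]))
      if (y[n, p] == 1) {
        total <- total + weights[p] * (1 - s)^gamma * (-log(s))
      } else {
        total <- total + s^gamma * (-log(1 - s))
      }
    }
  }
  if (reduction == "mean") total / nobs else total
}

# scalar reference for the per-class log-loss
ref_classwise <- function(y, f) {
  out <- NULL
  for (p in seq_len(ncol(y))) {
    lp <- c(); ln_ <- c()
    for (n in seq_len(nrow(y))) {
      if (is.na(y[n, p])) next
      s <- 1 / (1 + exp(-f[n, p]))
      if (y[n, p] == 1) lp <- c(lp, -log(s)) else ln_ <- c(ln_, -log(1 - s))
    }
    out <- rbind(out, data.frame(
      L_pos = if (length(lp)) mean(lp) else NA_real_,
      L_neg = if (length(ln_)) mean(ln_) else NA_real_))
  }
  out
}

# O(n^2) pairwise-comparison ROC-AUC
ref_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# random sparse {0,1,NA} label matrix and aligned logits
random_label_logits <- function(n, p, miss = 0.2) {
  y <- matrix(stats::rbinom(n * p, 1, 0.3), n, p)
  y[matrix(stats::runif(n * p) < miss, n, p)] <- NA
  # guarantee at least one observed positive and negative per task
  for (j in seq_len(p)) {
    obs <- which(!is.na(y[, j]))
    if (length(obs) < 2) {
      y[1:2, j] <- c(0, 1)
    } else {
      y[obs[1], j] <- 1
      y[obs[2], j] <- 0
    }
  }
  list(y = y, f = matrix(stats::rnorm(n * p, sd = 2), n, p))
}
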