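test_that("positive weights follow the alpha-blended inverse ratio", {
  expect_equal(positive_weights(10, 90, alpha = 1), 9.0)
  expect_equal(positive_weights(10, 90, alpha = 0), 1.0)
  expect_equal(positive_weights(10, 90, alpha = 0.5), 5.0)
  expect_warning(w <- positive_weights(c(0, 5), c(10, 10), 1), "undefined")
  expect_true(is.na(w[1]) && w[2] == 2)
  # invariant: w+ >= 1 - alpha for any counts
  set.seed(2)
  for (i in 1:20) {
    a <- stats::runif(1)
    w <- positive_weights(sample(1:50, 5), sample(0:50, 5), a)
    expect_true(all(w >= 1 - a - 1e-12))
  }
})

test_that("weighted focal loss matches hand-computed scalar values", {
  # standard BCE at f = 0: ln 2
  expect_equal(weighted_focal_loss(matrix(1), matrix(0),
                                   loss_config(0, 0, weights = 1)),
               log(2))
  # gamma = 2, w+ = 3, sigma(f) = 0.9 on a positive
  f <- stats::qlogis(0.9)
  expect_equal(weighted_focal_loss(matrix(1), matrix(f),
                                   loss_config(gamma = 2, weights = 3)),
               3 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  # perfect prediction drives the loss to zero
  expect_lt(weighted_focal_loss(matrix(1), matrix(30),
                                loss_config(1, 2, weights = 5)), 1e-10)
  expect_error(weighted_focal_loss(matrix(1), matrix(NaN)), "finite")
  expect_error(weighted_focal_loss(matrix(NA_real_), matrix(0)), "missing")
})

test_that("the loss family collapses to BCE, weighted BCE and focal loss", {
  set.seed(11)
  for (i in 1:50) {
    rl <- random_label_logits(12, 4)
    y <- rl$y; f <- rl$f
    obs <- !is.na(y)
    s <- stats::plogis(f)
    bce <- mean(ifelse(y == 1, -log(s), -log(1 - s))[obs])
    expect_equal(weighted_focal_loss(y, f, loss_config(0, 0)), bce,
                 tolerance = 1e-10)
    expect_equal(weighted_focal_loss(y, f, loss_config(0, 0)),
                 ref_weighted_focal(y, f, 0, 0), tolerance = 1e-10)
    # gamma = 0 is weighted BCE; alpha = 0 is plain focal loss
    expect_equal(weighted_focal_loss(y, f, loss_config(0.7, 0)),
                 ref_weighted_focal(y, f, 0.7, 0), tolerance = 1e-10)
    expect_equal(weighted_focal_loss(y, f, loss_config(0, 2)),
                 ref_weighted_focal(y, f, 0, 2), tolerance = 1e-10)
  }
})

test_that("vectorized loss equals the scalar double-loop reference", {
  set.seed(12)
  for (i in 1:25) {
    rl <- random_label_logits(10, 5)
    a <- stats::runif(1); g <- stats::runif(1, 0, 4)
    expect_equal(weighted_focal_loss(rl$y, rl$f, loss_config(a, g)),
                 ref_weighted_focal(rl$y, rl$f, a, g), tolerance = 1e-10)
    expect_equal(
      weighted_focal_loss(rl$y, rl$f, loss_config(a, g, reduction = "sum")),
      ref_weighted_focal(rl$y, rl$f, a, g, reduction = "sum"),
      tolerance = 1e-10)
  }
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(13)
  rl <- random_label_logits(6, 3)
  cfg <- loss_config(0.8, 2)
  cfg$weights <- c(2, 5, 1.3)
  g <- weighted_focal_grad(rl$y, rl$f, cfg)
  eps <- 1e-6
  for (k in 1:15) {
    i <- sample(6, 1); j <- sample(3, 1)
    fp <- rl$f; fp[i, j] <- fp[i, j] + eps
    fm <- rl$f; fm[i, j] <- fm[i, j] - eps
    fd <- (weighted_focal_loss(rl$y, fp, cfg) -
             weighted_focal_loss(rl$y, fm, cfg)) / (2 * eps)
    expect_equal(g[i, j], fd, tolerance = 1e-5)
  }
  # missing labels contribute exactly zero gradient
  expect_true(all(g[is.na(rl$y)] == 0))
})

test_that("increasing alpha never shrinks the positive-entry contribution", {
  set.seed(14)
  y <- matrix(stats::rbinom(60, 1, 0.2), 20, 3)  # negatives dominate
  y[1, ] <- 1
  f <- matrix(stats::rnorm(60), 20, 3)
  ypos <- ifelse(y == 1, 1, NA)  # positive entries only
  contrib <- function(a) {
    w <- positive_weights(colSums(y == 1), colSums(y == 0), a)
    weighted_focal_loss(ypos, f, loss_config(a, 1, reduction = "sum",
                                             weights = w))
  }
  vals <- vapply(seq(0, 1, by = 0.1), contrib, numeric(1))
  expect_true(all(diff(vals) >= -1e-10))
})

test_that("focusing strictly reduces loss on correctly classified entries", {
  # positive predicted above 0.5: (1-s)^gamma < 1 for gamma > 0
  f <- stats::qlogis(c(0.7, 0.9, 0.99))
  for (fi in f) {
    expect_lt(weighted_focal_loss(matrix(1), matrix(fi),
                                  loss_config(0, 2, weights = 1)),
              weighted_focal_loss(matrix(1), matrix(fi),
                                  loss_config(0, 0, weights = 1)))
  }
})

test_that("masking loss is the mean cross-entropy over masked positions", {
  V <- 7
  logits <- matrix(0, 4, V)                       # uniform
  expect_equal(masking_loss(logits, c(1, 2, 3, 4), c(1, 0, 0, 1)), log(V))
  conf <- matrix(-30, 2, V); conf[1, 3] <- 30; conf[2, 5] <- 30
  expect_lt(masking_loss(conf, c(3, 5), c(1, 1)), 1e-8)
  expect_error(masking_loss(logits, c(1, 2, 3, 4), rep(0, 4)),
               "no masked positions")
  # unmasked positions contribute exactly zero: perturbing them is inert
  l1 <- masking_loss(logits, c(1, 2, 3, 4), c(1, 0, 0, 0))
  logits2 <- logits; logits2[2, ] <- stats::rnorm(V)
  expect_equal(masking_loss(logits2, c(1, 2, 3, 4), c(1, 0, 0, 0)), l1)
})

test_that("physchem loss is the mean squared Euclidean norm", {
  y <- matrix(c(1, 2), 1, 2)
  expect_equal(physchem_loss(y, y), 0)
  expect_equal(physchem_loss(matrix(3), matrix(1)), 4)
  est <- rbind(c(2, 0), c(1, 2)); tgt <- rbind(c(0, 0), c(0, 1))
  expect_equal(physchem_loss(est, tgt), mean(c(4, 2)))
  expect_error(physchem_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("classwise log-loss separates positive and negative quality", {
  y <- cbind(c(1, 1, 0, 0))
  f05 <- matrix(0, 4, 1)
  cl <- classwise_logloss(y, f05)
  expect_equal(cl$L_pos, log(2))
  expect_equal(cl$L_neg, log(2))
  f91 <- matrix(stats::qlogis(c(0.9, 0.9, 0.1, 0.1)), 4, 1)
  cl2 <- classwise_logloss(y, f91)
  expect_equal(cl2$L_pos, -log(0.9), tolerance = 1e-12)
  expect_equal(cl2$L_neg, -log(0.9), tolerance = 1e-12)
  # confident-wrong positives blow up L_pos only
  fbad <- matrix(stats::qlogis(c(0.01, 0.01, 0.1, 0.1)), 4, 1)
  cl3 <- classwise_logloss(y, fbad)
  expect_equal(cl3$L_pos, -log(0.01), tolerance = 1e-10)
  expect_gt(cl3$L_pos, 10 * cl3$L_neg)
  # a side with no instances is NA, not zero
  cl4 <- classwise_logloss(cbind(c(1, 1)), matrix(0, 2, 1))
  expect_true(is.na(cl4$L_neg))
  # vectorized implementation matches the scalar reference
  set.seed(15)
  rl <- random_label_logits(10, 5)
  got <- classwise_logloss(rl$y, rl$f)
  ref <- ref_classwise(rl$y, rl$f)
  expect_equal(got$L_pos, ref$L_pos, tolerance = 1e-10)
  expect_equal(got$L_neg, ref$L_neg, tolerance = 1e-10)
})

test_that("loss configuration reads from YAML with optional weights", {
  tmp <- withr::local_tempdir()
  wfile <- file.path(tmp, "w.txt")
  writeLines(c("2.5", "1"), wfile)
  yaml::write_yaml(list(alpha = 0.5, gamma = 2, reduction = "sum",
                        per_task_weights = wfile),
                   file.path(tmp, "loss.yaml"))
  cfg <- read_loss_config(file.path(tmp, "loss.yaml"))
  expect_equal(cfg$alpha, 0.5)
  expect_equal(cfg$gamma, 2)
  expect_equal(cfg$reduction, "sum")
  expect_equal(cfg$weights, c(2.5, 1))
  expect_error(loss_config(alpha = 2), "alpha")
  expect_error(loss_config(gamma = -1), "gamma")
})
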