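# Minimal neural-network primitives with analytic backward passes.
#
# Parameters are nested named lists of numeric arrays; gradients mirror the
# parameter structure exactly. All forward functions that participate in
# training return a cache sufficient for their backward pass.

# ---- parameter-tree utilities ------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_sum_abs <- function(a) {
  s <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else s <<- s + sum(abs(x))
    invisible(NULL)
  }
  walk(a)
  s
}

# ---- initializers -------------------------------------------------------

.init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# ---- activations --------------------------------------------------------

# sigmoid approximation of GELU: x * sigma(1.702 x); much cheaper than the
# exact Gaussian-cdf form and indistinguishable for training purposes
GELU_C <- 1.702

gelu <- function(x) x * stats::plogis(GELU_C * x)
gelu_grad <- function(x) {
  sg <- stats::plogis(GELU_C * x)
  sg * (1 + GELU_C * x * (1 - sg))
}

# cached-gate variants used on the training hot path
gelu_fwd <- function(x) {
  sg <- stats::plogis(GELU_C * x)
  list(y = x * sg, pn = sg)
}
gelu_grad_cached <- function(x, sg) {
  sg * (1 + GELU_C * x * (1 - sg))
}

relu <- function(x) pmax(x, 0)

# fast column-broadcasts (avoid sweep()'s dispatch overhead)
add_cols <- function(x, b) x + rep(b, each = nrow(x))
mul_cols <- function(x, g) x * rep(g, each = nrow(x))

# ---- dense layer --------------------------------------------------------

dense_fwd <- function(x, W, b) {
  add_cols(x %*% W, b)
}

# returns list(dx, dW, db)
dense_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# ---- layer norm (per row) ----------------------------------------------

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- add_cols(mul_cols(xhat, g), b)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- mul_cols(dy, cache$g)
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dx <- inv * (dxh - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# ---- softmax over rows --------------------------------------------------

softmax_rows <- function(z) {
  zmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - zmax)
  e / rowSums(e)
}

# ---- Adam optimizer -----------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  if (weight_decay > 0) {
    upd <- tree_map2(function(u, p) u + weight_decay * p, upd, params)
  }
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
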