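# Small neural-net utilities shared by the attention head, the GCN encoder
# and the MI discriminators: fully-connected MLPs with analytic backprop and
# an Adam optimizer operating on named lists of arrays.

mlp_init <- function(sizes, out = c("sigmoid", "linear")) {
  out <- match.arg(out)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- glorot(sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes, out = out)
}

# X: rows = samples. Hidden activations are ReLU; output squashing per net$out.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    A <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1]] <- if (l < L) pmax(A, 0) else A
  }
  pre <- H[[L + 1]]
  out <- if (net$out == "sigmoid") stats::plogis(pre) else pre
  list(out = drop(out), pre = drop(pre), H = H)
}

# dpre: gradient of the objective w.r.t. the pre-squash output (n x 1).
# Returns parameter grads and the gradient w.r.t. the input rows.
mlp_backward <- function(net, cache, dpre) {
  L <- length(net$W)
  dpre <- matrix(dpre, ncol = ncol(net$W[[L]]))
  dW <- vector("list", L); db <- vector("list", L)
  d <- dpre
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$H[[l]], d)
    db[[l]] <- colSums(d)
    if (l > 1) {
      d <- d %*% t(net$W[[l]])
      d <- d * (cache$H[[l]] > 0)   # ReLU mask (H[[l]] is the post-ReLU input)
    } else {
      d <- d %*% t(net$W[[l]])
    }
  }
  list(W = dW, b = db, dX = d)
}

# Adam over arbitrarily nested lists of numeric arrays.
adam_init <- function(params) {
  zero <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# Numerically stable log-mean-exp.
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
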