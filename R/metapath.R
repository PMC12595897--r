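#' Enumerate the nine drug-to-target meta-path count matrices
#'
#' A meta-path is a typed node-sequence template starting at a drug and
#' ending at a target (length at most 5 node classes here). Entry (d, t) of
#' each matrix counts the path instances of that template from drug d to
#' target t, obtained by chained adjacency products:
#' \itemize{
#' \item `DT`   = `A_DT` (the known interactions, kept binary)
#' \item `DDT`  = `A_DD A_DT`
#' \item `DIT`  = `A_DI A_TI'`
#' \item `DTT`  = `A_DT A_TT`
#' \item `DIDT` = `A_DI A_DI' A_DT`
#' \item `DITT` = `A_DI A_TI' A_TT`
#' \item `DSDT` = `A_DS A_DS' A_DT`
#' \item `DDIT` = `A_DD A_DI A_TI'`
#' \item `DTDT` = `A_DT A_DT' A_DT`
#' }
#'
#' @param net a [hetero_network()].
#' @return An object of class `metapath_stack`: list with `names` (the nine
#'   template names, in the fixed order above) and `matrices` (named list of
#'   nonnegative integer `N_d x N_t` matrices).
#' @export
metapath_stack <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  DD <- net$A_DD; DT <- net$A_DT; DI <- net$A_DI
  DS <- net$A_DS; TT <- net$A_TT; TI <- net$A_TI
  m <- list(
    DT   = DT,
    DDT  = DD %*% DT,
    DIT  = DI %*% t(TI),
    DTT  = DT %*% TT,
    DIDT = DI %*% t(DI) %*% DT,
    DITT = DI %*% t(TI) %*% TT,
    DSDT = DS %*% t(DS) %*% DT,
    DDIT = DD %*% DI %*% t(TI),
    DTDT = DT %*% t(DT) %*% DT
  )
  structure(list(names = names(m), matrices = m), class = "metapath_stack")
}

#' @export
print.metapath_stack <- function(x, ...) {
  cat("Meta-path count stack:",
      paste(x$names, collapse = " "), "\n")
  cat(sprintf("  %d x %d; nonzero entries: %s\n",
              nrow(x$matrices[[1]]), ncol(x$matrices[[1]]),
              paste(vapply(x$matrices, function(A) sum(A > 0), 0), collapse = " ")))
  invisible(x)
}

#' Initialize semantic-attention parameters
#'
#' The eight indirect meta-path matrices are scored by a shared two-layer
#' attention head: each drug row of a count matrix is projected
#' (`z = A W1 + b1`), passed through `tanh(z W2 + b2)`, and reduced by the
#' attention vector `q`; rowwise scores are averaged into one scalar per
#' meta-path and softmax-normalized into fusion weights.
#'
#' @param stack a [metapath_stack()] (provides the input dimension `N_t`).
#' @param proj_dim projection width (default 128).
#' @param seed RNG seed for Glorot-uniform initialization.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(stack, proj_dim = 128, seed = 1) {
  Nt <- ncol(stack$matrices[[1]])
  set.seed(as.integer(seed))
  structure(list(
    W1 = glorot(Nt, proj_dim), b1 = numeric(proj_dim),
    W2 = glorot(proj_dim, proj_dim), b2 = numeric(proj_dim),
    q = glorot(proj_dim, 1)[, 1],
    proj_dim = proj_dim
  ), class = "attention_params")
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

# Forward pass shared by attention_fuse() and fit_attention().
attention_forward <- function(stack, params) {
  idx <- 2:9
  mats <- stack$matrices[idx]
  per <- lapply(mats, function(A) {
    Z <- sweep(A %*% params$W1, 2, params$b1, "+")
    U <- sweep(Z %*% params$W2, 2, params$b2, "+")
    Tn <- tanh(U)
    s <- drop(Tn %*% params$q)
    list(Z = Z, Tn = Tn, s = s, w = mean(s))
  })
  w <- vapply(per, `[[`, 0, "w")
  if (any(!is.finite(w))) stop("attention_fuse: non-finite attention scores")
  a <- softmax(w)
  fused <- Reduce(`+`, Map(function(A, ai) A * ai, mats, a))
  list(per = per, w = w, a = a, fused = fused, mats = mats)
}

softmax <- function(w) { e <- exp(w - max(w)); e / sum(e) }

#' Fuse indirect meta-path matrices with semantic attention
#'
#' Computes one scalar attention score per indirect meta-path (templates 2-9;
#' the direct `DT` matrix is supervision, not an input) and returns the
#' softmax-weighted sum of their count matrices. Since the weights form a
#' convex combination, the fused matrix stays on the path-count scale.
#'
#' @param stack a [metapath_stack()].
#' @param params an [attention_params()] object.
#' @return `A_path_fusion`, a nonnegative `N_d x N_t` matrix with attributes
#'   `weights` (softmax weights, named) and `scores` (pre-softmax scalars).
#' @export
attention_fuse <- function(stack, params) {
  fw <- attention_forward(stack, params)
  out <- fw$fused
  attr(out, "weights") <- stats::setNames(fw$a, stack$names[2:9])
  attr(out, "scores") <- stats::setNames(fw$w, stack$names[2:9])
  out
}

#' Train the attention head against the known interactions
#'
#' The discretization threshold blocks end-to-end gradients, so the attention
#' parameters are trained beforehand and then frozen: the fused matrix is
#' squashed through `sigmoid(A_path_fusion / s)` and fit to the binary known
#' DTI matrix `A_DT` by binary cross-entropy with Adam, which drives weight
#' onto the meta-paths whose counts track the known interactions.
#'
#' @param stack a [metapath_stack()].
#' @param params starting [attention_params()]; defaults to a fresh
#'   initialization with `seed`.
#' @param epochs full-batch gradient steps (0 returns `params` unchanged).
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization when `params` is NULL.
#' @param squash_scale scale `s` of the sigmoid squashing; default is the
#'   mean nonzero count across the indirect matrices (keeps the squashing in
#'   its responsive range whatever the count scale).
#' @return Trained `attention_params` with attribute `loss_trace`.
#' @export
fit_attention <- function(stack, params = NULL, epochs = 200, lr = 0.01,
                          seed = 1, squash_scale = NULL) {
  if (is.null(params)) params <- attention_params(stack, seed = seed)
  if (epochs == 0) return(params)
  A1 <- stack$matrices[[1]]
  n_entries <- length(A1)
  if (is.null(squash_scale)) {
    v <- unlist(lapply(stack$matrices[2:9], function(A) A[A > 0]))
    squash_scale <- if (length(v)) mean(v) else 1
  }
  opt <- adam_init(params[c("W1", "b1", "W2", "b2", "q")])
  trace <- numeric(epochs)
  Nd <- nrow(A1)
  for (ep in seq_len(epochs)) {
    fw <- attention_forward(stack, params)
    P <- stats::plogis(fw$fused / squash_scale)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    trace[ep] <- -mean(A1 * log(P) + (1 - A1) * log(1 - P))
    if (!is.finite(trace[ep]))
      stop("fit_attention: loss diverged (NaN); try a smaller lr")
    dF <- (P - A1) / (squash_scale * n_entries)
    g <- vapply(fw$mats, function(A) sum(dF * A), 0)
    dw <- fw$a * (g - sum(fw$a * g))
    grads <- list(W1 = 0 * params$W1, b1 = 0 * params$b1,
                  W2 = 0 * params$W2, b2 = 0 * params$b2, q = 0 * params$q)
    for (i in seq_along(fw$mats)) {
      pf <- fw$per[[i]]
      dS <- rep(dw[i] / Nd, Nd)             # d w_i / d s_r = 1/N_d
      dT <- outer(dS, params$q)             # scores s_r = T_r . q
      grads$q <- grads$q + drop(crossprod(pf$Tn, dS))
      dU <- dT * (1 - pf$Tn^2)
      grads$W2 <- grads$W2 + crossprod(pf$Z, dU)
      grads$b2 <- grads$b2 + colSums(dU)
      dZ <- dU %*% t(params$W2)
      grads$W1 <- grads$W1 + crossprod(fw$mats[[i]], dZ)
      grads$b1 <- grads$b1 + colSums(dZ)
    }
    upd <- adam_step(opt, params[c("W1", "b1", "W2", "b2", "q")], grads, lr)
    opt <- upd$state
    params[c("W1", "b1", "W2", "b2", "q")] <- upd$params
  }
  attr(params, "loss_trace") <- trace
  attr(params, "squash_scale") <- squash_scale
  params
}

#' Threshold the fused meta-path matrix and merge with known interactions
#'
#' Discretizes the fused matrix at `tau` (entries `>= tau` become 1) and
#' takes the elementwise maximum with the known binary interaction matrix,
#' so the densified DTI matrix never loses a known interaction.
#'
#' @param A_path_fusion fused meta-path matrix (from [attention_fuse()]).
#' @param tau finite discretization threshold (use `Inf` to disable
#'   densification, leaving `Y_DTI = A1`).
#' @param A1 binary known-interaction matrix (`A_DT`).
#' @return Object of class `fused_dti`: list with `A_path_fusion`, `tau`,
#'   `Y_meta` (thresholded matrix) and `Y_DTI` (merged matrix).
#' @export
threshold_and_merge <- function(A_path_fusion, tau, A1) {
  if (is.na(tau)) stop("threshold_and_merge: tau must not be NA")
  Y_meta <- (A_path_fusion >= tau) * 1
  storage.mode(Y_meta) <- "double"
  Y <- pmax(A1, Y_meta)
  structure(list(A_path_fusion = A_path_fusion, tau = tau,
                 Y_meta = Y_meta, Y_DTI = Y),
            class = "fused_dti")
}

#' @export
print.fused_dti <- function(x, ...) {
  cat(sprintf("Fused DTI network: tau = %g, meta-path positives %d, merged positives %d\n",
              x$tau, sum(x$Y_meta), sum(x$Y_DTI)))
  invisible(x)
}
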