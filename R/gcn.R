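#' Symmetric-normalized propagation matrix with self-loops
#'
#' Adds self-loops to the interaction matrix (`A' = A + I`, so isolated
#' nodes keep positive degree) and returns the symmetric normalization
#' `L = D^{-1/2} A' D^{-1/2}` with `D_i = sum_j A'(i, j)`.
#'
#' @param A_tilde block interaction matrix (a `block_hetero` or plain
#'   symmetric nonnegative matrix).
#' @return Symmetric propagation matrix of the same dimension.
#' @export
normalize_adjacency <- function(A_tilde) {
  A <- block_matrix(A_tilde)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12)))
    stop("normalize_adjacency: matrix must be symmetric")
  Ap <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ap))
  Ap * outer(dinv, dinv)
}

#' Initialize GCN encoder weights
#'
#' Two weight matrices, Glorot-uniform: `W1` maps the `(N_d + N_t)`-wide
#' similarity features to the hidden width `m`, `W2` maps `m` to the latent
#' width `k`. No bias terms. Layer activations are fixed: sigmoid after the
#' first layer, tanh after the second.
#'
#' @param n_nodes `N_d + N_t`.
#' @param m hidden width (default 512).
#' @param k latent width (default 256).
#' @param seed RNG seed.
#' @return Object of class `encoder_params` (list with `W1`, `W2`, `m`, `k`).
#' @export
encoder_params <- function(n_nodes, m = 512, k = 256, seed = 1) {
  set.seed(as.integer(seed))
  structure(list(W1 = glorot(n_nodes, m), W2 = glorot(m, k), m = m, k = k),
            class = "encoder_params")
}

#' Two-layer GCN encoding
#'
#' `H1 = sigmoid(L S W1)`, `Z = tanh(L H1 W2)`, where `L` is the normalized
#' propagation matrix and the fused similarity matrix `S` provides the node
#' features. `Z` rows are node embeddings: the first `split_index` rows are
#' drugs, the rest targets.
#'
#' @param S_tilde block similarity matrix (`block_hetero` or plain matrix).
#' @param L_hat propagation matrix from [normalize_adjacency()].
#' @param params an [encoder_params()] object.
#' @return Object of class `embedding_matrix`: list with `Z`, `H1`,
#'   `split_index` (NA when `S_tilde` is a plain matrix).
#' @export
encode <- function(S_tilde, L_hat, params) {
  split <- if (inherits(S_tilde, "block_hetero")) S_tilde$split_index else NA_integer_
  S <- block_matrix(S_tilde)
  H1 <- stats::plogis(L_hat %*% S %*% params$W1)
  Z <- tanh(L_hat %*% H1 %*% params$W2)
  if (any(!is.finite(Z))) stop("encode: non-finite embeddings")
  structure(list(Z = Z, H1 = H1, split_index = split),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("Node embeddings: %d x %d (split at %s)\n",
              nrow(x$Z), ncol(x$Z), x$split_index))
  invisible(x)
}

#' Drug / target blocks of an embedding matrix
#' @param emb an `embedding_matrix`.
#' @return The drug rows (`embedding_drugs`) or target rows
#'   (`embedding_targets`) of `Z`.
#' @export
embedding_drugs <- function(emb) emb$Z[seq_len(emb$split_index), , drop = FALSE]

#' @rdname embedding_drugs
#' @export
embedding_targets <- function(emb)
  emb$Z[(emb$split_index + 1):nrow(emb$Z), , drop = FALSE]

#' Inner-product decoder
#'
#' `A_hat = sigmoid(Z Z')`; entry (i, j) is the predicted interaction score
#' for nodes i and j. Symmetric by construction, entries in (0, 1).
#'
#' @param Z embedding matrix (or `embedding_matrix` object).
#' @return Reconstructed score matrix.
#' @export
decode <- function(Z) {
  if (inherits(Z, "embedding_matrix")) Z <- Z$Z
  stats::plogis(tcrossprod(Z))
}

#' Squared-error reconstruction loss
#'
#' `sum_ij (A_tilde(i,j) - A_hat(i,j))^2` over all entries, diagonal
#' included.
#'
#' @param A_tilde block interaction matrix (or plain matrix).
#' @param A_hat reconstructed matrix from [decode()].
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(A_tilde, A_hat) {
  A <- block_matrix(A_tilde)
  sum((A - A_hat)^2)
}

# --- internal gradients -----------------------------------------------------

# Forward pass with cached intermediates for backprop.
encoder_forward <- function(X1, L_hat, params) {
  # X1 = L_hat %*% S_tilde, precomputed once per fit
  P1 <- X1 %*% params$W1
  H1 <- stats::plogis(P1)
  B <- L_hat %*% H1
  Z <- tanh(B %*% params$W2)
  list(Z = Z, H1 = H1, B = B)
}

# Gradient of the reconstruction loss w.r.t. Z (and the loss itself).
recon_grad_z <- function(A, Z) {
  Ahat <- stats::plogis(tcrossprod(Z))
  R <- A - Ahat
  G <- -2 * R * Ahat * (1 - Ahat)     # dL/d(Z Z'), symmetric
  list(loss = sum(R^2), dZ = 2 * G %*% Z)
}

# Backprop an embedding gradient dZ to the encoder weights.
encoder_backward <- function(X1, L_hat, params, fw, dZ) {
  dP2 <- dZ * (1 - fw$Z^2)
  dW2 <- crossprod(fw$B, dP2)
  dH1 <- L_hat %*% (dP2 %*% t(params$W2))   # L_hat symmetric
  dP1 <- dH1 * fw$H1 * (1 - fw$H1)
  dW1 <- crossprod(X1, dP1)
  list(W1 = dW1, W2 = dW2)
}
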