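#' Mutual p-nearest-neighbor mask
#'
#' For each node i, `N_p(i)` holds the indices of the `p` largest
#' off-diagonal similarities of row i (ties broken toward the lower index).
#' The mask is 1 for mutual neighbors, 0 when neither direction holds, and
#' 0.5 when only one direction holds.
#'
#' @param S symmetric similarity matrix (or `fused_similarity`).
#' @param p neighbor count, `1 <= p <= n - 1`.
#' @return Object of class `pnn_mask`: list with `N` (matrix with entries in
#'   \{0, 0.5, 1\}) and `p`.
#' @export
pnn_mask <- function(S, p) {
  if (inherits(S, "fused_similarity")) S <- S$S
  n <- nrow(S)
  if (p < 1 || p > n - 1) stop("pnn_mask: p must be in [1, n-1]")
  member <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    top <- cand[order(-S[i, cand], cand)[seq_len(p)]]
    member[i, top] <- TRUE
  }
  N <- (member + t(member)) / 2
  structure(list(N = N, p = p), class = "pnn_mask")
}

#' Sparse similarity network
#'
#' Elementwise product of the neighbor mask and the fused similarity, so
#' only (mutual or one-sided) near-neighbor similarities survive.
#'
#' @param mask a [pnn_mask()].
#' @param S similarity matrix of the same dimension (or `fused_similarity`).
#' @return Matrix `S_hat` with `0 <= S_hat <= S`.
#' @export
sparse_similarity <- function(mask, S) {
  if (inherits(S, "fused_similarity")) S <- S$S
  N <- if (inherits(mask, "pnn_mask")) mask$N else mask
  if (!all(dim(N) == dim(S))) stop("sparse_similarity: dimension mismatch")
  N * S
}

#' STC loss weights
#' @param lambda1,lambda2,lambda3 nonnegative weights of the Frobenius
#'   penalty, the drug pairwise term, and the target pairwise term
#'   (defaults 0.001, 0.001, 0.01).
#' @return Object of class `stc_weights`.
#' @export
stc_weights <- function(lambda1 = 0.001, lambda2 = 0.001, lambda3 = 0.01) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop("stc_weights must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "stc_weights")
}

# Unnormalized graph Laplacian of a symmetric weight matrix.
graph_laplacian <- function(W) diag(rowSums(W), nrow(W)) - W

#' Spatial topological consistency loss
#'
#' \deqn{\lambda_1(\|Z_D\|_F^2 + \|Z_T\|_F^2)
#'   + \lambda_2 \sum_{i,r} \hat S^D(i,r)\,\|Z_{D,i} - Z_{D,r}\|^2
#'   + \lambda_3 \sum_{j,q} \hat S^T(j,q)\,\|Z_{T,j} - Z_{T,q}\|^2}
#' with both ordered pairs summed. Computed through the graph-Laplacian
#' identity `sum_{i,r} W(i,r) ||z_i - z_r||^2 = 2 tr(Z' L_W Z)` for
#' symmetric `W`.
#'
#' @param Z_D,Z_T drug and target embedding blocks.
#' @param S_hat_D,S_hat_T sparse similarity networks from
#'   [sparse_similarity()].
#' @param weights an [stc_weights()] object.
#' @return Nonnegative scalar.
#' @export
stc_loss <- function(Z_D, Z_T, S_hat_D, S_hat_T, weights = stc_weights()) {
  weights$lambda1 * (sum(Z_D^2) + sum(Z_T^2)) +
    2 * weights$lambda2 * sum(Z_D * (graph_laplacian(S_hat_D) %*% Z_D)) +
    2 * weights$lambda3 * sum(Z_T * (graph_laplacian(S_hat_T) %*% Z_T))
}

# stc_loss on precomputed Laplacians (trainer hot path).
stc_loss_lap <- function(Z, split, L_D, L_T, weights) {
  di <- seq_len(split); ti <- (split + 1):nrow(Z)
  ZD <- Z[di, , drop = FALSE]; ZT <- Z[ti, , drop = FALSE]
  weights$lambda1 * sum(Z^2) +
    2 * weights$lambda2 * sum(ZD * (L_D %*% ZD)) +
    2 * weights$lambda3 * sum(ZT * (L_T %*% ZT))
}

# Gradient of stc_loss w.r.t. the full embedding matrix Z.
stc_grad_z <- function(Z, split, L_D, L_T, weights) {
  dZ <- 2 * weights$lambda1 * Z
  di <- seq_len(split); ti <- (split + 1):nrow(Z)
  dZ[di, ] <- dZ[di, ] + 4 * weights$lambda2 * (L_D %*% Z[di, , drop = FALSE])
  dZ[ti, ] <- dZ[ti, ] + 4 * weights$lambda3 * (L_T %*% Z[ti, , drop = FALSE])
  dZ
}
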