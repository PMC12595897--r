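#' Training configuration
#'
#' Collects every tunable of the embedding model in one record. Defaults
#' follow the reference settings (learning rate 0.001, hidden width 512,
#' latent width 256, minibatch 64 for the MI estimators, tau = 17,
#' lambda = (0.001, 0.001, 0.01), (alpha, beta, gamma) =
#' (0.001, 0.001, 0.0001)); `epochs` defaults to the desk-scale 300 (the
#' reference full-scale schedule of 5000 remains available by setting it).
#'
#' @param learning_rate Adam learning rate shared by encoder and
#'   discriminators.
#' @param epochs training epochs.
#' @param batch MI-estimator node minibatch size.
#' @param seed integer seed governing initialization, MI sampling and
#'   shuffles.
#' @param tau meta-path discretization threshold (`Inf` disables
#'   densification).
#' @param p neighbor count of the mutual p-nearest-neighbor masks.
#' @param stc an [stc_weights()] object.
#' @param mi an [mi_weights()] object.
#' @param m,k hidden and latent widths.
#' @param attn_epochs,attn_lr,attn_proj_dim attention-head training schedule
#'   and projection width.
#' @param M,local_c,mi_hidden,mi_proj_dim MI discriminator architecture.
#' @param classifier `"xgb"`, `"rf"` or `"logistic"`.
#' @param feature_mode `"concat"` or `"hadamard"` pair features.
#' @param neg_ratio `"all"` (every unknown pair is a negative) or a numeric
#'   negatives-per-positive subsampling ratio.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 300, batch = 64,
                         seed = 1, tau = 17, p = 5,
                         stc = stc_weights(), mi = mi_weights(),
                         m = 512, k = 256,
                         attn_epochs = 200, attn_lr = 0.01,
                         attn_proj_dim = 128,
                         M = 2, local_c = 64, mi_hidden = 256,
                         mi_proj_dim = 64,
                         classifier = c("xgb", "rf", "logistic"),
                         feature_mode = c("concat", "hadamard"),
                         neg_ratio = "all") {
  stopifnot(epochs >= 0, batch >= 2, m > 0, k > 0, p >= 1)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch = batch, seed = as.integer(seed), tau = tau, p = p,
                 stc = stc, mi = mi, m = m, k = k,
                 attn_epochs = attn_epochs, attn_lr = attn_lr,
                 attn_proj_dim = attn_proj_dim,
                 M = M, local_c = local_c, mi_hidden = mi_hidden,
                 mi_proj_dim = mi_proj_dim,
                 classifier = match.arg(classifier),
                 feature_mode = match.arg(feature_mode),
                 neg_ratio = neg_ratio),
            class = "train_config")
}

#' Total training loss
#'
#' Sum of the reconstruction, spatial-topological-consistency and
#' mutual-information components; lower is better.
#'
#' @param recon,stc,mi finite scalars.
#' @return Their sum.
#' @export
total_loss <- function(recon, stc, mi) {
  stopifnot(is.finite(recon), is.finite(stc), is.finite(mi))
  recon + stc + mi
}

#' Fit the regularized graph-convolutional autoencoder
#'
#' Joint optimization of the two-layer GCN encoder under the combined loss
#' (reconstruction + STC + MI) with Adam, alternating one discriminator
#' ascent step and one encoder descent step per epoch. All randomness
#' (initialization, MI minibatches, prior draws) derives from `cfg$seed`.
#'
#' @param A_tilde block interaction matrix (from [assemble_block()]).
#' @param S_tilde block similarity matrix.
#' @param S_D,S_T fused drug / target similarity matrices (plain matrices or
#'   `fused_similarity` objects); the mutual p-nearest-neighbor masks are
#'   built from these with `cfg$p`.
#' @param cfg a [train_config()].
#' @return Object of class `gcn_fit`: `embedding` (an `embedding_matrix`),
#'   `trace` (per-epoch data.frame with columns `total`, `recon`, `stc`,
#'   `mi_global`, `mi_local`, `mi_prior`), `encoder`, `mi_state`, `cfg`.
#' @export
fit_embeddings <- function(A_tilde, S_tilde, S_D, S_T, cfg = train_config()) {
  A <- block_matrix(A_tilde)
  split <- if (inherits(A_tilde, "block_hetero")) A_tilde$split_index
           else stop("fit_embeddings: A_tilde must be a block_hetero")
  if (inherits(S_D, "fused_similarity")) S_D <- S_D$S
  if (inherits(S_T, "fused_similarity")) S_T <- S_T$S
  n <- nrow(A)
  L_hat <- normalize_adjacency(A_tilde)
  X1 <- L_hat %*% block_matrix(S_tilde)

  enc <- encoder_params(n, cfg$m, cfg$k, seed = substream_seed(cfg$seed, 10L))
  L_D <- graph_laplacian(sparse_similarity(pnn_mask(S_D, cfg$p), S_D))
  L_T <- graph_laplacian(sparse_similarity(pnn_mask(S_T, cfg$p), S_T))
  use_stc <- with(cfg$stc, lambda1 > 0 || lambda2 > 0 || lambda3 > 0)
  use_mi <- with(cfg$mi, alpha > 0 || beta > 0 || gamma > 0)
  mi_state <- if (use_mi)
    mi_state_init(n, cfg$k, cfg$M, cfg$local_c, cfg$mi_hidden,
                  cfg$mi_proj_dim, seed = substream_seed(cfg$seed, 11L))
  else NULL
  opt <- adam_init(enc[c("W1", "W2")])

  cols <- c("total", "recon", "stc", "mi_global", "mi_local", "mi_prior", "mi")
  trace <- matrix(0, cfg$epochs, length(cols), dimnames = list(NULL, cols))
  batch <- min(cfg$batch, n)
  fw <- encoder_forward(X1, L_hat, enc)
  for (ep in seq_len(cfg$epochs)) {
    rg <- recon_grad_z(A, fw$Z)
    dZ <- rg$dZ
    stc_val <- 0
    if (use_stc) {
      stc_val <- stc_loss_lap(fw$Z, split, L_D, L_T, cfg$stc)
      dZ <- dZ + stc_grad_z(fw$Z, split, L_D, L_T, cfg$stc)
    }
    mi_terms <- c(global = 0, local = 0, prior = 0)
    mi_val <- 0
    if (use_mi) {
      mu <- mi_update(A, fw$Z, mi_state, cfg$mi, batch, cfg$learning_rate,
                      seed = substream_seed(cfg$seed, 100L + ep))
      mi_state <- mu$state
      mi_terms <- mu$terms
      mi_val <- mu$scalar
      dZ <- dZ + mu$dZ
    }
    gr <- encoder_backward(X1, L_hat, enc, fw, dZ)
    upd <- adam_step(opt, enc[c("W1", "W2")], gr, cfg$learning_rate)
    opt <- upd$state
    enc[c("W1", "W2")] <- upd$params
    loss <- total_loss(rg$loss, stc_val, mi_val)
    if (is.nan(loss))
      stop(sprintf("fit_embeddings: NaN loss at epoch %d (recon=%g stc=%g mi=%g)",
                   ep, rg$loss, stc_val, mi_val))
    trace[ep, ] <- c(loss, rg$loss, stc_val, mi_terms, mi_val)
    fw <- encoder_forward(X1, L_hat, enc)
  }
  emb <- structure(list(Z = fw$Z, H1 = fw$H1, split_index = split),
                   class = "embedding_matrix")
  structure(list(embedding = emb, trace = as.data.frame(trace),
                 encoder = enc, mi_state = mi_state, cfg = cfg),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  n <- nrow(x$embedding$Z)
  cat(sprintf("GCN autoencoder fit: %d nodes, latent width %d, %d epochs\n",
              n, ncol(x$embedding$Z), nrow(x$trace)))
  if (nrow(x$trace))
    cat(sprintf("  total loss: %.4f (first) -> %.4f (last)\n",
                x$trace$total[1], x$trace$total[nrow(x$trace)]))
  invisible(x)
}

#' Save / load a fit checkpoint
#'
#' Single-file serialized checkpoint (embeddings, encoder weights,
#' discriminators, trace and configuration); reloading reproduces the
#' embeddings bit-identically.
#'
#' @param fit a `gcn_fit`.
#' @param path file path.
#' @export
save_checkpoint <- function(fit, path) { saveRDS(fit, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
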