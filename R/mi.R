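#' Mutual-information loss weights
#' @param alpha,beta,gamma nonnegative weights of the global, local and prior
#'   terms (defaults 0.001, 0.001, 0.0001).
#' @return Object of class `mi_weights`.
#' @export
mi_weights <- function(alpha = 0.001, beta = 0.001, gamma = 0.0001) {
  if (any(c(alpha, beta, gamma) < 0)) stop("mi_weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "mi_weights")
}

#' Neural discriminators for mutual-information estimation
#'
#' Builds one discriminator for a given role:
#' \itemize{
#' \item `global`: scores (input-row, embedding) pairs; the input row is
#'   first passed through a learned linear projection, concatenated with the
#'   embedding, then through a ReLU MLP (2 hidden layers of `hidden` units).
#' \item `local`: scores (local-block feature, embedding) pairs with shared
#'   weights across blocks.
#' \item `prior`: scores embedding rows against standard-Gaussian draws
#'   (2 hidden layers of 64 units).
#' }
#' Output squashing is sigmoid for the JS and prior objectives (range (0,1))
#' and linear for the Donsker-Varadhan objective.
#'
#' @param role `"global"`, `"local"` or `"prior"`.
#' @param input_dim width of the input-side feature (ignored for `prior`).
#' @param latent_dim embedding width `k`.
#' @param hidden hidden-layer width (default 256; 64 for `prior`).
#' @param proj_dim width of the global input-row projection (default 64).
#' @param objective `"js"` (sigmoid output) or `"dv"` (linear output).
#' @param seed RNG seed for initialization.
#' @return Object of class `mi_discriminator`.
#' @export
mi_discriminator <- function(role = c("global", "local", "prior"),
                             input_dim = NULL, latent_dim,
                             hidden = if (role == "prior") 64 else 256,
                             proj_dim = 64,
                             objective = c("js", "dv"), seed = 1) {
  role <- match.arg(role)
  objective <- match.arg(objective)
  out <- if (objective == "dv") "linear" else "sigmoid"
  set.seed(as.integer(seed))
  d <- switch(role,
    global = {
      proj <- list(U = glorot(input_dim, proj_dim), c = numeric(proj_dim))
      list(role = role, proj = proj,
           mlp = mlp_init(c(proj_dim + latent_dim, hidden, hidden, 1), out = out))
    },
    local = list(role = role, proj = NULL,
                 mlp = mlp_init(c(input_dim + latent_dim, hidden, hidden, 1),
                                out = out)),
    prior = list(role = role, proj = NULL,
                 mlp = mlp_init(c(latent_dim, hidden, hidden, 1), out = out))
  )
  d$objective <- objective
  structure(d, class = "mi_discriminator")
}

# Score a batch. x (may be NULL for prior role) and z are matrices with one
# sample per row. Returns scores plus caches for backprop.
disc_score <- function(disc, x, z) {
  input <- switch(disc$role,
    global = {
      P <- sweep(x %*% disc$proj$U, 2, disc$proj$c, "+")
      cbind(P, z)
    },
    local = cbind(x, z),
    prior = z)
  fwd <- mlp_forward(disc$mlp, input)
  list(T = fwd$out, cache = fwd, input = input)
}

#' Sample joint and marginal (input, embedding) pair batches
#'
#' Joint pairs match each sampled node's input row with its own embedding;
#' marginal pairs keep the same input rows but permute the embeddings with a
#' derangement (no fixed points), realizing the product of marginals with
#' identical input multisets.
#'
#' @param A_tilde block interaction matrix (rows are the flattened per-node
#'   inputs) or plain matrix.
#' @param Z embedding matrix (or `embedding_matrix`).
#' @param batch number of nodes to sample (`<=` number of nodes, `>= 2`).
#' @param seed RNG seed.
#' @return List with `idx`, `perm` (indices into `idx`), `joint` and
#'   `marginal` (each a list with `x` and `z` matrices).
#' @export
sample_pairs <- function(A_tilde, Z, batch, seed = 1) {
  A <- block_matrix(A_tilde)
  if (inherits(Z, "embedding_matrix")) Z <- Z$Z
  n <- nrow(A)
  if (batch > n) stop("sample_pairs: batch exceeds the number of nodes")
  if (batch < 2) stop("sample_pairs: batch must be at least 2")
  set.seed(as.integer(seed))
  idx <- sample.int(n, batch)
  perm <- derangement(batch)
  list(idx = idx, perm = perm,
       joint = list(x = A[idx, , drop = FALSE], z = Z[idx, , drop = FALSE]),
       marginal = list(x = A[idx, , drop = FALSE],
                       z = Z[idx[perm], , drop = FALSE]))
}

derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Donsker-Varadhan lower-bound estimate of mutual information
#'
#' `mean_joint[T] - log mean_marginal[exp(T)]`, with the log-mean-exp
#' computed by max-shift so large scores never overflow. `T` must be a
#' linear-output (`objective = "dv"`) discriminator.
#'
#' @param joint,marginal pair batches (lists with `x`, `z`), e.g. from
#'   [sample_pairs()].
#' @param disc an [mi_discriminator()].
#' @return Scalar lower-bound estimate (nats).
#' @export
dv_estimate <- function(joint, marginal, disc) {
  if (disc$objective != "dv")
    stop("dv_estimate: discriminator must have a linear ('dv') output")
  tj <- disc_score(disc, joint$x, joint$z)$T
  tm <- disc_score(disc, marginal$x, marginal$z)$T
  v <- mean(tj) - log_mean_exp(tm)
  if (!is.finite(v)) stop("dv_estimate: non-finite estimate")
  v
}

#' Jensen-Shannon-form mutual-information estimate
#'
#' `mean_joint[log T] + mean_marginal[log(1 - T)]` for a sigmoid-output
#' discriminator; always `<= 0`, equal to `2 log 0.5` for an uninformative
#' discriminator, and approaching 0 from below as joint and marginal become
#' separable.
#'
#' @inheritParams dv_estimate
#' @return Scalar estimate (nonpositive).
#' @export
js_estimate <- function(joint, marginal, disc) {
  if (disc$objective != "js")
    stop("js_estimate: discriminator must have a sigmoid ('js') output")
  tj <- disc_score(disc, joint$x, joint$z)$T
  tm <- disc_score(disc, marginal$x, marginal$z)$T
  if (any(tj < 0 | tj > 1 | tm < 0 | tm > 1))
    stop("js_estimate: discriminator output outside (0,1)")
  mean(log(clamp01(tj))) + mean(log(1 - clamp01(tm)))
}

#' Local-structure encoder
#'
#' Realizes the `M x M` local-region feature map for a row-vector input: a
#' learned linear projection of the node's input row to `M^2 * c` features,
#' reshaped into `M^2` blocks of width `c`, each block playing the role of
#' one local region.
#'
#' @param input_dim width of the node input rows.
#' @param M region grid size (the map yields `M^2` blocks).
#' @param c_dim block feature width.
#' @param seed RNG seed.
#' @return Object of class `local_encoder`.
#' @export
local_encoder <- function(input_dim, M = 2, c_dim = 64, seed = 1) {
  if (M < 1) stop("local_encoder: M must be >= 1")
  if (input_dim < M^2)
    stop("local_encoder: input rows shorter than M^2; use a smaller M")
  set.seed(as.integer(seed))
  structure(list(W = glorot(input_dim, M^2 * c_dim), b = numeric(M^2 * c_dim),
                 M = M, c_dim = c_dim),
            class = "local_encoder")
}

# All M^2 block features for a batch: list of (n x c_dim) matrices.
local_blocks <- function(C, x) {
  V <- sweep(x %*% C$W, 2, C$b, "+")
  lapply(seq_len(C$M^2), function(r)
    V[, ((r - 1) * C$c_dim + 1):(r * C$c_dim), drop = FALSE])
}

#' Average local mutual-information estimate
#'
#' Encodes each sampled node's input row into `M^2` local blocks and
#' averages the JS-form estimate of the (block, embedding) dependence over
#' the blocks (maximized during training).
#'
#' @param A_tilde,Z,batch,seed as in [sample_pairs()].
#' @param C_psi a [local_encoder()].
#' @param T_local a `local`-role [mi_discriminator()] (JS objective).
#' @return Scalar average estimate with attribute `per_block`.
#' @export
local_mi_loss <- function(A_tilde, Z, C_psi, T_local, batch, seed = 1) {
  sp <- sample_pairs(A_tilde, Z, batch, seed)
  bj <- local_blocks(C_psi, sp$joint$x)
  per <- vapply(seq_along(bj), function(r)
    js_estimate(list(x = bj[[r]], z = sp$joint$z),
                list(x = bj[[r]], z = sp$marginal$z), T_local), 0)
  out <- mean(per)
  attr(out, "per_block") <- per
  out
}

#' Prior-matching adversarial estimate
#'
#' `mean_{z ~ N(0, I)}[log D(z)] + mean_{rows of Z}[log(1 - D(z))]`; the
#' discriminator ascends this (separating embeddings from Gaussian draws)
#' while the encoder descends its second term, pushing the embedding
#' distribution toward the Gaussian prior.
#'
#' @param Z embedding matrix (or `embedding_matrix`).
#' @param D_phi a `prior`-role [mi_discriminator()] (JS objective).
#' @param batch rows sampled from `Z` and draws from the prior.
#' @param seed RNG seed.
#' @return Scalar estimate.
#' @export
prior_loss <- function(Z, D_phi, batch, seed = 1) {
  if (inherits(Z, "embedding_matrix")) Z <- Z$Z
  if (D_phi$objective != "js")
    stop("prior_loss: discriminator must have a sigmoid output")
  if (batch > nrow(Z)) stop("prior_loss: batch exceeds the number of rows")
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(Z), batch)
  zp <- matrix(stats::rnorm(batch * ncol(Z)), batch)
  tp <- disc_score(D_phi, NULL, zp)$T
  tz <- disc_score(D_phi, NULL, Z[idx, , drop = FALSE])$T
  if (any(c(tp, tz) < 0 | c(tp, tz) > 1))
    stop("prior_loss: discriminator output outside (0,1)")
  mean(log(clamp01(tp))) + mean(log(1 - clamp01(tz)))
}

#' Bundle of the three MI discriminators and the local encoder
#'
#' @param n_input width of the flattened per-node input rows
#'   (`N_d + N_t` for the block interaction matrix).
#' @param latent_dim embedding width `k`.
#' @param M local-region grid size.
#' @param c_dim local block width.
#' @param hidden hidden width of the global/local discriminators.
#' @param proj_dim global input-row projection width.
#' @param seed RNG seed.
#' @return List with `global`, `local`, `prior` discriminators and `C_psi`.
#' @export
mi_discriminators <- function(n_input, latent_dim, M = 2, c_dim = 64,
                              hidden = 256, proj_dim = 64, seed = 1) {
  list(global = mi_discriminator("global", n_input, latent_dim, hidden,
                                 proj_dim, "js", seed = seed),
       local = mi_discriminator("local", c_dim, latent_dim, hidden,
                                objective = "js", seed = seed + 1L),
       prior = mi_discriminator("prior", NULL, latent_dim,
                                objective = "js", seed = seed + 2L),
       C_psi = local_encoder(n_input, M, c_dim, seed = seed + 3L))
}

#' Combined mutual-information loss (encoder side)
#'
#' `alpha * t_global + beta * t_local + gamma * t_prior`, with sign
#' conventions such that the encoder minimizes the returned scalar while
#' each discriminator maximizes its own objective: `t_global = -JS_global`,
#' `t_local = -JS_local`, `t_prior = mean log(1 - D(z_rows))`. A term whose
#' weight is zero contributes exactly 0 and is not evaluated.
#'
#' @param A_tilde,Z,batch,seed as in [sample_pairs()].
#' @param discs a [mi_discriminators()] bundle.
#' @param weights an [mi_weights()] object.
#' @return Scalar with attribute `terms` (named per-term values, unweighted).
#' @export
mi_loss <- function(A_tilde, Z, discs, weights = mi_weights(), batch = 64,
                    seed = 1) {
  terms <- c(global = 0, local = 0, prior = 0)
  if (weights$alpha > 0) {
    sp <- sample_pairs(A_tilde, Z, batch, seed)
    terms["global"] <- -js_estimate(sp$joint, sp$marginal, discs$global)
  }
  if (weights$beta > 0)
    terms["local"] <- -as.numeric(
      local_mi_loss(A_tilde, Z, discs$C_psi, discs$local, batch, seed))
  if (weights$gamma > 0) {
    Zm <- if (inherits(Z, "embedding_matrix")) Z$Z else Z
    set.seed(as.integer(seed) + 1L)
    idx <- sample.int(nrow(Zm), min(batch, nrow(Zm)))
    tz <- disc_score(discs$prior, NULL, Zm[idx, , drop = FALSE])$T
    terms["prior"] <- mean(log(1 - clamp01(tz)))
  }
  if (any(is.nan(terms)))
    stop("mi_loss: NaN in term(s): ",
         paste(names(terms)[is.nan(terms)], collapse = ", "))
  out <- weights$alpha * terms["global"] + weights$beta * terms["local"] +
    weights$gamma * terms["prior"]
  out <- unname(out)
  attr(out, "terms") <- terms
  out
}

#' Train a standalone MI estimator on empirical pairs
#'
#' Fits a global-style discriminator to maximize the chosen bound on fixed
#' empirical (x, z) samples, reporting the full-sample estimate per epoch.
#' Useful as a diagnostic estimator and for validating the estimators on
#' toys with known mutual information.
#'
#' @param x,z matrices with one paired sample per row.
#' @param objective `"dv"` (Donsker-Varadhan, linear output) or `"js"`.
#' @param epochs discriminator updates.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param hidden,proj_dim discriminator architecture.
#' @param seed RNG seed.
#' @return List with `disc`, `trace` (per-epoch full-sample estimates) and
#'   `estimate` (final value).
#' @export
mi_train_estimator <- function(x, z, objective = c("dv", "js"), epochs = 200,
                               batch = 128, lr = 0.001, hidden = 64,
                               proj_dim = 8, seed = 1) {
  objective <- match.arg(objective)
  x <- as.matrix(x); z <- as.matrix(z)
  n <- nrow(x)
  batch <- min(batch, n)
  disc <- mi_discriminator("global", ncol(x), ncol(z), hidden, proj_dim,
                           objective, seed = seed)
  opt <- adam_init(disc_params(disc))
  all_joint <- list(x = x, z = z)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    sp <- sample_pairs(x, z, batch, seed = substream_seed(seed, ep))
    gr <- global_term_grads(disc, sp, objective)
    upd <- adam_step(opt, disc_params(disc), neg_grads(gr$grads), lr)
    opt <- upd$state
    disc <- disc_set_params(disc, upd$params)
    # full-sample estimate; the marginal expectation is averaged over many
    # derangements to keep its Monte-Carlo variance well below the bound's bias
    set.seed(substream_seed(seed, epochs + ep))
    zm <- do.call(rbind, lapply(1:20, function(k) z[derangement(n), , drop = FALSE]))
    full_marg <- list(x = x[rep(seq_len(n), 20), , drop = FALSE], z = zm)
    trace[ep] <- if (objective == "dv") dv_estimate(all_joint, full_marg, disc)
                 else js_estimate(all_joint, full_marg, disc)
  }
  list(disc = disc, trace = trace, estimate = trace[epochs])
}

# --- internal: parameter plumbing and gradient steps ------------------------

disc_params <- function(disc) {
  p <- list(mlp = list(W = disc$mlp$W, b = disc$mlp$b))
  if (!is.null(disc$proj)) p$proj <- disc$proj
  p
}

disc_set_params <- function(disc, p) {
  disc$mlp$W <- p$mlp$W; disc$mlp$b <- p$mlp$b
  if (!is.null(disc$proj)) disc$proj <- p$proj
  disc
}

neg_grads <- function(g) rapply(g, function(x) -x, how = "replace")

# Gradients of the chosen bound w.r.t. the discriminator parameters for one
# sampled batch, plus gradients w.r.t. the joint/marginal z rows.
global_term_grads <- function(disc, sp, objective = c("js", "dv")) {
  objective <- match.arg(objective)
  B <- nrow(sp$joint$x)
  scj <- disc_score(disc, sp$joint$x, sp$joint$z)
  scm <- disc_score(disc, sp$marginal$x, sp$marginal$z)
  if (objective == "js") {
    tj <- clamp01(scj$T); tm <- clamp01(scm$T)
    dpre_j <- (1 - tj) / B
    dpre_m <- -tm / B
  } else {
    dpre_j <- rep(1 / B, B)
    w <- exp(scm$T - max(scm$T))
    dpre_m <- -w / sum(w)
  }
  bj <- mlp_backward(disc$mlp, scj$cache, dpre_j)
  bm <- mlp_backward(disc$mlp, scm$cache, dpre_m)
  grads <- list(mlp = list(W = Map(`+`, bj$W, bm$W),
                           b = Map(`+`, bj$b, bm$b)))
  pd <- ncol(disc$proj$U)
  dPj <- bj$dX[, seq_len(pd), drop = FALSE]
  dPm <- bm$dX[, seq_len(pd), drop = FALSE]
  grads$proj <- list(
    U = crossprod(sp$joint$x, dPj) + crossprod(sp$marginal$x, dPm),
    c = colSums(dPj) + colSums(dPm))
  kz <- ncol(sp$joint$z)
  list(grads = grads,
       dZ_joint = bj$dX[, (pd + 1):(pd + kz), drop = FALSE],
       dZ_marginal = bm$dX[, (pd + 1):(pd + kz), drop = FALSE],
       value = if (objective == "js")
         mean(log(clamp01(scj$T))) + mean(log(1 - clamp01(scm$T)))
       else mean(scj$T) - log_mean_exp(scm$T))
}

local_term_grads <- function(disc, C_psi, sp) {
  B <- nrow(sp$joint$x)
  M2 <- C_psi$M^2
  blocks <- local_blocks(C_psi, sp$joint$x)
  kz <- ncol(sp$joint$z)
  dV <- matrix(0, B, M2 * C_psi$c_dim)
  acc <- NULL
  dZ_joint <- matrix(0, B, kz); dZ_marginal <- matrix(0, B, kz)
  value <- 0
  for (r in seq_len(M2)) {
    scj <- disc_score(disc, blocks[[r]], sp$joint$z)
    scm <- disc_score(disc, blocks[[r]], sp$marginal$z)
    tj <- clamp01(scj$T); tm <- clamp01(scm$T)
    value <- value + (mean(log(tj)) + mean(log(1 - tm))) / M2
    bj <- mlp_backward(disc$mlp, scj$cache, (1 - tj) / (B * M2))
    bm <- mlp_backward(disc$mlp, scm$cache, -tm / (B * M2))
    g <- list(W = Map(`+`, bj$W, bm$W), b = Map(`+`, bj$b, bm$b))
    acc <- if (is.null(acc)) g else list(W = Map(`+`, acc$W, g$W),
                                         b = Map(`+`, acc$b, g$b))
    cols <- ((r - 1) * C_psi$c_dim + 1):(r * C_psi$c_dim)
    dV[, cols] <- bj$dX[, seq_len(C_psi$c_dim), drop = FALSE] +
      bm$dX[, seq_len(C_psi$c_dim), drop = FALSE]
    dZ_joint <- dZ_joint + bj$dX[, (C_psi$c_dim + 1):(C_psi$c_dim + kz), drop = FALSE]
    dZ_marginal <- dZ_marginal + bm$dX[, (C_psi$c_dim + 1):(C_psi$c_dim + kz), drop = FALSE]
  }
  list(grads = list(mlp = acc),
       C_grads = list(W = crossprod(sp$joint$x, dV), b = colSums(dV)),
       dZ_joint = dZ_joint, dZ_marginal = dZ_marginal, value = value)
}

prior_term_grads <- function(disc, Z, batch, seed) {
  n <- nrow(Z)
  set.seed(as.integer(seed))
  idx <- sample.int(n, min(batch, n))
  B <- length(idx)
  zp <- matrix(stats::rnorm(B * ncol(Z)), B)
  scp <- disc_score(disc, NULL, zp)
  scz <- disc_score(disc, NULL, Z[idx, , drop = FALSE])
  tp <- clamp01(scp$T); tz <- clamp01(scz$T)
  bp <- mlp_backward(disc$mlp, scp$cache, (1 - tp) / B)
  bz <- mlp_backward(disc$mlp, scz$cache, -tz / B)
  list(grads = list(mlp = list(W = Map(`+`, bp$W, bz$W),
                               b = Map(`+`, bp$b, bz$b))),
       idx = idx,
       dZ_rows = bz$dX,                  # grad of mean log(1 - D(z)) w.r.t. z
       enc_value = mean(log(1 - tz)),
       value = mean(log(tp)) + mean(log(1 - tz)))
}

# One alternating MI update: ascend each active discriminator's objective,
# then return the encoder-side per-term values and the gradient of the
# weighted encoder MI loss w.r.t. the full embedding matrix (computed with
# the updated discriminators).
mi_update <- function(A, Z, state, weights, batch, lr, seed) {
  n <- nrow(Z)
  dZ <- matrix(0, n, ncol(Z))
  terms <- c(global = 0, local = 0, prior = 0)
  sp <- if (weights$alpha > 0 || weights$beta > 0)
    sample_pairs(A, Z, min(batch, n), seed) else NULL

  if (weights$alpha > 0) {
    g <- global_term_grads(state$discs$global, sp, "js")
    upd <- adam_step(state$opt$global, disc_params(state$discs$global),
                     neg_grads(g$grads), lr)
    state$opt$global <- upd$state
    state$discs$global <- disc_set_params(state$discs$global, upd$params)
    g2 <- global_term_grads(state$discs$global, sp, "js")
    terms["global"] <- -g2$value
    add_rows <- function(M, rows, G) { M[rows, ] <- M[rows, ] + G; M }
    dZ <- add_rows(dZ, sp$idx, -weights$alpha * g2$dZ_joint)
    dZ <- add_rows(dZ, sp$idx[sp$perm], -weights$alpha * g2$dZ_marginal)
  }
  if (weights$beta > 0) {
    l <- local_term_grads(state$discs$local, state$discs$C_psi, sp)
    cp <- list(mlp = l$grads$mlp, C = l$C_grads)
    upd <- adam_step(state$opt$local,
                     list(mlp = list(W = state$discs$local$mlp$W,
                                     b = state$discs$local$mlp$b),
                          C = list(W = state$discs$C_psi$W,
                                   b = state$discs$C_psi$b)),
                     neg_grads(cp), lr)
    state$opt$local <- upd$state
    state$discs$local$mlp$W <- upd$params$mlp$W
    state$discs$local$mlp$b <- upd$params$mlp$b
    state$discs$C_psi$W <- upd$params$C$W
    state$discs$C_psi$b <- upd$params$C$b
    l2 <- local_term_grads(state$discs$local, state$discs$C_psi, sp)
    terms["local"] <- -l2$value
    dZ[sp$idx, ] <- dZ[sp$idx, ] - weights$beta * l2$dZ_joint
    dZ[sp$idx[sp$perm], ] <- dZ[sp$idx[sp$perm], ] - weights$beta * l2$dZ_marginal
  }
  if (weights$gamma > 0) {
    p <- prior_term_grads(state$discs$prior, Z, batch, seed + 1L)
    upd <- adam_step(state$opt$prior, disc_params(state$discs$prior),
                     neg_grads(p$grads), lr)
    state$opt$prior <- upd$state
    state$discs$prior <- disc_set_params(state$discs$prior, upd$params)
    p2 <- prior_term_grads(state$discs$prior, Z, batch, seed + 1L)
    terms["prior"] <- p2$enc_value
    dZ[p2$idx, ] <- dZ[p2$idx, ] + weights$gamma * p2$dZ_rows
  }
  if (any(is.nan(terms)))
    stop("mi_update: NaN in term(s): ",
         paste(names(terms)[is.nan(terms)], collapse = ", "))
  list(state = state, terms = terms, dZ = dZ,
       scalar = weights$alpha * terms[["global"]] +
         weights$beta * terms[["local"]] + weights$gamma * terms[["prior"]])
}

mi_state_init <- function(n_input, latent_dim, M = 2, c_dim = 64,
                          hidden = 256, proj_dim = 64, seed = 1) {
  discs <- mi_discriminators(n_input, latent_dim, M, c_dim, hidden, proj_dim,
                             seed = seed)
  list(discs = discs,
       opt = list(
         global = adam_init(disc_params(discs$global)),
         local = adam_init(list(mlp = list(W = discs$local$mlp$W,
                                           b = discs$local$mlp$b),
                                C = list(W = discs$C_psi$W, b = discs$C_psi$b))),
         prior = adam_init(disc_params(discs$prior))))
}
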