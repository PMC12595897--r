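# Independent oracles and small fixture builders shared across test files.
# Every oracle here is a deliberately naive reimplementation (explicit loops,
# exhaustive enumeration) kept independent of the package's vectorized code.

# ---- tiny random networks --------------------------------------------------

random_tiny_network <- function(seed, n_per_class = 8, p = 0.25) {
  set.seed(seed)
  rb <- function(nr, nc) matrix(rbinom(nr * nc, 1, p), nr, nc)
  sym <- function(A) { A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0; A }
  n <- n_per_class
  hetero_network(
    paste0("d", 1:n), paste0("t", 1:n), paste0("i", 1:n), paste0("s", 1:n),
    A_DD = sym(rb(n, n)), A_DT = rb(n, n), A_DI = rb(n, n),
    A_DS = rb(n, n), A_TT = sym(rb(n, n)), A_TI = rb(n, n)
  )
}

# ---- exhaustive typed-path enumerator --------------------------------------

# Adjacency lookup between two node classes, honoring direction of the blocks.
class_adjacency <- function(net, a, b) {
  key <- paste(a, b)
  switch(key,
    "D D" = net$A_DD, "T T" = net$A_TT,
    "D T" = net$A_DT, "T D" = t(net$A_DT),
    "D I" = net$A_DI, "I D" = t(net$A_DI),
    "D S" = net$A_DS, "S D" = t(net$A_DS),
    "T I" = net$A_TI, "I T" = t(net$A_TI),
    stop("no adjacency for class pair ", key))
}

# Count instances of a typed path template (e.g. c("D","I","D","T")) from
# drug d to target t by depth-first enumeration of intermediate nodes.
count_typed_paths <- function(net, template, d, t) {
  L <- length(template)
  recurse <- function(pos, node) {
    if (pos == L) return(as.integer(node == t))
    A <- class_adjacency(net, template[pos], template[pos + 1])
    nxt <- which(A[node, ] == 1)
    if (!length(nxt)) return(0L)
    sum(vapply(nxt, function(v) recurse(pos + 1, v), 0L))
  }
  recurse(1, d)
}

metapath_templates <- list(
  DT = c("D", "T"), DDT = c("D", "D", "T"), DIT = c("D", "I", "T"),
  DTT = c("D", "T", "T"), DIDT = c("D", "I", "D", "T"),
  DITT = c("D", "I", "T", "T"), DSDT = c("D", "S", "D", "T"),
  DDIT = c("D", "D", "I", "T"), DTDT = c("D", "T", "D", "T"))

brute_force_stack <- function(net) {
  Nd <- length(net$drug_ids); Nt <- length(net$target_ids)
  lapply(metapath_templates, function(tpl) {
    M <- matrix(0, Nd, Nt)
    for (d in seq_len(Nd)) for (t in seq_len(Nt))
      M[d, t] <- count_typed_paths(net, tpl, d, t)
    M
  })
}

# ---- loop-based similarity oracles -----------------------------------------

jaccard_loops <- function(A) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Ni <- which(A[i, ] == 1); Nj <- which(A[j, ] == 1)
    u <- length(union(Ni, Nj))
    S[i, j] <- if (u == 0) 0 else length(intersect(Ni, Nj)) / u
  }
  diag(S) <- 1
  S
}

tanimoto_loops <- function(fp) {
  n <- nrow(fp)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dot <- sum(fp[i, ] * fp[j, ])
    den <- sum(fp[i, ]^2) + sum(fp[j, ]^2) - dot
    S[i, j] <- if (den == 0) 0 else dot / den
  }
  diag(S) <- 1
  S
}

entropy_weights_loops <- function(views) {
  Em <- sapply(views, function(S) {
    es <- numeric(0)
    for (i in seq_len(nrow(S))) {
      tot <- sum(S[i, ])
      if (tot == 0) next
      e <- 0
      for (j in seq_len(ncol(S))) {
        p <- S[i, j] / tot
        if (p > 0) e <- e - p * log(p)
      }
      es <- c(es, e)
    }
    mean(es)
  })
  inv <- 1 / Em
  list(weights = inv / sum(inv), mean_entropies = Em)
}

minmax_loops <- function(raw) {
  n <- nrow(raw)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    off <- setdiff(seq_len(n), i)
    lo <- min(raw[i, off]); hi <- max(raw[i, off])
    for (j in off) S[i, j] <- if (hi > lo) (raw[i, j] - lo) / (hi - lo) else 0
  }
  S
}

# ---- brute-force mutual top-p mask -----------------------------------------

pnn_mask_loops <- function(S, p) {
  n <- nrow(S)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(-S[i, cand], cand)]
    neigh[[i]] <- ord[seq_len(p)]
  }
  N <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- j %in% neigh[[i]]; b <- i %in% neigh[[j]]
    N[i, j] <- if (a && b) 1 else if (!a && !b) 0 else 0.5
  }
  N
}

# ---- STC double-loop oracle ------------------------------------------------

stc_loss_loops <- function(Z_D, Z_T, S_hat_D, S_hat_T, w) {
  pair_term <- function(S, Z) {
    tot <- 0
    for (i in seq_len(nrow(S))) for (r in seq_len(ncol(S)))
      tot <- tot + S[i, r] * sum((Z[i, ] - Z[r, ])^2)
    tot
  }
  w$lambda1 * (sum(Z_D^2) + sum(Z_T^2)) +
    w$lambda2 * pair_term(S_hat_D, Z_D) +
    w$lambda3 * pair_term(S_hat_T, Z_T)
}

# ---- misc ------------------------------------------------------------------

random_symmetric_similarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}
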