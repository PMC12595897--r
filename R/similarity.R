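#' Tanimoto chemical similarity from binary fingerprints
#'
#' `T(i,j) = f_i.f_j / (||f_i||^2 + ||f_j||^2 - f_i.f_j)` over binary
#' fingerprint rows. Symmetric, entries in \[0, 1\], unit diagonal. A drug
#' with an all-zero fingerprint gets off-diagonal similarity 0 (with a
#' warning) and diagonal 1.
#'
#' @param fingerprints binary `N_d x B` matrix.
#' @return `N_d x N_d` similarity matrix.
#' @export
tanimoto_matrix <- function(fingerprints) {
  fp <- as.matrix(fingerprints)
  if (length(fp) && !all(fp %in% c(0, 1)))
    stop("tanimoto_matrix: fingerprints must be binary")
  inter <- tcrossprod(fp)
  n <- diag(inter)
  denom <- outer(n, n, "+") - inter
  S <- ifelse(denom > 0, inter / denom, 0)
  if (any(n == 0)) warning("tanimoto_matrix: all-zero fingerprint row(s); ",
                           "their off-diagonal similarities are set to 0")
  diag(S) <- 1
  dimnames(S) <- list(rownames(fp), rownames(fp))
  S
}

#' Smith-Waterman target sequence similarity
#'
#' Raw pairwise local-alignment scores (BLOSUM62, affine gaps, defaults gap
#' open 10 / extend 1) are normalized rowwise by min-max over each row's
#' off-diagonal scores, clipped to \[0, 1\], symmetrized by averaging with
#' the transpose (rowwise normalization is not symmetric on its own), and
#' the diagonal is forced to 1. A degenerate row whose off-diagonal scores
#' are all equal normalizes to 0 off-diagonal.
#'
#' @param sequences named character vector of amino-acid sequences
#'   (standard 20-letter alphabet).
#' @param gap_open,gap_extend affine gap penalties.
#' @param substitution_matrix name of the substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @return `N_t x N_t` similarity matrix.
#' @export
sw_similarity <- function(sequences, gap_open = 10, gap_extend = 1,
                          substitution_matrix = "BLOSUM62") {
  if (!length(sequences)) stop("sw_similarity: no sequences")
  bad <- grepl(sprintf("[^%s]", paste(amino_acids, collapse = "")), sequences)
  if (any(bad))
    stop("sw_similarity: invalid residue characters in sequence ",
         if (!is.null(names(sequences))) names(sequences)[bad][1] else which(bad)[1])
  subst <- get(data(list = substitution_matrix,
                    package = "Biostrings",
                    envir = environment()))
  n <- length(sequences)
  aa <- Biostrings::AAStringSet(sequences)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      aa[i:n], aa[[i]], type = "local", substitutionMatrix = subst,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    raw[i, i:n] <- sc
    raw[i:n, i] <- sc
  }
  S <- minmax_normalize_rows(raw)
  S <- (S + t(S)) / 2
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(names(sequences), names(sequences))
  S
}

# Rowwise min-max over off-diagonal entries; degenerate rows (max == min)
# map to 0 off-diagonal.
minmax_normalize_rows <- function(raw) {
  n <- nrow(raw)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    off <- raw[i, -i]
    lo <- min(off); hi <- max(off)
    if (hi > lo) S[i, -i] <- (off - lo) / (hi - lo)
  }
  S
}

#' Jaccard similarity over shared neighborhoods
#'
#' `Sim(i,j) = |N(i) n N(j)| / |N(i) u N(j)|`, where the rows of `adj` index
#' the entities being compared and the columns their neighbor space (the
#' same entities for a unipartite relation, another node class for a
#' bipartite one). Diagonal is set to 1; a pair with both neighbor sets
#' empty gets similarity 0 (warned once).
#'
#' @param adj binary matrix.
#' @return square symmetric similarity matrix over the rows of `adj`.
#' @export
jaccard_matrix <- function(adj) {
  A <- as.matrix(adj)
  if (length(A) && !all(A %in% c(0, 1)))
    stop("jaccard_matrix: adjacency must be binary")
  inter <- tcrossprod(A)
  deg <- rowSums(A)
  uni <- outer(deg, deg, "+") - inter
  if (any(uni == 0))
    warning("jaccard_matrix: pair(s) with both neighbor sets empty; similarity set to 0")
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- 1
  dimnames(S) <- list(rownames(A), rownames(A))
  S
}

#' Information-entropy fusion weights over similarity views
#'
#' For each view, every row is normalized to a probability vector and its
#' Shannon entropy (natural log, `0 log 0 := 0`) computed; the view's mean
#' row entropy summarizes how unstructured it is. Weights are proportional
#' to inverse mean entropy, so less-random views dominate the fusion:
#' `w_m = (1/E_m) / sum_n (1/E_n)`.
#'
#' All-zero rows get entropy 0 and are excluded from the view mean (warned);
#' a view whose mean entropy is 0 is a hard error (its weight is undefined).
#'
#' @param views named list of >= 2 square similarity matrices of identical
#'   dimension.
#' @return List with `weights` (named, nonnegative, summing to 1) and
#'   `mean_entropies` (named).
#' @export
entropy_weights <- function(views) {
  if (length(views) < 2) stop("entropy_weights: need at least two views")
  d <- dim(views[[1]])
  if (!all(vapply(views, function(S) all(dim(S) == d), TRUE)))
    stop("entropy_weights: views must share dimensions")
  mean_e <- vapply(views, function(S) {
    e <- apply(S, 1, row_entropy)
    zero_rows <- rowSums(S) == 0
    if (any(zero_rows)) {
      warning("entropy_weights: all-zero row(s) excluded from a view's mean entropy")
      e <- e[!zero_rows]
    }
    if (!length(e)) 0 else mean(e)
  }, 0)
  if (any(mean_e == 0))
    stop("entropy_weights: a view has zero mean entropy; its weight is undefined")
  inv <- 1 / mean_e
  w <- inv / sum(inv)
  list(weights = w, mean_entropies = mean_e)
}

row_entropy <- function(s) {
  tot <- sum(s)
  if (tot == 0) return(0)
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Fuse similarity views with given weights
#'
#' Weighted sum of the views; weights must sum to 1 (within 1e-9), so the
#' fused matrix inherits symmetry, the \[0, 1\] range and the unit diagonal
#' from its inputs.
#'
#' @param views named list of square similarity matrices.
#' @param weights numeric weights in view order (or named like `views`).
#' @return Object of class `fused_similarity`: list with `S`, `weights`,
#'   `mean_entropies` (NA unless produced by [fused_similarity()]).
#' @export
fuse_views <- function(views, weights) {
  if (!is.null(names(weights)) && !is.null(names(views)))
    weights <- weights[names(views)]
  if (length(weights) != length(views))
    stop("fuse_views: one weight per view required")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("fuse_views: weights must sum to 1")
  S <- Reduce(`+`, Map(function(V, w) V * w, views, as.numeric(weights)))
  structure(list(S = S, weights = weights, mean_entropies = NA),
            class = "fused_similarity")
}

#' Entropy-weighted fusion of similarity views
#'
#' Convenience composition of [entropy_weights()] and [fuse_views()].
#'
#' @param views named list of square similarity matrices.
#' @return A `fused_similarity` object carrying the entropy-derived weights.
#' @export
fused_similarity <- function(views) {
  ew <- entropy_weights(views)
  out <- fuse_views(views, ew$weights)
  out$mean_entropies <- ew$mean_entropies
  out
}

#' @export
print.fused_similarity <- function(x, ...) {
  cat(sprintf("Fused similarity network: %d x %d\n", nrow(x$S), ncol(x$S)))
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = " "), "\n")
  invisible(x)
}

#' Drug-view similarity matrices
#'
#' The four drug views: `chemical` (Tanimoto over fingerprints),
#' `interaction` (Jaccard over drug-drug neighbors), `disease` (Jaccard over
#' drug-disease neighbors) and `sider` (Jaccard over drug-side-effect
#' neighbors). `chemical` is omitted when `fingerprints` is NULL.
#'
#' @param net a [hetero_network()].
#' @param fingerprints optional binary fingerprint matrix (rows = drugs).
#' @return Named list of similarity matrices.
#' @export
drug_similarity_views <- function(net, fingerprints = NULL) {
  v <- list(interaction = jaccard_matrix(net$A_DD),
            disease = jaccard_matrix(net$A_DI),
            sider = jaccard_matrix(net$A_DS))
  if (!is.null(fingerprints)) v$chemical <- tanimoto_matrix(fingerprints)
  v
}

#' Target-view similarity matrices
#'
#' The three target views: `sequence` (normalized Smith-Waterman),
#' `interaction` (Jaccard over target-target neighbors) and `disease`
#' (Jaccard over target-disease neighbors). `sequence` is omitted when
#' `sequences` is NULL.
#'
#' @param net a [hetero_network()].
#' @param sequences optional named character vector of target sequences.
#' @return Named list of similarity matrices.
#' @export
target_similarity_views <- function(net, sequences = NULL) {
  v <- list(interaction = jaccard_matrix(net$A_TT),
            disease = jaccard_matrix(net$A_TI))
  if (!is.null(sequences)) v$sequence <- sw_similarity(sequences)
  v
}
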