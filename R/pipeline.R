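#' Fit the full drug-target interaction model
#'
#' End-to-end estimator over a heterogeneous network:
#' \enumerate{
#' \item compute the drug and target multi-view similarities and fuse each
#'   set with information-entropy weights;
#' \item enumerate the nine meta-path count matrices, train the semantic
#'   attention head against the known interactions, fuse, threshold at
#'   `cfg$tau` and merge with the known interactions into the densified
#'   `Y_DTI`;
#' \item assemble the block interaction and similarity matrices and train
#'   the regularized GCN autoencoder ([fit_embeddings()]);
#' \item train a gradient-boosted pair classifier on embedding-derived
#'   features of all labelled pairs.
#' }
#'
#' @param net a [hetero_network()].
#' @param fingerprints optional binary drug fingerprint matrix (enables the
#'   chemical similarity view).
#' @param sequences optional named target sequences (enables the sequence
#'   view).
#' @param cfg a [train_config()].
#' @return Object of class `hetdti` with components `network`, `cfg`,
#'   `similarity` (fused drug/target similarities), `metapath` (attention
#'   weights, `Y_DTI`, densification counts), `fit` (the `gcn_fit`),
#'   `Z_D`, `Z_T`, `pairs` and `classifier`.
#' @seealso [predict.hetdti()], [rank_predictions()], [hetdti_cv()]
#' @export
hetdti_fit <- function(net, fingerprints = NULL, sequences = NULL,
                       cfg = train_config()) {
  stopifnot(inherits(net, "hetero_network"), inherits(cfg, "train_config"))
  S_D <- fused_similarity(drug_similarity_views(net, fingerprints))
  S_T <- fused_similarity(target_similarity_views(net, sequences))
  st <- pipeline_embed(net, net$A_DT, S_D, S_T, cfg)
  pairs <- build_pairs(net$A_DT, st$Z_D, st$Z_T, cfg$feature_mode,
                       cfg$neg_ratio, cfg$seed)
  clf <- fit_pair_classifier(pairs$features, pairs$pairs$label,
                             cfg$classifier, cfg$seed)
  structure(list(network = net, cfg = cfg,
                 similarity = list(drug = S_D, target = S_T),
                 metapath = list(attention = st$attention,
                                 Y_DTI = st$Y_DTI,
                                 n_known = sum(net$A_DT),
                                 n_densified = sum(st$Y_DTI)),
                 fit = st$fit, Z_D = st$Z_D, Z_T = st$Z_T,
                 pairs = pairs, classifier = clf),
            class = "hetdti")
}

#' @export
print.hetdti <- function(x, ...) {
  net <- x$network
  cat("Drug-target interaction model (meta-path fused GCN autoencoder)\n")
  cat(sprintf("  network: %d drugs, %d targets, %d diseases, %d side-effects\n",
              length(net$drug_ids), length(net$target_ids),
              length(net$disease_ids), length(net$side_effect_ids)))
  cat(sprintf("  DTI densification (tau = %g): %d known -> %d fused positives\n",
              x$cfg$tau, x$metapath$n_known, x$metapath$n_densified))
  cat(sprintf("  embeddings: k = %d, %d epochs, final total loss %.4f\n",
              ncol(x$Z_D), nrow(x$fit$trace),
              x$fit$trace$total[nrow(x$fit$trace)]))
  cat(sprintf("  classifier: %s on %s pair features\n",
              x$cfg$classifier, x$cfg$feature_mode))
  invisible(x)
}

#' @export
summary.hetdti <- function(object, ...) {
  out <- list(model = object,
              attention = object$metapath$attention,
              drug_view_weights = object$similarity$drug$weights,
              target_view_weights = object$similarity$target$weights,
              loss = utils::tail(object$fit$trace$total, 1))
  class(out) <- "summary.hetdti"
  out
}

#' @export
print.summary.hetdti <- function(x, ...) {
  print(x$model)
  if (!is.null(x$attention)) {
    cat("Meta-path attention weights:\n")
    print(round(x$attention, 4))
  }
  cat("Drug similarity view weights (entropy-derived):\n")
  print(round(x$drug_view_weights, 4))
  cat("Target similarity view weights (entropy-derived):\n")
  print(round(x$target_view_weights, 4))
  invisible(x)
}

#' Model coefficients: fusion weights
#'
#' Returns the model's learned/derived weighting coefficients: the softmax
#' attention weights over the eight indirect meta-paths and the
#' entropy-derived similarity-view weights for drugs and targets.
#'
#' @param object a fitted `hetdti` model.
#' @param ... unused.
#' @export
coef.hetdti <- function(object, ...) {
  list(attention = object$metapath$attention,
       drug_views = object$similarity$drug$weights,
       target_views = object$similarity$target$weights)
}

#' Predict interaction scores for drug-target pairs
#'
#' Scores pairs with the fitted classifier on embedding-derived features.
#' By default all pairs are scored; `drugs`/`targets` restrict to a
#' sub-grid.
#'
#' @param object a fitted `hetdti` model.
#' @param drugs,targets optional id vectors restricting the pair grid.
#' @param ... unused.
#' @return data.frame with `drug`, `target`, `known` (label in the training
#'   network) and `score`.
#' @export
predict.hetdti <- function(object, drugs = NULL, targets = NULL, ...) {
  net <- object$network
  di <- if (is.null(drugs)) seq_along(net$drug_ids)
        else match(drugs, net$drug_ids)
  ti <- if (is.null(targets)) seq_along(net$target_ids)
        else match(targets, net$target_ids)
  if (anyNA(di)) stop("predict.hetdti: unknown drug id(s)")
  if (anyNA(ti)) stop("predict.hetdti: unknown target id(s)")
  idx <- as.matrix(expand.grid(drug = di, target = ti))
  feats <- pair_features(idx, object$Z_D, object$Z_T, object$cfg$feature_mode)
  data.frame(drug = net$drug_ids[idx[, 1]], target = net$target_ids[idx[, 2]],
             known = net$A_DT[idx], score = predict(object$classifier, feats))
}

#' Plot the training loss trace
#'
#' Total loss plus the reconstruction, STC and MI components per epoch.
#'
#' @param x a fitted `hetdti` model or a `gcn_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hetdti <- function(x, ...) plot(x$fit, ...)

#' @export
plot.gcn_fit <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(seq_len(nrow(tr)), tr[, c("total", "recon", "stc", "mi")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "steelblue", "darkorange", "forestgreen"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "reconstruction", "STC", "MI"),
                   lty = 1, lwd = 2,
                   col = c("black", "steelblue", "darkorange", "forestgreen"),
                   bty = "n")
  invisible(x)
}
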