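#' Build a labelled drug-target pair dataset from embeddings
#'
#' Every known interaction (`A_DT = 1`) is a positive; every unknown pair is
#' a negative. The per-pair feature vector is either the concatenation
#' `[z_d, z_t]` (length 2k, default) or the Hadamard product `z_d * z_t`
#' (length k). `neg_ratio = "all"` keeps every negative (the reference
#' protocol); a numeric ratio subsamples negatives at `ratio` per positive
#' with `seed`.
#'
#' @param A_DT binary known-interaction matrix.
#' @param Z_D,Z_T drug and target embedding blocks.
#' @param feature_mode `"concat"` or `"hadamard"`.
#' @param neg_ratio `"all"` or a positive number.
#' @param seed RNG seed for negative subsampling.
#' @return Object of class `pair_dataset`: list with `pairs` (data.frame
#'   `drug`, `target`, `label`), `features` (matrix, one row per pair) and
#'   `feature_mode`.
#' @export
build_pairs <- function(A_DT, Z_D, Z_T, feature_mode = c("concat", "hadamard"),
                        neg_ratio = "all", seed = 1) {
  feature_mode <- match.arg(feature_mode)
  A_DT <- as.matrix(A_DT)
  if (sum(A_DT) == 0) stop("build_pairs: no positive pairs in A_DT")
  idx <- which(A_DT >= -Inf, arr.ind = TRUE)   # all pairs, column-major
  lab <- as.integer(A_DT[idx] == 1)
  if (!identical(neg_ratio, "all")) {
    neg <- which(lab == 0)
    keepn <- min(length(neg), ceiling(as.numeric(neg_ratio) * sum(lab)))
    set.seed(as.integer(seed))
    keep <- sort(c(which(lab == 1), sample(neg, keepn)))
    idx <- idx[keep, , drop = FALSE]; lab <- lab[keep]
  }
  feats <- pair_features(idx, Z_D, Z_T, feature_mode)
  structure(list(pairs = data.frame(drug = idx[, 1], target = idx[, 2],
                                    label = lab),
                 features = feats, feature_mode = feature_mode),
            class = "pair_dataset")
}

pair_features <- function(idx, Z_D, Z_T, feature_mode) {
  zd <- Z_D[idx[, 1], , drop = FALSE]
  zt <- Z_T[idx[, 2], , drop = FALSE]
  if (feature_mode == "concat") cbind(zd, zt) else zd * zt
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("Pair dataset: %d pairs (%d positive), %d features (%s)\n",
              nrow(x$pairs), sum(x$pairs$label), ncol(x$features),
              x$feature_mode))
  invisible(x)
}

# Stratified 5-fold assignment: positives and negatives are independently
# split into `nfolds` random disjoint subsets.
assign_folds <- function(labels, nfolds = 5, seed = 1) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in c(1L, 0L)) {
    i <- which(labels == cl)
    if (length(i) < nfolds)
      stop(sprintf("assign_folds: class %d has fewer than %d members", cl, nfolds))
    fold[i] <- sample(rep_len(seq_len(nfolds), length(i)))
  }
  fold
}

#' Classification metrics for scored pairs
#'
#' AUC by the rank (Mann-Whitney) statistic with ties averaged; AUPR by
#' step integration of the precision-recall curve; Recall, F1 and Accuracy
#' from scores thresholded at `threshold`.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more likely positive.
#' @param threshold classification threshold for Recall/F1/ACC.
#' @return Named numeric vector `AUC`, `AUPR`, `Recall`, `F1`, `ACC`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("compute_metrics: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(-scores)
  tp <- cumsum(labels[o] == 1)
  prec <- tp / seq_along(tp)
  rec <- tp / npos
  aupr <- sum(prec * diff(c(0, rec)))
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  recall <- TP / (TP + FN)
  precv <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (precv + recall > 0) 2 * precv * recall / (precv + recall) else 0
  acc <- (TP + TN) / length(labels)
  c(AUC = auc, AUPR = aupr, Recall = recall, F1 = f1, ACC = acc)
}

# --- classifiers ------------------------------------------------------------

fit_pair_classifier <- function(x, y, spec = c("xgb", "rf", "logistic"),
                                seed = 1) {
  spec <- match.arg(spec)
  set.seed(as.integer(seed))
  model <- switch(spec,
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      max_depth = 6, eta = 0.1, seed = as.integer(seed)),
        data = dtrain, nrounds = 100, verbose = 0)
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("randomForest is required for spec = 'rf'")
      randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 200)
    },
    logistic = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("V", seq_len(ncol(df)))
      suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                  family = stats::binomial()))
    })
  structure(list(spec = spec, model = model), class = "pair_classifier")
}

#' @export
predict.pair_classifier <- function(object, newdata, ...) {
  switch(object$spec,
    xgb = stats::predict(object$model,
                         xgboost::xgb.DMatrix(newdata, nthread = 1)),
    rf = stats::predict(object$model, newdata, type = "prob")[, "1"],
    logistic = {
      df <- as.data.frame(newdata)
      colnames(df) <- paste0("V", seq_len(ncol(df)))
      suppressWarnings(
        as.numeric(stats::predict(object$model, df, type = "response")))
    })
}

#' Five-fold cross-validation of a pair classifier
#'
#' Positives and negatives are independently partitioned into five random
#' disjoint subsets; each subset is rotated as the test set while the other
#' four train the classifier. This evaluates a fixed feature matrix (no
#' per-fold rebuilding); for the leakage-guarded protocol that re-derives
#' the densified network and embeddings per fold, see [hetdti_cv()].
#'
#' @param dataset a [build_pairs()] result.
#' @param model_spec `"xgb"`, `"rf"` or `"logistic"`.
#' @param seed RNG seed for fold assignment and classifier fitting.
#' @param nfolds number of folds.
#' @param threshold classification threshold.
#' @return A `metrics_report`: data.frame of per-fold metrics with the mean
#'   row attached, plus the fold assignment.
#' @export
crossvalidate <- function(dataset, model_spec = "xgb", seed = 1, nfolds = 5,
                          threshold = 0.5) {
  fold <- assign_folds(dataset$pairs$label, nfolds, seed)
  rows <- lapply(seq_len(nfolds), function(f) {
    tr <- fold != f; te <- fold == f
    clf <- fit_pair_classifier(dataset$features[tr, , drop = FALSE],
                               dataset$pairs$label[tr], model_spec, seed)
    sc <- predict(clf, dataset$features[te, , drop = FALSE])
    compute_metrics(dataset$pairs$label[te], sc, threshold)
  })
  metrics_report(do.call(rbind, rows), fold)
}

metrics_report <- function(per_fold, fold = NULL) {
  df <- as.data.frame(per_fold)
  df$fold <- seq_len(nrow(df))
  structure(list(per_fold = df,
                 mean = colMeans(df[, setdiff(names(df), "fold")]),
                 fold_assignment = fold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-validation metrics (per fold):\n")
  print(round(x$per_fold, 4), row.names = FALSE)
  cat("Mean:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Leakage-aware five-fold cross-validation of the full pipeline
#'
#' Known interactions (positives) and unknown pairs (negatives) are each
#' split into five disjoint subsets. In every fold, with the leakage guard
#' on (default), the test-fold positives are removed from `A_DT` before
#' anything that consumes known interactions is built: the meta-path stack,
#' the attention fit, the densified `Y_DTI`, the block matrices and the
#' embedding training all see only training positives. With the guard off,
#' the networks are built once from the full `A_DT` (embeddings then encode
#' test labels, which optimistically inflates the measured performance —
#' provided for documentation of that hazard, not for reporting).
#'
#' Drug/target similarity views do not involve `A_DT` and are computed once.
#'
#' @param net a [hetero_network()].
#' @param fingerprints optional drug fingerprint matrix (adds the chemical
#'   view).
#' @param sequences optional target sequences (adds the sequence view).
#' @param cfg a [train_config()].
#' @param nfolds number of folds.
#' @param guard logical; mask test positives before network construction.
#' @param threshold classification threshold.
#' @return A `metrics_report` with per-fold and mean AUC, AUPR, Recall, F1,
#'   ACC.
#' @export
hetdti_cv <- function(net, fingerprints = NULL, sequences = NULL,
                      cfg = train_config(), nfolds = 5, guard = TRUE,
                      threshold = 0.5) {
  S_D <- fused_similarity(drug_similarity_views(net, fingerprints))
  S_T <- fused_similarity(target_similarity_views(net, sequences))
  A_DT <- net$A_DT
  lab <- as.integer(A_DT[which(A_DT >= -Inf, arr.ind = TRUE)] == 1)
  all_idx <- which(A_DT >= -Inf, arr.ind = TRUE)
  fold <- assign_folds(lab, nfolds, cfg$seed)

  shared <- if (!guard)
    pipeline_embed(net, A_DT, S_D, S_T, cfg)
  rows <- lapply(seq_len(nfolds), function(f) {
    te <- fold == f
    st <- if (guard) {
      A_train <- A_DT
      A_train[all_idx[te & lab == 1, , drop = FALSE]] <- 0
      pipeline_embed(net, A_train, S_D, S_T, cfg)
    } else shared
    feats <- pair_features(all_idx, st$Z_D, st$Z_T, cfg$feature_mode)
    clf <- fit_pair_classifier(feats[!te, , drop = FALSE], lab[!te],
                               cfg$classifier, cfg$seed)
    sc <- predict(clf, feats[te, , drop = FALSE])
    compute_metrics(lab[te], sc, threshold)
  })
  metrics_report(do.call(rbind, rows), fold)
}

# Shared pipeline stage: densify the DTI matrix from a (possibly masked)
# A_DT, assemble the block matrices and train the embeddings.
pipeline_embed <- function(net, A_DT, S_D, S_T, cfg) {
  net2 <- net
  net2$A_DT <- A_DT
  if (is.finite(cfg$tau)) {
    stack <- metapath_stack(net2)
    ap <- attention_params(stack, cfg$attn_proj_dim,
                           seed = substream_seed(cfg$seed, 20L))
    ap <- fit_attention(stack, ap, cfg$attn_epochs, cfg$attn_lr)
    fused <- attention_fuse(stack, ap)
    fd <- threshold_and_merge(fused, cfg$tau, A_DT)
    Y <- fd$Y_DTI
    attn <- attr(fused, "weights")
  } else {
    Y <- A_DT
    fd <- NULL
    attn <- NULL
  }
  A_tilde <- assemble_block(net2, Y, net2$A_DD, net2$A_TT, "interaction")
  S_tilde <- assemble_block(net2, Y, S_D$S, S_T$S, "similarity")
  fit <- fit_embeddings(A_tilde, S_tilde, S_D, S_T, cfg)
  list(fit = fit, fused = fd, attention = attn, Y_DTI = Y,
       Z_D = embedding_drugs(fit$embedding),
       Z_T = embedding_targets(fit$embedding))
}

#' Ranked interaction predictions for a query drug or target
#'
#' Scores every non-positive partner of the query entity with the fitted
#' classifier and returns the top of the descending-score list.
#'
#' @param object a fitted [hetdti_fit()] model.
#' @param query drug or target identifier.
#' @param type `"drug"` (rank candidate targets) or `"target"` (rank
#'   candidate drugs).
#' @param top_n list length (truncated to the number of candidates).
#' @return data.frame with `partner_id` and `score`, sorted descending.
#' @export
rank_predictions <- function(object, query, type = c("drug", "target"),
                             top_n = 10) {
  stopifnot(inherits(object, "hetdti"))
  type <- match.arg(type)
  net <- object$network
  if (type == "drug") {
    qi <- match(query, net$drug_ids)
    if (is.na(qi)) stop("rank_predictions: unknown drug id ", query)
    cand <- which(net$A_DT[qi, ] == 0)
    idx <- cbind(rep(qi, length(cand)), cand)
    ids <- net$target_ids[cand]
  } else {
    qi <- match(query, net$target_ids)
    if (is.na(qi)) stop("rank_predictions: unknown target id ", query)
    cand <- which(net$A_DT[, qi] == 0)
    idx <- cbind(cand, rep(qi, length(cand)))
    ids <- net$drug_ids[cand]
  }
  feats <- pair_features(idx, object$Z_D, object$Z_T, object$cfg$feature_mode)
  sc <- predict(object$classifier, feats)
  o <- order(-sc)
  utils::head(data.frame(partner_id = ids[o], score = sc[o],
                         row.names = NULL), top_n)
}
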