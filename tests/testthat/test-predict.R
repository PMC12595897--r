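test_that("pair construction counts labels and builds the stated features", {
  A <- rbind(c(1, 0), c(0, 0))
  ZD <- matrix(1:4 / 10, 2, 2); ZT <- matrix(5:8 / 10, 2, 2)
  ds <- build_pairs(A, ZD, ZT)
  expect_equal(sum(ds$pairs$label), 1)
  expect_equal(sum(ds$pairs$label == 0), 3)
  expect_equal(ncol(ds$features), 4)          # concat of two k=2 blocks

  dh <- build_pairs(A, ZD, ZT, feature_mode = "hadamard")
  expect_equal(ncol(dh$features), 2)
  for (r in seq_len(nrow(dh$pairs))) {
    expect_equal(unname(dh$features[r, ]),
                 ZD[dh$pairs$drug[r], ] * ZT[dh$pairs$target[r], ])
  }
  expect_error(build_pairs(matrix(0, 2, 2), ZD, ZT), "no positive")

  # negative subsampling keeps all positives and the requested ratio
  set.seed(1)
  A2 <- matrix(rbinom(100, 1, 0.2), 10, 10)
  Z10 <- matrix(rnorm(30), 10, 3)
  dsub <- build_pairs(A2, Z10, Z10, neg_ratio = 2, seed = 5)
  expect_equal(sum(dsub$pairs$label), sum(A2))
  expect_equal(sum(dsub$pairs$label == 0), 2 * sum(A2))
})

test_that("fold assignment partitions each class into five disjoint subsets", {
  set.seed(2)
  lab <- rbinom(200, 1, 0.3)
  fold <- hetdti:::assign_folds(lab, 5, seed = 7)
  expect_setequal(unique(fold), 1:5)
  for (cl in 0:1) {
    tab <- table(fold[lab == cl])
    expect_equal(length(tab), 5L)
    expect_lte(diff(range(tab)), 1)   # balanced partition
  }
  expect_identical(fold, hetdti:::assign_folds(lab, 5, seed = 7))
  expect_error(hetdti:::assign_folds(c(1, 1, 1, 0, 0, 0, 0, 0), 5), "fewer")
})

test_that("metrics match confusion-matrix arithmetic and rank statistics", {
  # TP=3 FP=1 FN=1 TN=5 at threshold 0.5
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(.9, .8, .7, .2, .6, .1, .2, .3, .4, .45)
  m <- compute_metrics(labels, scores)
  expect_equal(unname(m["Recall"]), 0.75)
  expect_equal(unname(m["F1"]), 0.75)
  expect_equal(unname(m["ACC"]), 0.8)

  expect_equal(unname(compute_metrics(c(0, 1, 0, 1), rep(0.3, 4))["AUC"]), 0.5)
  expect_error(compute_metrics(c(1, 1), c(.2, .3)), "both classes")

  # AUC equals the Mann-Whitney pairwise comparison on random cases
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(10:40, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- round(runif(n), 2)            # rounded scores force ties
    u <- 0
    for (i in which(lab == 1)) for (j in which(lab == 0))
      u <- u + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    expect_equal(unname(compute_metrics(lab, sc)["AUC"]),
                 u / (sum(lab == 1) * sum(lab == 0)),
                 info = paste("seed", seed))
  }

  # independent cross-check of the rank AUC against pROC
  set.seed(99)
  lab <- rbinom(60, 1, 0.5); sc <- runif(60)
  expect_equal(unname(compute_metrics(lab, sc)["AUC"]),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))))

  # perfect separation
  mp <- compute_metrics(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_equal(unname(mp["AUC"]), 1)
  expect_equal(unname(mp["AUPR"]), 1)

  # random scores on many balanced pairs sit near chance
  set.seed(5)
  lab <- rep(c(0, 1), 1000)
  mr <- compute_metrics(lab, runif(2000))
  expect_lt(abs(mr["AUC"] - 0.5), 0.05)
})

test_that("dataset-level cross-validation rotates every pair once", {
  set.seed(3)
  n <- 300
  lab <- rbinom(n, 1, 0.3)
  feats <- cbind(lab + rnorm(n, 0, 0.05), matrix(rnorm(n * 2), n))
  ds <- structure(list(pairs = data.frame(drug = 1, target = 1, label = lab),
                       features = feats, feature_mode = "concat"),
                  class = "pair_dataset")
  rep <- crossvalidate(ds, "logistic", seed = 4)
  expect_equal(sort(unique(rep$fold_assignment)), 1:5)
  expect_length(rep$fold_assignment, n)
  # a feature that encodes the label yields near-perfect fold AUCs
  expect_true(all(rep$per_fold$AUC > 0.95))
  expect_equal(nrow(rep$per_fold), 5)
})

test_that("all three classifier plug-ins honor the same interface", {
  set.seed(6)
  n <- 240
  lab <- rbinom(n, 1, 0.4)
  feats <- cbind(lab + rnorm(n, 0, 0.3), matrix(rnorm(n * 3), n))
  ds <- structure(list(pairs = data.frame(drug = 1, target = 1, label = lab),
                       features = feats, feature_mode = "concat"),
                  class = "pair_dataset")
  for (spec in c("xgb", "rf", "logistic")) {
    rep <- crossvalidate(ds, spec, seed = 8)
    expect_true(all(is.finite(as.matrix(rep$per_fold))), info = spec)
    expect_gt(rep$mean[["AUC"]], 0.7)   # informative feature is learnable
    expect_true(all(rep$per_fold$AUC >= 0 & rep$per_fold$AUC <= 1))
  }
})

# One small end-to-end model reused by the interface tests below.
small_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      ds <- generate_synthetic_dataset(
        synthetic_config(N_d = 12, N_t = 12, N_i = 8, N_s = 8, n_groups = 2,
                         p_in = 0.5, p_out = 0.05, fingerprint_len = 32,
                         seq_len_range = c(40, 60), motif_len = 8, seed = 9))
      cfg <- train_config(epochs = 25, tau = 2, attn_epochs = 30, m = 16,
                          k = 8, p = 3, batch = 12, mi_hidden = 16,
                          mi_proj_dim = 4, local_c = 8, seed = 2)
      model <<- suppressWarnings(
        hetdti_fit(ds$network, ds$fingerprints, ds$sequences, cfg))
    }
    model
  }
})

test_that("the fitted model exposes the classic S3 surface", {
  m <- small_model()
  expect_s3_class(m, "hetdti")
  expect_output(print(m), "densification")
  expect_output(print(summary(m)), "attention")
  cf <- coef(m)
  expect_equal(sum(cf$attention), 1, tolerance = 1e-9)
  expect_equal(sum(cf$drug_views), 1, tolerance = 1e-9)
  expect_equal(sum(cf$target_views), 1, tolerance = 1e-9)
  pr <- predict(m)
  expect_equal(nrow(pr), 144)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  pr2 <- predict(m, drugs = "D001", targets = c("T001", "T002"))
  expect_equal(nrow(pr2), 2)
  expect_error(predict(m, drugs = "D999"), "unknown")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("ranked predictions scan all non-positive partners in order", {
  m <- small_model()
  net <- m$network
  rk <- rank_predictions(m, "D001", "drug", top_n = 5)
  expect_lte(nrow(rk), 5)
  expect_true(all(diff(rk$score) <= 0))
  # top-1 equals an exhaustive argmax over candidate scores
  cand <- net$target_ids[net$A_DT[1, ] == 0]
  all_sc <- predict(m, drugs = "D001", targets = cand)
  expect_equal(rk$partner_id[1], all_sc$target[which.max(all_sc$score)])
  # n larger than the candidate pool returns the full list
  rk_all <- rank_predictions(m, "D001", "drug", top_n = 1000)
  expect_equal(nrow(rk_all), length(cand))
  rk_t <- rank_predictions(m, "T002", "target", top_n = 3)
  expect_lte(nrow(rk_t), 3)
  expect_error(rank_predictions(m, "D999", "drug"), "unknown")
})

test_that("disabling the leakage guard optimistically inflates the measured AUC", {
  ds <- generate_synthetic_dataset(
    synthetic_config(N_d = 16, N_t = 16, N_i = 8, N_s = 8, n_groups = 2,
                     p_in = 0.5, p_out = 0.05, fingerprint_len = 32,
                     seq_len_range = c(40, 60), motif_len = 8, seed = 12))
  cfg <- train_config(epochs = 60, tau = 2, attn_epochs = 40, m = 24, k = 12,
                      p = 3, batch = 16, mi_hidden = 16, mi_proj_dim = 4,
                      local_c = 8, seed = 3)
  on_rep <- suppressWarnings(
    hetdti_cv(ds$network, ds$fingerprints, ds$sequences, cfg, guard = TRUE))
  off_rep <- suppressWarnings(
    hetdti_cv(ds$network, ds$fingerprints, ds$sequences, cfg, guard = FALSE))
  # guard-off encodes the test labels into Y_DTI and the embeddings
  expect_lte(on_rep$mean[["AUC"]], off_rep$mean[["AUC"]] + 0.05)
  # same seed -> identical fold assignment across both protocols
  expect_identical(on_rep$fold_assignment, off_rep$fold_assignment)
})
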