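# A discriminator with all-zero parameters scores every pair identically
# (0 pre-squash, 0.5 after the sigmoid), giving closed-form estimates.
zero_disc <- function(objective, input_dim = 3, k = 2, role = "global") {
  d <- mi_discriminator(role, input_dim, k, hidden = 4, proj_dim = 2,
                        objective = objective, seed = 1)
  d$mlp$W <- lapply(d$mlp$W, function(W) W * 0)
  d$mlp$b <- lapply(d$mlp$b, function(b) b * 0)
  if (!is.null(d$proj)) d$proj <- list(U = d$proj$U * 0, c = d$proj$c * 0)
  d
}

toy_pairs <- function(n = 10, seed = 2) {
  set.seed(seed)
  A <- matrix(rnorm(n * 3), n, 3)
  Z <- matrix(rnorm(n * 2), n, 2)
  sample_pairs(A, Z, n, seed = seed)
}

test_that("pair sampling mismatches every marginal pair and is reproducible", {
  set.seed(1)
  A <- matrix(rnorm(24), 8, 3); Z <- matrix(rnorm(16), 8, 2)
  sp <- sample_pairs(A, Z, 8, seed = 4)
  expect_true(all(sp$perm != seq_along(sp$perm)))      # derangement
  expect_identical(sp, sample_pairs(A, Z, 8, seed = 4))
  # the marginal batch reuses exactly the joint inputs
  expect_identical(sp$marginal$x, sp$joint$x)
  expect_equal(sort(sp$marginal$z[, 1]), sort(sp$joint$z[, 1]))
  expect_error(sample_pairs(A, Z, 9, seed = 1), "batch")
})

test_that("constant discriminators give the closed-form estimates", {
  sp <- toy_pairs()
  expect_equal(dv_estimate(sp$joint, sp$marginal, zero_disc("dv")), 0)
  expect_equal(js_estimate(sp$joint, sp$marginal, zero_disc("js")),
               2 * log(0.5), tolerance = 1e-12)
  # role/squashing mismatches are hard errors
  expect_error(dv_estimate(sp$joint, sp$marginal, zero_disc("js")), "linear")
  expect_error(js_estimate(sp$joint, sp$marginal, zero_disc("dv")), "sigmoid")
})

test_that("large discriminator scores do not overflow the DV log-mean-exp", {
  sp <- toy_pairs()
  d <- zero_disc("dv")
  d$mlp$b[[length(d$mlp$b)]] <- 900    # e^900 overflows naively
  expect_true(is.finite(dv_estimate(sp$joint, sp$marginal, d)))
  expect_equal(dv_estimate(sp$joint, sp$marginal, d), 0)  # constant shift cancels
})

test_that("JS estimates are nonpositive for any admissible discriminator", {
  sp <- toy_pairs(n = 12, seed = 5)
  for (seed in 1:5) {
    d <- mi_discriminator("global", 3, 2, hidden = 8, proj_dim = 2,
                          objective = "js", seed = seed)
    expect_lte(js_estimate(sp$joint, sp$marginal, d), 0)
  }
})

test_that("the local estimate averages per-block JS terms", {
  set.seed(6)
  A <- matrix(rnorm(80), 10, 8); Z <- matrix(rnorm(20), 10, 2)
  C <- local_encoder(8, M = 2, c_dim = 3, seed = 2)
  Td <- mi_discriminator("local", 3, 2, hidden = 6, objective = "js", seed = 3)
  v <- local_mi_loss(A, Z, C, Td, batch = 10, seed = 9)
  per <- attr(v, "per_block")
  expect_length(per, 4)
  expect_equal(as.numeric(v), mean(per))
  # block-by-block recomputation with the same sampled batch
  sp <- sample_pairs(A, Z, 10, seed = 9)
  blocks <- hetdti:::local_blocks(C, sp$joint$x)
  per2 <- vapply(seq_len(4), function(r)
    js_estimate(list(x = blocks[[r]], z = sp$joint$z),
                list(x = blocks[[r]], z = sp$marginal$z), Td), 0)
  expect_equal(per, per2)

  # constant discriminator: 2 log 0.5 regardless of the grid
  Tz <- zero_disc("js", input_dim = 3, role = "local")
  expect_equal(as.numeric(local_mi_loss(A, Z, C, Tz, batch = 10, seed = 9)),
               2 * log(0.5), tolerance = 1e-12)

  # M = 1 degenerates to a single global-style term
  C1 <- local_encoder(8, M = 1, c_dim = 3, seed = 2)
  v1 <- local_mi_loss(A, Z, C1, Td, batch = 10, seed = 9)
  expect_length(attr(v1, "per_block"), 1)

  expect_error(local_encoder(3, M = 2), "smaller M")
})

test_that("the prior term is at chance for a constant discriminator", {
  set.seed(7)
  Z <- matrix(rnorm(40), 20, 2)
  Dz <- zero_disc("js", role = "prior", k = 2)
  expect_equal(prior_loss(Z, Dz, batch = 20, seed = 1), 2 * log(0.5),
               tolerance = 1e-12)
  expect_error(prior_loss(Z, zero_disc("dv", role = "prior", k = 2),
                          batch = 5, seed = 1), "sigmoid")
})

test_that("the combined MI loss books its terms consistently", {
  set.seed(8)
  A <- matrix(rnorm(14 * 14), 14); A <- (A + t(A)) / 2
  Z <- matrix(rnorm(14 * 4), 14, 4)
  discs <- mi_discriminators(14, 4, M = 2, c_dim = 3, hidden = 8,
                             proj_dim = 4, seed = 2)
  w0 <- mi_weights(0, 0, 0)
  expect_equal(as.numeric(mi_loss(A, Z, discs, w0, batch = 10, seed = 3)), 0)
  wg <- mi_weights(1, 0, 0)
  vg <- mi_loss(A, Z, discs, wg, batch = 10, seed = 3)
  expect_equal(as.numeric(vg), unname(attr(vg, "terms")["global"]))
  expect_equal(unname(attr(vg, "terms")[c("local", "prior")]), c(0, 0))
  w <- mi_weights(0.3, 0.2, 0.1)
  v <- mi_loss(A, Z, discs, w, batch = 10, seed = 3)
  terms <- attr(v, "terms")
  expect_equal(as.numeric(v),
               0.3 * terms[["global"]] + 0.2 * terms[["local"]] +
                 0.1 * terms[["prior"]], tolerance = 1e-9)
})

test_that("trained estimators behave on dependent and independent toys", {
  # correlated bits: z = x, true MI = log 2 (exact from the 2x2 joint table)
  set.seed(10)
  n <- 1500
  b <- rbinom(n, 1, 0.5)
  x <- matrix(b, ncol = 1); z <- matrix(b, ncol = 1)
  dv <- mi_train_estimator(x, z, "dv", epochs = 120, batch = 256, lr = 0.01,
                           hidden = 16, proj_dim = 4, seed = 3)
  expect_gt(dv$estimate, 0.5)
  expect_lt(dv$estimate, log(2) + 0.05)

  # independent pairs: JS stays near the chance value -2 log 2
  z_ind <- matrix(rbinom(n, 1, 0.5), ncol = 1)
  js <- mi_train_estimator(x, z_ind, "js", epochs = 120, batch = 256,
                           lr = 0.01, hidden = 16, proj_dim = 4, seed = 4)
  expect_lt(abs(js$estimate - 2 * log(0.5)), 0.1)
})
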