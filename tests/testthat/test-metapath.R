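test_that("a shared disease creates an indirect DIDT path instance", {
  # d1 and d2 share disease i1; d2 interacts with t1
  net <- hetero_network(c("d1", "d2"), "t1", "i1", "s1",
                        A_DD = matrix(0, 2, 2),
                        A_DT = rbind(0, 1),
                        A_DI = rbind(1, 1),
                        A_DS = matrix(0, 2, 1),
                        A_TT = matrix(0, 1, 1),
                        A_TI = matrix(0, 1, 1))
  st <- metapath_stack(net)
  expect_equal(unname(st$matrices$DIDT[1, 1]), 1)
  expect_equal(unname(st$matrices$DIDT[2, 1]), 1)  # d2-i1-d2-t1 (revisit allowed)
})

test_that("an empty network yields nine zero matrices", {
  net <- hetero_network(c("d1", "d2"), c("t1", "t2"), "i1", "s1",
                        matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 1),
                        matrix(0, 2, 1), matrix(0, 2, 2), matrix(0, 2, 1))
  st <- metapath_stack(net)
  expect_equal(length(st$matrices), 9L)
  for (A in st$matrices) expect_equal(sum(A), 0)
})

test_that("adjacency-product counts equal exhaustive typed-path enumeration", {
  for (seed in 1:10) {
    net <- random_tiny_network(seed, n_per_class = 8)
    st <- metapath_stack(net)
    oracle <- brute_force_stack(net)
    for (nm in names(oracle))
      expect_equal(unname(st$matrices[[nm]]), oracle[[nm]],
                   info = sprintf("seed %d path %s", seed, nm))
  }
})

make_stack <- function(mats) {
  nm <- c("DT", "DDT", "DIT", "DTT", "DIDT", "DITT", "DSDT", "DDIT", "DTDT")
  structure(list(names = nm, matrices = setNames(mats, nm)),
            class = "metapath_stack")
}

test_that("attention fusion is a convex combination of the indirect matrices", {
  set.seed(1)
  B <- matrix(rpois(12, 2), 4, 3)
  stack <- make_stack(c(list(matrix(rbinom(12, 1, .3), 4, 3)),
                        replicate(8, B, simplify = FALSE)))
  params <- attention_params(stack, proj_dim = 6, seed = 2)
  fused <- attention_fuse(stack, params)
  expect_equal(unname(fused), unname(B), tolerance = 1e-12,
               ignore_attr = TRUE)  # identical inputs
  expect_equal(sum(attr(fused, "weights")), 1)

  # q = 0 makes every score equal -> uniform softmax -> plain average
  mats <- c(list(matrix(0, 4, 3)),
            lapply(1:8, function(i) matrix(rpois(12, i), 4, 3)))
  stack2 <- make_stack(mats)
  p2 <- attention_params(stack2, proj_dim = 6, seed = 3)
  p2$q <- p2$q * 0
  f2 <- attention_fuse(stack2, p2)
  expect_equal(unname(f2), unname(Reduce(`+`, mats[2:9]) / 8),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion matches an explicit loop-based softmax-weighted sum", {
  set.seed(9)
  mats <- c(list(matrix(rbinom(12, 1, .3), 4, 3)),
            lapply(1:8, function(i) matrix(rpois(12, 1.5), 4, 3)))
  stack <- make_stack(mats)
  params <- attention_params(stack, proj_dim = 5, seed = 4)
  fused <- attention_fuse(stack, params)
  # independent recomputation with explicit loops
  w <- numeric(8)
  for (i in 2:9) {
    A <- mats[[i]]
    s <- numeric(nrow(A))
    for (r in seq_len(nrow(A))) {
      z <- as.numeric(A[r, ] %*% params$W1) + params$b1
      u <- as.numeric(z %*% params$W2) + params$b2
      s[r] <- sum(params$q * tanh(u))
    }
    w[i - 1] <- mean(s)
  }
  a <- exp(w - max(w)); a <- a / sum(a)
  fo <- matrix(0, 4, 3)
  for (i in 1:8) fo <- fo + mats[[i + 1]] * a[i]
  expect_equal(unname(fused), fo, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(attr(fused, "weights")), a, tolerance = 1e-10)
})

test_that("fusion is equivariant under node relabeling", {
  net <- random_tiny_network(21, n_per_class = 6)
  stack <- metapath_stack(net)
  params <- attention_params(stack, proj_dim = 8, seed = 5)
  fused <- attention_fuse(stack, params)
  # drug permutation: permutes rows of every A_i; rowwise scores are averaged,
  # so the fused matrix is the row-permuted original with the same weights
  pd <- sample(6)
  stack_pd <- make_stack(lapply(stack$matrices, function(A) A[pd, ]))
  fused_pd <- attention_fuse(stack_pd, params)
  expect_equal(unname(fused_pd), unname(fused[pd, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # target permutation: permuting columns together with the projection rows
  pt <- sample(6)
  params_pt <- params
  params_pt$W1 <- params$W1[pt, , drop = FALSE]
  stack_pt <- make_stack(lapply(stack$matrices, function(A) A[, pt]))
  fused_pt <- attention_fuse(stack_pt, params_pt)
  expect_equal(unname(fused_pt), unname(fused[, pt]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("attention training rewards the meta-path that tracks known DTIs", {
  set.seed(13)
  A1 <- matrix(rbinom(80, 1, 0.3), 8, 10)
  mats <- c(list(A1), lapply(1:8, function(i) matrix(rpois(80, 2), 8, 10)))
  mats[[4]] <- 3 * A1                      # DTT proportional to the label matrix
  stack <- make_stack(mats)
  fit <- fit_attention(stack, epochs = 300, lr = 0.05, seed = 1)
  w <- attr(attention_fuse(stack, fit), "weights")
  expect_equal(names(which.max(w)), "DTT")

  # epochs = 0 leaves parameters untouched
  p0 <- attention_params(stack, seed = 2)
  expect_identical(fit_attention(stack, p0, epochs = 0), p0)

  # fixed seed -> identical trained weights
  f2 <- fit_attention(stack, epochs = 50, lr = 0.05, seed = 3)
  f3 <- fit_attention(stack, epochs = 50, lr = 0.05, seed = 3)
  expect_identical(f2$W1, f3$W1)
  expect_identical(attr(f2, "loss_trace"), attr(f3, "loss_trace"))
})

test_that("thresholding keeps every known interaction and respects tau", {
  fd <- threshold_and_merge(rbind(c(16, 3)), 15, rbind(c(0, 0)))
  expect_equal(unname(fd$Y_DTI), rbind(c(1, 0)))
  # known DTIs survive even with zero fused support
  fd2 <- threshold_and_merge(rbind(c(0, 0)), 15, rbind(c(1, 0)))
  expect_equal(unname(fd2$Y_DTI), rbind(c(1, 0)))
  # tau above everything with empty A1 -> empty
  fd3 <- threshold_and_merge(rbind(c(16, 3)), 100, rbind(c(0, 0)))
  expect_equal(sum(fd3$Y_DTI), 0)
  # tie at tau counts as a positive
  expect_equal(unname(threshold_and_merge(rbind(5), 5, rbind(0))$Y_meta), rbind(1))
})

test_that("densified positives never shrink and decrease monotonically in tau", {
  set.seed(2)
  F <- matrix(rpois(48, 3), 6, 8)
  A1 <- matrix(rbinom(48, 1, 0.2), 6, 8)
  taus <- c(0, 1, 2, 4, 8, Inf)
  counts <- sapply(taus, function(tau) sum(threshold_and_merge(F, tau, A1)$Y_DTI))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(counts >= sum(A1)))
  for (tau in taus[-6]) {
    fd <- threshold_and_merge(F, tau, A1)
    expect_true(all(fd$Y_DTI >= A1))
    expect_true(all(fd$Y_DTI >= fd$Y_meta))
    expect_equal(unname(fd$Y_meta), unname((F >= tau) * 1))
  }
})
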