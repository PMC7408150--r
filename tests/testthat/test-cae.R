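test_that("aggregation is an element-wise product with dimension checks", {
  f1 <- array(runif(2 * 2 * 3), c(2, 2, 3))
  expect_identical(aggregate_features(f1, array(1, dim(f1))), f1)
  expect_equal(aggregate_features(f1, f1), f1^2)

  a <- array(c(1, 2), c(1, 1, 2))
  b <- array(c(3, 4), c(1, 1, 2))
  expect_equal(as.numeric(aggregate_features(a, b)), c(3, 8))
  expect_error(aggregate_features(f1, array(1, c(2, 2, 4))),
               class = "gliomap_input_error")
})

test_that("bilinear pooling equals the brute-force double sum and is symmetric", {
  ones <- array(1, c(2, 2, 3))
  expect_equal(bilinear_pool(ones), matrix(4, 3, 3))
  expect_equal(bilinear_pool(array(0, c(2, 2, 3))), matrix(0, 3, 3))

  set.seed(12)
  for (i in 1:100) {
    f <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
    H <- bilinear_pool(f)
    oracle <- matrix(0, 3, 3)
    for (r in 1:2) for (cl in 1:2) {
      v <- f[r, cl, ]
      oracle <- oracle + v %*% t(v)
    }
    expect_equal(H, oracle)
    expect_identical(max(abs(H - t(H))), 0)
  }
})

test_that("signed-sqrt L2 normalization has unit norm and fixed points", {
  v <- c(-4, 0, 9)
  u <- signed_sqrt_l2(v)
  expect_equal(sum(u^2), 1)
  expect_equal(u, c(-2, 0, 3) / sqrt(13))
  expect_equal(signed_sqrt_l2(rep(0, 4)), rep(0, 4))
})

test_that("encoder contracts shapes per spec and is deterministic", {
  spec <- toy_cae_spec(seed = 3)
  set.seed(3)
  cae <- gliomap:::build_cae(spec)
  img <- matrix(runif(16 * 16), 16, 16)
  f <- encode(cae, img)
  expect_identical(dim(f), c(4L, 4L, 16L))
  expect_identical(f, encode(cae, img))
  expect_equal(encode(cae, matrix(0, 16, 16)), array(0, c(4, 4, 16)))
  expect_error(encode(cae, matrix(0, 8, 8)), class = "gliomap_input_error")

  recon <- reconstruct(cae, img)
  expect_identical(dim(recon), c(16L, 16L, 1L, 1L))

  # untrained CAE, zero input: reconstruction MSE equals mean squared output
  z <- matrix(0, 16, 16)
  rz <- reconstruct(cae, z)
  expect_equal(mean((rz - 0)^2), mean(rz^2))
})

test_that("reconstruction pre-training reduces the loss", {
  set.seed(6)
  coh <- generate_cohort(toy_phantom(seed = 6, n_a = c(2, 2), n_b = c(2, 2),
                                     slices = 4))
  ds <- build_slice_dataset(coh, k = 3, out_size = 16, seed = 1)
  cae <- pretrain_cae(ds$x2, toy_cae_spec(seed = 2, epochs = 8))
  expect_true(cae$pretrained)
  expect_equal(nrow(cae$history), 8)
  expect_true(all(is.finite(cae$history$mse)))
  expect_lt(tail(cae$history$mse, 1), 0.5 * cae$history$mse[1])
})

test_that("refinement trains, early-stops and yields normalized probabilities", {
  coh <- generate_cohort(toy_phantom(seed = 31, n_a = c(3, 3), n_b = c(3, 3),
                                     slices = 5))
  ds <- build_slice_dataset(coh, k = 3, out_size = 16, seed = 1)
  sp <- split_toy_dataset(ds, seed = 1)
  set.seed(1)
  cae1 <- gliomap:::build_cae(toy_cae_spec(seed = 1))
  cae2 <- gliomap:::build_cae(toy_cae_spec(seed = 2))
  clf <- refine_train(cae1, cae2, sp$train, sp$val, epochs = 3, patience = 5,
                      batch_size = 8, fc_width = 16, seed = 3)
  expect_s3_class(clf, "glioma_classifier")
  expect_lte(clf$best_epoch, 3)
  expect_true(all(is.finite(clf$history$train_loss)))

  p <- predict(clf, sp$test)
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_true(all(p >= 0))
  expect_identical(p, predict(clf, sp$test))
  cls <- predict(clf, sp$test, type = "class")
  expect_identical(as.integer(p[, 2] > p[, 1]), cls)

  expect_error(predict(clf, list(x1 = sp$test$x1)),
               class = "gliomap_input_error")
  bad <- sp$train
  bad$x2 <- bad$x2[, , , 1:2, drop = FALSE]
  expect_error(refine_train(cae1, cae2, bad, NULL, epochs = 1),
               class = "gliomap_input_error")
})

test_that("a trained toy model fits most of its training samples", {
  coh <- generate_cohort(toy_phantom(seed = 41, n_a = c(2, 2), n_b = c(4, 4),
                                     slices = 5))
  b <- gliomap:::cohort_domain(coh, "B")
  ds <- build_slice_dataset(b, k = 4, out_size = 16, seed = 1)
  set.seed(9)
  cae1 <- gliomap:::build_cae(toy_cae_spec(seed = 4))
  cae2 <- gliomap:::build_cae(toy_cae_spec(seed = 5))
  clf <- refine_train(cae1, cae2, ds, val = NULL, epochs = 30, patience = 30,
                      batch_size = 8, fc_width = 32, lr = 1e-3,
                      augment = FALSE, seed = 6)
  acc_train <- mean(predict(clf, ds, type = "class") == ds$y)
  expect_gt(acc_train, 0.7)
})
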