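test_that("least-squares adversarial loss matches hand arithmetic", {
  expect_equal(lsgan_loss(d_real = c(1, 1), d_fake = c(0, 0)), 0)
  expect_equal(lsgan_loss(d_real = 0, d_fake = 1), 2)
  expect_equal(lsgan_loss(d_real = c(0.5, 1.0), d_fake = 0.5), 0.375)
  expect_equal(lsgan_loss(d_fake = c(1, 1), form = "generator"), 0)
  expect_equal(lsgan_loss(d_fake = 0.5, form = "generator"), 0.25)
  expect_error(lsgan_loss(d_real = Inf, d_fake = 0.5),
               class = "gliomap_input_error")
})

test_that("cycle-consistency loss has exact identity and shift behavior", {
  set.seed(2)
  a <- array(runif(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  b <- array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  ident <- function(x) x
  expect_equal(cycle_loss(a, b, ident, ident), 0)

  # one-directional +0.1 shift: G_B adds 0.1, G_A identity
  expect_equal(cycle_loss(a, b, G_A = ident, G_B = function(x) x + 0.1), 0.2)

  z <- array(0, c(2, 2, 1, 1))
  expect_equal(cycle_loss(z, z, function(x) x * 0, function(x) x * 0), 0)
  expect_error(cycle_loss(array(0, c(2, 2, 1, 0)), b, ident, ident),
               class = "gliomap_input_error")
})

test_that("total objective is additive in lambda", {
  expect_equal(total_objective(0.4, 0.6, 5, lambda = 0), 1.0)
  expect_equal(total_objective(0, 0, 0, lambda = 10), 0)
  expect_equal(total_objective(0.5, 0.3, 0.2, lambda = 10), 2.8)
  expect_error(total_objective(1, 1, 1, lambda = -1),
               class = "gliomap_config_error")
})

test_that("learning rate is constant then linearly decayed to zero", {
  spec <- cyclegan_spec(epochs = 150, lr_decay_start = 100, lr = 2e-4)
  expect_equal(cyclegan_lr(spec, 1), 2e-4)
  expect_equal(cyclegan_lr(spec, 100), 2e-4)
  expect_equal(cyclegan_lr(spec, 125), 1e-4)
  expect_equal(cyclegan_lr(spec, 150), 0)
})

test_that("generator preserves spatial size and discriminator scores lie in (0,1)", {
  spec <- toy_cyclegan_spec(seed = 8)
  set.seed(8)
  g <- gliomap:::build_generator(spec)
  d <- gliomap:::build_patch_discriminator(spec)
  x <- array(runif(32 * 32 * 1 * 2) * 2 - 1, c(32, 32, 1, 2))
  out <- gliomap:::net_predict(g, x)
  expect_identical(dim(out)[1:2], dim(x)[1:2])
  expect_identical(dim(out)[4], dim(x)[4])
  expect_true(all(out >= -1 & out <= 1))
  scores <- gliomap:::net_predict(d, x)
  expect_true(all(scores > 0 & scores < 1))
})

test_that("a one-epoch training run returns finite recorded losses", {
  set.seed(1)
  a <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  b <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  spec <- cyclegan_spec(image_size = 16, channels = 1, gen_filters = c(6),
                        n_resblocks = 1, disc_filters = c(6), epochs = 1,
                        lr_decay_start = 1, iters_per_epoch = 4, seed = 2)
  st <- train_cyclegan(a, b, spec)
  expect_equal(nrow(st$history), 1)
  expect_true(all(is.finite(unlist(st$history))))
  expect_true(all(st$history$gan_ab >= 0 & st$history$cyc >= 0))
})

test_that("mapping preserves slice count, dimensions and the [0,1] range", {
  set.seed(3)
  a <- lapply(1:5, function(i) matrix(runif(16 * 16), 16, 16))
  spec <- cyclegan_spec(image_size = 16, channels = 1, gen_filters = c(6),
                        n_resblocks = 1, disc_filters = c(6), epochs = 1,
                        lr_decay_start = 1, iters_per_epoch = 2, seed = 2)
  st <- train_cyclegan(a, a, spec)
  mapped <- map_domain(st, a)
  expect_identical(dim(mapped), c(16L, 16L, 1L, 5L))
  expect_true(all(mapped >= 0 & mapped <= 1))

  # identity generator stub: outputs equal inputs after the range round trip
  stub <- list(trained = TRUE, G_B = function(x) x, spec = list(channels = 1L))
  expect_equal(map_domain(stub, a)[, , 1, 2], a[[2]])
  expect_error(map_domain(list(trained = FALSE), a),
               class = "gliomap_input_error")
})

test_that("domain pooling adds cohort sizes and rejects duplicate ids", {
  fake_cohort <- function(ids) {
    structure(lapply(ids, function(i) list(patient_id = i)),
              class = "phantom_cohort")
  }
  a <- fake_cohort(sprintf("FR%03d", 1:82))
  b <- fake_cohort(sprintf("US%03d", 1:79))
  expect_length(combine_domains(a, b), 161)

  empty <- fake_cohort(character(0))
  expect_identical(lapply(combine_domains(empty, b), `[[`, "patient_id"),
                   lapply(b, `[[`, "patient_id"))
  expect_error(combine_domains(a, a), class = "gliomap_input_error")
})
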