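# Finite-difference gradient verification of the network engine. Each layer's
# analytic backward pass is checked against central differences on a random
# projection loss.

fd_gradcheck <- function(net, x, n_probe = 4, eps = 1e-5) {
  nf <- gliomap:::net_forward
  nb <- gliomap:::net_backward
  fwd <- nf(net, x, training = TRUE)
  set.seed(99)
  r <- array(rnorm(length(fwd$out)), dim(fwd$out))
  if (is.matrix(fwd$out)) r <- matrix(r, nrow(fwd$out))
  loss_of <- function(net2, x2 = x) sum(nf(net2, x2, training = TRUE)$out * r)
  bwd <- nb(net, fwd$caches, r)
  worst <- 0
  check <- function(get_p, set_p, g) {
    p <- get_p()
    for (i in sample(length(p), min(n_probe, length(p)))) {
      lp <- loss_of(set_p(i, p[i] + eps))
      lm <- loss_of(set_p(i, p[i] - eps))
      num <- (lp - lm) / (2 * eps)
      worst <<- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
    }
  }
  for (li in seq_along(net$layers)) {
    g <- bwd$grads[[li]]
    if (is.null(g)) next
    if (!is.null(g$sub)) {
      for (sj in seq_along(g$sub)) {
        gs <- g$sub[[sj]]
        if (is.null(gs)) next
        for (pn in names(gs)) {
          check(function() net$layers[[li]]$sub[[sj]]$par[[pn]],
                function(i, v) {
                  n2 <- net; n2$layers[[li]]$sub[[sj]]$par[[pn]][i] <- v; n2
                }, gs[[pn]])
        }
      }
    } else {
      for (pn in names(g)) {
        check(function() net$layers[[li]]$par[[pn]],
              function(i, v) {
                n2 <- net; n2$layers[[li]]$par[[pn]][i] <- v; n2
              }, g[[pn]])
      }
    }
  }
  for (i in sample(length(x), min(n_probe, length(x)))) {
    x2 <- x; x2[i] <- x[i] + eps; lp <- loss_of(net, x2)
    x2[i] <- x[i] - eps; lm <- loss_of(net, x2)
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - bwd$dx[i]) /
                   max(1e-6, abs(num) + abs(bwd$dx[i])))
  }
  worst
}

test_that("layer gradients match finite differences", {
  ns <- asNamespace("gliomap")
  set.seed(17)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  cases <- list(
    conv_s1 = list(ns$layer_conv(2, 4, k = 3)),
    conv_s2 = list(ns$layer_conv(2, 4, k = 3, stride = 2)),
    conv_reflect = list(ns$layer_conv(2, 3, k = 7, pad = 3,
                                      pad_mode = "reflect")),
    convt = list(ns$layer_convt(2, 4, k = 3, stride = 2)),
    batchnorm = list(ns$layer_bn(2)),
    instnorm = list(ns$layer_instnorm(2)),
    pool_lrelu = list(ns$layer_maxpool(), ns$layer_act("lrelu")),
    upsample_tanh = list(ns$layer_upsample(), ns$layer_act("tanh")),
    resblock = list(ns$layer_resblock(2))
  )
  for (nm in names(cases)) {
    worst <- fd_gradcheck(ns$net_init(cases[[nm]]), x)
    expect_lt(worst, 1e-4, label = sprintf("%s worst rel grad err", nm))
  }
})

test_that("composite network gradients match finite differences", {
  ns <- asNamespace("gliomap")
  set.seed(24)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  net <- ns$net_init(list(
    ns$layer_conv(1, 4, k = 3), ns$layer_bn(4), ns$layer_act("relu"),
    ns$layer_maxpool(), ns$layer_conv(4, 6, k = 3, stride = 2),
    ns$layer_act("lrelu"), ns$layer_flatten(), ns$layer_dense(2 * 2 * 6, 3)))
  expect_lt(fd_gradcheck(net, x), 1e-4)

  z <- matrix(runif(2 * 6), 2, 6)
  gen <- ns$net_init(list(
    ns$layer_dense(6, 2 * 2 * 4), ns$layer_act("relu"),
    ns$layer_reshape(c(2, 2, 4)), ns$layer_convt(4, 3, k = 4, stride = 2),
    ns$layer_bn(3), ns$layer_act("relu"), ns$layer_conv(3, 1, k = 3),
    ns$layer_act("tanh")))
  expect_lt(fd_gradcheck(gen, z), 1e-4)
})

test_that("adam steps reduce a simple regression loss", {
  ns <- asNamespace("gliomap")
  set.seed(5)
  x <- matrix(rnorm(40 * 3), 40, 3)
  yt <- x %*% c(1, -2, 0.5) + 0.3
  net <- ns$net_init(list(ns$layer_dense(3, 1, init = "he")))
  losses <- numeric(150)
  for (it in 1:150) {
    f <- ns$net_forward(net, x, TRUE)
    losses[it] <- mean((f$out - yt)^2)
    bk <- ns$net_backward(net, f$caches, 2 * (f$out - yt) / length(yt))
    net <- ns$net_adam_step(net, bk$grads, 0.05)
  }
  expect_lt(losses[150], 0.01 * losses[1])
})
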