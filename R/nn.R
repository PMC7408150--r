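# Minimal convolutional-network engine: plain-list layers, manual backprop,
# Adam updates. Images flow through as arrays (H, W, C, N); dense activations
# as matrices (N, features). Convolutions are im2col + BLAS matrix products
# (C++ kernels in src/convops.cpp). Written for the small networks this
# package trains; not a general-purpose framework.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- weight initializers ----

init_weight <- function(dims, scheme = c("gan", "he")) {
  scheme <- match.arg(scheme)
  n <- prod(dims)
  if (scheme == "gan") {
    w <- stats::rnorm(n, 0, 0.02)
  } else {
    fan_in <- if (length(dims) == 4L) prod(dims[1:3]) else dims[1L]
    w <- stats::rnorm(n, 0, sqrt(2 / fan_in))
  }
  array(w, dims)
}

# ---- layer constructors ----

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                       pad_mode = c("zero", "reflect"), init = "gan") {
  pad_mode <- match.arg(pad_mode)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), pad_mode = match(pad_mode, c("zero", "reflect")) - 1L,
       cin = cin, cout = cout,
       par = list(W = init_weight(c(k, k, cin, cout), init),
                  b = numeric(cout)),
       decay = c(W = TRUE, b = FALSE))
}

# Transposed convolution with stride s: output H,W = s * input H,W.
# Implemented as the adjoint of a strided convolution (pad 1, k in {3,4}).
layer_convt <- function(cin, cout, k = 4L, stride = 2L, init = "gan") {
  list(type = "convt", k = as.integer(k), stride = as.integer(stride),
       pad = 1L, cin = cin, cout = cout,
       par = list(W = init_weight(c(k, k, cout, cin), init),
                  b = numeric(cout)),
       decay = c(W = TRUE, b = FALSE))
}

layer_dense <- function(din, dout, init = "gan") {
  list(type = "dense", din = din, dout = dout,
       par = list(W = init_weight(c(din, dout), init), b = numeric(dout)),
       decay = c(W = TRUE, b = FALSE))
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       par = list(gamma = rep(1, c), beta = rep(0, c)),
       decay = c(gamma = FALSE, beta = FALSE),
       run_mean = rep(0, c), run_var = rep(1, c))
}

layer_instnorm <- function(c, eps = 1e-5) {
  list(type = "instnorm", c = c, eps = eps,
       par = list(gamma = rep(1, c), beta = rep(0, c)),
       decay = c(gamma = FALSE, beta = FALSE))
}

layer_act <- function(fun = c("relu", "lrelu", "tanh", "sigmoid"),
                      alpha = 0.2) {
  list(type = "act", fun = match.arg(fun), alpha = alpha)
}

layer_maxpool <- function() list(type = "maxpool")

layer_upsample <- function() list(type = "upsample")

layer_dropout <- function(p = 0.5) list(type = "dropout", p = p)

layer_flatten <- function() list(type = "flatten")

# reshape (N, prod(dims)) -> (dims, N)
layer_reshape <- function(dims) list(type = "reshape", dims = as.integer(dims))

# residual block: x + IN(conv(relu(IN(conv(x))))), reflect-padded 3x3 convs.
# The closing instance norm starts with gamma = 0 (zero-gamma residual init),
# so the block is an exact identity at initialization and the residual
# branch grows from zero during training.
layer_resblock <- function(c, init = "gan") {
  in2 <- layer_instnorm(c)
  in2$par$gamma <- rep(0, c)
  list(type = "resblock", c = c,
       sub = list(layer_conv(c, c, k = 3, pad_mode = "reflect", init = init),
                  layer_instnorm(c),
                  layer_act("relu"),
                  layer_conv(c, c, k = 3, pad_mode = "reflect", init = init),
                  in2))
}

net_init <- function(layers) {
  structure(list(layers = layers, t = 0L, opt = NULL), class = "gliomap_net")
}

# ---- forward ----

act_fwd <- function(x, fun, alpha) {
  switch(fun,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, alpha * x),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)))
}

act_bwd <- function(dout, out, fun, alpha) {
  switch(fun,
    relu = dout * (out > 0),
    lrelu = dout * ifelse(out > 0, 1, alpha),
    tanh = dout * (1 - out^2),
    sigmoid = dout * out * (1 - out))
}

conv_fwd <- function(layer, x) {
  d <- dim(x)
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (d[1] + 2L * p - k) %/% s + 1L
  Wo <- (d[2] + 2L * p - k) %/% s + 1L
  cols <- .im2col_batch(x, d[1], d[2], d[3], d[4], k, k, s, p, layer$pad_mode)
  Wmat <- matrix(layer$par$W, k * k * layer$cin, layer$cout)
  out <- cols %*% Wmat
  out <- out + rep(layer$par$b, each = nrow(out))
  out <- aperm(array(out, c(Ho, Wo, d[4], layer$cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(cols = cols, dims = d))
}

conv_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  k <- layer$k
  dm <- aperm(dout, c(1, 2, 4, 3))
  dm <- matrix(dm, ncol = layer$cout)
  dW <- array(crossprod(cache$cols, dm), dim(layer$par$W))
  db <- colSums(dm)
  Wmat <- matrix(layer$par$W, k * k * layer$cin, layer$cout)
  dx <- .col2im_batch(dm %*% t(Wmat), d[1], d[2], d[3], d[4],
                      k, k, layer$stride, layer$pad, layer$pad_mode)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

convt_fwd <- function(layer, x) {
  d <- dim(x)  # (h, w, cin, N)
  s <- layer$stride; k <- layer$k
  H <- d[1] * s; W <- d[2] * s
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = layer$cin)
  Wmat <- matrix(layer$par$W, k * k * layer$cout, layer$cin)
  out <- .col2im_batch(xm %*% t(Wmat), H, W, layer$cout, d[4],
                       k, k, s, layer$pad, 0L)
  dim(out) <- c(H, W, layer$cout, d[4])
  out <- sweep_bias4(out, layer$par$b)
  list(out = out, cache = list(xm = xm, dims = d, H = H, W = W))
}

# add per-channel bias to (H, W, C, N) array
sweep_bias4 <- function(x, b) {
  d <- dim(x)
  x + rep(rep(b, each = d[1] * d[2]), d[4])
}

convt_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  k <- layer$k
  cols <- .im2col_batch(dout, cache$H, cache$W, layer$cout, d[4],
                        k, k, layer$stride, layer$pad, 0L)
  Wmat <- matrix(layer$par$W, k * k * layer$cout, layer$cin)
  dxm <- cols %*% Wmat
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  dW <- array(crossprod(cols, cache$xm), dim(layer$par$W))
  db <- colSums(matrix(aperm(dout, c(1, 2, 4, 3)), ncol = layer$cout))
  list(dx = dx, grads = list(W = dW, b = db))
}

# Column-wise normalization core shared by batch/instance norm.
# x: (m, ncolumns); gamma/beta recycled to columns by `gidx`.
norm_fwd <- function(xm, gamma, beta, gidx, eps) {
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, gamma[gidx], `*`), 2, beta[gidx], `+`)
  list(out = out, xhat = xhat, istd = istd, mu = mu, v = v)
}

norm_bwd <- function(cache, dout, gamma, gidx) {
  m <- nrow(dout)
  dgamma_col <- colSums(dout * cache$xhat)
  dbeta_col <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma[gidx], `*`)
  # dx = (istd/m) * (m*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- m * dxhat
  t2 <- matrix(colSums(dxhat), m, ncol(dout), byrow = TRUE)
  t3 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2 - t3, 2, cache$istd / m, `*`)
  list(dx = dx, dgamma_col = dgamma_col, dbeta_col = dbeta_col)
}

bn_fwd <- function(layer, x, training) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = layer$c)  # channels as columns
  gidx <- seq_len(layer$c)
  if (training) {
    nf <- norm_fwd(xm, layer$par$gamma, layer$par$beta, gidx, layer$eps)
    out <- aperm(array(nf$out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    list(out = out, cache = list(nf = nf, dims = d, gidx = gidx),
         run_update = list(mean = nf$mu, var = nf$v))
  } else {
    xhat <- sweep(sweep(xm, 2, layer$run_mean), 2,
                  1 / sqrt(layer$run_var + layer$eps), `*`)
    out <- sweep(sweep(xhat, 2, layer$par$gamma, `*`), 2, layer$par$beta, `+`)
    out <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    list(out = out, cache = NULL)
  }
}

bn_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = layer$c)
  nb <- norm_bwd(cache$nf, dm, layer$par$gamma, cache$gidx)
  dx <- aperm(array(nb$dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = nb$dgamma_col, beta = nb$dbeta_col))
}

instnorm_fwd <- function(layer, x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2])          # columns ordered (c, n)
  gidx <- rep(seq_len(layer$c), d[4])
  nf <- norm_fwd(xm, layer$par$gamma, layer$par$beta, gidx, layer$eps)
  out <- nf$out
  dim(out) <- d
  list(out = out, cache = list(nf = nf, dims = d, gidx = gidx))
}

instnorm_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  dm <- matrix(dout, nrow = d[1] * d[2])
  nb <- norm_bwd(cache$nf, dm, layer$par$gamma, cache$gidx)
  dx <- nb$dx
  dim(dx) <- d
  list(dx = dx,
       grads = list(gamma = rowsum_vec(nb$dgamma_col, cache$gidx, layer$c),
                    beta = rowsum_vec(nb$dbeta_col, cache$gidx, layer$c)))
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample_bwd <- function(dout) {
  d <- dim(dout)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  dout[i1, j1, , , drop = FALSE] + dout[i2, j1, , , drop = FALSE] +
    dout[i1, j2, , , drop = FALSE] + dout[i2, j2, , , drop = FALSE]
}

# ---- network forward / backward ----

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    res <- switch(layer$type,
      conv = conv_fwd(layer, x),
      convt = convt_fwd(layer, x),
      dense = {
        out <- x %*% layer$par$W
        out <- sweep(out, 2, layer$par$b, `+`)
        list(out = out, cache = list(x = x))
      },
      bn = {
        r <- bn_fwd(layer, x, training)
        if (training) {
          m <- layer$momentum
          net$layers[[li]]$run_mean <- m * layer$run_mean + (1 - m) * r$run_update$mean
          net$layers[[li]]$run_var <- m * layer$run_var + (1 - m) * r$run_update$var
        }
        r
      },
      instnorm = instnorm_fwd(layer, x),
      act = {
        out <- act_fwd(x, layer$fun, layer$alpha)
        list(out = out, cache = list(out = out))
      },
      maxpool = {
        d <- dim(x)
        r <- .maxpool2_fwd(x, d[1], d[2], d[3], d[4])
        out <- r$out
        dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
        list(out = out, cache = list(idx = r$idx, input_len = length(x), dims = d))
      },
      upsample = list(out = upsample_fwd(x), cache = NULL),
      dropout = {
        if (training && layer$p > 0) {
          mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
          dim(mask) <- dim(x)
          list(out = x * mask, cache = list(mask = mask))
        } else list(out = x, cache = list(mask = NULL))
      },
      flatten = {
        d <- dim(x)
        nfeat <- prod(d[-length(d)])
        list(out = t(matrix(x, nfeat, d[length(d)])), cache = list(dims = d))
      },
      reshape = {
        n <- nrow(x)
        out <- array(t(x), c(layer$dims, n))
        list(out = out, cache = list(n = n))
      },
      resblock = {
        inner <- list(layers = layer$sub, t = 0L, opt = NULL)
        r <- net_forward(inner, x, training)
        list(out = x + r$out, cache = r$caches)
      },
      stop("unknown layer type: ", layer$type))
    x <- res$out
    caches[li] <- list(res$cache)
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    cache <- caches[[li]]
    res <- switch(layer$type,
      conv = conv_bwd(layer, cache, dout),
      convt = convt_bwd(layer, cache, dout),
      dense = list(dx = dout %*% t(layer$par$W),
                   grads = list(W = crossprod(cache$x, dout),
                                b = colSums(dout))),
      bn = bn_bwd(layer, cache, dout),
      instnorm = instnorm_bwd(layer, cache, dout),
      act = list(dx = act_bwd(dout, cache$out, layer$fun, layer$alpha)),
      maxpool = {
        dx <- .maxpool2_bwd(dout, cache$idx, cache$input_len)
        dim(dx) <- cache$dims
        list(dx = dx)
      },
      upsample = list(dx = upsample_bwd(dout)),
      dropout = {
        if (!is.null(cache$mask)) list(dx = dout * cache$mask)
        else list(dx = dout)
      },
      flatten = {
        dx <- array(t(dout), cache$dims)
        list(dx = dx)
      },
      reshape = list(dx = t(matrix(dout, ncol = cache$n))),
      resblock = {
        inner <- list(layers = layer$sub, t = 0L, opt = NULL)
        r <- net_backward(inner, cache, dout)
        list(dx = dout + r$dx, grads = list(sub = r$grads))
      })
    dout <- res$dx
    grads[li] <- list(res$grads)
  }
  list(dx = dout, grads = grads)
}

# ---- Adam ----

opt_init_layer <- function(layer) {
  if (layer$type == "resblock") return(lapply(layer$sub, opt_init_layer))
  if (is.null(layer$par)) return(NULL)
  lapply(layer$par, function(p) list(m = p * 0, v = p * 0))
}

adam_update_layer <- function(layer, g, opt, lr, beta1, beta2, bc1, bc2,
                              eps, weight_decay) {
  if (layer$type == "resblock") {
    for (sj in seq_along(layer$sub)) {
      if (is.null(g$sub[[sj]])) next
      r <- adam_update_layer(layer$sub[[sj]], g$sub[[sj]], opt[[sj]],
                             lr, beta1, beta2, bc1, bc2, eps, weight_decay)
      layer$sub[[sj]] <- r$layer
      opt[[sj]] <- r$opt
    }
    return(list(layer = layer, opt = opt))
  }
  for (pn in names(g)) {
    gg <- g[[pn]]
    if (weight_decay > 0 && isTRUE(layer$decay[[pn]]))
      gg <- gg + weight_decay * layer$par[[pn]]
    st <- opt[[pn]]
    st$m <- beta1 * st$m + (1 - beta1) * gg
    st$v <- beta2 * st$v + (1 - beta2) * gg^2
    opt[[pn]] <- st
    layer$par[[pn]] <- layer$par[[pn]] -
      lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
  }
  list(layer = layer, opt = opt)
}

net_adam_step <- function(net, grads, lr, beta1 = 0.5, beta2 = 0.999,
                          eps = 1e-8, weight_decay = 0) {
  if (is.null(net$opt)) net$opt <- lapply(net$layers, opt_init_layer)
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t
  bc2 <- 1 - beta2^net$t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    r <- adam_update_layer(net$layers[[li]], g, net$opt[[li]],
                           lr, beta1, beta2, bc1, bc2, eps, weight_decay)
    net$layers[[li]] <- r$layer
    net$opt[li] <- list(r$opt)
  }
  net
}

# run forward in inference mode, return output only
net_predict <- function(net, x) net_forward(net, x, training = FALSE)$out

# scale a list of per-layer grads by a scalar
grads_scale <- function(grads, s) {
  lapply(grads, function(g) if (is.null(g)) NULL else lapply(g, function(p) p * s))
}

grads_add <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  if (!is.list(g1)) return(g1 + g2)
  out <- vector("list", length(g1))
  names(out) <- names(g1)
  for (i in seq_along(g1)) out[i] <- list(grads_add(g1[[i]], g2[[i]]))
  out
}

# deterministic local RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
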