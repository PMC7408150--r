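# Deep convolutional GAN for enlarging the pre-training set: a generator
# maps a 100-dimensional uniform noise vector to a tumor slice through a
# dense projection and stride-2 transposed convolutions; the discriminator
# is a stride-2 convolutional stack ending in a single probability. Trained
# with binary cross-entropy until the discriminator output approaches the
# 0.5 equilibrium.

#' DCGAN specification
#'
#' Defaults follow the published architecture: z of 100 uniform samples,
#' dense projection to `(image_size/8)^2 x 1024` followed by three stride-2
#' transposed convolutions (512, 256, 128 filters, 4x4 kernels, batch norm,
#' ReLU) and a final convolution to `channels` with Tanh; discriminator with
#' four stride-2 5x5 convolutions (128, 256, 512, 1024 filters, batch norm,
#' LeakyReLU 0.2) and a dense sigmoid head. Adam at learning rate 0.002 with
#' minibatch 64 and binary cross-entropy. The final generator convolution
#' uses a 3x3 kernel so the output keeps the transposed-convolution size
#' with symmetric padding.
#'
#' @param image_size generator output pixels per side (divisible by 8).
#' @param channels generator output channels.
#' @param z_dim noise dimension (uniform on `[-1, 1]`).
#' @param g_dense_channels channels of the dense projection.
#' @param g_filters transposed-convolution filter counts (3 stride-2 stages).
#' @param d_filters discriminator filter counts (stride-2 stages).
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param equilibrium_tol stop early once the epoch means of
#'   `|D(real) - 0.5|` and `|D(fake) - 0.5|` both fall below this tolerance.
#' @param seed RNG seed.
#' @return object of class `dcgan_spec`.
#' @export
dcgan_spec <- function(image_size = 128L, channels = 3L, z_dim = 100L,
                       g_dense_channels = 1024L,
                       g_filters = c(512L, 256L, 128L),
                       d_filters = c(128L, 256L, 512L, 1024L),
                       lr = 0.002, beta1 = 0.5, beta2 = 0.999,
                       batch_size = 64L, epochs = 50L,
                       equilibrium_tol = 0.05, seed = 1L) {
  image_size <- as.integer(image_size)
  stages <- length(g_filters)
  if (image_size %% (2L^stages) != 0L)
    config_error("image_size must be divisible by 2^length(g_filters)")
  structure(list(image_size = image_size, channels = as.integer(channels),
                 z_dim = as.integer(z_dim),
                 g_dense_channels = as.integer(g_dense_channels),
                 g_filters = as.integer(g_filters),
                 d_filters = as.integer(d_filters),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 equilibrium_tol = equilibrium_tol,
                 seed = as.integer(seed)),
            class = "dcgan_spec")
}

build_dcgan_generator <- function(spec) {
  hw <- spec$image_size %/% (2L^length(spec$g_filters))
  c0 <- spec$g_dense_channels
  layers <- list(layer_dense(spec$z_dim, hw * hw * c0),
                 layer_act("relu"),
                 layer_reshape(c(hw, hw, c0)))
  cin <- c0
  for (f in spec$g_filters) {
    layers <- c(layers, list(layer_convt(cin, f, k = 4, stride = 2),
                             layer_bn(f), layer_act("relu")))
    cin <- f
  }
  layers <- c(layers, list(layer_conv(cin, spec$channels, k = 3),
                           layer_act("tanh")))
  net_init(layers)
}

# ends at logits (no sigmoid layer): the BCE gradient is computed on the
# logit scale for numerical stability; probabilities via dcgan_discriminate()
build_dcgan_discriminator <- function(spec) {
  layers <- list()
  cin <- spec$channels
  hw <- spec$image_size
  for (f in spec$d_filters) {
    layers[[length(layers) + 1L]] <- layer_conv(cin, f, k = 5, stride = 2, pad = 2)
    layers[[length(layers) + 1L]] <- layer_bn(f)
    layers[[length(layers) + 1L]] <- layer_act("lrelu", alpha = 0.2)
    cin <- f
    hw <- hw %/% 2L
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(hw * hw * cin, 1L)))
  net_init(layers)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Binary cross-entropy GAN losses
#'
#' `loss_D = -mean(log d_real) - mean(log(1 - d_fake))`; the generator loss
#' is the non-saturating form `-mean(log d_fake)` by default, with the
#' saturating form `mean(log(1 - d_fake))` as an option. Probabilities at
#' exactly 0 or 1 are clamped by `eps`.
#'
#' @param d_real,d_fake discriminator probabilities on real and generated
#'   images.
#' @param saturating use the saturating generator form.
#' @param eps clamping constant.
#' @return list with `loss_d` and `loss_g`.
#' @export
dcgan_loss <- function(d_real, d_fake, saturating = FALSE, eps = 1e-7) {
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  list(loss_d = -mean(log(d_real)) - mean(log(1 - d_fake)),
       loss_g = if (saturating) mean(log(1 - d_fake)) else -mean(log(d_fake)))
}

#' Discriminator probability for images
#'
#' @param state a `dcgan_state`.
#' @param images `(H, W, C, N)` array in generator range `[-1, 1]`.
#' @return vector of probabilities in (0, 1).
#' @export
dcgan_discriminate <- function(state, images) {
  as.numeric(sigmoid(net_predict(state$D, images)))
}

#' Train a DCGAN on tumor slices
#'
#' Alternating Adam updates with binary cross-entropy: the discriminator is
#' trained against real images and detached generator samples, the generator
#' against the non-saturating objective. Training stops at `spec$epochs` or
#' as soon as the epoch means of `|D(real) - 0.5|` and `|D(fake) - 0.5|`
#' fall below `spec$equilibrium_tol` (the Nash-equilibrium criterion).
#'
#' @param images list of matrices or `(H, W, 1, N)` array in `[0, 1]`, one
#'   modality/class subset.
#' @param spec a [dcgan_spec()].
#' @param verbose print per-epoch discriminator means.
#' @return object of class `dcgan_state`: generator `G`, discriminator `D`,
#'   per-epoch history of mean `D(real)` and `D(fake)`, and `stopped_epoch`.
#' @export
train_dcgan <- function(images, spec = dcgan_spec(), verbose = FALSE) {
  x <- as_image_batch(images)
  n <- dim(x)[4]
  if (dim(x)[1] != spec$image_size)
    config_error("image size does not match spec$image_size")
  bs <- spec$batch_size
  if (n < bs) {
    warning(sprintf("only %d images for batch size %d; shrinking batch", n, bs))
    bs <- n
  }
  with_seed(spec$seed, {
    G <- build_dcgan_generator(spec)
    D <- build_dcgan_discriminator(spec)
    hist <- vector("list", spec$epochs)
    stopped <- spec$epochs
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_dr <- ep_df <- 0; nb <- 0L
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        idx <- ord[start:(start + bs - 1L)]
        xr <- to_gen_range(x[, , , idx, drop = FALSE], spec$channels)
        z <- matrix(runif(bs * spec$z_dim, -1, 1), bs, spec$z_dim)
        gf <- net_forward(G, z, TRUE)
        G <- gf$net  # batch-norm running stats

        # discriminator step (generator output detached)
        dr <- net_forward(D, xr, TRUE); D <- dr$net
        df <- net_forward(D, gf$out, TRUE); D <- df$net
        p_r <- sigmoid(dr$out); p_f <- sigmoid(df$out)
        gd <- net_backward(D, dr$caches, (p_r - 1) / bs)$grads
        gd <- grads_add(gd, net_backward(D, df$caches, p_f / bs)$grads)
        D <- net_adam_step(D, gd, spec$lr, spec$beta1, spec$beta2)

        # generator step (non-saturating): fresh z through updated D
        z2 <- matrix(runif(bs * spec$z_dim, -1, 1), bs, spec$z_dim)
        gf2 <- net_forward(G, z2, TRUE); G <- gf2$net
        df2 <- net_forward(D, gf2$out, TRUE)
        gproxy <- (sigmoid(df2$out) - 1) / bs
        dxg <- net_backward(D, df2$caches, gproxy)$dx
        gg <- net_backward(G, gf2$caches, dxg)$grads
        G <- net_adam_step(G, gg, spec$lr, spec$beta1, spec$beta2)

        ep_dr <- ep_dr + mean(p_r); ep_df <- ep_df + mean(p_f)
        nb <- nb + 1L
      }
      hist[[epoch]] <- data.frame(epoch = epoch, d_real = ep_dr / nb,
                                  d_fake = ep_df / nb)
      if (verbose)
        message(sprintf("epoch %d: D(real) %.3f D(fake) %.3f",
                        epoch, ep_dr / nb, ep_df / nb))
      if (abs(ep_dr / nb - 0.5) < spec$equilibrium_tol &&
          abs(ep_df / nb - 0.5) < spec$equilibrium_tol) {
        stopped <- epoch
        break
      }
    }
    structure(list(G = G, D = D, spec = spec,
                   history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                   stopped_epoch = stopped, trained = TRUE),
              class = "dcgan_state")
  })
}

#' Sample augmented images from a trained DCGAN
#'
#' Draws `n` noise vectors from Uniform(-1, 1)^z_dim, runs the generator in
#' inference mode, averages channels and rescales the Tanh output to
#' `[0, 1]`. Deterministic under `seed`.
#'
#' @param state a trained `dcgan_state`.
#' @param n number of images.
#' @param seed RNG seed.
#' @param chunk forward-pass batch size.
#' @return `(H, W, 1, n)` array.
#' @export
sample_augmented <- function(state, n, seed = 1L, chunk = 16L) {
  if (!isTRUE(state$trained)) input_error("state is not a trained dcgan_state")
  sz <- state$spec$image_size
  out <- array(0, c(sz, sz, 1L, n))
  if (n == 0L) return(out)
  with_seed(seed, {
    z <- matrix(runif(n * state$spec$z_dim, -1, 1), n, state$spec$z_dim)
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      y <- net_predict(state$G, z[idx, , drop = FALSE])
      out[, , , idx] <- from_gen_range(y)
    }
  })
  out
}
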