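# Unpaired cycle-consistent adversarial domain mapping between two scanner
# domains. Two generators (A->B and B->A) with a residual-block architecture
# and instance normalization are trained against two patch-level
# discriminators under a least-squares adversarial loss plus an L1
# cycle-consistency penalty; the mapped source domain is pooled with the
# target domain for downstream classification.

#' CycleGAN specification
#'
#' Architecture and optimization hyperparameters for the unpaired domain
#' mapper. Defaults follow the published configuration: generator encoder
#' filters 32/64/128, nine 128-filter residual blocks, transposed-convolution
#' decoder 64/32, Tanh output; discriminator filters 64/128/256/512/1 with
#' 4x4 kernels, LeakyReLU(0.2) and sigmoid patch outputs; Adam with learning
#' rate 2e-4 decayed linearly to zero after epoch 100 of 150.
#'
#' @param image_size input/output pixels per side.
#' @param channels generator I/O channels; grayscale slices are replicated on
#'   input and averaged back on output.
#' @param gen_filters encoder filter counts (decoder mirrors them).
#' @param n_resblocks residual blocks at the bottleneck.
#' @param disc_filters discriminator filter counts (stride-2 4x4 layers).
#' @param lambda cycle-consistency weight.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param epochs training epochs; `lr_decay_start` is the epoch after which
#'   the rate decays linearly to zero at `epochs`.
#' @param iters_per_epoch image pairs sampled per epoch (defaults to the
#'   larger domain size).
#' @param batch_size minibatch size.
#' @param residual add a global input-to-output skip so the generator learns
#'   a residual correction to its input (`tanh(x + body(x))`, with the body's
#'   closing convolution initialized at zero so the map starts near the
#'   identity). Useful for intensity harmonization at reduced scale; `FALSE`
#'   is the published architecture.
#' @param seed RNG seed for initialization and batch sampling.
#' @return object of class `cyclegan_spec`.
#' @export
cyclegan_spec <- function(image_size = 128L, channels = 3L,
                          gen_filters = c(32L, 64L, 128L), n_resblocks = 9L,
                          disc_filters = c(64L, 128L, 256L, 512L),
                          lambda = 10, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                          epochs = 150L, lr_decay_start = 100L,
                          iters_per_epoch = NULL, batch_size = 1L,
                          residual = FALSE, seed = 1L) {
  if (lambda < 0) config_error("lambda must be >= 0")
  stages <- length(gen_filters) - 1L
  if (image_size %% (2L^stages) != 0L)
    config_error("image_size must be divisible by 2^(stride-2 stages)")
  structure(list(image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 gen_filters = as.integer(gen_filters),
                 n_resblocks = as.integer(n_resblocks),
                 disc_filters = as.integer(disc_filters),
                 lambda = lambda, lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 lr_decay_start = as.integer(lr_decay_start),
                 iters_per_epoch = iters_per_epoch,
                 batch_size = as.integer(batch_size),
                 residual = isTRUE(residual),
                 seed = as.integer(seed)),
            class = "cyclegan_spec")
}

# encoder: 7x7 stem then one stride-2 stage per additional filter entry;
# residual blocks at the bottleneck; mirrored transposed-convolution decoder
build_generator <- function(spec) {
  f <- spec$gen_filters
  ch <- spec$channels
  layers <- list(
    layer_conv(ch, f[1], k = 7, pad = 3, pad_mode = "reflect"),
    layer_instnorm(f[1]), layer_act("relu"))
  for (i in seq_along(f)[-1]) {
    layers <- c(layers, list(layer_conv(f[i - 1], f[i], k = 3, stride = 2),
                             layer_instnorm(f[i]), layer_act("relu")))
  }
  bott <- f[length(f)]
  for (i in seq_len(spec$n_resblocks))
    layers[[length(layers) + 1L]] <- layer_resblock(bott)
  for (i in rev(seq_along(f)[-1])) {
    layers <- c(layers, list(layer_convt(f[i], f[i - 1], k = 3, stride = 2),
                             layer_instnorm(f[i - 1]), layer_act("relu")))
  }
  out_conv <- layer_conv(f[1], ch, k = 7, pad = 3, pad_mode = "reflect")
  if (isTRUE(spec$residual)) {
    out_conv$par$W[] <- 0
    body <- c(layers, list(out_conv))
    layers <- list(list(type = "resblock", c = ch, sub = body))
  } else {
    layers <- c(layers, list(out_conv))
  }
  net_init(c(layers, list(layer_act("tanh"))))
}

build_patch_discriminator <- function(spec) {
  f <- spec$disc_filters
  cin <- spec$channels
  layers <- list()
  for (i in seq_along(f)) {
    layers[[length(layers) + 1L]] <- layer_conv(cin, f[i], k = 4, stride = 2, pad = 1)
    if (i > 1) layers[[length(layers) + 1L]] <- layer_instnorm(f[i])
    layers[[length(layers) + 1L]] <- layer_act("lrelu", alpha = 0.2)
    cin <- f[i]
  }
  layers <- c(layers, list(layer_conv(cin, 1L, k = 4, stride = 1, pad = 1),
                           layer_act("sigmoid")))
  net_init(layers)
}

#' Least-squares adversarial loss
#'
#' Squared-error adversarial objective on discriminator patch scores. The
#' discriminator form is `mean((d_real - 1)^2) + mean(d_fake^2)`; the
#' generator form is `mean((d_fake - 1)^2)`.
#'
#' @param d_real discriminator scores on real images (ignored for the
#'   generator form).
#' @param d_fake discriminator scores on generated images.
#' @param form `"discriminator"` or `"generator"`.
#' @return nonnegative scalar.
#' @export
lsgan_loss <- function(d_real = NULL, d_fake,
                       form = c("discriminator", "generator")) {
  form <- match.arg(form)
  if (!all(is.finite(d_fake)) ||
      (!is.null(d_real) && !all(is.finite(d_real))))
    input_error("discriminator scores must be finite")
  if (form == "generator") return(mean((d_fake - 1)^2))
  if (is.null(d_real)) input_error("d_real required for the discriminator form")
  mean((d_real - 1)^2) + mean(d_fake^2)
}

#' Cycle-consistency loss
#'
#' Mean absolute error of the two round trips:
#' `mean|G_A(G_B(a)) - a| + mean|G_B(G_A(b)) - b|` (per-pixel means).
#'
#' @param a_batch,b_batch arrays of domain-A and domain-B images.
#' @param G_A,G_B functions mapping an image array to an image array
#'   (B->A and A->B respectively).
#' @return nonnegative scalar; exactly 0 when both maps are identities.
#' @export
cycle_loss <- function(a_batch, b_batch, G_A, G_B) {
  if (length(a_batch) == 0L || length(b_batch) == 0L)
    input_error("batches must be non-empty")
  mean(abs(G_A(G_B(a_batch)) - a_batch)) +
    mean(abs(G_B(G_A(b_batch)) - b_batch))
}

#' Total CycleGAN objective
#'
#' `L_GAN(G_B, D_B, A, B) + L_GAN(G_A, D_A, B, A) + lambda * L_cyc`,
#' minimized over generators and maximized over discriminators by
#' alternating updates.
#'
#' @param gan_ab,gan_ba adversarial loss components for the two directions.
#' @param cyc cycle-consistency component.
#' @param lambda cycle weight (>= 0).
#' @return scalar objective value.
#' @export
total_objective <- function(gan_ab, gan_ba, cyc, lambda = 10) {
  if (lambda < 0) config_error("lambda must be >= 0")
  gan_ab + gan_ba + lambda * cyc
}

#' Learning-rate schedule
#'
#' Constant at `spec$lr` through `lr_decay_start`, then linearly decayed to
#' zero at `spec$epochs`.
#'
#' @param spec a [cyclegan_spec()].
#' @param epoch 1-based epoch number.
#' @return learning rate for that epoch.
#' @export
cyclegan_lr <- function(spec, epoch) {
  if (epoch <= spec$lr_decay_start) return(spec$lr)
  spec$lr * max(0, (spec$epochs - epoch) / (spec$epochs - spec$lr_decay_start))
}

# images in [0,1], (H,W,1,N) -> generator range [-1,1] with channel
# replication; and the inverse
to_gen_range <- function(x, channels) {
  x <- x * 2 - 1
  if (channels > 1L) {
    d <- dim(x)
    x <- array(x[, , rep(1L, channels), , drop = FALSE], c(d[1], d[2], channels, d[4]))
  }
  x
}

from_gen_range <- function(x) {
  d <- dim(x)
  if (d[3] > 1L) {
    y <- x[, , 1L, , drop = FALSE]
    for (c in 2:d[3]) y <- y + x[, , c, , drop = FALSE]
    x <- y / d[3]
  }
  pmin(pmax((x + 1) / 2, 0), 1)
}

as_image_batch <- function(x) {
  if (is.list(x)) {
    n <- length(x)
    array(unlist(x), c(nrow(x[[1]]), ncol(x[[1]]), 1L, n))
  } else if (length(dim(x)) == 2L) {
    array(x, c(dim(x), 1L, 1L))
  } else x
}

#' Train an unpaired CycleGAN between two image domains
#'
#' Alternating Adam updates: generators minimize the least-squares
#' adversarial losses plus `lambda` times the L1 cycle-consistency loss;
#' discriminators minimize the least-squares real/fake objective. The
#' learning rate follows [cyclegan_lr()]. No pairing between the domains is
#' assumed.
#'
#' @param domain_a,domain_b lists of matrices or `(H, W, 1, N)` arrays of
#'   slices in `[0, 1]`.
#' @param spec a [cyclegan_spec()].
#' @param verbose print per-epoch losses.
#' @return object of class `cyclegan_state` with the four networks and a
#'   per-epoch history of the recorded loss components (`gan_ab`, `gan_ba`,
#'   `cyc`, `lr`).
#' @export
train_cyclegan <- function(domain_a, domain_b, spec = cyclegan_spec(),
                           verbose = FALSE) {
  a <- as_image_batch(domain_a)
  b <- as_image_batch(domain_b)
  if (dim(a)[4] == 0L || dim(b)[4] == 0L)
    input_error("both domains must be non-empty")
  if (dim(a)[1] != spec$image_size || dim(b)[1] != spec$image_size)
    config_error("image size does not match spec$image_size")
  na <- dim(a)[4]; nb <- dim(b)[4]
  iters <- spec$iters_per_epoch %||% max(na, nb)
  bs <- spec$batch_size

  with_seed(spec$seed, {
    G_B <- build_generator(spec)  # A -> B
    G_A <- build_generator(spec)  # B -> A
    D_B <- build_patch_discriminator(spec)
    D_A <- build_patch_discriminator(spec)
    hist <- vector("list", spec$epochs)

    for (epoch in seq_len(spec$epochs)) {
      lr <- cyclegan_lr(spec, epoch)
      ep_gan_ab <- ep_gan_ba <- ep_cyc <- 0
      for (it in seq_len(iters)) {
        ia <- sample.int(na, bs, replace = bs > na)
        ib <- sample.int(nb, bs, replace = bs > nb)
        xa <- to_gen_range(a[, , , ia, drop = FALSE], spec$channels)
        xb <- to_gen_range(b[, , , ib, drop = FALSE], spec$channels)

        # ---- generator update ----
        fb <- net_forward(G_B, xa, TRUE)   # fake B
        fa <- net_forward(G_A, xb, TRUE)   # fake A
        ra <- net_forward(G_A, fb$out, TRUE)  # reconstructed a
        rb <- net_forward(G_B, fa$out, TRUE)  # reconstructed b
        db_f <- net_forward(D_B, fb$out, TRUE)
        da_f <- net_forward(D_A, fa$out, TRUE)

        g_adv_b <- 2 * (db_f$out - 1) / length(db_f$out)
        d_fb_adv <- net_backward(D_B, db_f$caches, g_adv_b)$dx
        g_cyc_a <- spec$lambda * sign(ra$out - xa) / length(ra$out)
        bk_ga1 <- net_backward(G_A, ra$caches, g_cyc_a)
        bk_gb1 <- net_backward(G_B, fb$caches, d_fb_adv + bk_ga1$dx)

        g_adv_a <- 2 * (da_f$out - 1) / length(da_f$out)
        d_fa_adv <- net_backward(D_A, da_f$caches, g_adv_a)$dx
        g_cyc_b <- spec$lambda * sign(rb$out - xb) / length(rb$out)
        bk_gb2 <- net_backward(G_B, rb$caches, g_cyc_b)
        bk_ga2 <- net_backward(G_A, fa$caches, d_fa_adv + bk_gb2$dx)

        G_A <- net_adam_step(G_A, grads_add(bk_ga1$grads, bk_ga2$grads),
                             lr, spec$beta1, spec$beta2)
        G_B <- net_adam_step(G_B, grads_add(bk_gb1$grads, bk_gb2$grads),
                             lr, spec$beta1, spec$beta2)

        # ---- discriminator update (fakes detached); the discriminator
        # objective is halved, the usual slowing of D relative to G ----
        db_r <- net_forward(D_B, xb, TRUE)
        db_f2 <- net_forward(D_B, fb$out, TRUE)
        gd <- net_backward(D_B, db_r$caches, (db_r$out - 1) / length(db_r$out))$grads
        gd <- grads_add(gd, net_backward(D_B, db_f2$caches,
                                         db_f2$out / length(db_f2$out))$grads)
        D_B <- net_adam_step(D_B, gd, lr, spec$beta1, spec$beta2)

        da_r <- net_forward(D_A, xa, TRUE)
        da_f2 <- net_forward(D_A, fa$out, TRUE)
        gd <- net_backward(D_A, da_r$caches, (da_r$out - 1) / length(da_r$out))$grads
        gd <- grads_add(gd, net_backward(D_A, da_f2$caches,
                                         da_f2$out / length(da_f2$out))$grads)
        D_A <- net_adam_step(D_A, gd, lr, spec$beta1, spec$beta2)

        ep_gan_ab <- ep_gan_ab + lsgan_loss(db_r$out, db_f2$out)
        ep_gan_ba <- ep_gan_ba + lsgan_loss(da_r$out, da_f2$out)
        ep_cyc <- ep_cyc + mean(abs(ra$out - xa)) + mean(abs(rb$out - xb))
      }
      hist[[epoch]] <- data.frame(epoch = epoch, gan_ab = ep_gan_ab / iters,
                                  gan_ba = ep_gan_ba / iters,
                                  cyc = ep_cyc / iters, lr = lr)
      if (verbose)
        message(sprintf("epoch %d: gan_ab %.4f gan_ba %.4f cyc %.4f",
                        epoch, ep_gan_ab / iters, ep_gan_ba / iters,
                        ep_cyc / iters))
    }
    structure(list(G_A = G_A, G_B = G_B, D_A = D_A, D_B = D_B,
                   spec = spec, history = do.call(rbind, hist),
                   trained = TRUE),
              class = "cyclegan_state")
  })
}

#' Map source-domain slices onto the target domain
#'
#' Applies the trained A-to-B generator to each slice and rescales the Tanh
#' output back to `[0, 1]`.
#'
#' @param state a trained `cyclegan_state` (for testing, `state$G_B` may be a
#'   plain function on image arrays).
#' @param slices list of matrices or `(H, W, 1, N)` array.
#' @param chunk forward-pass batch size.
#' @return `(H, W, 1, N)` array of mapped slices; count equals input count.
#' @export
map_domain <- function(state, slices, chunk = 8L) {
  if (!isTRUE(state$trained)) input_error("state is not a trained cyclegan_state")
  x <- as_image_batch(slices)
  n <- dim(x)[4]
  out <- array(0, dim(x))
  channels <- state$spec$channels %||% 1L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xb <- to_gen_range(x[, , , idx, drop = FALSE], channels)
    yb <- if (is.function(state$G_B)) state$G_B(xb) else net_predict(state$G_B, xb)
    out[, , , idx] <- from_gen_range(yb)
  }
  out
}

#' Map every slice of a cohort onto the target domain
#'
#' Runs [map_domain()] over both modalities of each patient, keeping masks,
#' labels and patient ids unchanged (the mapping is intensity-only).
#'
#' @param cohort a `phantom_cohort` (typically the domain-A subset).
#' @param states named list of trained `cyclegan_state`s, one per modality
#'   (`T1ce`, `FLAIR`); a single state is recycled for both.
#' @return the cohort with mapped slices; patients gain `mapped = TRUE`.
#' @export
map_cohort <- function(cohort, states) {
  if (inherits(states, "cyclegan_state"))
    states <- list(T1ce = states, FLAIR = states)
  mapped <- lapply(cohort, function(p) {
    for (mod in names(p$slices)) {
      st <- states[[mod]] %||% states[[1L]]
      arr <- map_domain(st, p$slices[[mod]])
      p$slices[[mod]] <- lapply(seq_len(dim(arr)[4]), function(i) arr[, , 1L, i])
    }
    p$mapped <- TRUE
    p
  })
  structure(mapped, class = "phantom_cohort", config = attr(cohort, "config"))
}

#' Pool the mapped source cohort with the target cohort
#'
#' Concatenates two cohorts into the combined dataset used downstream,
#' preserving patient ids and labels. Patient ids must not overlap.
#'
#' @param mapped_a,b `phantom_cohort` objects.
#' @return a `phantom_cohort` with `length(mapped_a) + length(b)` patients.
#' @export
combine_domains <- function(mapped_a, b) {
  ids <- c(vapply(mapped_a, function(p) p$patient_id, character(1)),
           vapply(b, function(p) p$patient_id, character(1)))
  if (anyDuplicated(ids))
    input_error("duplicate patient_id across domains")
  structure(c(unclass(mapped_a), unclass(b)), class = "phantom_cohort",
            config = attr(b, "config") %||% attr(mapped_a, "config"))
}
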