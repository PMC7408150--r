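# Two-stream convolutional autoencoder classifier. Each modality stream is a
# CAE whose encoder maps a 64x64 tumor crop to an 8x8x512 feature map (three
# max-pool stages). Stage 1 trains each stream unsupervised on GAN-augmented
# slices (mean squared reconstruction error); stage 2 discards the decoders,
# fuses the two encoder outputs by element-wise aggregation and bilinear
# pooling, and fine-tunes encoders plus a fully connected softmax head on
# labeled slices with categorical cross-entropy.

#' Convolutional autoencoder specification
#'
#' Defaults follow the published single-stream architecture: encoder of six
#' 3x3 convolutions with filters 64/128/128/256/256/512 and max-pooling
#' after convolutions 2, 3 and 5 (64x64x1 input to 8x8x512 feature map);
#' decoder of five 3x3 convolutions (256/256/128/128/1) with three nearest
#' upsamplings back to 64x64x1; L2 penalty 1e-4 on convolution weights; Adam
#' at learning rate 0.002, minibatch 16, 200 epochs of reconstruction
#' pre-training.
#'
#' @param input_size crop pixels per side.
#' @param enc_filters encoder convolution filter counts.
#' @param pool_after 1-based indices of encoder convolutions followed by
#'   2x2 max pooling.
#' @param dec_filters decoder convolution filter counts (last must be 1).
#' @param up_before 1-based indices of decoder convolutions preceded by 2x
#'   nearest upsampling (same count as `pool_after`).
#' @param l2 weight penalty on convolution weights.
#' @param lr,beta1,beta2 Adam hyperparameters for pre-training.
#' @param batch_size pre-training minibatch size.
#' @param epochs pre-training epochs.
#' @param seed RNG seed.
#' @return object of class `cae_spec`.
#' @export
cae_spec <- function(input_size = 64L,
                     enc_filters = c(64L, 128L, 128L, 256L, 256L, 512L),
                     pool_after = c(2L, 3L, 5L),
                     dec_filters = c(256L, 256L, 128L, 128L, 1L),
                     up_before = c(1L, 3L, 4L),
                     l2 = 1e-4, lr = 0.002, beta1 = 0.5, beta2 = 0.999,
                     batch_size = 16L, epochs = 200L, seed = 1L) {
  if (length(pool_after) != length(up_before))
    config_error("pool_after and up_before must have equal length")
  if (dec_filters[length(dec_filters)] != 1L)
    config_error("decoder must end with 1 filter (reconstruction)")
  pools <- length(pool_after)
  if (input_size %% (2L^pools) != 0L)
    config_error("input_size must be divisible by 2^pools")
  structure(list(input_size = as.integer(input_size),
                 enc_filters = as.integer(enc_filters),
                 pool_after = as.integer(pool_after),
                 dec_filters = as.integer(dec_filters),
                 up_before = as.integer(up_before),
                 l2 = l2, lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "cae_spec")
}

# latent spatial size and channel count implied by the spec
cae_latent <- function(spec) {
  c(hw = spec$input_size %/% (2L^length(spec$pool_after)),
    ch = spec$enc_filters[length(spec$enc_filters)])
}

build_cae <- function(spec) {
  enc <- list()
  cin <- 1L
  for (i in seq_along(spec$enc_filters)) {
    f <- spec$enc_filters[i]
    enc[[length(enc) + 1L]] <- layer_conv(cin, f, k = 3, init = "he")
    if (i %in% spec$pool_after) enc[[length(enc) + 1L]] <- layer_maxpool()
    enc[[length(enc) + 1L]] <- layer_bn(f)
    enc[[length(enc) + 1L]] <- layer_act("relu")
    cin <- f
  }
  dec <- list()
  for (i in seq_along(spec$dec_filters)) {
    f <- spec$dec_filters[i]
    if (i %in% spec$up_before) dec[[length(dec) + 1L]] <- layer_upsample()
    dec[[length(dec) + 1L]] <- layer_conv(cin, f, k = 3, init = "he")
    if (i < length(spec$dec_filters)) {
      dec[[length(dec) + 1L]] <- layer_bn(f)
      dec[[length(dec) + 1L]] <- layer_act("relu")
    } else {
      dec[[length(dec) + 1L]] <- layer_act("sigmoid")
    }
    cin <- f
  }
  structure(list(encoder = net_init(enc), decoder = net_init(dec),
                 spec = spec, pretrained = FALSE, history = NULL),
            class = "cae")
}

#' Pre-train a convolutional autoencoder by reconstruction
#'
#' Unsupervised stage-1 training: minimizes the mean squared error between
#' input and reconstruction with Adam, applying the spec's L2 penalty to
#' convolution weights. Typically run on GAN-augmented slices of one
#' modality.
#'
#' @param images list of matrices or `(H, W, 1, N)` array in `[0, 1]`.
#' @param spec a [cae_spec()] (or an existing `cae` to continue training).
#' @param verbose print per-epoch reconstruction loss.
#' @return a `cae` with `pretrained = TRUE` and a per-epoch loss history.
#' @export
pretrain_cae <- function(images, spec = cae_spec(), verbose = FALSE) {
  x <- as_image_batch(images)
  n <- dim(x)[4]
  if (n == 0L) input_error("need at least one image")
  have_cae <- inherits(spec, "cae")
  if (have_cae) {
    cae <- spec
    spec <- cae$spec
  }
  if (dim(x)[1] != spec$input_size)
    input_error("image size does not match spec$input_size")
  bs <- min(spec$batch_size, n)
  with_seed(spec$seed, {
    if (!have_cae) cae <- build_cae(spec)
    hist <- numeric(spec$epochs)
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        idx <- ord[start:(start + bs - 1L)]
        xb <- x[, , , idx, drop = FALSE]
        ef <- net_forward(cae$encoder, xb, TRUE); cae$encoder <- ef$net
        df <- net_forward(cae$decoder, ef$out, TRUE); cae$decoder <- df$net
        loss <- mean((df$out - xb)^2)
        g <- 2 * (df$out - xb) / length(xb)
        bkd <- net_backward(cae$decoder, df$caches, g)
        bke <- net_backward(cae$encoder, ef$caches, bkd$dx)
        cae$decoder <- net_adam_step(cae$decoder, bkd$grads, spec$lr,
                                     spec$beta1, spec$beta2,
                                     weight_decay = spec$l2)
        cae$encoder <- net_adam_step(cae$encoder, bke$grads, spec$lr,
                                     spec$beta1, spec$beta2,
                                     weight_decay = spec$l2)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      hist[epoch] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d: recon MSE %.5f", epoch, hist[epoch]))
    }
    cae$pretrained <- TRUE
    cae$history <- data.frame(epoch = seq_len(spec$epochs), mse = hist)
    cae
  })
}

#' Encode slices to feature maps
#'
#' Deterministic inference-mode forward pass through the encoder.
#'
#' @param cae a `cae` (initialized or pre-trained).
#' @param image matrix, list of matrices, or `(H, W, 1, N)` array.
#' @return feature map array: `(h, w, c)` for a single image, otherwise
#'   `(h, w, c, N)` (8x8x512 at the default spec).
#' @export
encode <- function(cae, image) {
  single <- is.matrix(image)
  x <- as_image_batch(image)
  if (dim(x)[1] != cae$spec$input_size)
    input_error("image size does not match the CAE input size")
  f <- net_predict(cae$encoder, x)
  if (single) array(f, dim(f)[1:3]) else f
}

#' Reconstruct slices through the full autoencoder
#'
#' @param cae a `cae`.
#' @param image matrix, list, or `(H, W, 1, N)` array.
#' @return reconstruction with the same dimensions as the input batch.
#' @export
reconstruct <- function(cae, image) {
  x <- as_image_batch(image)
  net_predict(cae$decoder, net_predict(cae$encoder, x))
}

#' Element-wise aggregation of two feature maps
#'
#' `f = f1 * f2` entry-wise, preserving the spatial correspondence of the
#' two modality streams.
#'
#' @param f1,f2 arrays of identical dimensions.
#' @return array of the same dimensions.
#' @export
aggregate_features <- function(f1, f2) {
  if (!identical(dim(f1), dim(f2)))
    input_error("feature maps must have identical dimensions")
  f1 * f2
}

#' Bilinear pooling of a feature map
#'
#' Flattens `f` (h x w x c) to the `(h*w) x c` matrix `F` and returns
#' `H = t(F) %*% F`, the c x c matrix of channel co-activations summed over
#' spatial positions. `H` is exactly symmetric and positive semidefinite.
#'
#' @param f feature map array `(h, w, c)`.
#' @return c x c matrix.
#' @export
bilinear_pool <- function(f) {
  d <- dim(f)
  if (length(d) != 3L) input_error("f must be a (h, w, c) array")
  crossprod(matrix(f, d[1] * d[2], d[3]))
}

#' Signed square root and L2 normalization
#'
#' The standard bilinear-pooling stabilization applied to the vectorized
#' bilinear map before the fully connected head: `sign(v) * sqrt(|v|)`,
#' then division by the Euclidean norm.
#'
#' @param v numeric vector.
#' @return normalized vector (zero vector if `v` is all zeros).
#' @export
signed_sqrt_l2 <- function(v) {
  u <- sign(v) * sqrt(abs(v))
  nrm <- sqrt(sum(u^2))
  if (nrm > 0) u / nrm else u
}

# ---- fusion head and refinement ----

build_fusion_head <- function(in_dim, fc_width = 256L, dropout = 0.5,
                              n_classes = 2L) {
  net_init(list(layer_dense(in_dim, fc_width, init = "he"),
                layer_act("relu"), layer_dropout(dropout),
                layer_dense(fc_width, fc_width, init = "he"),
                layer_act("relu"), layer_dropout(dropout),
                layer_dense(fc_width, n_classes, init = "he")))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward fusion for a batch: encoder maps -> aggregate -> per-sample
# bilinear map -> signed-sqrt + L2 -> feature matrix (N, c^2)
fusion_features <- function(f1, f2, use_ssqrt = TRUE) {
  d <- dim(f1)
  hw <- d[1] * d[2]; ch <- d[3]; n <- d[4]
  f <- f1 * f2
  feats <- matrix(0, n, ch * ch)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    Fm <- matrix(f[, , , i], hw, ch)
    H <- crossprod(Fm)
    v <- as.numeric(H)
    if (use_ssqrt) {
      u <- sign(v) * sqrt(abs(v))
      nrm <- sqrt(sum(u^2))
      w <- if (nrm > 0) u / nrm else u
      caches[[i]] <- list(Fm = Fm, v = v, u = u, nrm = nrm)
      feats[i, ] <- w
    } else {
      caches[[i]] <- list(Fm = Fm, v = v)
      feats[i, ] <- v
    }
  }
  list(feats = feats, caches = caches, dims = d)
}

# backward through fusion: dfeats (N, c^2) -> gradients for f1, f2
fusion_backward <- function(dfeats, caches, f1, f2, use_ssqrt = TRUE) {
  d <- dim(f1)
  hw <- d[1] * d[2]; ch <- d[3]; n <- d[4]
  df <- array(0, d)
  for (i in seq_len(n)) {
    cc <- caches[[i]]
    dv <- dfeats[i, ]
    if (use_ssqrt) {
      if (cc$nrm > 0) {
        w <- cc$u / cc$nrm
        dv <- (dv - w * sum(dv * w)) / cc$nrm       # through L2 normalization
      }
      dv <- dv * 0.5 / pmax(sqrt(abs(cc$v)), 1e-8)  # through signed sqrt
    }
    dH <- matrix(dv, ch, ch)
    dF <- cc$Fm %*% (dH + t(dH))
    df[, , , i] <- array(dF, c(d[1], d[2], ch))
  }
  list(df1 = df * f2, df2 = df * f1)
}

# identical geometric runtime augmentation for both modality streams:
# horizontal flip w.p. 0.5 + rotation uniform in [-max_angle, max_angle]
augment_pair <- function(x1, x2, max_angle = 10) {
  n <- dim(x1)[4]
  for (i in seq_len(n)) {
    if (runif(1) < 0.5) {
      x1[, , 1L, i] <- x1[, rev(seq_len(dim(x1)[2])), 1L, i]
      x2[, , 1L, i] <- x2[, rev(seq_len(dim(x2)[2])), 1L, i]
    }
    ang <- runif(1, -max_angle, max_angle)
    x1[, , 1L, i] <- rotate_image(x1[, , 1L, i], ang)
    x2[, , 1L, i] <- rotate_image(x2[, , 1L, i], ang)
  }
  list(x1 = x1, x2 = x2)
}

#' Supervised refinement of the two-stream classifier
#'
#' Stage-2 training: the decoders are discarded; both encoders and the
#' fusion head (element-wise aggregation, bilinear pooling with signed-sqrt
#' and L2 normalization, two 256-unit fully connected layers with dropout
#' 0.5, softmax) are jointly trained on categorical cross-entropy with
#' runtime augmentation (random horizontal flip and rotation uniform in
#' +/-10 degrees). Early stopping keeps the parameters of the best
#' validation accuracy.
#'
#' @param cae1,cae2 `cae` objects for the T1ce and FLAIR streams (pre-trained
#'   or freshly initialized). For a single-modality model pass the same
#'   object and set `modality`.
#' @param train a `slice_dataset` (paired `x1`/`x2` with labels `y`).
#' @param val validation `slice_dataset` for early stopping (optional; when
#'   `NULL`, the final-epoch parameters are kept).
#' @param epochs maximum refinement epochs.
#' @param patience early-stopping patience in epochs.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size minibatch size.
#' @param fc_width fully connected layer width.
#' @param dropout dropout rate of the head.
#' @param l2 weight penalty on trained weights.
#' @param modality `"both"` for two-stream fusion, or `"T1ce"`/`"FLAIR"` for
#'   a single-stream model (bilinear pooling of that stream only).
#' @param freeze_encoders train only the head.
#' @param augment enable runtime augmentation.
#' @param use_ssqrt apply signed-sqrt + L2 normalization to the bilinear map.
#' @param seed RNG seed.
#' @param verbose print per-epoch progress.
#' @return object of class `glioma_classifier` with the trained encoders,
#'   head, training history and `best_epoch`.
#' @export
refine_train <- function(cae1, cae2, train, val = NULL, epochs = 60L,
                         patience = 20L, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 16L, fc_width = 256L,
                         dropout = 0.5, l2 = 1e-4,
                         modality = c("both", "T1ce", "FLAIR"),
                         freeze_encoders = FALSE, augment = TRUE,
                         use_ssqrt = TRUE, seed = 1L, verbose = FALSE) {
  modality <- match.arg(modality)
  if (!inherits(train, "slice_dataset"))
    input_error("train must be a slice_dataset")
  if (length(train$y) != dim(train$x1)[4] ||
      !identical(dim(train$x1), dim(train$x2)))
    input_error("modalities must be paired per sample")
  n <- length(train$y)
  enc1 <- cae1$encoder
  enc2 <- cae2$encoder
  lat <- cae_latent(cae1$spec)
  in_dim <- as.integer(lat["ch"])^2

  with_seed(seed, {
    head <- build_fusion_head(in_dim, fc_width, dropout)
    best <- list(acc = -Inf, enc1 = enc1, enc2 = enc2, head = head,
                 epoch = 0L)
    hist <- vector("list", epochs)
    since_best <- 0L
    bs <- min(batch_size, n)

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n - bs + 1L, by = bs)) {
        idx <- ord[start:(start + bs - 1L)]
        x1 <- train$x1[, , , idx, drop = FALSE]
        x2 <- train$x2[, , , idx, drop = FALSE]
        if (augment) {
          au <- augment_pair(x1, x2)
          x1 <- au$x1; x2 <- au$x2
        }
        y <- train$y[idx]
        onehot <- cbind(y == 0L, y == 1L) * 1

        e1 <- net_forward(enc1, x1, TRUE); enc1 <- e1$net
        e2 <- net_forward(enc2, x2, TRUE); enc2 <- e2$net
        f1 <- e1$out; f2 <- e2$out
        if (modality == "T1ce") f2 <- array(1, dim(f1))
        if (modality == "FLAIR") f1 <- array(1, dim(f2))
        fu <- fusion_features(f1, f2, use_ssqrt)
        hf <- net_forward(head, fu$feats, TRUE)
        p <- softmax_rows(hf$out)
        ep_loss <- ep_loss - mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
        dlogits <- (p - onehot) / length(y)
        bkh <- net_backward(head, hf$caches, dlogits)
        head <- net_adam_step(head, bkh$grads, lr, beta1, beta2,
                              weight_decay = l2)
        if (!freeze_encoders) {
          fb <- fusion_backward(bkh$dx, fu$caches, f1, f2, use_ssqrt)
          if (modality != "FLAIR") {
            bk1 <- net_backward(enc1, e1$caches, fb$df1)
            enc1 <- net_adam_step(enc1, bk1$grads, lr, beta1, beta2,
                                  weight_decay = l2)
          }
          if (modality != "T1ce") {
            bk2 <- net_backward(enc2, e2$caches, fb$df2)
            enc2 <- net_adam_step(enc2, bk2$grads, lr, beta1, beta2,
                                  weight_decay = l2)
          }
        }
        nb <- nb + 1L
      }
      clf <- structure(list(enc1 = enc1, enc2 = enc2, head = head,
                            modality = modality, use_ssqrt = use_ssqrt,
                            input_size = cae1$spec$input_size),
                       class = "glioma_classifier")
      val_acc <- if (!is.null(val)) {
        mean(predict(clf, val, type = "class") == val$y)
      } else NA_real_
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_acc = val_acc)
      track <- if (is.na(val_acc)) -ep_loss / nb else val_acc
      if (track > best$acc) {
        best <- list(acc = track, enc1 = enc1, enc2 = enc2, head = head,
                     epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val_acc %s", epoch, ep_loss / nb,
                        format(val_acc, digits = 3)))
    }
    structure(list(enc1 = best$enc1, enc2 = best$enc2, head = best$head,
                   modality = modality, use_ssqrt = use_ssqrt,
                   input_size = cae1$spec$input_size,
                   best_epoch = best$epoch,
                   history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)])),
              class = "glioma_classifier")
  })
}

#' Predict molecular subtype probabilities
#'
#' Inference-mode forward pass (dropout disabled, batch-norm running
#' statistics): encoder features, aggregation, bilinear pooling, softmax.
#'
#' @param object a `glioma_classifier`.
#' @param newdata a `slice_dataset`, or a list with `x1` (T1ce) and `x2`
#'   (FLAIR) arrays/matrices; both modalities are required for a two-stream
#'   model.
#' @param type `"prob"` for the (N, 2) probability matrix (rows sum to 1) or
#'   `"class"` for 0/1 labels.
#' @param chunk forward-pass batch size.
#' @param ... unused.
#' @return probability matrix or integer labels.
#' @export
predict.glioma_classifier <- function(object, newdata,
                                      type = c("prob", "class"),
                                      chunk = 32L, ...) {
  type <- match.arg(type)
  if (is.null(newdata$x1) || is.null(newdata$x2))
    input_error("both modalities (x1, x2) are required")
  x1 <- as_image_batch(newdata$x1)
  x2 <- as_image_batch(newdata$x2)
  n <- dim(x1)[4]
  probs <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f1 <- net_predict(object$enc1, x1[, , , idx, drop = FALSE])
    f2 <- net_predict(object$enc2, x2[, , , idx, drop = FALSE])
    if (object$modality == "T1ce") f2 <- array(1, dim(f1))
    if (object$modality == "FLAIR") f1 <- array(1, dim(f2))
    fu <- fusion_features(f1, f2, object$use_ssqrt)
    probs[idx, ] <- softmax_rows(net_predict(object$head, fu$feats))
  }
  if (type == "prob") probs else as.integer(probs[, 2L] > probs[, 1L])
}
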