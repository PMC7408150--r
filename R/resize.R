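# Bilinear resampling with a pixel-center convention: output pixel center
# (i + 0.5) maps to input coordinate (i + 0.5) * scale - 0.5 (0-based), and
# source coordinates are clamped to the image (edge replication). The same
# sampler backs resizing, ROI rescaling and the small-angle runtime rotation.

bilinear_sample <- function(img, src_r, src_c) {
  h <- nrow(img); w <- ncol(img)
  r0 <- pmin(pmax(floor(src_r), 0), h - 1)
  c0 <- pmin(pmax(floor(src_c), 0), w - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)
  r1 <- pmin(r0 + 1, h - 1)
  c1 <- pmin(c0 + 1, w - 1)
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r1 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, c1 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
}

bilinear_resize <- function(img, out_h, out_w = out_h) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  src_r <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  src_c <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  rr <- rep(src_r, times = out_w)
  cc <- rep(src_c, each = out_h)
  matrix(bilinear_sample(img, rr, cc), out_h, out_w)
}

# rotate about the image center by `angle` degrees (counter-clockwise),
# bilinear interpolation, edge-replicated sampling outside the frame
rotate_image <- function(img, angle) {
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  ctr_r <- (h - 1) / 2; ctr_c <- (w - 1) / 2
  gr <- rep(seq_len(h) - 1 - ctr_r, times = w)
  gc <- rep(seq_len(w) - 1 - ctr_c, each = h)
  src_r <- cos(th) * gr - sin(th) * gc + ctr_r
  src_c <- sin(th) * gr + cos(th) * gc + ctr_c
  matrix(bilinear_sample(img, src_r, src_c), h, w)
}
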