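test_that("normalization rescales to [0,1] and handles degenerate input", {
  img <- matrix(seq(10, 20, length.out = 256 * 256), 256, 256)
  out <- normalize_and_resize(img, 128)
  expect_identical(dim(out), c(128L, 128L))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  expect_equal(normalize_and_resize(matrix(7, 16, 16), 8), matrix(0, 8, 8))
  expect_error(normalize_and_resize(numeric(0)), class = "gliomap_input_error")

  once <- normalize_and_resize(img, 64)
  expect_equal(normalize_and_resize(once, 64), once)
})

test_that("bilinear downsampling averages with pixel-center weights", {
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(gliomap:::bilinear_resize(cb, 2, 2), matrix(0.5, 2, 2))
})

test_that("bilinear upsampling matches a closed-form oracle", {
  img <- matrix(c(0, 1, 1, 0), 2, 2)
  out <- crop_to_roi(img, tight_bbox(matrix(1, 2, 2)), out_size = 4)
  # independent oracle: evaluate the interpolant at output pixel centers
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    sr <- min(max((i - 0.5) * 2 / 4 - 0.5, 0), 1)
    sc <- min(max((j - 0.5) * 2 / 4 - 0.5, 0), 1)
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    r1 <- min(r0 + 1, 1); c1 <- min(c0 + 1, 1)
    oracle[i, j] <- (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
      fr * (1 - fc) * img[r1 + 1, c0 + 1] +
      (1 - fr) * fc * img[r0 + 1, c1 + 1] +
      fr * fc * img[r1 + 1, c1 + 1]
  }
  expect_equal(out, oracle)
})

test_that("tight bounding boxes are minimal, half-open and 0-based", {
  m <- matrix(0, 128, 128)
  m[11:21, 31:41] <- 1   # 0-based rows 10..20, cols 30..40 inclusive
  bb <- tight_bbox(m)
  expect_equal(unclass(bb)[c("row0", "col0", "row1", "col1")],
               list(row0 = 10L, col0 = 30L, row1 = 21L, col1 = 41L))

  m1 <- matrix(0, 16, 16); m1[6, 8] <- 1  # 0-based (5, 7)
  bb1 <- tight_bbox(m1)
  expect_equal(c(bb1$row0, bb1$col0, bb1$row1, bb1$col1), c(5, 7, 6, 8))

  bbf <- tight_bbox(matrix(1, 128, 128))
  expect_equal(c(bbf$row0, bbf$col0, bbf$row1, bbf$col1), c(0, 0, 128, 128))

  expect_error(tight_bbox(matrix(0, 8, 8)), class = "gliomap_input_error")
})

test_that("tight_bbox equals brute-force min/max over random masks", {
  set.seed(31)
  for (i in 1:300) {
    m <- matrix(rbinom(20 * 20, 1, 0.05), 20, 20)
    if (sum(m) == 0) m[sample(400, 1)] <- 1
    bb <- tight_bbox(m)
    fg <- which(m > 0, arr.ind = TRUE)
    expect_identical(c(bb$row0, bb$col0, bb$row1, bb$col1),
                     c(min(fg[, 1]) - 1L, min(fg[, 2]) - 1L,
                       max(fg[, 1]), max(fg[, 2])))
  }
})

test_that("ROI crops resize to the requested size and validate bounds", {
  img <- matrix(runif(64 * 64), 64, 64)
  full <- structure(list(row0 = 0L, col0 = 0L, row1 = 64L, col1 = 64L),
                    class = "bbox")
  expect_identical(crop_to_roi(img, full, 64), img)

  small <- structure(list(row0 = 8L, col0 = 8L, row1 = 40L, col1 = 40L),
                     class = "bbox")
  expect_identical(dim(crop_to_roi(img, small, 64)), c(64L, 64L))

  bad <- structure(list(row0 = 0L, col0 = 0L, row1 = 65L, col1 = 64L),
                   class = "bbox")
  expect_error(crop_to_roi(img, bad), class = "gliomap_input_error")
})

test_that("slice selection ranks by tumor area with deterministic top-up", {
  mk <- function(area) {
    m <- matrix(0, 10, 10)
    if (area > 0) m[seq_len(area)] <- 1
    m
  }
  patient <- list(masks = lapply(c(0, 5, 3, 9), mk),
                  slices = list(T1ce = as.list(1:4), FLAIR = as.list(5:8)))
  sel <- select_tumor_slices(patient, k = 2)
  expect_identical(sel$indices, c(3L, 1L))

  all3 <- select_tumor_slices(patient, k = 3)
  expect_identical(all3$indices, c(3L, 1L, 2L))

  top6 <- select_tumor_slices(patient, k = 6, seed = 4)
  expect_length(top6$indices, 6)
  expect_identical(top6$indices[1:3], c(3L, 1L, 2L))
  expect_true(all(top6$indices[4:6] %in% c(1L, 2L, 3L)))
  expect_identical(top6$indices, select_tumor_slices(patient, 6, seed = 4)$indices)

  no_tumor <- list(masks = list(mk(0)), slices = list(T1ce = list(1)))
  expect_error(select_tumor_slices(no_tumor, 1), class = "gliomap_input_error")
})

test_that("patient partitions are disjoint, exhaustive and correctly sized", {
  ids10 <- sprintf("p%02d", 1:10)
  s <- partition_patients(ids10, seed = 3)
  expect_identical(sort(unique(names(s))), sort(ids10))
  expect_equal(as.integer(table(factor(s, c("train", "val", "test")))),
               c(6L, 2L, 2L))

  ids161 <- sprintf("p%03d", 1:161)
  cls <- rep(c(0, 1), c(77, 84))
  s161 <- partition_patients(ids161, labels = cls, seed = 1)
  expect_equal(as.integer(table(factor(s161, c("train", "val", "test")))),
               c(97L, 32L, 32L))

  s161b <- partition_patients(ids161, labels = cls, seed = 2)
  expect_false(identical(s161, s161b))
  expect_equal(table(factor(s161b, c("train", "val", "test"))),
               table(factor(s161, c("train", "val", "test"))))

  expect_warning(partition_patients(ids10, labels = rep(c(0, 1), c(2, 8)),
                                    seed = 1),
                 "fewer than 3")
  expect_error(partition_patients(ids10[1:4]), class = "gliomap_input_error")
  expect_error(partition_patients(ids10, fractions = c(0.5, 0.2, 0.2)),
               class = "gliomap_input_error")
})

test_that("NIfTI volumes load as normalized axial slices", {
  vol <- array(runif(16 * 16 * 5, 100, 900), c(16, 16, 5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  sl <- read_nifti_slices(f, size = 8)
  expect_length(sl, 5)
  expect_identical(dim(sl[[3]]), c(8L, 8L))
  expect_true(all(vapply(sl, max, 0) <= 1))

  raw <- read_nifti_slices(f, slices = 2, size = NULL)
  expect_equal(raw[[1]], vol[, , 2])
})

test_that("Otsu fallback boxes the dominant bright component", {
  img <- matrix(0.05, 64, 64)
  img[20:35, 30:50] <- 0.9          # dominant component
  img[50:52, 5:7] <- 0.9            # small distractor
  bb <- roi_from_otsu(img)
  expect_equal(c(bb$row0, bb$col0, bb$row1, bb$col1), c(19, 29, 35, 50))
})

test_that("slice datasets keep all slices of a patient in one subset", {
  coh <- generate_cohort(toy_phantom(seed = 21, n_a = c(3, 3), n_b = c(3, 3),
                                     slices = 5))
  ds <- build_slice_dataset(coh, k = 3, out_size = 16, seed = 1)
  expect_equal(length(ds$y), 12 * 3)
  expect_identical(dim(ds$x1), dim(ds$x2))
  sp <- split_toy_dataset(ds, seed = 2)
  for (s in names(sp)) {
    overlap <- intersect(unique(sp[[s]]$patient_id),
                         unlist(lapply(setdiff(names(sp), s), function(o)
                           unique(sp[[o]]$patient_id))))
    expect_length(overlap, 0)
  }
})
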