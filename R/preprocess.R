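# Intensity normalization, tight bounding-box tumor extraction, per-class
# slice selection, and strictly patient-separated partitioning. Coordinates
# are 0-based, half-open, row-major throughout.

#' Resize a slice and normalize intensities to [0, 1]
#'
#' Bilinear resize to `size` x `size`, followed by min-max scaling. A
#' constant image maps to all zeros (avoids division by zero). Idempotent at
#' a fixed size.
#'
#' @param image non-empty numeric matrix.
#' @param size output pixels per side (default 128).
#' @return a `size` x `size` matrix with min 0 and max 1 (or all zeros).
#' @export
normalize_and_resize <- function(image, size = 128L) {
  if (is.null(dim(image)) || length(image) == 0L)
    input_error("image must be a non-empty matrix")
  out <- bilinear_resize(image, size, size)
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1])
  else matrix(0, size, size)
}

#' Tight bounding box of a binary mask
#'
#' The minimal axis-aligned rectangle containing every foreground pixel,
#' in 0-based half-open coordinates: rows `[row0, row1)`, columns
#' `[col0, col1)`.
#'
#' @param mask matrix; pixels `> 0` are foreground.
#' @return object of class `bbox`: list with `row0`, `col0`, `row1`, `col1`.
#' @export
tight_bbox <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) input_error("mask has no foreground pixels (no ROI)")
  structure(list(row0 = min(fg[, 1]) - 1L, col0 = min(fg[, 2]) - 1L,
                 row1 = max(fg[, 1]), col1 = max(fg[, 2])),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("bbox [%d, %d) x [%d, %d)\n", x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}

bbox_union <- function(boxes) {
  structure(list(row0 = min(vapply(boxes, `[[`, 0L, "row0")),
                 col0 = min(vapply(boxes, `[[`, 0L, "col0")),
                 row1 = max(vapply(boxes, `[[`, 0L, "row1")),
                 col1 = max(vapply(boxes, `[[`, 0L, "col1"))),
            class = "bbox")
}

#' Crop a slice to a bounding box and rescale
#'
#' Crops the half-open box and bilinearly resizes the crop to
#' `out_size` x `out_size` (the tumor-region input size of the classifier).
#' A crop already at `out_size` is returned pixel-identical.
#'
#' @param image numeric matrix.
#' @param box a [tight_bbox()] result (or list with the same fields).
#' @param out_size output pixels per side (default 64).
#' @return `out_size` x `out_size` matrix.
#' @export
crop_to_roi <- function(image, box, out_size = 64L) {
  if (box$row0 < 0L || box$col0 < 0L ||
      box$row1 > nrow(image) || box$col1 > ncol(image) ||
      box$row0 >= box$row1 || box$col0 >= box$col1)
    input_error("bounding box does not fit inside the image")
  crop <- image[(box$row0 + 1L):box$row1, (box$col0 + 1L):box$col1, drop = FALSE]
  bilinear_resize(crop, out_size, out_size)
}

#' Select tumor-bearing slices for a patient
#'
#' Returns the `k` slices with the largest tumor mask area (ties broken by
#' the lower slice index). If the patient has fewer than `k` tumor-bearing
#' slices, the shortfall is sampled with replacement from the available ones,
#' deterministically under `seed`.
#'
#' @param patient a `synthetic_patient` (or any list with a `masks` field).
#' @param k slices to select.
#' @param seed seed for the with-replacement top-up.
#' @return list with `indices` (0-based slice indices, length `k`), `slices`
#'   (per-modality lists of the selected slices) and `masks`.
#' @export
select_tumor_slices <- function(patient, k, seed = 1L) {
  areas <- vapply(patient$masks, sum, numeric(1))
  avail <- which(areas > 0)
  if (length(avail) == 0L) input_error("patient has no tumor-bearing slices")
  ord <- avail[order(-areas[avail], avail)]
  sel <- if (length(ord) >= k) ord[seq_len(k)]
  else c(ord, with_seed(seed, sample(rep(ord, 2L), k - length(ord),
                                     replace = TRUE)))
  slices <- lapply(patient$slices, function(mod) mod[sel])
  list(indices = sel - 1L, slices = slices, masks = patient$masks[sel])
}

#' Patient-separated train/validation/test partition
#'
#' Splits patients into train/validation/test by patient (all slices of a
#' patient share one subset). Subset sizes are `floor(f * n)` for validation
#' and test with the remainder assigned to train. When `labels` are supplied
#' the split is stratified by class via largest-remainder apportionment of
#' the global validation/test targets across classes; a class with fewer
#' than 3 patients triggers a warning and an unstratified split.
#'
#' @param patient_ids character vector of unique patient ids (>= 5).
#' @param labels optional class label per patient (same length).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed; a new seed reshuffles assignments but preserves
#'   subset sizes and disjointness.
#' @return named character vector mapping patient_id to
#'   `"train"`, `"val"` or `"test"`.
#' @export
partition_patients <- function(patient_ids, labels = NULL,
                               fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- length(patient_ids)
  if (n < 5L) input_error("need at least 5 patients to partition")
  if (anyDuplicated(patient_ids)) input_error("patient_ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-8) input_error("fractions must sum to 1")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)

  if (!is.null(labels)) {
    tab <- table(labels)
    if (any(tab < 3L)) {
      warning("a class has fewer than 3 patients; falling back to unstratified split")
      labels <- NULL
    }
  }
  assign_counts <- function(target, sizes) {
    quota <- target * sizes / sum(sizes)
    base <- floor(quota)
    extra <- target - sum(base)
    if (extra > 0) {
      ord <- order(-(quota - base), -sizes)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
    }
    base
  }
  out <- character(n)
  names(out) <- patient_ids
  with_seed(seed, {
    if (is.null(labels)) {
      ids <- sample(patient_ids)
      out[ids[seq_len(n_val)]] <- "val"
      out[ids[n_val + seq_len(n_test)]] <- "test"
      out[out == ""] <- "train"
    } else {
      groups <- split(patient_ids, labels)
      sizes <- lengths(groups)
      vc <- assign_counts(n_val, sizes)
      tc <- assign_counts(n_test, sizes)
      for (g in seq_along(groups)) {
        ids <- sample(groups[[g]])
        if (vc[g] > 0) out[ids[seq_len(vc[g])]] <- "val"
        if (tc[g] > 0) out[ids[vc[g] + seq_len(tc[g])]] <- "test"
      }
      out[out == ""] <- "train"
    }
  })
  out
}

#' Read axial slices from a NIfTI volume
#'
#' Real-data entry point: loads a 3D volume (any format RNifti reads),
#' extracts axial (third-axis) slices, and optionally normalizes each to the
#' pipeline's working size and intensity range with [normalize_and_resize()].
#'
#' @param file path to a NIfTI file.
#' @param slices indices along the third axis (default: all).
#' @param size target size for [normalize_and_resize()]; `NULL` returns raw
#'   slices.
#' @return list of 2D matrices.
#' @export
read_nifti_slices <- function(file, slices = NULL, size = 128L) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_nifti_slices requires the RNifti package")
  vol <- as.array(RNifti::readNifti(file))
  if (length(dim(vol)) < 3L) vol <- array(vol, c(dim(vol), 1L))
  idx <- slices %||% seq_len(dim(vol)[3])
  lapply(idx, function(s) {
    sl <- vol[, , s]
    if (is.null(size)) sl else normalize_and_resize(sl, size)
  })
}

#' Otsu-threshold fallback ROI
#'
#' Heuristic bounding box for slices without a tumor mask: Otsu thresholding
#' followed by the largest connected component (uses EBImage).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @return a `bbox`.
#' @export
roi_from_otsu <- function(image) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("roi_from_otsu requires the EBImage package")
  th <- EBImage::otsu(EBImage::Image(image))
  lab <- EBImage::bwlabel(EBImage::Image((image > th) * 1))
  labs <- as.integer(EBImage::imageData(lab))
  if (all(labs == 0L)) input_error("no foreground after Otsu thresholding")
  biggest <- as.integer(names(which.max(table(labs[labs > 0L]))))
  tight_bbox(matrix(labs == biggest, nrow(image), ncol(image)))
}

#' Build a paired-modality tumor-crop dataset from a cohort
#'
#' For each patient: select tumor-bearing slices (minority-class patients get
#' `minority_multiplier` times the base count, mirroring the extraction used
#' for imbalanced cohorts), fix one box per patient (the union of the
#' selected slices' tight boxes, applied to both modalities so the two
#' streams stay spatially aligned), crop, and rescale to
#' `out_size` x `out_size`.
#'
#' @param cohort a `phantom_cohort`.
#' @param k base number of slices per patient.
#' @param minority_multiplier multiplier on `k` for patients of the class
#'   with fewer patients (1 = balanced extraction).
#' @param out_size crop output size (default 64).
#' @param seed RNG seed for the slice top-up.
#' @return object of class `slice_dataset`: list with arrays `x1` (T1ce) and
#'   `x2` (FLAIR) of dim `(out_size, out_size, 1, N)`, integer labels `y`
#'   (0/1), `patient_id`, `domain` and 0-based `slice_index` per sample.
#' @export
build_slice_dataset <- function(cohort, k = 10L, minority_multiplier = 1L,
                                out_size = 64L, seed = 1L) {
  cls <- vapply(cohort, function(p) p$class, integer(1))
  tab <- table(factor(cls, levels = c(0L, 1L)))
  minority <- if (tab[1] == tab[2]) NA_integer_
  else as.integer(names(which.min(tab)))
  x1 <- list(); x2 <- list(); y <- integer(); pid <- character()
  dom <- character(); sidx <- integer()
  for (p in cohort) {
    kp <- if (!is.na(minority) && p$class == minority)
      as.integer(k * minority_multiplier) else as.integer(k)
    sel <- select_tumor_slices(p, kp, seed = seed)
    box <- bbox_union(lapply(sel$masks, tight_bbox))
    for (s in seq_along(sel$indices)) {
      x1[[length(x1) + 1L]] <- crop_to_roi(sel$slices$T1ce[[s]], box, out_size)
      x2[[length(x2) + 1L]] <- crop_to_roi(sel$slices$FLAIR[[s]], box, out_size)
      y <- c(y, p$class)
      pid <- c(pid, p$patient_id)
      dom <- c(dom, p$domain)
      sidx <- c(sidx, sel$indices[s])
    }
  }
  n <- length(x1)
  a1 <- array(unlist(x1), c(out_size, out_size, 1L, n))
  a2 <- array(unlist(x2), c(out_size, out_size, 1L, n))
  structure(list(x1 = a1, x2 = a2, y = y, patient_id = pid,
                 domain = dom, slice_index = sidx),
            class = "slice_dataset")
}

dataset_subset <- function(ds, keep) {
  structure(list(x1 = ds$x1[, , , keep, drop = FALSE],
                 x2 = ds$x2[, , , keep, drop = FALSE],
                 y = ds$y[keep], patient_id = ds$patient_id[keep],
                 domain = ds$domain[keep], slice_index = ds$slice_index[keep]),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("slice_dataset: %d paired samples (%dx%d), classes: %s\n",
              length(x$y), dim(x$x1)[1], dim(x$x1)[2],
              paste(sprintf("%d:%d", as.integer(names(table(x$y))),
                            as.integer(table(x$y))), collapse = ", ")))
  invisible(x)
}
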