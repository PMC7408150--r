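# Synthetic two-domain, two-modality, two-class phantom cohort with
# ground-truth tumor masks. Stands in for multi-site clinical MRI when no
# real data are available: domain differences are modelled as a smooth
# multiplicative bias field, a gamma/contrast transform and additive noise;
# the class-discriminative signal is a sinusoidal texture inside the tumor
# whose spatial frequency differs between classes, so it is learnable by a
# convolutional classifier but invisible to global intensity statistics.

config_error <- function(msg) {
  stop(structure(class = c("gliomap_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

input_error <- function(msg) {
  stop(structure(class = c("gliomap_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Configuration for the synthetic phantom cohort
#'
#' Defines the study conditions under which a synthetic cohort is generated:
#' per (domain, class) patient counts, per-domain scanner-shift parameters,
#' and the per-class tumor texture that carries the molecular-subtype signal.
#'
#' @param image_size pixels per side; a power of two, at least 32.
#' @param n_patients named list with elements `A` and `B`, each a length-2
#'   vector `c(class0, class1)` of patient counts.
#' @param slices_per_patient number of axial slices simulated per patient.
#' @param domain_shift named list with elements `A` and `B`, each a list with
#'   `gamma` (exponent, > 0), `bias_amplitude` (peak deviation of the smooth
#'   multiplicative bias field, in `[0, 1)`), `noise_sd` (additive Gaussian
#'   noise, >= 0) and `contrast_scale` (> 0).
#' @param class_texture named list `class0`/`class1`, each with `frequency`
#'   (cycles per image width of the intratumoral sinusoidal texture) and
#'   `amplitude` (intensity amplitude of the texture).
#' @param modality_params named list `T1ce`/`FLAIR`, each with base `tumor`
#'   and `background` intensities and a `texture_scale` multiplier on the
#'   class texture; FLAIR defaults to the higher tumor/background contrast
#'   and full texture visibility, so it is the more informative stream.
#' @param seed RNG seed; the same seed yields a bit-identical cohort.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           n_patients = list(A = c(class0 = 10L, class1 = 10L),
                                             B = c(class0 = 10L, class1 = 10L)),
                           slices_per_patient = 10L,
                           domain_shift = list(
                             A = list(gamma = 1.4, bias_amplitude = 0.3,
                                      noise_sd = 0.05, contrast_scale = 0.9),
                             B = list(gamma = 1.0, bias_amplitude = 0.0,
                                      noise_sd = 0.02, contrast_scale = 1.0)),
                           class_texture = list(
                             class0 = list(frequency = 3, amplitude = 0.18),
                             class1 = list(frequency = 8, amplitude = 0.18)),
                           modality_params = list(
                             T1ce = list(tumor = 0.60, background = 0.45,
                                         texture_scale = 0.6),
                             FLAIR = list(tumor = 0.78, background = 0.35,
                                          texture_scale = 1.0)),
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L || bitwAnd(image_size, image_size - 1L) != 0L)
    config_error("image_size must be a power of two >= 32")
  for (d in c("A", "B")) {
    if (is.null(n_patients[[d]]) || length(n_patients[[d]]) != 2L)
      config_error(sprintf("n_patients$%s must have two class counts", d))
    validate_shift(domain_shift[[d]])
  }
  if (as.integer(slices_per_patient) < 1L)
    config_error("slices_per_patient must be >= 1")
  structure(list(image_size = image_size,
                 n_patients = lapply(n_patients, function(v)
                   stats::setNames(as.integer(v), c("class0", "class1"))),
                 slices_per_patient = as.integer(slices_per_patient),
                 domain_shift = domain_shift,
                 class_texture = class_texture,
                 modality_params = modality_params,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

validate_shift <- function(shift) {
  if (is.null(shift$gamma) || shift$gamma <= 0)
    config_error("domain shift gamma must be > 0")
  if (shift$bias_amplitude < 0 || shift$bias_amplitude >= 1)
    config_error("bias_amplitude must lie in [0, 1)")
  if (shift$noise_sd < 0) config_error("noise_sd must be >= 0")
  if (shift$contrast_scale <= 0) config_error("contrast_scale must be > 0")
  invisible(shift)
}

# smooth random surface in [-1, 1]: a few low-frequency cosine waves,
# normalized so the peak absolute deviation is exactly 1
smooth_field <- function(n, n_waves = 3L) {
  gr <- matrix(rep(seq_len(n), times = n), n, n) / n
  gc <- matrix(rep(seq_len(n), each = n), n, n) / n
  f <- matrix(0, n, n)
  for (k in seq_len(n_waves)) {
    fx <- runif(1, 0.4, 1.6); fy <- runif(1, 0.4, 1.6)
    ph <- runif(1, 0, 2 * pi)
    f <- f + runif(1, 0.5, 1) * cos(2 * pi * (fx * gr + fy * gc) + ph)
  }
  m <- max(abs(f))
  if (m > 0) f / m else f
}

ellipse_mask <- function(n, cr, cc, ar, ac) {
  gr <- matrix(rep(seq_len(n), times = n), n, n)
  gc <- matrix(rep(seq_len(n), each = n), n, n)
  ((gr - cr) / ar)^2 + ((gc - cc) / ac)^2 <= 1
}

#' Apply a scanner-domain shift to a slice
#'
#' Models the scanner-dependent intensity distribution of one acquisition
#' site: `clip(contrast_scale * (bias_field * image)^gamma + noise, 0, 1)`,
#' where the bias field is a smooth multiplicative field with peak deviation
#' `bias_amplitude`. Uses the current RNG state for the bias field and noise.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param shift list with `gamma`, `bias_amplitude`, `noise_sd`,
#'   `contrast_scale` (see [phantom_config()]).
#' @return shifted matrix, clipped to `[0, 1]`.
#' @export
apply_domain_shift <- function(image, shift) {
  validate_shift(shift)
  field <- if (shift$bias_amplitude > 0)
    1 + shift$bias_amplitude * smooth_field(nrow(image)) else 1
  out <- shift$contrast_scale * (field * image)^shift$gamma
  if (shift$noise_sd > 0)
    out <- out + rnorm(length(image), 0, shift$noise_sd)
  matrix(pmin(pmax(out, 0), 1), nrow(image), ncol(image))
}

generate_patient <- function(config, domain, cls, idx, counter) {
  n <- config$image_size
  S <- config$slices_per_patient
  patient_seed <- (config$seed %% 1000000L) + 1009L * counter
  with_seed(patient_seed, {
    # shared anatomy across modalities and slices
    brain_ar <- runif(1, 0.32, 0.42) * n
    brain_ac <- runif(1, 0.32, 0.42) * n
    brain <- ellipse_mask(n, n / 2, n / 2, brain_ar, brain_ac)
    bg_field <- smooth_field(n)
    tum_cr <- runif(1, 0.38, 0.62) * n
    tum_cc <- runif(1, 0.38, 0.62) * n
    tum_ar <- runif(1, 0.10, 0.18) * n
    tum_ac <- runif(1, 0.10, 0.18) * n
    tex <- config$class_texture[[paste0("class", cls)]]
    theta <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    gr <- matrix(rep(seq_len(n), times = n), n, n)
    gc <- matrix(rep(seq_len(n), each = n), n, n)
    texture <- tex$amplitude *
      sin(2 * pi * tex$frequency * (cos(theta) * gr + sin(theta) * gc) / n + phase)

    shift <- config$domain_shift[[domain]]
    slices <- list(T1ce = vector("list", S), FLAIR = vector("list", S))
    masks <- vector("list", S)
    for (s in seq_len(S)) {
      rel <- if (S > 1) (s - (S + 1) / 2) / ((S + 1) / 2) else 0
      scale <- sqrt(max(0, 1 - rel^2))
      mask <- if (scale * min(tum_ar, tum_ac) >= 1)
        ellipse_mask(n, tum_cr, tum_cc, tum_ar * scale, tum_ac * scale) & brain
      else matrix(FALSE, n, n)
      masks[[s]] <- mask * 1L
      for (mod in names(config$modality_params)) {
        mp <- config$modality_params[[mod]]
        img <- mp$background * (0.85 + 0.15 * bg_field) * brain
        img[mask] <- mp$tumor + (mp$texture_scale %||% 1) * texture[mask]
        img <- pmin(pmax(img, 0), 1)
        slices[[mod]][[s]] <- apply_domain_shift(img, shift)
      }
    }
    structure(list(patient_id = sprintf("%s_c%d_%03d", domain, cls, idx),
                   domain = domain, class = cls,
                   label_1p19q = if (cls == 1L) "codeleted" else "non-codeleted",
                   label_idh = if (cls == 1L) "mutated" else "wild-type",
                   slices = slices, masks = masks),
              class = "synthetic_patient")
  })
}

#' Generate a synthetic two-domain cohort
#'
#' Produces exactly the configured number of patients per (domain, class).
#' Each patient has one shared anatomy imaged in two modalities (T1ce, FLAIR)
#' over `slices_per_patient` axial slices, with elliptical tumors carrying a
#' class-dependent texture, ground-truth binary masks, and the configured
#' scanner shift of its domain applied. Deterministic under `config$seed`;
#' per-patient RNG substreams are derived by counter so each patient is
#' independent of generation order.
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom_cohort`: a list of `synthetic_patient`
#'   objects with the config attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "phantom_config"))
    config_error("config must be a phantom_config object")
  if (any(unlist(config$n_patients) < 1L))
    config_error("per (domain, class) patient counts must be >= 1")
  patients <- list()
  counter <- 0L
  for (domain in c("A", "B")) {
    for (cls in c(0L, 1L)) {
      n_pc <- config$n_patients[[domain]][[paste0("class", cls)]]
      for (i in seq_len(n_pc)) {
        counter <- counter + 1L
        patients[[length(patients) + 1L]] <-
          generate_patient(config, domain, cls, i, counter)
      }
    }
  }
  structure(patients, class = "phantom_cohort", config = config)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  doms <- vapply(x, function(p) p$domain, character(1))
  cls <- vapply(x, function(p) p$class, integer(1))
  cat(sprintf("phantom_cohort: %d patients (%dx%d, %d slices/patient)\n",
              length(x), cfg$image_size, cfg$image_size,
              cfg$slices_per_patient))
  print(table(domain = doms, class = cls))
  invisible(x)
}

cohort_subset <- function(cohort, keep) {
  structure(unclass(cohort)[keep], class = "phantom_cohort",
            config = attr(cohort, "config"))
}

cohort_domain <- function(cohort, domain) {
  cohort_subset(cohort, vapply(cohort, function(p) p$domain, character(1)) == domain)
}

#' Write a cohort to disk as PNG slices plus a patient table
#'
#' Lays out `dir/<patient_id>/<modality>_<slice>.png` 8-bit images and
#' `dir/<patient_id>/mask_<slice>.png` masks, with an index `patients.csv`
#' (patient_id, domain, label_1p19q, label_idh, modality, slice_index,
#' slice_path, mask_path).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return the path of the written `patients.csv`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort) {
    pdir <- file.path(dir, p$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (s in seq_along(p$masks)) {
      mask_path <- file.path(p$patient_id, sprintf("mask_%03d.png", s - 1L))
      png::writePNG(p$masks[[s]] + 0.0, file.path(dir, mask_path))
      for (mod in names(p$slices)) {
        slice_path <- file.path(p$patient_id, sprintf("%s_%03d.png", mod, s - 1L))
        png::writePNG(p$slices[[mod]][[s]], file.path(dir, slice_path))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id, domain = p$domain,
          label_1p19q = p$label_1p19q, label_idh = p$label_idh,
          modality = mod, slice_index = s - 1L,
          slice_path = slice_path, mask_path = mask_path)
      }
    }
  }
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "patients.csv")
  write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `patients.csv`.
#' @return a `phantom_cohort` (intensities quantized to 8 bits by the PNG
#'   round trip; no generation config attached).
#' @export
read_cohort <- function(dir) {
  tab <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  patients <- lapply(split(tab, tab$patient_id), function(pt) {
    pt <- pt[order(pt$modality, pt$slice_index), ]
    s_idx <- sort(unique(pt$slice_index))
    slices <- lapply(split(pt, pt$modality), function(mt) {
      lapply(mt$slice_path[order(mt$slice_index)], function(f)
        png::readPNG(file.path(dir, f)))
    })
    mrows <- pt[!duplicated(pt$slice_index), ]
    masks <- lapply(mrows$mask_path[order(mrows$slice_index)], function(f)
      (png::readPNG(file.path(dir, f)) > 0.5) * 1L)
    structure(list(patient_id = pt$patient_id[1], domain = pt$domain[1],
                   class = if (pt$label_1p19q[1] == "codeleted") 1L else 0L,
                   label_1p19q = pt$label_1p19q[1],
                   label_idh = pt$label_idh[1],
                   slices = slices, masks = masks),
              class = "synthetic_patient")
  })
  ord <- order(vapply(patients, function(p) p$patient_id, character(1)))
  structure(unname(patients[ord]), class = "phantom_cohort")
}
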