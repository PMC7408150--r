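# Confusion-matrix metrics, multi-run orchestration with fresh
# patient-separated partitions per run, and the ablation harness
# (with/without domain mapping, with/without pre-training, augmentation-size
# sweep).

#' Confusion counts for binary predictions
#'
#' "Positive" is the molecular alteration of interest (1p/19q codeletion or
#' IDH mutation).
#'
#' @param y_true,y_pred equal-length binary label vectors.
#' @param positive the label counted as positive (default 1).
#' @return object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred))
    input_error("y_true and y_pred must have equal length")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2*precision*recall/(precision+recall)`.
#' An undefined precision or recall (zero denominator) is returned as `NA`
#' with the metric name recorded in the `flags` field, never silently 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return object of class `classification_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1` and a character vector `flags` naming any
#'   undefined metrics.
#' @export
classification_metrics <- function(counts) {
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0L) input_error("no samples")
  flags <- character(0)
  precision <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
  else { flags <- c(flags, "precision"); NA_real_ }
  recall <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
  else { flags <- c(flags, "recall"); NA_real_ }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { flags <- c(flags, "f1"); NA_real_ }
  structure(list(accuracy = (counts$TP + counts$TN) / total,
                 precision = precision, recall = recall, f1 = f1,
                 flags = flags),
            class = "classification_metrics")
}

#' Patient-level labels by majority vote over slice predictions
#'
#' Aggregates slice-level class predictions to one label per patient; ties
#' are broken toward the positive class.
#'
#' @param pred slice-level 0/1 predictions.
#' @param patient_id patient id per slice.
#' @param positive label counted as positive (default 1).
#' @return named vector of per-patient labels.
#' @export
patient_majority_vote <- function(pred, patient_id, positive = 1L) {
  if (length(pred) != length(patient_id))
    input_error("pred and patient_id must have equal length")
  vapply(split(pred, patient_id), function(v) {
    pos <- sum(v == positive)
    if (pos >= length(v) - pos) positive else as.integer(!positive)
  }, integer(1))
}

#' Pipeline options for multi-run evaluation and ablation
#'
#' Collects the stage configurations of the full pipeline. Defaults are the
#' published scale (64x64 crops, 10 slices per patient, full network specs);
#' pass reduced specs for desk-scale experiments.
#'
#' @param k base slices per patient.
#' @param minority_multiplier slice multiplier for the minority class.
#' @param out_size tumor crop size.
#' @param mapping train a CycleGAN and map domain A onto domain B before
#'   classification (FALSE pools the raw domains).
#' @param separate_mapping one CycleGAN per modality (FALSE shares one).
#' @param pretrain DCGAN-augment the training subset and pre-train the CAEs
#'   (FALSE trains the classifier from scratch).
#' @param n_augment augmented images per class, length 2 (class0, class1).
#' @param cyclegan,dcgan,cae stage specs; `NULL` uses the published-scale
#'   defaults at the data's image sizes.
#' @param refine named list of [refine_train()] arguments.
#' @return a named list of options.
#' @export
pipeline_options <- function(k = 10L, minority_multiplier = 1L,
                             out_size = 64L, mapping = TRUE,
                             separate_mapping = TRUE, pretrain = TRUE,
                             n_augment = c(1500L, 1500L),
                             cyclegan = NULL, dcgan = NULL, cae = NULL,
                             refine = list()) {
  list(k = k, minority_multiplier = minority_multiplier, out_size = out_size,
       mapping = mapping, separate_mapping = separate_mapping,
       pretrain = pretrain, n_augment = rep(n_augment, length.out = 2L),
       cyclegan = cyclegan, dcgan = dcgan, cae = cae, refine = refine)
}

cohort_slices <- function(cohort, modality) {
  unlist(lapply(cohort, function(p) p$slices[[modality]]), recursive = FALSE)
}

# train CycleGANs on all slices and map the A cohort onto B; one model per
# modality by default, or a single model trained on the union of modalities
map_source_domain <- function(cohort, opts, seed) {
  a <- cohort_domain(cohort, "A")
  b <- cohort_domain(cohort, "B")
  size <- nrow(a[[1]]$slices[[1]][[1]])
  mods <- names(a[[1]]$slices)
  states <- list()
  if (opts$separate_mapping) {
    for (m in mods) {
      spec <- opts$cyclegan %||% cyclegan_spec(image_size = size)
      spec$seed <- seed + match(m, mods)
      states[[m]] <- train_cyclegan(cohort_slices(a, m), cohort_slices(b, m),
                                    spec)
    }
  } else {
    spec <- opts$cyclegan %||% cyclegan_spec(image_size = size)
    spec$seed <- seed + 1L
    shared <- train_cyclegan(unlist(lapply(mods, cohort_slices, cohort = a),
                                    recursive = FALSE),
                             unlist(lapply(mods, cohort_slices, cohort = b),
                                    recursive = FALSE),
                             spec)
    for (m in mods) states[[m]] <- shared
  }
  list(mapped = combine_domains(map_cohort(a, states), b), states = states)
}

split_datasets <- function(cohort, opts, seed) {
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  cls <- vapply(cohort, function(p) p$class, integer(1))
  split <- partition_patients(ids, labels = cls, seed = seed)
  lapply(c(train = "train", val = "val", test = "test"), function(s) {
    build_slice_dataset(cohort_subset(cohort, split[ids] == s),
                        k = opts$k,
                        minority_multiplier = opts$minority_multiplier,
                        out_size = opts$out_size, seed = seed)
  })
}

# DCGAN per (modality, class) on the training crops, then pre-train one CAE
# per modality on its pooled augmented samples
pretrain_streams <- function(train_ds, opts, seed) {
  caes <- list()
  for (m in c(1L, 2L)) {
    xs <- if (m == 1L) train_ds$x1 else train_ds$x2
    aug <- list()
    for (cls in c(0L, 1L)) {
      keep <- which(train_ds$y == cls)
      n_aug <- opts$n_augment[cls + 1L]
      if (n_aug == 0L || length(keep) == 0L) next
      spec <- opts$dcgan %||% dcgan_spec(image_size = opts$out_size)
      spec$seed <- seed + 10L * m + cls
      st <- train_dcgan(xs[, , , keep, drop = FALSE], spec)
      aug[[length(aug) + 1L]] <- sample_augmented(st, n_aug,
                                                  seed = spec$seed + 1L)
    }
    imgs <- if (length(aug)) {
      n <- sum(vapply(aug, function(a) dim(a)[4], 0))
      array(unlist(aug), c(opts$out_size, opts$out_size, 1L, n))
    } else xs
    cspec <- opts$cae %||% cae_spec(input_size = opts$out_size)
    cspec$seed <- seed + 100L * m
    caes[[m]] <- pretrain_cae(imgs, cspec)
  }
  caes
}

fresh_streams <- function(opts, seed) {
  lapply(c(1L, 2L), function(m) {
    cspec <- opts$cae %||% cae_spec(input_size = opts$out_size)
    with_seed(seed + 100L * m, build_cae(cspec))
  })
}

run_once <- function(datasets, opts, seed, pretrain = opts$pretrain,
                     modality = "both") {
  caes <- if (pretrain) pretrain_streams(datasets$train, opts, seed)
  else fresh_streams(opts, seed)
  args <- c(list(cae1 = caes[[1]], cae2 = caes[[2]], train = datasets$train,
                 val = datasets$val, modality = modality, seed = seed),
            opts$refine)
  clf <- do.call(refine_train, args)
  pred <- predict(clf, datasets$test, type = "class")
  m <- classification_metrics(confusion_counts(datasets$test$y, pred))
  list(metrics = m, classifier = clf)
}

#' Run the full pipeline over multiple patient-separated partitions
#'
#' For each run: a fresh stratified patient-separated 60/20/20 partition,
#' optional DCGAN augmentation of the new training subset and CAE
#' pre-training, supervised refinement, and test-set evaluation. Domain
#' mapping (when enabled) is trained once on all slices — it is unsupervised
#' and uses no label or partition information — and reused across runs. The
#' report gives per-run metrics plus their mean and sample standard
#' deviation (n-1 denominator).
#'
#' @param cohort a `phantom_cohort` containing domains A and B.
#' @param n_runs number of runs (each with a new partition).
#' @param seed master seed; run `r` derives its seed as `seed + r`.
#' @param opts a [pipeline_options()] list.
#' @return object of class `metrics_report`: list with `runs` (one row per
#'   run) and `summary` (mean and sd per metric).
#' @export
run_experiment <- function(cohort, n_runs = 5L, seed = 1L,
                           opts = pipeline_options()) {
  data_cohort <- if (opts$mapping)
    map_source_domain(cohort, opts, seed)$mapped
  else combine_domains(cohort_domain(cohort, "A"), cohort_domain(cohort, "B"))
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    datasets <- split_datasets(data_cohort, opts, run_seed)
    res <- run_once(datasets, opts, run_seed)
    m <- res$metrics
    rows[[r]] <- data.frame(run = r, seed = run_seed,
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1)
  }
  runs <- do.call(rbind, rows)
  vals <- runs[, c("accuracy", "precision", "recall", "f1")]
  summary <- data.frame(metric = names(vals),
                        mean = vapply(vals, mean, 0),
                        sd = if (n_runs > 1) vapply(vals, sd, 0) else rep(0, 4),
                        row.names = NULL)
  structure(list(runs = runs, summary = summary, n_runs = n_runs,
                 seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d runs\n", x$n_runs))
  print(x$runs, row.names = FALSE, digits = 3)
  cat("\nmean +/- sd over runs:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Ablation over domain arms, pre-training, and augmentation size
#'
#' Evaluates the arms {A only, B only, A+B unmapped, mapped A+B} crossed
#' with {pre-trained, from scratch}, plus an optional augmentation-size
#' sweep on the mapped pre-trained arm, each over the given seeds. Reports
#' a tidy table; trends are reported, not asserted.
#'
#' @param cohort a `phantom_cohort` with domains A and B.
#' @param seeds integer vector; each seed is a full independent run.
#' @param opts a [pipeline_options()] list.
#' @param sweep_sizes optional list of per-class augmentation size pairs for
#'   the sweep, e.g. `list(c(0, 0), c(500, 500), c(1500, 1500))`.
#' @return data.frame with columns `arm`, `pretrain`, `n_augment`, `seed`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
run_ablation <- function(cohort, seeds = 1:3, opts = pipeline_options(),
                         sweep_sizes = NULL) {
  a <- cohort_domain(cohort, "A")
  b <- cohort_domain(cohort, "B")
  rows <- list()
  for (seed in seeds) {
    mapped <- map_source_domain(cohort, opts, seed)$mapped
    arms <- list(A_only = a, B_only = b,
                 pooled_unmapped = combine_domains(a, b),
                 pooled_mapped = mapped)
    for (arm in names(arms)) {
      for (pre in c(TRUE, FALSE)) {
        datasets <- split_datasets(arms[[arm]], opts, seed)
        m <- run_once(datasets, opts, seed, pretrain = pre)$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, pretrain = pre,
          n_augment = if (pre) paste(opts$n_augment, collapse = "+") else "0+0",
          seed = seed, accuracy = m$accuracy, precision = m$precision,
          recall = m$recall, f1 = m$f1)
      }
    }
    for (sz in sweep_sizes %||% list()) {
      o2 <- opts
      o2$n_augment <- rep(sz, length.out = 2L)
      datasets <- split_datasets(mapped, o2, seed)
      pre <- any(o2$n_augment > 0)
      m <- run_once(datasets, o2, seed, pretrain = pre)$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        arm = "sweep_mapped", pretrain = pre,
        n_augment = paste(o2$n_augment, collapse = "+"), seed = seed,
        accuracy = m$accuracy, precision = m$precision, recall = m$recall,
        f1 = m$f1)
    }
  }
  do.call(rbind, rows)
}
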