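test_that("confusion counts enumerate the four outcomes", {
  cm <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 2L, FN = 1L, TN = 1L, FP = 1L))

  y <- c(0, 1, 1, 0)
  same <- confusion_counts(y, y)
  expect_equal(same$FP + same$FN, 0)
  inv <- confusion_counts(y, 1 - y)
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), class = "gliomap_input_error")
})

test_that("metrics match the printed formulas and flag undefined values", {
  m <- classification_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                                        class = "confusion_counts"))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35)

  y <- rep(c(0, 1), 5)
  perfect <- classification_metrics(confusion_counts(y, y))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  allneg <- classification_metrics(confusion_counts(c(0, 0, 1), c(0, 0, 0)))
  expect_true(is.na(allneg$precision))
  expect_true("precision" %in% allneg$flags)
})

test_that("accuracy is invariant under class relabeling; counts mirror", {
  set.seed(8)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
    c1 <- confusion_counts(y, p, positive = 1)
    c0 <- confusion_counts(y, p, positive = 0)
    expect_identical(c0$TP, c1$TN)
    expect_identical(c0$FP, c1$FN)
    expect_identical(c0$TN, c1$TP)
    expect_identical(c0$FN, c1$FP)
    expect_equal(classification_metrics(c0)$accuracy,
                 classification_metrics(c1)$accuracy)
  }
})

test_that("majority vote aggregates slices per patient with positive ties", {
  pred <- c(1, 1, 0, 0, 0, 1, 0, 1)
  pid <- c("a", "a", "a", "b", "b", "c", "c", "c")
  v <- patient_majority_vote(pred, pid)
  expect_identical(v, c(a = 1L, b = 0L, c = 1L))
  expect_identical(patient_majority_vote(c(1, 0), c("x", "x"))[["x"]], 1L)
  expect_error(patient_majority_vote(1, c("a", "b")),
               class = "gliomap_input_error")
})

micro_opts <- function() pipeline_options(
  k = 3, out_size = 16, mapping = FALSE, pretrain = FALSE,
  n_augment = c(8, 8),
  cyclegan = cyclegan_spec(image_size = 32, channels = 1, gen_filters = c(6),
                           n_resblocks = 1, disc_filters = c(6),
                           residual = TRUE, epochs = 1, lr_decay_start = 1,
                           iters_per_epoch = 4, batch_size = 2),
  dcgan = toy_dcgan_spec(epochs = 1),
  cae = toy_cae_spec(epochs = 2),
  refine = list(epochs = 2, patience = 3, batch_size = 8, fc_width = 16))

test_that("a single-run report has zero dispersion and the report layout", {
  coh <- generate_cohort(toy_phantom(seed = 51, n_a = c(3, 3), n_b = c(3, 3),
                                     slices = 4))
  rep1 <- run_experiment(coh, n_runs = 1, seed = 2, opts = micro_opts())
  expect_s3_class(rep1, "metrics_report")
  expect_equal(nrow(rep1$runs), 1)
  expect_equal(rep1$summary$sd, rep(0, 4))
  expect_true(all(rep1$summary$metric ==
                    c("accuracy", "precision", "recall", "f1")))
  expect_true(rep1$runs$accuracy >= 0 && rep1$runs$accuracy <= 1)
})

test_that("multi-run reports carry one row per run plus a summary", {
  coh <- generate_cohort(toy_phantom(seed = 52, n_a = c(3, 3), n_b = c(3, 3),
                                     slices = 4))
  rep2 <- run_experiment(coh, n_runs = 2, seed = 5, opts = micro_opts())
  expect_equal(nrow(rep2$runs), 2)
  expect_equal(rep2$runs$seed, c(6, 7))
  expect_equal(rep2$summary$mean[1], mean(rep2$runs$accuracy))
  expect_equal(rep2$summary$sd[1], sd(rep2$runs$accuracy))
})

test_that("the ablation table enumerates all arms plus sweep rows", {
  coh <- generate_cohort(toy_phantom(seed = 53, n_a = c(3, 3), n_b = c(3, 3),
                                     slices = 4))
  opts <- micro_opts()
  opts$mapping <- TRUE
  # micro-scale arms have fewer images than the DCGAN batch; the shrink
  # warning is expected here
  tab <- suppressWarnings(run_ablation(coh, seeds = 1, opts = opts,
                                       sweep_sizes = list(c(0, 0), c(8, 8))))
  expect_s3_class(tab, "data.frame")
  expect_equal(sum(tab$arm != "sweep_mapped"), 8)
  expect_equal(sum(tab$arm == "sweep_mapped"), 2)
  expect_setequal(unique(tab$arm[tab$arm != "sweep_mapped"]),
                  c("A_only", "B_only", "pooled_unmapped", "pooled_mapped"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})
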