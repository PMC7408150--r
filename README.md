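# gliomap

Pooling small multi-site brain-MRI cohorts for molecular subtype prediction
in low grade glioma (LGG). Hospitals hold small, scanner-biased MRI
collections; naively merging them makes a classifier spend its limited data
on coping with site effects. gliomap implements a harmonize-then-classify
pipeline in R:

1. **Unpaired CycleGAN domain mapping.** Generators `G_B : A -> B` and
   `G_A : B -> A` with patch-level discriminators, trained on the
   least-squares adversarial loss

   `L_GAN(G_B, D_B, A, B) = E_b[(D_B(b) - 1)^2] + E_a[D_B(G_B(a))^2]`

   plus an L1 cycle-consistency penalty
   `L_cyc = E_a ||G_A(G_B(a)) - a||_1 + E_b ||G_B(G_A(b)) - b||_1`,
   combined as `L = L_GAN^{A->B} + L_GAN^{B->A} + lambda * L_cyc`.
   The source domain is mapped and pooled: `D = mapped(A) ∪ B`.
2. **DCGAN augmentation.** Per modality (and class), a generator maps 100
   uniform noise values to a tumor slice; training stops near the
   discriminator's 0.5 equilibrium. Samples enlarge the pre-training set.
3. **Two-stream convolutional autoencoder classifier.** Tumor regions are
   extracted by a tight bounding box and rescaled to 64x64. Each modality
   stream encodes to an 8x8x512 map; streams are fused by element-wise
   aggregation `f = f1 ⊙ f2` and bilinear pooling `H = F'F`, then classified
   by two 256-unit fully connected layers with dropout and softmax. Training
   is two-stage: unsupervised reconstruction pre-training on augmented data,
   then supervised refinement with early stopping.
4. **Evaluation.** Strictly patient-separated 60/20/20 partitions, redrawn
   per run; accuracy / precision / recall / F1 with mean ± sd over runs; an
   ablation harness over {A, B, pooled raw, pooled mapped} × {pre-trained,
   from scratch} and an augmentation-size sweep.

Because the clinical cohorts are not publicly deposited, the package ships a
**synthetic phantom cohort generator** (two scanner domains differing by a
smooth bias field, gamma/contrast transform and noise; elliptical tumors
whose internal texture frequency encodes the class; two correlated
modalities; ground-truth masks), so the entire pipeline is testable and its
claims checkable without any download. All networks run on a small built-in
convolution engine (Rcpp im2col kernels + BLAS, manual backprop verified by
finite differences); no external deep-learning framework is required.

## Worked example

A scaled-down comparison of naive versus harmonized pooling on data-limited
phantom cohorts (6 patients per domain and class, 32x32 slices, 16x16 tumor
crops), three independent cohorts:

```r
library(gliomap)

toy <- function(mapping, seed) pipeline_options(
  k = 4, out_size = 16, mapping = mapping, separate_mapping = FALSE,
  pretrain = FALSE,
  cyclegan = cyclegan_spec(image_size = 32, channels = 1,
                           gen_filters = c(10), n_resblocks = 2,
                           disc_filters = c(8, 16), lambda = 20,
                           residual = TRUE, epochs = 10, lr_decay_start = 7,
                           iters_per_epoch = 50, lr = 4e-4, batch_size = 2),
  cae = cae_spec(input_size = 16, enc_filters = c(8, 16, 16),
                 pool_after = c(1, 2), dec_filters = c(16, 8, 1),
                 up_before = c(1, 2), batch_size = 8, epochs = 10),
  refine = list(epochs = 40, patience = 20, batch_size = 8, fc_width = 32,
                lr = 1e-3))

accs <- sapply(1:3, function(seed) {
  cohort <- generate_cohort(phantom_config(
    image_size = 32, n_patients = list(A = c(6, 6), B = c(6, 6)),
    slices_per_patient = 6, seed = seed))
  c(raw_pool = run_experiment(cohort, n_runs = 1, seed = seed,
                              opts = toy(FALSE, seed))$runs$accuracy,
    mapped_pool = run_experiment(cohort, n_runs = 1, seed = seed,
                                 opts = toy(TRUE, seed))$runs$accuracy)
})
round(accs, 3)
#>              [,1]  [,2]  [,3]
#> raw_pool    0.688 0.500 0.688
#> mapped_pool 0.750 0.875 0.812
round(rowMeans(accs), 3)
#>    raw_pool mapped_pool
#>       0.625       0.812
```

Each column is one synthetic two-site cohort. In the `raw_pool` arm the two
scanner domains are simply concatenated; in the `mapped_pool` arm a CycleGAN
is first trained (unsupervised, no labels) on all slices, domain A is mapped
onto domain B, and the pooled data are used instead. Both arms then train
the two-stream classifier on a patient-separated 60/20/20 partition and
report slice-level test accuracy (16 held-out slices per cohort; 0.812 = 13
of 16 correct). Harmonized pooling wins in every cohort — mean +18.7
accuracy points — which is the effect the pipeline exists to deliver.
`run_experiment(..., n_runs = 5)` reproduces the mean ± sd report layout of
a multi-run evaluation, `run_ablation()` produces the full arm table, and
`scripts/acceptance.R` (below) recomputes the seed-averaged comparison
including the pre-training arm.

At published scale the constructors default to the full configuration
(128x128 slices, 9 residual blocks of 128 filters, 512-channel encoders,
DCGAN at z = 100 / batch 64 / lr 0.002, CAE pre-training at lr 0.002 /
batch 16 / 200 epochs, L2 1e-4, dropout 0.5); see the methods vignette
(`vignettes/harmonization-pipeline.Rmd`) for every parameter, the numerical
choices, and what phantom results do and do not demonstrate.

A thin command-line front-end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gliomap", package="gliomap"))')" \
  phantom --out cohort_dir --size 128 --patients 10 --seed 1
```

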