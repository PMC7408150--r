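# Shared reduced-scale constructors for the test suite. These mirror the
# full pipeline at 32x32 phantom resolution and 16x16 tumor crops with
# reduced filter counts so training-based properties run on one CPU.

toy_phantom <- function(seed = 1, n_a = c(8, 8), n_b = c(8, 8),
                        slices = 6, size = 32) {
  phantom_config(image_size = size,
                 n_patients = list(A = n_a, B = n_b),
                 slices_per_patient = slices, seed = seed)
}

toy_cyclegan_spec <- function(seed = 1, epochs = 12, iters = 50) {
  cyclegan_spec(image_size = 32, channels = 1, gen_filters = c(10),
                n_resblocks = 2, disc_filters = c(8, 16), lambda = 20,
                residual = TRUE, epochs = epochs,
                lr_decay_start = ceiling(epochs * 2 / 3),
                iters_per_epoch = iters, lr = 4e-4, batch_size = 2,
                seed = seed)
}

toy_dcgan_spec <- function(seed = 1, epochs = 8) {
  dcgan_spec(image_size = 16, channels = 1, z_dim = 16,
             g_dense_channels = 32, g_filters = c(16, 8),
             d_filters = c(8, 16), batch_size = 8, epochs = epochs,
             equilibrium_tol = 0.02, seed = seed)
}

toy_cae_spec <- function(seed = 1, epochs = 10) {
  cae_spec(input_size = 16, enc_filters = c(8, 16, 16), pool_after = c(1, 2),
           dec_filters = c(16, 8, 1), up_before = c(1, 2), batch_size = 8,
           epochs = epochs, seed = seed)
}

toy_refine_args <- function() {
  list(epochs = 50, patience = 25, batch_size = 8, fc_width = 32, lr = 1e-3)
}

# stratified patient-level split of a slice_dataset
split_toy_dataset <- function(ds, seed = 1) {
  ids <- unique(ds$patient_id)
  cls <- ds$y[match(ids, ds$patient_id)]
  split <- partition_patients(ids, labels = cls, seed = seed)
  lapply(c(train = "train", val = "val", test = "test"), function(s)
    gliomap:::dataset_subset(ds, split[ds$patient_id] == s))
}
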