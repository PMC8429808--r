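# Shared miniature fixtures, built once per test session.

mini_grid <- c(12L, 12L, 8L)

mini_sim_config <- function(signature_amplitude = 5, group_amplitude = 0,
                            n_timepoints = 12L, seed = 11L, ...) {
  sim_config(grid_shape = mini_grid, n_timepoints = n_timepoints,
             signature_amplitude = signature_amplitude,
             group_amplitude = group_amplitude, noise_sd = 1,
             smoothing_sigma_vox = 1, seed = seed, ...)
}

mini_encoder_config <- function(n_subjects = 6L) {
  encoder_config(mini_grid, n_subjects = n_subjects, n_blocks = 1L,
                 base_channels = 4L, n_tail_convs = 1L)
}

.fixture_cache <- new.env(parent = emptyenv())

# A small trained encoder plus its training data, cached for the session.
mini_trained <- function() {
  if (!is.null(.fixture_cache$mini)) return(.fixture_cache$mini)
  cohort <- make_cohort(3, 3, seed = 11L)
  ds <- simulate_dataset(cohort, mini_sim_config())
  enc <- train_encoder(ds$scans, names(ds$scans), mini_encoder_config(),
                       train_config(lr_schedule = list(c(1e-3, 400L)),
                                    batch_size = 4L, seed = 11L,
                                    log_every = 100L))
  .fixture_cache$mini <- list(cohort = cohort, ds = ds, enc = enc)
  .fixture_cache$mini
}

# An untrained encoder (zero dense layer) over n subjects.
untrained_encoder <- function(n_subjects = 5L, seed = 2L) {
  cfg <- mini_encoder_config(n_subjects)
  spec <- build_encoder(cfg)
  structure(list(spec = spec,
                 weights = fmrisid:::init_weights(spec, seed),
                 log = data.frame(), subjects = sprintf("s%d", 1:n_subjects),
                 train_config = NULL),
            class = "trained_encoder")
}

random_feature_set <- function(n_subjects, n_per, d, sd_within = 1,
                               separation = 0, seed = 1L) {
  set.seed(seed)
  ctr <- matrix(rnorm(n_subjects * d), n_subjects) * separation
  X <- ctr[rep(seq_len(n_subjects), each = n_per), , drop = FALSE] +
    matrix(rnorm(n_subjects * n_per * d, sd = sd_within), n_subjects * n_per)
  feature_set(X, rep(sprintf("s%02d", seq_len(n_subjects)), each = n_per),
              rep(seq_len(n_per), n_subjects))
}
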