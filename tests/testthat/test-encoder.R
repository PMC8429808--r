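test_that("the full-scale architecture matches its worked examples", {
  cfg <- encoder_config(c(80, 96, 80), n_subjects = 105)
  spec <- build_encoder(cfg)
  expect_identical(spec$dense_channels, 128L)       # channels before dense
  expect_identical(spec$pre_flatten_shape, c(5L, 6L, 5L))
  dense <- spec$layers[nrow(spec$layers), ]
  expect_identical(dense$kind, "dense")
  expect_identical(dense$channels_out, 105L)
  # spatial volume shrinks 8x per block
  pools <- spec$layers[spec$layers$kind == "pool", ]
  vols <- pools$out_x * pools$out_y * pools$out_z
  expect_equal(vols[-length(vols)] / vols[-1], rep(8, 3))
})

test_that("parameter totals equal an independent hand count", {
  spec <- build_encoder(encoder_config(c(12, 12, 8), n_subjects = 6,
                                       n_blocks = 1, base_channels = 4,
                                       n_tail_convs = 1))
  # conv 1->4, conv 4->8, pool, conv 8->8, dense on 6*6*4*8 = 1152 features
  hand <- (27 * 1 + 1) * 4 + (27 * 4 + 1) * 8 + (27 * 8 + 1) * 8 +
    (6 * 6 * 4 * 8 + 1) * 6
  expect_equal(spec$total_parameters, hand)
  # global pooling variant swaps the dense input width
  spec_gp <- build_encoder(encoder_config(c(12, 12, 8), n_subjects = 6,
                                          n_blocks = 1, base_channels = 4,
                                          n_tail_convs = 1,
                                          dense_input = "global_pool"))
  expect_equal(spec_gp$total_parameters,
               hand - (6 * 6 * 4 * 8 + 1) * 6 + (8 + 1) * 6)
})

test_that("indivisible input shapes fail at build with the axis named", {
  expect_error(encoder_config(c(81, 96, 80), n_subjects = 10), "dim x")
  expect_error(encoder_config(c(80, 98, 80), n_subjects = 10), "dim y")
  expect_no_error(encoder_config(c(80, 96, 80), n_subjects = 10))
})

test_that("an untrained encoder classifies every timepoint uniformly", {
  enc <- untrained_encoder(n_subjects = 5)
  set.seed(3)
  vol <- array(rnorm(prod(mini_grid)), mini_grid)
  p <- classify_timepoint(enc, vol)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(unname(p), rep(1 / 5, 5), tolerance = 1e-6)
  expect_error(classify_timepoint(enc, array(0, c(4, 4, 4))),
               "does not match")
})

test_that("softmax probabilities are shift invariant and normalised", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(9) * 10^runif(1, -2, 2)
    p <- softmax(x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(softmax(x - mean(x)), p, tolerance = 1e-12)
  }
})

test_that("training on a strong identity signal recovers the subjects", {
  fx <- mini_trained()
  acc <- training_accuracy(fx$enc, fx$ds$scans, names(fx$ds$scans))
  expect_gte(acc, 0.9)
  # log well-formed: finite losses, monotone iterations
  expect_true(all(is.finite(fx$enc$log$loss)))
  expect_true(all(diff(fx$enc$log$iteration) > 0))
})

test_that("training reaches high accuracy across seeds; null stays at chance", {
  cohort <- make_cohort(3, 3, seed = 17)
  ds <- simulate_dataset(cohort, mini_sim_config(seed = 91L))
  for (seed in c(1L, 2L, 3L)) {
    enc <- train_encoder(ds$scans, names(ds$scans), mini_encoder_config(),
                         train_config(lr_schedule = list(c(1e-3, 400L)),
                                      batch_size = 4L, seed = seed,
                                      log_every = 400L))
    expect_gte(training_accuracy(enc, ds$scans, names(ds$scans)), 0.9)
  }
  # zero-signal null: held-out accuracy within binomial noise of chance
  cfg0 <- mini_sim_config(signature_amplitude = 0, seed = 92L)
  ds0 <- simulate_dataset(cohort, cfg0)
  enc0 <- train_encoder(ds0$scans, names(ds0$scans), mini_encoder_config(),
                        train_config(lr_schedule = list(c(1e-3, 300L)),
                                     batch_size = 4L, seed = 1L,
                                     log_every = 300L))
  held <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_scan(cohort[i, ], cfg0, session = 2L))
  acc0 <- training_accuracy(enc0, held, cohort$subject_id)
  n <- nrow(cohort) * 12
  expect_lt(acc0, 1 / 6 + 3 * sqrt((1 / 6) * (5 / 6) / n))
})

test_that("training is deterministic under fixed seeds", {
  cohort <- make_cohort(2, 2, seed = 19)
  ds <- simulate_dataset(cohort, mini_sim_config(seed = 93L, n_timepoints = 6L))
  run <- function() {
    train_encoder(ds$scans, names(ds$scans),
                  mini_encoder_config(n_subjects = 4L),
                  train_config(lr_schedule = list(c(1e-3, 60L)),
                               batch_size = 4L, seed = 7L, log_every = 10L))
  }
  e1 <- run(); e2 <- run()
  expect_identical(e1$log, e2$log)
  expect_identical(e1$weights, e2$weights)
})

test_that("training_accuracy equals a per-timepoint classification loop", {
  fx <- mini_trained()
  scans <- fx$ds$scans[1:3]
  acc <- training_accuracy(fx$enc, scans, names(scans))
  correct <- 0L; total <- 0L
  for (id in names(scans)) {
    a <- scans[[id]]$data
    for (t in seq_len(dim(a)[4])) {
      p <- classify_timepoint(fx$enc, a[, , , t])
      if (names(which.max(p)) == id) correct <- correct + 1L
      total <- total + 1L
    }
  }
  expect_equal(acc, correct / total)
})

test_that("checkpoints round-trip through save and load", {
  fx <- mini_trained()
  dir <- file.path(tempdir(), "ckpt")
  save_encoder(fx$enc, dir)
  back <- load_encoder(dir)
  expect_equal(back$weights, fx$enc$weights, tolerance = 1e-12)
  expect_identical(back$subjects, fx$enc$subjects)
  set.seed(5)
  vol <- array(rnorm(prod(mini_grid)), mini_grid)
  expect_equal(classify_timepoint(back, vol), classify_timepoint(fx$enc, vol),
               tolerance = 1e-12)
})
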