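test_that("make_cohort produces the requested structure deterministically", {
  tab <- make_cohort(9, 9, age_range = c(18, 65), seed = 1)
  expect_identical(nrow(tab), 18L)
  expect_identical(sum(tab$group == "patient"), 9L)
  expect_true(all(tab$age >= 18 & tab$age <= 65))
  expect_identical(tab, make_cohort(9, 9, age_range = c(18, 65), seed = 1))
  single <- make_cohort(1, 0, seed = 3)
  expect_identical(nrow(single), 1L)
  expect_error(make_cohort(0, 0), "empty cohort")
})

test_that("identical seeds give bit-identical datasets", {
  cohort <- make_cohort(2, 2, seed = 5)
  cfg <- mini_sim_config(seed = 21L, n_timepoints = 4L)
  d1 <- simulate_dataset(cohort, cfg)
  d2 <- simulate_dataset(cohort, cfg)
  for (id in cohort$subject_id) {
    expect_identical(d1$scans[[id]]$data, d2$scans[[id]]$data)
  }
  expect_identical(d1$group_map, d2$group_map)
})

test_that("voxelwise temporal variance matches the configured noise", {
  cfg <- sim_config(grid_shape = c(8, 8, 8), n_timepoints = 400L,
                    signature_amplitude = 2, noise_sd = 1.3,
                    smoothing_sigma_vox = 1, seed = 31L)
  sub <- make_cohort(1, 0, seed = 1)
  scan <- simulate_scan(sub, cfg)
  v <- apply(scan$data, 1:3, var)
  expect_equal(mean(v), 1.3^2, tolerance = 0.03)
})

test_that("the subject signature persists across sessions", {
  cfg <- mini_sim_config(seed = 41L)
  cohort <- make_cohort(0, 2, seed = 7)
  a1 <- simulate_scan(cohort[1, ], cfg, session = 1)
  a2 <- simulate_scan(cohort[1, ], cfg, session = 2)
  b1 <- simulate_scan(cohort[2, ], cfg, session = 1)
  expect_false(identical(a1$data, a2$data))  # fresh noise per session
  m_a1 <- apply(a1$data, 1:3, mean); m_a2 <- apply(a2$data, 1:3, mean)
  m_b1 <- apply(b1$data, 1:3, mean)
  same <- cor(as.vector(m_a1), as.vector(m_a2))
  diff <- cor(as.vector(m_a1 - m_b1), as.vector(m_a2 - m_b1))
  expect_gt(same, 0.99)  # shared baseline + signature dominate
  # subject-specific residual agrees across sessions only for the owner
  expect_gt(diff, 0.5)
})

test_that("with no spatial effects two subjects differ only by noise", {
  cfg <- mini_sim_config(signature_amplitude = 0, seed = 51L,
                         n_timepoints = 50L)
  cohort <- make_cohort(1, 1, seed = 9)
  m1 <- apply(simulate_scan(cohort[1, ], cfg)$data, 1:3, mean)
  m2 <- apply(simulate_scan(cohort[2, ], cfg)$data, 1:3, mean)
  # mean difference is zero-mean noise of order noise_sd / sqrt(T)
  expect_lt(abs(mean(m1 - m2)), 3 * 1 / sqrt(50 * prod(mini_grid)))
  expect_lt(sd(m1 - m2), 3 * sqrt(2 / 50))
})

test_that("subject identifiability rises with the signature amplitude", {
  cohort <- make_cohort(3, 3, seed = 13)
  accs <- vapply(c(0, 1, 5), function(a) {
    oracle_nearest_mean_accuracy(cohort,
                                 mini_sim_config(signature_amplitude = a,
                                                 n_timepoints = 10L,
                                                 seed = 61L))
  }, numeric(1))
  expect_lt(accs[1], 0.45)          # near chance (1/6) without a signature
  expect_gt(accs[3], 0.9)           # strong signature is identifiable
  expect_true(all(diff(accs) >= -0.05))  # monotone within noise
})

test_that("the group effect map is recoverable from group mean difference", {
  cfg <- mini_sim_config(group_amplitude = 3, seed = 71L, n_timepoints = 20L)
  cohort <- make_cohort(6, 6, seed = 15)
  ds <- simulate_dataset(cohort, cfg)
  means <- lapply(ds$scans, function(s) apply(s$data, 1:3, mean))
  pat <- Reduce(`+`, means[cohort$subject_id[cohort$group == "patient"]]) / 6
  ctl <- Reduce(`+`, means[cohort$subject_id[cohort$group == "control"]]) / 6
  expect_gt(cor(as.vector(pat - ctl), as.vector(ds$group_map)), 0.6)
})

test_that("simulate_dataset writes consumable NIfTI scans and a table", {
  dir <- file.path(tempdir(), "simds")
  cohort <- make_cohort(1, 1, seed = 2)
  cfg <- mini_sim_config(n_timepoints = 3L, seed = 81L)
  ds <- simulate_dataset(cohort, cfg, dir = dir)
  back <- read_scan(file.path(dir, paste0(cohort$subject_id[1], ".nii.gz")))
  expect_equal(back$data, ds$scans[[1]]$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(as.data.frame(read_subject_table(file.path(dir, "subjects.csv"))),
               as.data.frame(cohort))
})
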