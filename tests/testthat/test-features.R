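test_that("feature extraction yields one dense-layer vector per timepoint", {
  fx <- mini_trained()
  scans <- fx$ds$scans[1:2]
  fs <- extract_features(fx$enc, scans)
  expect_s3_class(fs, "feature_set")
  expect_identical(nrow(fs), 2L * 12L)
  expect_identical(attr(fs, "variant"), "classification")
  # loop oracle: single-timepoint dense evaluations agree with the batch
  X <- fmrisid:::feature_matrix(fs)
  i <- 0L
  for (id in names(scans)) {
    a <- scans[[id]]$data
    for (t in seq_len(dim(a)[4])) {
      i <- i + 1L
      single <- drop(fmrisid:::encoder_logits(
        fx$enc, matrix(as.numeric(a[, , , t]), ncol = 1)))
      expect_equal(unname(X[i, ]), unname(single), tolerance = 1e-5)
    }
  }
  # identical timepoints give identical vectors
  dup <- scans[[1]]
  dup$data[, , , 2] <- dup$data[, , , 1]
  fs2 <- extract_features(fx$enc, list(dup))
  X2 <- fmrisid:::feature_matrix(fs2)
  expect_identical(X2[1, ], X2[2, ])
})

test_that("mean-centring behaves as classification+ and keeps the softmax", {
  expect_equal(center_features(c(1, 2, 3)), c(-1, 0, 1))
  fs <- random_feature_set(3, 4, 6, seed = 2)
  fp <- center_features(fs)
  expect_identical(attr(fp, "variant"), "classification_plus")
  Xp <- fmrisid:::feature_matrix(fp)
  expect_lt(max(abs(rowMeans(Xp))), 1e-9)
  # idempotent
  expect_equal(fmrisid:::feature_matrix(center_features(fp)), Xp,
               tolerance = 1e-14)
  # softmax unchanged to 1e-12
  X <- fmrisid:::feature_matrix(fs)
  for (i in seq_len(nrow(X))) {
    expect_equal(softmax(Xp[i, ]), softmax(X[i, ]), tolerance = 1e-12)
  }
})

test_that("identity features are per-subject means and commute with centring", {
  fs <- feature_set(rbind(c(0, 2), c(2, 0)), c("a", "a"), c(1, 2))
  ident <- identity_features(fs)
  expect_equal(unname(fmrisid:::identity_matrix(ident)), rbind(c(1, 1)))
  expect_identical(ident$n_timepoints, 2L)
  # single vector: identity is itself
  one <- identity_features(feature_set(rbind(c(3, 4)), "z", 1L))
  expect_equal(unname(fmrisid:::identity_matrix(one)), rbind(c(3, 4)))
  # linearity: identity(center(F)) = center-by-row(identity(F))
  fs2 <- random_feature_set(4, 5, 7, seed = 3)
  a <- fmrisid:::identity_matrix(identity_features(center_features(fs2)))
  b <- fmrisid:::identity_matrix(identity_features(fs2))
  expect_equal(a, b - rowMeans(b), tolerance = 1e-12)
})

test_that("precision_at_k matches the exhaustive selection-sort oracle", {
  set.seed(14)
  for (rep in 1:4) {
    n_sub <- sample(3:6, 1)
    n_per <- sample(3:8, 1)
    d <- sample(2:5, 1)
    fs <- random_feature_set(n_sub, n_per, d, separation = runif(1, 0, 3),
                             seed = 100 + rep)
    ident <- identity_features(fs)
    k <- sample.int(n_sub * n_per, 1)
    got <- precision_at_k(fs, ident, k = k)
    want <- oracle_precision_at_k(
      fmrisid:::feature_matrix(fs), fs$subject_id, fs$timepoint,
      fmrisid:::identity_matrix(ident), ident$subject_id, k)
    expect_equal(got$precision, want, tolerance = 1e-12)
    expect_equal(attr(got, "mean_precision"), mean(want), tolerance = 1e-12)
    # precision@k <= min(1, n_i / k)
    expect_true(all(got$precision <= pmin(1, n_per / k) + 1e-12))
  }
})

test_that("precision handles its limit cases and degenerate ties", {
  # well-separated clusters: every precision is 1
  fs <- random_feature_set(5, 20, 4, sd_within = 0.01, separation = 10,
                           seed = 6)
  pr <- precision_at_k(fs, k = 20)
  expect_true(all(pr$precision == 1))
  # k = 1 with the subject's own vector closest
  fs1 <- feature_set(rbind(c(0, 0), c(5, 5)), c("a", "b"), c(1, 1))
  id1 <- identity_features(fs1)
  expect_equal(precision_at_k(fs1, id1, k = 1)$precision, c(1, 1))
  # identical vectors: deterministic tie-break by subject then timepoint
  fs_tie <- feature_set(matrix(1, 4, 2), c("a", "a", "b", "b"), c(1, 2, 1, 2))
  pr_tie <- precision_at_k(fs_tie, k = 2)
  expect_equal(pr_tie$precision[pr_tie$subject_id == "a"], 1)
  expect_equal(pr_tie$precision[pr_tie$subject_id == "b"], 0)
  # errors
  expect_error(precision_at_k(fs1, id1, k = 3), "exceeds the pool")
  id_bad <- id1; id_bad$subject_id <- c("a", "zzz")
  expect_error(precision_at_k(fs1, id_bad, k = 1), "missing from")
})

test_that("distance ranking is invariant to a common translation", {
  fs <- random_feature_set(4, 6, 5, separation = 2, seed = 8)
  ident <- identity_features(fs)
  shift <- rnorm(5)
  fs_sh <- feature_set(sweep(fmrisid:::feature_matrix(fs), 2, -shift),
                       fs$subject_id, fs$timepoint)
  ident_sh <- identity_features(fs_sh)
  expect_equal(precision_at_k(fs, ident, k = 6)$precision,
               precision_at_k(fs_sh, ident_sh, k = 6)$precision)
})

test_that("feature tables round-trip through TSV", {
  fs <- random_feature_set(3, 4, 5, seed = 10)
  path <- tempfile(fileext = ".tsv")
  write_features(fs, path)
  back <- read_features(path)
  expect_equal(fmrisid:::feature_matrix(back), fmrisid:::feature_matrix(fs),
               tolerance = 1e-12)
  expect_identical(attr(back, "variant"), attr(fs, "variant"))
  ident <- identity_features(fs)
  write_features(ident, path)
  back2 <- read_features(path)
  expect_equal(fmrisid:::identity_matrix(back2),
               fmrisid:::identity_matrix(ident), tolerance = 1e-12)
})
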