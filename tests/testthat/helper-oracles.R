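# Independent brute-force oracles used to cross-check the implementation.

# ROI pooling by explicit voxel loop.
oracle_pool_rois <- function(a, labels, n_rois) {
  Tn <- dim(a)[4L]
  out <- matrix(NA_real_, Tn, n_rois)
  for (t in seq_len(Tn)) {
    for (r in seq_len(n_rois)) {
      vals <- c()
      for (x in seq_len(dim(a)[1L])) for (y in seq_len(dim(a)[2L]))
        for (z in seq_len(dim(a)[3L])) {
          if (labels[x, y, z] == r) vals <- c(vals, a[x, y, z, t])
        }
      out[t, r] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  out
}

# precision@k by repeated minimum extraction under the lexicographic
# (distance, subject_id, timepoint) order: an O(N^2) selection sort that
# shares no code with the ranking implementation.
oracle_precision_at_k <- function(X, subject_id, timepoint, ident_X,
                                  ident_subject, k) {
  prec <- numeric(length(ident_subject))
  for (i in seq_along(ident_subject)) {
    d <- sqrt(rowSums(sweep(X, 2L, ident_X[i, ])^2))
    remaining <- seq_len(nrow(X))
    hits <- 0L
    for (pick in seq_len(k)) {
      best <- remaining[1L]
      for (j in remaining) {
        if (d[j] < d[best] ||
            (d[j] == d[best] && subject_id[j] < subject_id[best]) ||
            (d[j] == d[best] && subject_id[j] == subject_id[best] &&
             timepoint[j] < timepoint[best])) {
          best <- j
        }
      }
      if (subject_id[best] == ident_subject[i]) hits <- hits + 1L
      remaining <- setdiff(remaining, best)
    }
    prec[i] <- hits / k
  }
  prec
}

# Exact upper-tail binomial probability at p = 1/2 by integer enumeration:
# sum_{j >= j0} choose(n, j) / 2^n with exact integer arithmetic (doubles
# are exact here for n <= 25 since choose(25, j) < 2^53).
oracle_sign_test_half <- function(n_correct, n) {
  total <- 0
  for (j in seq.int(n_correct, n)) total <- total + choose(n, j)
  total / 2^n
}

# Pearson r and its two-sided t-based p-value from the explicit formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# Nearest-centroid subject classification on raw volumes: centroids from
# session-1 scans, queries from session-2 timepoints.
oracle_nearest_mean_accuracy <- function(cohort, cfg) {
  centroids <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- simulate_scan(cohort[i, ], cfg, session = 1L)
    apply(s$data, 1:3, mean)
  })
  correct <- 0L
  total <- 0L
  for (i in seq_len(nrow(cohort))) {
    s <- simulate_scan(cohort[i, ], cfg, session = 2L)
    for (t in seq_len(dim(s$data)[4L])) {
      d <- vapply(centroids, function(ctr) sum((s$data[, , , t] - ctr)^2),
                  numeric(1))
      if (which.min(d) == i) correct <- correct + 1L
      total <- total + 1L
    }
  }
  correct / total
}
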