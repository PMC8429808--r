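make_identities <- function(X, ids) {
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  out <- data.frame(subject_id = ids, n_timepoints = 1L, X,
                    stringsAsFactors = FALSE)
  class(out) <- c("identity_set", "data.frame")
  out
}

test_that("the diagnosis classifier separates separable identities", {
  set.seed(31)
  X <- rbind(matrix(rnorm(10 * 2, mean = 2, sd = 0.3), 10),
             matrix(rnorm(10 * 2, mean = -2, sd = 0.3), 10))
  ids <- sprintf("s%02d", 1:20)
  labels <- rep(c("patient", "control"), each = 10)
  ident <- make_identities(X, ids)
  fit <- fit_diagnosis(ident, labels, lambda = 0.01)
  expect_identical(unname(predict(fit, ident)), labels)
  # duplicated dataset gives the identical decision function
  fit2 <- fit_diagnosis(ident, labels, lambda = 0.01)
  expect_identical(fit$weights, fit2$weights)
  expect_error(fit_diagnosis(ident, rep("patient", 20)), "both classes")
})

test_that("diagnosis predictions follow the sign rule with ties to control", {
  model <- structure(list(weights = c(1, 0), intercept = 0,
                          task = "diagnosis"), class = "diagnosis_model")
  X <- rbind(c(2, 9), c(-2, 9), c(0, 9))
  expect_identical(unname(predict(model, X)),
                   c("patient", "control", "control"))
  expect_error(predict(model, matrix(1, 1, 3)), "dimension")
})

test_that("shuffled labels give chance-level test accuracy", {
  set.seed(32)
  accs <- replicate(20, {
    X <- matrix(rnorm(24 * 4), 24)
    ident <- make_identities(X, sprintf("s%02d", 1:24))
    labels <- sample(rep(c("patient", "control"), each = 12))
    fit <- fit_diagnosis(ident[1:16, ], labels[1:16], lambda = 0.1)
    mean(predict(fit, ident[17:24, ]) == labels[17:24])
  })
  # replicate accuracies are overdispersed relative to pooled binomial
  # noise (all 8 test predictions share one fitted model), so compare the
  # mean to chance with a t-test across replicates
  expect_gt(t.test(accs, mu = 0.5)$p.value, 0.01)
})

test_that("sign_test reproduces printed p-values and the exact tail", {
  expect_equal(signif(sign_test(14, 18), 2), 0.015)
  expect_equal(signif(sign_test(13, 18), 2), 0.048)
  expect_equal(sign_test(18, 18), 2^-18, tolerance = 1e-12)
  expect_equal(sign_test(0, 18), 1)
  expect_error(sign_test(19, 18), "n_correct")
})

test_that("sign_test equals exact binomial enumeration for all n <= 25", {
  for (n in 1:25) {
    for (k in 0:n) {
      expect_equal(sign_test(k, n), oracle_sign_test_half(k, n),
                   tolerance = 1e-12)
    }
    # monotone decreasing in n_correct
    p <- vapply(0:n, sign_test, numeric(1), n = n)
    expect_true(all(diff(p) < 0))
  }
  # non-half chance probability agrees with the distribution function
  expect_equal(sign_test(7, 10, p0 = 0.3),
               sum(dbinom(7:10, 10, 0.3)), tolerance = 1e-12)
})

test_that("age regression recovers an exact linear signal at lambda zero", {
  set.seed(33)
  X <- cbind(runif(12, 20, 60), rnorm(12))
  ages <- 2 * X[, 1] + 5
  ident <- make_identities(X, sprintf("s%02d", 1:12))
  fit <- fit_age(ident, ages, lambda = 0)
  expect_equal(unname(fit$weights[1]), 2, tolerance = 1e-8)
  expect_equal(unname(predict(fit, ident)), unname(ages), tolerance = 1e-6)
  # pure-noise features: test-set correlation near zero on average
  set.seed(34)
  rs <- replicate(20, {
    Xn <- matrix(rnorm(30 * 3), 30)
    idn <- make_identities(Xn, sprintf("s%02d", 1:30))
    agesn <- runif(30, 20, 60)
    f <- fit_age(idn[1:20, ], agesn[1:20], lambda = 1)
    cor(predict(f, idn[21:30, ]), agesn[21:30])
  })
  expect_lt(abs(mean(rs)), 0.25)
  expect_error(fit_age(make_identities(matrix(1, 1, 2), "a"), 30), "2 subjects")
})

test_that("pearson_test matches cor.test and its explicit formula", {
  expect_equal(pearson_test(1:5, 1:5)$r, 1)
  set.seed(35)
  x <- rnorm(5); y <- x + rnorm(5)
  got <- pearson_test(x, y)
  want <- oracle_pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  # r = 0.57 at n = 18 sits at the printed p = 0.013 within rounding of r
  r <- 0.57; n <- 18
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tt), df = n - 2)
  expect_gt(p, 0.012); expect_lt(p, 0.015)
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

test_that("run_experiment3 produces one well-formed row per method and task", {
  set.seed(36)
  tab <- make_cohort(8, 8, seed = 36)
  sp <- stratified_split(tab, list(train2 = c(4, 4), test = c(4, 4)), seed = 1)
  # a signal method: feature 1 encodes the group; and a noise method
  grp <- as.integer(tab$group == "patient")
  Xs <- cbind(grp * 4 + rnorm(16, sd = 0.3), rnorm(16))
  Xn <- matrix(rnorm(16 * 2), 16)
  methods <- list(signal = make_identities(Xs, tab$subject_id),
                  noise = make_identities(Xn, tab$subject_id))
  res <- run_experiment3(methods, tab, sp)
  expect_identical(nrow(res), 4L)
  expect_setequal(res$task, c("diagnosis", "age"))
  diag_rows <- res[res$task == "diagnosis", ]
  expect_true(all(diag_rows$value * diag_rows$n_test ==
                    round(diag_rows$value * diag_rows$n_test)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_lt(diag_rows$p_value[diag_rows$method == "signal"], 0.05)
  # determinism
  res2 <- run_experiment3(methods, tab, sp)
  expect_equal(as.data.frame(res), as.data.frame(res2))
  # empty method list gives an empty table
  empty <- run_experiment3(list(), tab, sp)
  expect_identical(nrow(empty), 0L)
  # missing subjects are an error
  expect_error(run_experiment3(list(bad = methods$signal[1:3, ]), tab, sp),
               "lacks identity features")
})
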