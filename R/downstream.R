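#' Linear diagnosis classifier on identity features
#'
#' Logistic-loss linear model predicting patient vs control from identity
#' features. With D features and few training subjects the problem is
#' underdetermined, so an L2 (ridge) penalty with a fixed strength is
#' applied; the fit is deterministic given the data and `lambda`.
#'
#' @param identities an `identity_set` for the training subjects.
#' @param labels character vector (`"patient"`/`"control"`) aligned with
#'   `identities`, or a `subject_table` to look them up in.
#' @param lambda ridge penalty (glmnet scale).
#' @return a `diagnosis_model`.
#' @export
fit_diagnosis <- function(identities, labels, lambda = 0.1) {
  X <- identity_matrix(identities)
  y <- lookup_labels(identities$subject_id, labels, "group")
  if (length(unique(y)) < 2L) stop("both classes must be present for the fit")
  yb <- as.integer(y == "patient")
  fit <- glmnet::glmnet(X, yb, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(weights = as.numeric(fit$beta), intercept = as.numeric(fit$a0),
                 lambda = lambda, task = "diagnosis", loss = "logistic"),
            class = "diagnosis_model")
}

#' Predict diagnosis from identity features
#'
#' Classifies by the sign of the linear score; a score of exactly 0 is
#' assigned to the control class.
#'
#' @param object a `diagnosis_model`.
#' @param identities an `identity_set` (or bare feature matrix).
#' @param ... unused.
#' @return character vector of `"patient"` / `"control"`.
#' @export
predict.diagnosis_model <- function(object, identities, ...) {
  X <- if (is.matrix(identities)) identities else identity_matrix(identities)
  if (ncol(X) != length(object$weights)) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), length(object$weights)))
  }
  score <- drop(X %*% object$weights) + object$intercept
  ifelse(score > 0, "patient", "control")
}

#' Exact one-sided sign test against chance
#'
#' Upper-tail exact binomial probability `P(X >= n_correct)` for `X ~
#' Binomial(n, p0)`: the probability of at least the observed number of
#' correct test classifications if the true per-subject success probability
#' were the chance level `p0`.
#'
#' @param n_correct number of correct classifications, `0..n`.
#' @param n number of test subjects.
#' @param p0 chance probability (default 0.5).
#' @return the one-sided p-value.
#' @export
sign_test <- function(n_correct, n, p0 = 0.5) {
  if (n_correct < 0 || n_correct > n || n < 1) {
    stop("need 0 <= n_correct <= n with n >= 1")
  }
  stats::pbinom(n_correct - 1L, size = n, prob = p0, lower.tail = FALSE)
}

#' Linear age regression on identity features
#'
#' Ridge-penalised least squares fitted in closed form on centred features:
#' `(X'X + n * lambda * I) b = X'y`. `lambda = 0` gives ordinary least
#' squares (requiring full column rank).
#'
#' @param identities an `identity_set` for the training subjects.
#' @param ages numeric vector aligned with `identities`, or a
#'   `subject_table` to look ages up in.
#' @param lambda ridge penalty; default 1 is conservative for the p >> n
#'   regime of identity features.
#' @return an `age_model`.
#' @export
fit_age <- function(identities, ages, lambda = 1) {
  X <- identity_matrix(identities)
  y <- as.numeric(lookup_labels(identities$subject_id, ages, "age"))
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ybar <- mean(y)
  A <- crossprod(Xc) + nrow(X) * lambda * diag(ncol(X))
  beta <- tryCatch(solve(A, crossprod(Xc, y - ybar)),
                   error = function(e) stop("degenerate design: ", conditionMessage(e)))
  structure(list(weights = drop(beta), center = ctr, intercept = ybar,
                 lambda = lambda, task = "age", loss = "squared"),
            class = "age_model")
}

#' @export
predict.age_model <- function(object, identities, ...) {
  X <- if (is.matrix(identities)) identities else identity_matrix(identities)
  drop(sweep(X, 2L, object$center) %*% object$weights) + object$intercept
}

#' Pearson correlation test between predicted and actual values
#'
#' Pearson r with a two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param predicted,actual numeric vectors of equal length >= 3, neither
#'   constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_test <- function(predicted, actual) {
  n <- length(predicted)
  stopifnot(length(actual) == n)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    stop("constant vector: correlation undefined")
  }
  r <- sum(scale(predicted) * scale(actual)) / (n - 1L)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = min(p, 1), n = n)
}

lookup_labels <- function(subject_ids, labels, column) {
  if (inherits(labels, "subject_table") ||
      (is.data.frame(labels) && column %in% names(labels))) {
    idx <- match(subject_ids, labels$subject_id)
    if (anyNA(idx)) stop("subject id(s) missing from the subject table")
    labels[[column]][idx]
  } else {
    stopifnot(length(labels) == length(subject_ids))
    labels
  }
}

#' Evaluate feature methods on diagnosis and age tasks
#'
#' For every feature method, fits the linear diagnosis classifier and age
#' regressor on the train2 identity features and evaluates on the test
#' split: diagnosis accuracy with its one-sided sign-test p-value, and age
#' Pearson r with its two-sided p-value.
#'
#' @param features_by_method named list of `identity_set`s covering at least
#'   the train2 and test subjects.
#' @param table a `subject_table` with group and age.
#' @param split a `split_spec` with `train2` and `test` splits.
#' @param tasks subset of `c("diagnosis", "age")`.
#' @param lambda_diagnosis,lambda_age ridge penalties passed to the fits.
#' @return an `eval_table` data.frame: one row per (method, task) with
#'   columns `method, task, n_test, metric, value, statistic, p_value`,
#'   and per-subject test predictions in `attr(, "predictions")`.
#' @export
run_experiment3 <- function(features_by_method, table, split,
                            tasks = c("diagnosis", "age"),
                            lambda_diagnosis = 0.1, lambda_age = 1) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  table <- as_subject_table(as.data.frame(table))
  tr2 <- split_subjects(split, "train2")
  te <- split_subjects(split, "test")
  rows <- list()
  preds <- list()
  for (method in names(features_by_method)) {
    ident <- features_by_method[[method]]
    missing_ids <- setdiff(c(tr2, te), ident$subject_id)
    if (length(missing_ids) > 0L) {
      stop(sprintf("method '%s' lacks identity features for: %s", method,
                   paste(missing_ids, collapse = ", ")))
    }
    itr <- ident[match(tr2, ident$subject_id), , drop = FALSE]
    ite <- ident[match(te, ident$subject_id), , drop = FALSE]
    if ("diagnosis" %in% tasks) {
      fit <- fit_diagnosis(itr, table, lambda = lambda_diagnosis)
      pred <- predict(fit, ite)
      truth <- lookup_labels(te, table, "group")
      n_correct <- sum(pred == truth)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, task = "diagnosis", n_test = length(te),
        metric = "accuracy", value = n_correct / length(te),
        statistic = n_correct, p_value = sign_test(n_correct, length(te)),
        stringsAsFactors = FALSE)
      preds[[paste0(method, ".diagnosis")]] <-
        data.frame(subject_id = te, predicted = pred, actual = truth,
                   stringsAsFactors = FALSE)
    }
    if ("age" %in% tasks) {
      fit <- fit_age(itr, table, lambda = lambda_age)
      pred <- predict(fit, ite)
      truth <- as.numeric(lookup_labels(te, table, "age"))
      ct <- pearson_test(pred, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, task = "age", n_test = length(te),
        metric = "pearson_r", value = ct$r,
        statistic = ct$r * sqrt(ct$n - 2) / sqrt(max(1 - ct$r^2, 1e-15)),
        p_value = ct$p_value, stringsAsFactors = FALSE)
      preds[[paste0(method, ".age")]] <-
        data.frame(subject_id = te, predicted = pred, actual = truth,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), task = character(0),
               n_test = integer(0), metric = character(0),
               value = numeric(0), statistic = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  attr(out, "predictions") <- preds
  class(out) <- c("eval_table", "data.frame")
  out
}

#' @export
print.eval_table <- function(x, ...) {
  cat("downstream evaluation (train2 fit, test evaluation)\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
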