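#' Per-timepoint feature vectors from the trained encoder
#'
#' Evaluates the encoder's dense layer (pre-softmax) on every timepoint of
#' every scan: the per-timepoint outputs are the `classification` feature
#' vectors, one vector of length `n_subjects` per (subject, timepoint).
#'
#' @param enc a `trained_encoder`.
#' @param scans list of [volume4d()] scans cropped to the encoder input
#'   shape; names/ids are taken from each scan's `subject_id`.
#' @return a `feature_set`: data.frame with columns `subject_id`,
#'   `timepoint` and feature columns `f1..fD`; attribute `variant =
#'   "classification"`.
#' @export
extract_features <- function(enc, scans) {
  ids <- vapply(scans, function(s) s$subject_id, character(1))
  stacked <- stack_timepoints(scans, ids, enc$spec$config$input_shape)
  logits <- encoder_logits(enc, stacked$X)
  feature_set(t(logits), stacked$col_subject, stacked$col_time,
              variant = "classification")
}

#' Assemble a feature set from a matrix of feature vectors
#'
#' @param values numeric matrix, one row per feature vector.
#' @param subject_id character vector, one per row.
#' @param timepoint integer vector, one per row.
#' @param variant `"classification"`, `"classification_plus"`, or a baseline
#'   method name.
#' @return a `feature_set` data.frame.
#' @export
feature_set <- function(values, subject_id, timepoint, variant = "classification") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(subject_id),
            nrow(values) == length(timepoint), all(is.finite(values)))
  colnames(values) <- sprintf("f%d", seq_len(ncol(values)))
  out <- data.frame(subject_id = as.character(subject_id),
                    timepoint = as.integer(timepoint),
                    values, stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  class(out) <- c("feature_set", "data.frame")
  out
}

feature_matrix <- function(fs) {
  as.matrix(as.data.frame(fs)[, grep("^f\\d+$", names(fs)), drop = FALSE])
}

#' Mean-centre feature vectors ("classification+")
#'
#' Subtracts each vector's element mean from its elements. The softmax is
#' invariant to this shift, so centred and raw vectors induce identical
#' subject-classification probabilities; only the feature geometry changes.
#'
#' @param fs a `feature_set` (or a bare numeric vector).
#' @return the centred `feature_set` with `variant = "classification_plus"`
#'   (or the centred vector).
#' @export
center_features <- function(fs) {
  if (is.numeric(fs) && is.null(dim(fs))) return(fs - mean(fs))
  stopifnot(inherits(fs, "feature_set"))
  X <- feature_matrix(fs)
  X <- X - rowMeans(X)
  out <- feature_set(X, fs$subject_id, fs$timepoint,
                     variant = "classification_plus")
  out
}

#' Per-subject identity features
#'
#' Averages each subject's feature vectors over timepoints, yielding one
#' identity feature per subject (the subject's centroid in feature space).
#'
#' @param fs a `feature_set`.
#' @return an `identity_set`: data.frame with `subject_id`, `n_timepoints`
#'   and the feature columns; same `variant` attribute as the input.
#' @export
identity_features <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  X <- feature_matrix(fs)
  ids <- sort(unique(fs$subject_id))
  M <- rowsum(X, group = fs$subject_id, reorder = TRUE)
  n <- as.vector(table(factor(fs$subject_id, levels = ids)))
  out <- data.frame(subject_id = ids, n_timepoints = n, M / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "variant") <- attr(fs, "variant")
  class(out) <- c("identity_set", "data.frame")
  out
}

identity_matrix <- function(ident) {
  as.matrix(as.data.frame(ident)[, grep("^f\\d+$", names(ident)), drop = FALSE])
}

#' Cluster quality of identity features: precision at k
#'
#' For each identity feature, all feature vectors (every subject's, pooled)
#' are ranked by Euclidean distance in the original feature space, and
#' precision at k is the fraction of the k nearest vectors that belong to
#' the identity's subject. Ties are broken by (distance, subject_id,
#' timepoint) so the ranking is deterministic. The identity feature itself
#' is a centroid, not an observation, and is not part of the ranked pool.
#'
#' @param fs a `feature_set`: the pooled ranking pool.
#' @param identities an `identity_set`; defaults to [identity_features()] of
#'   `fs`. Every identity's subject must have vectors in the pool.
#' @param k neighbourhood size; defaults to the per-subject timepoint count
#'   when that is shared by all subjects.
#' @return a `precision_report`: data.frame (subject_id, precision) with
#'   attributes `k` and `mean_precision`.
#' @export
precision_at_k <- function(fs, identities = identity_features(fs), k = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  X <- feature_matrix(fs)
  N <- nrow(X)
  if (is.null(k)) {
    per <- table(fs$subject_id)
    if (length(unique(per)) != 1L) {
      stop("k has no default when subjects have unequal vector counts")
    }
    k <- as.integer(per[1L])
  }
  if (k > N) stop(sprintf("k = %d exceeds the pool of %d feature vectors", k, N))
  if (!all(identities$subject_id %in% fs$subject_id)) {
    stop("identity subject(s) missing from the feature pool")
  }
  Xi <- identity_matrix(identities)
  prec <- numeric(nrow(Xi))
  ord_sub <- fs$subject_id
  ord_tp <- fs$timepoint
  for (i in seq_len(nrow(Xi))) {
    d <- sqrt(colSums((t(X) - Xi[i, ])^2))
    ranked <- order(d, ord_sub, ord_tp)[seq_len(k)]
    prec[i] <- sum(ord_sub[ranked] == identities$subject_id[i]) / k
  }
  out <- data.frame(subject_id = identities$subject_id, precision = prec,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "mean_precision") <- mean(prec)
  class(out) <- c("precision_report", "data.frame")
  out
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision@%d over %d identity features: mean %.3f\n",
              attr(x, "k"), nrow(x), attr(x, "mean_precision")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read / write feature and identity tables as TSV
#'
#' Features serialize as `subject_id  timepoint  f1..fD`, identities as
#' `subject_id  n_timepoints  f1..fD`; the variant is kept in a `# variant:`
#' header comment.
#'
#' @param fs a `feature_set` or `identity_set`.
#' @param path TSV file path.
#' @return `path` (writers) or the reconstructed object (readers).
#' @export
write_features <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variant: %s", attr(fs, "variant") %||% "unknown"), con)
  utils::write.table(as.data.frame(fs), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  header <- readLines(path, n = 1L)
  variant <- sub("^# variant: ", "", header)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  X <- as.matrix(tab[, grep("^f\\d+$", names(tab)), drop = FALSE])
  if ("timepoint" %in% names(tab)) {
    feature_set(X, tab$subject_id, tab$timepoint, variant = variant)
  } else {
    out <- data.frame(subject_id = tab$subject_id,
                      n_timepoints = tab$n_timepoints, X,
                      stringsAsFactors = FALSE)
    attr(out, "variant") <- variant
    class(out) <- c("identity_set", "data.frame")
    out
  }
}
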