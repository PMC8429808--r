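#' ROI-pooled baseline features
#'
#' Each row of an ROI time-series matrix (one timepoint's R region means)
#' becomes that timepoint's feature vector, flowing through the same
#' identity-feature and precision machinery as the encoder features.
#'
#' @param ts T x R matrix from [pool_rois()].
#' @param subject_id owner of the scan.
#' @return a `feature_set` with variant `"roi"`.
#' @export
roi_features <- function(ts, subject_id) {
  feature_set(unname(ts), rep(subject_id, nrow(ts)), seq_len(nrow(ts)),
              variant = "roi")
}

#' Fit a principal-component feature model
#'
#' Mean-centred PCA of a timepoints-by-voxels matrix (rows = observations).
#' Components are ordered by decreasing explained variance and loadings are
#' orthonormal.
#'
#' @param X numeric matrix, training timepoints x voxels.
#' @param m number of components, `<= min(nrow(X) - 1, ncol(X))`.
#' @return a `pca_model` with elements `loadings` (m x voxels), `variance`
#'   (length m), `center` (voxel means) and `m`.
#' @export
fit_pca <- function(X, m) {
  X <- as.matrix(X)
  m_max <- min(nrow(X) - 1L, ncol(X))
  if (m > m_max) {
    stop(sprintf("m = %d exceeds the rank bound %d for %d x %d data",
                 m, m_max, nrow(X), ncol(X)))
  }
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2L, ctr), nu = 0L, nv = m)
  structure(list(loadings = t(sv$v),
                 variance = sv$d[seq_len(m)]^2 / (nrow(X) - 1L),
                 center = ctr, m = as.integer(m)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA feature model: %d components over %d voxels\n",
              x$m, length(x$center)))
  cat("variance of first components:",
      paste(signif(utils::head(x$variance, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Project timepoints onto a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param X numeric matrix (timepoints x voxels) or a single flattened
#'   timepoint vector; voxel count must match the training data.
#' @return matrix of centred projections, timepoints x m.
#' @export
project_pca <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$center)) {
    stop(sprintf("input has %d voxels but the model was fitted on %d",
                 ncol(X), length(model$center)))
  }
  sweep(X, 2L, model$center) %*% t(model$loadings)
}

#' @rdname project_pca
#' @param scans list of [volume4d()]; each timepoint is flattened to a voxel
#'   vector and projected.
#' @return `pca_features`: a `feature_set` with variant `"pca_<m>"`.
#' @export
pca_features <- function(model, scans) {
  rows <- lapply(scans, function(s) {
    a <- volume_data(s)
    t(matrix(a, ncol = dim(a)[4L]))
  })
  X <- do.call(rbind, rows)
  proj <- project_pca(model, X)
  feature_set(proj,
              rep(vapply(scans, function(s) s$subject_id, character(1)),
                  vapply(rows, nrow, integer(1))),
              unlist(lapply(rows, function(r) seq_len(nrow(r)))),
              variant = sprintf("pca_%d", model$m))
}

#' Functional connectivity of ROI time series
#'
#' Pearson correlation between every pair of region time series over the
#' whole scan (static functional connectivity). The vectorised upper
#' triangle (excluding the diagonal) is the subject's downstream feature.
#'
#' @param ts T x R matrix from [pool_rois()], T >= 3.
#' @param subject_id owner of the scan.
#' @return a `connectivity_feature`: list with `matrix` (R x R), `vector`
#'   (length R(R-1)/2) and `subject_id`.
#' @export
connectivity <- function(ts, subject_id = NA_character_) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 timepoints for connectivity")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(ts) %||% sprintf("roi_%03d", seq_len(ncol(ts)))
    stop(sprintf("constant ROI time series: %s",
                 paste(nm[sds == 0], collapse = ", ")))
  }
  C <- stats::cor(ts)
  structure(list(matrix = C, vector = C[upper.tri(C)],
                 subject_id = as.character(subject_id)),
            class = "connectivity_feature")
}

#' @export
print.connectivity_feature <- function(x, ...) {
  cat(sprintf("functional connectivity of '%s': %d x %d regions\n",
              x$subject_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Connectivity features for a set of scans as an identity-style table
#'
#' One vectorised connectivity matrix per subject; being per-subject (not
#' per-timepoint), these enter the downstream models directly as the
#' subject's feature.
#'
#' @param scans list of [volume4d()].
#' @param atlas an [atlas_volume()].
#' @return an `identity_set`-like data.frame with variant `"connectivity"`.
#' @export
connectivity_features <- function(scans, atlas) {
  vecs <- lapply(scans, function(s) connectivity(pool_rois(s, atlas),
                                                 s$subject_id))
  X <- do.call(rbind, lapply(vecs, `[[`, "vector"))
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  out <- data.frame(subject_id = vapply(vecs, `[[`, character(1), "subject_id"),
                    n_timepoints = vapply(scans, function(s) dim(s)[4L],
                                          integer(1)),
                    X, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "variant") <- "connectivity"
  class(out) <- c("identity_set", "data.frame")
  out
}
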