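#' 4D fMRI volume container
#'
#' A light wrapper around a 4D numeric array (X, Y, Z, T) of signal
#' intensities with voxel-size metadata and the owning subject's id.
#' Volumes are used in stored voxel order throughout; the package assumes
#' already-preprocessed input co-registered with any atlas applied to it.
#'
#' @param data 4D numeric array, all dims >= 1, no NaN/Inf.
#' @param voxel_size_mm numeric 3-vector of voxel edge lengths in mm.
#' @param subject_id character scalar.
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size_mm = c(1, 1, 1), subject_id = NA_character_) {
  if (length(dim(data)) != 4L) {
    stop(sprintf("not a 4D scan: %d dims", length(dim(data))))
  }
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L) {
    stop(sprintf("scan contains %d non-finite voxel values", n_bad))
  }
  stopifnot(all(dim(data) >= 1L), length(voxel_size_mm) == 3L)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 subject_id = as.character(subject_id),
                 provenance = list()),
            class = "volume4d")
}

volume_data <- function(vol) {
  if (inherits(vol, "volume4d")) vol$data else vol
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("4D fMRI volume '%s': %d x %d x %d voxels, %d timepoints, voxel %s mm\n",
              x$subject_id, d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size_mm), collapse = " x ")))
  if (length(x$provenance)) {
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

#' Read a 4D NIfTI scan
#'
#' @param path a NIfTI-1 file (.nii or .nii.gz) with exactly 4 dimensions.
#' @param subject_id subject id to attach; defaults to the file stem.
#' @return a [volume4d()].
#' @export
read_scan <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such scan file: %s", path))
  img <- RNifti::readNifti(path)
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  if (length(dim(a)) != 4L) {
    stop(sprintf("not a 4D scan: %s has %d dims", path, length(dim(a))))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume4d(a, voxel_size_mm = RNifti::pixdim(img)[1:3], subject_id = subject_id)
}

#' Write a 4D scan as NIfTI-1
#'
#' @param vol a [volume4d()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_scan <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Integer-labelled ROI atlas volume
#'
#' @param labels 3D integer array; 0 is background, 1..R are region ids.
#' @param roi_names optional character vector of length `max(labels)`.
#' @return an object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, roi_names = NULL) {
  stopifnot(length(dim(labels)) == 3L)
  labels <- array(as.integer(labels), dim = dim(labels))
  if (any(labels < 0L)) stop("atlas labels must be non-negative")
  R <- max(labels)
  if (is.null(roi_names)) roi_names <- sprintf("roi_%03d", seq_len(R))
  stopifnot(length(roi_names) == R)
  structure(list(labels = labels, roi_names = as.character(roi_names)),
            class = "atlas_volume")
}

#' Read an atlas volume from a 3D NIfTI file
#'
#' @param path NIfTI file of integer labels.
#' @param roi_names optional region names.
#' @return an [atlas_volume()].
#' @export
read_atlas <- function(path, roi_names = NULL) {
  if (!file.exists(path)) stop(sprintf("no such atlas file: %s", path))
  img <- RNifti::readNifti(path)
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
  atlas_volume(round(a), roi_names = roi_names)
}

#' Crop a volume to a target spatial shape
#'
#' Trims the spatial axes (timepoints untouched), by default symmetrically
#' about the volume centre; the window used is recorded in the volume's
#' provenance.
#'
#' @param vol a [volume4d()].
#' @param target_shape integer 3-vector, elementwise <= the volume shape.
#' @param mode `"center"` or `"offset"`.
#' @param offset integer 3-vector of 0-based lower corner indices, required
#'   for `mode = "offset"`.
#' @return the cropped [volume4d()].
#' @export
crop_volume <- function(vol, target_shape, mode = c("center", "offset"),
                        offset = NULL) {
  mode <- match.arg(mode)
  d <- dim(vol$data)[1:3]
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L)
  if (any(target_shape > d)) {
    stop(sprintf("crop target (%s) exceeds volume shape (%s)",
                 paste(target_shape, collapse = ","), paste(d, collapse = ",")))
  }
  start <- if (mode == "center") (d - target_shape) %/% 2L else as.integer(offset)
  stopifnot(length(start) == 3L, all(start >= 0L), all(start + target_shape <= d))
  idx <- lapply(1:3, function(i) seq.int(start[i] + 1L, start[i] + target_shape[i]))
  out <- vol$data[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  res <- volume4d(out, vol$voxel_size_mm, vol$subject_id)
  res$provenance <- c(vol$provenance,
                      list(crop = list(start = start, shape = target_shape)))
  res
}

#' Crop an atlas with the same window as a cropped volume
#'
#' @param atlas an [atlas_volume()].
#' @param start integer 3-vector of 0-based lower corner indices.
#' @param target_shape integer 3-vector.
#' @return the cropped [atlas_volume()].
#' @export
crop_atlas <- function(atlas, start, target_shape) {
  idx <- lapply(1:3, function(i) seq.int(start[i] + 1L, start[i] + target_shape[i]))
  atlas_volume(atlas$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               roi_names = atlas$roi_names)
}

#' Average signals over atlas regions
#'
#' Pools a scan into one time series per atlas region: entry (t, r) is the
#' mean intensity over voxels labelled r at timepoint t. Regions with no
#' voxels (e.g. after cropping) are dropped with a warning so downstream
#' correlation matrices never contain constant columns.
#'
#' @param vol a [volume4d()].
#' @param atlas an [atlas_volume()] on the same grid.
#' @return a T x R numeric matrix with region names as column names and
#'   attribute `dropped_rois` listing any empty regions.
#' @export
pool_rois <- function(vol, atlas) {
  a <- volume_data(vol)
  if (!all(dim(a)[1:3] == dim(atlas$labels))) {
    stop(sprintf("atlas shape (%s) does not match scan spatial shape (%s)",
                 paste(dim(atlas$labels), collapse = ","),
                 paste(dim(a)[1:3], collapse = ",")))
  }
  lab <- as.integer(atlas$labels)
  R <- length(atlas$roi_names)
  counts <- tabulate(lab, nbins = R)
  present <- which(counts > 0L)
  if (length(present) == 0L) stop("no ROIs: atlas is all background")
  Tn <- dim(a)[4L]
  X <- matrix(a, nrow = length(lab), ncol = Tn)
  keep <- lab > 0L
  # sum voxel values per (label, timepoint), then divide by voxel counts
  sums <- rowsum(X[keep, , drop = FALSE], group = lab[keep], reorder = TRUE)
  got <- as.integer(rownames(sums))
  ts <- t(sums / counts[got])
  colnames(ts) <- atlas$roi_names[got]
  dropped <- setdiff(seq_len(R), got)
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d empty ROI(s): %s", length(dropped),
                    paste(atlas$roi_names[dropped], collapse = ", ")))
  }
  attr(ts, "dropped_rois") <- atlas$roi_names[dropped]
  ts
}
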