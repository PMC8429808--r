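#' Simulation configuration for a synthetic fMRI cohort
#'
#' The generator emulates the statistical structure that makes
#' single-timepoint subject identification possible: every voxel value is
#'
#'   `v(x, t) = B(x) + a_sig * S_i(x) + a_grp * G(x) * 1(patient)`
#'   `       + a_age * A(x) * z(age_i) + eps(x, t)`
#'
#' where `B` is a smooth ellipsoidal "brain" baseline, `S_i` a per-subject
#' smoothed Gaussian random field that is constant over time (the subject's
#' persistent spatial signature), `G` and `A` fixed smooth group/age effect
#' maps, `z` the standardised age, and `eps` i.i.d. Gaussian temporal noise.
#'
#' @param grid_shape integer 3-vector of voxel dims.
#' @param n_timepoints timepoints per scan.
#' @param signature_amplitude strength of the subject signature (in noise-SD
#'   units when `noise_sd = 1`).
#' @param group_amplitude strength of the patient-vs-control spatial effect.
#' @param age_amplitude strength of the age-linked spatial effect.
#' @param noise_sd temporal noise standard deviation, > 0.
#' @param smoothing_sigma_vox Gaussian smoothing sigma (voxels) applied to
#'   signature and effect maps so they are spatially structured like fMRI
#'   rather than white noise.
#' @param age_mean,age_sd cohort age standardisation constants (years).
#' @param seed integer; keys all random fields.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 28L, 24L), n_timepoints = 40L,
                       signature_amplitude = 5, group_amplitude = 0,
                       age_amplitude = 0, noise_sd = 1,
                       smoothing_sigma_vox = 1.5, age_mean = 40, age_sd = 13,
                       seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L), n_timepoints >= 1L,
            signature_amplitude >= 0, group_amplitude >= 0, age_amplitude >= 0,
            noise_sd > 0, smoothing_sigma_vox >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 signature_amplitude = signature_amplitude,
                 group_amplitude = group_amplitude,
                 age_amplitude = age_amplitude, noise_sd = noise_sd,
                 smoothing_sigma_vox = smoothing_sigma_vox,
                 age_mean = age_mean, age_sd = age_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic cohort table
#'
#' @param n_patients,n_controls group sizes (>= 0, not both 0).
#' @param age_range `c(lo, hi)` in years; ages drawn uniformly.
#' @param seed integer seed.
#' @param female_ratio probability a subject is female.
#' @return a `subject_table` with ids `sub_001`, `sub_002`, ...
#' @export
make_cohort <- function(n_patients, n_controls, age_range = c(18, 65),
                        seed = 1L, female_ratio = 0.25) {
  n <- n_patients + n_controls
  if (n < 1L) stop("empty cohort")
  set.seed(seed)
  tab <- data.frame(
    subject_id = sprintf("sub_%03d", seq_len(n)),
    group = rep(c("patient", "control"), c(n_patients, n_controls)),
    age = round(stats::runif(n, age_range[1], age_range[2]), 1),
    sex = ifelse(stats::runif(n) < female_ratio, "f", "m"),
    stringsAsFactors = FALSE)
  as_subject_table(tab)
}

# Separable 3D Gaussian smoothing by banded matrix products along each axis.
smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  kern_mat <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  a <- array(kern_mat(d[1]) %*% matrix(a, d[1]), d)
  a <- aperm(array(kern_mat(d[2]) %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(kern_mat(d[3]) %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
              d[c(3, 1, 2)]), c(2, 3, 1))
}

# Smooth ellipsoidal brain mask (1 inside, tapering at the edge).
brain_mask <- function(grid_shape) {
  d <- grid_shape
  cx <- (d + 1) / 2
  r <- d / 2 - 1
  x <- (seq_len(d[1]) - cx[1]) / r[1]
  y <- (seq_len(d[2]) - cx[2]) / r[2]
  z <- (seq_len(d[3]) - cx[3]) / r[3]
  rho <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  m <- array(0, d)
  m[rho <= 1] <- 1
  smooth3d(m, 1)
}

# Smoothed, mask-weighted Gaussian random field with unit SD inside the
# mask; keyed by (seed, key) so fields are reproducible and independent.
random_field <- function(cfg, key, mask) {
  set.seed(derive_seed(cfg$seed, key))
  f <- array(stats::rnorm(prod(cfg$grid_shape)), cfg$grid_shape)
  f <- smooth3d(f, cfg$smoothing_sigma_vox)
  inside <- mask > 0.5
  f <- f / stats::sd(f[inside])
  f * mask
}

#' Simulate one subject's 4D scan
#'
#' The subject's spatial signature is keyed by `subject_id` and the config
#' seed, so repeated calls (and separate sessions via `session`) share the
#' same signature while temporal noise differs across sessions.
#'
#' @param subject one row of a `subject_table`.
#' @param cfg a [sim_config()].
#' @param session integer session index; scans of the same subject with the
#'   same session are bit-identical.
#' @return a [volume4d()].
#' @export
simulate_scan <- function(subject, cfg, session = 1L) {
  stopifnot(inherits(cfg, "sim_config"), nrow(subject) == 1L)
  mask <- brain_mask(cfg$grid_shape)
  base <- 100 * mask
  S <- random_field(cfg, paste0("sig:", subject$subject_id), mask)
  G <- random_field(cfg, "group", mask)
  A <- random_field(cfg, "age", mask)
  z_age <- (subject$age - cfg$age_mean) / cfg$age_sd
  still <- base + cfg$signature_amplitude * S +
    cfg$group_amplitude * G * (subject$group == "patient") +
    cfg$age_amplitude * A * z_age
  set.seed(derive_seed(cfg$seed, paste0("noise:", subject$subject_id, ":", session)))
  nvox <- prod(cfg$grid_shape)
  eps <- array(stats::rnorm(nvox * cfg$n_timepoints, sd = cfg$noise_sd),
               c(cfg$grid_shape, cfg$n_timepoints))
  volume4d(array(still, c(cfg$grid_shape, cfg$n_timepoints)) + eps,
           voxel_size_mm = c(3, 3, 3), subject_id = subject$subject_id)
}

#' Simulate scans for a whole cohort
#'
#' @param cohort a `subject_table`.
#' @param cfg a [sim_config()].
#' @param dir optional directory: scans are additionally written as NIfTI
#'   (`<subject_id>.nii.gz`) together with `subjects.csv`.
#' @return list with `scans` (named list of [volume4d()]), and the
#'   ground-truth `signatures` (named list), `group_map` and `age_map` for
#'   test assertions.
#' @export
simulate_dataset <- function(cohort, cfg, dir = NULL) {
  cohort <- as_subject_table(as.data.frame(cohort))
  mask <- brain_mask(cfg$grid_shape)
  scans <- list()
  sigs <- list()
  for (i in seq_len(nrow(cohort))) {
    scans[[cohort$subject_id[i]]] <- simulate_scan(cohort[i, ], cfg)
    sigs[[cohort$subject_id[i]]] <-
      random_field(cfg, paste0("sig:", cohort$subject_id[i]), mask)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(scans)) {
      write_scan(scans[[id]], file.path(dir, paste0(id, ".nii.gz")))
    }
    write_subject_table(cohort, file.path(dir, "subjects.csv"))
  }
  list(scans = scans, signatures = sigs,
       group_map = random_field(cfg, "group", mask),
       age_map = random_field(cfg, "age", mask))
}
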