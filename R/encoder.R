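#' Encoder architecture configuration
#'
#' Describes the 3D convolutional subject-identification network: `n_blocks`
#' blocks of two 3x3x3 convolutions (stride 1, zero padding 1) followed by a
#' 2x2x2 average pooling, then `n_tail_convs` further convolutions at constant
#' channel width, and a single dense layer mapping the flattened feature map
#' to one output per training subject. Channel width starts at
#' `base_channels` and doubles once per block; with the default
#' `double_at = "before_pool"` the second convolution of each block performs
#' the doubling.
#'
#' @param input_shape integer 3-vector, spatial input dims (x, y, z). Each
#'   dim must be divisible by `2^n_blocks`.
#' @param n_subjects integer, number of training subjects (dense output dim).
#' @param n_blocks number of conv-conv-pool blocks.
#' @param base_channels channels after the first convolution.
#' @param n_tail_convs convolutions after the last pooling layer.
#' @param double_at where the per-block channel doubling happens:
#'   `"before_pool"` (second conv of the block) or `"block_entry"`.
#' @param dense_input `"flatten"` (dense layer on the flattened feature map)
#'   or `"global_pool"` (dense layer on channelwise spatial means).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(input_shape, n_subjects, n_blocks = 4L,
                           base_channels = 8L, n_tail_convs = 2L,
                           double_at = c("before_pool", "block_entry"),
                           dense_input = c("flatten", "global_pool")) {
  double_at <- match.arg(double_at)
  dense_input <- match.arg(dense_input)
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L),
            n_subjects >= 2L, n_blocks >= 1L, base_channels >= 1L,
            n_tail_convs >= 0L)
  div <- 2L^n_blocks
  bad <- which(input_shape %% div != 0L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "input dim %s (%d) is not divisible by pool_stride^n_blocks = %d",
      c("x", "y", "z")[bad[1L]], input_shape[bad[1L]], div))
  }
  structure(list(input_shape = input_shape, n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 n_tail_convs = as.integer(n_tail_convs),
                 conv_kernel = 3L, conv_stride = 1L,
                 pool_kernel = 2L, pool_stride = 2L,
                 double_at = double_at, dense_input = dense_input),
            class = "encoder_config")
}

#' Build the layer-by-layer encoder specification
#'
#' Expands an [encoder_config()] into an explicit layer table (kind, channels
#' in/out, output spatial shape, parameter count per layer) without
#' allocating any weights. Convolutions preserve spatial size (kernel 3,
#' stride 1, symmetric zero padding 1); each pooling layer halves every
#' spatial dimension.
#'
#' @param cfg an [encoder_config()].
#' @return an object of class `encoder_spec` with elements `layers` (a
#'   data.frame), `total_parameters`, `dense_channels` (channels entering the
#'   dense stage) and the originating `config`.
#' @export
build_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  shape <- cfg$input_shape
  rows <- list()
  cin <- 1L
  add <- function(kind, cin, cout, shape, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, channels_in = cin, channels_out = cout,
      out_x = shape[1L], out_y = shape[2L], out_z = shape[3L],
      n_parameters = params, stringsAsFactors = FALSE)
  }
  for (b in seq_len(cfg$n_blocks)) {
    width <- as.integer(cfg$base_channels * 2^(b - 1))
    if (cfg$double_at == "before_pool") {
      c1 <- width; c2 <- 2L * width
    } else {
      c1 <- 2L * width; c2 <- 2L * width
    }
    add("conv", cin, c1, shape, (27L * cin + 1L) * c1); cin <- c1
    add("conv", cin, c2, shape, (27L * cin + 1L) * c2); cin <- c2
    shape <- shape %/% 2L
    add("pool", cin, cin, shape, 0L)
  }
  for (i in seq_len(cfg$n_tail_convs)) {
    add("conv", cin, cin, shape, (27L * cin + 1L) * cin)
  }
  n_feat <- if (cfg$dense_input == "flatten") prod(shape) * cin else cin
  add("dense", cin, cfg$n_subjects, c(1L, 1L, 1L),
      (n_feat + 1L) * cfg$n_subjects)
  layers <- do.call(rbind, rows)
  structure(list(layers = layers,
                 total_parameters = sum(layers$n_parameters),
                 dense_channels = cin,
                 pre_flatten_shape = shape,
                 n_dense_inputs = n_feat,
                 config = cfg),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("3D conv subject-identification encoder: %d blocks, input (%s)\n",
              cfg$n_blocks, paste(cfg$input_shape, collapse = ", ")))
  print(x$layers, row.names = FALSE)
  cat(sprintf("channels before dense layer: %d\n", x$dense_channels))
  cat(sprintf("spatial shape before dense layer: (%s)\n",
              paste(x$pre_flatten_shape, collapse = ", ")))
  cat(sprintf("total parameters: %s\n",
              format(x$total_parameters, big.mark = ",")))
  invisible(x)
}

# Integer layer plan consumed by the C++ kernels: one row per layer,
# columns (type, cin, cout, dx, dy, dz); types 0 conv / 1 pool / 2 dense
# on flattened map / 3 dense on global mean pool.
encoder_plan <- function(spec) {
  shape <- spec$config$input_shape
  L <- spec$layers
  plan <- matrix(0L, nrow = nrow(L), ncol = 6L)
  for (i in seq_len(nrow(L))) {
    type <- switch(L$kind[i], conv = 0L, pool = 1L,
                   dense = if (spec$config$dense_input == "flatten") 2L else 3L)
    plan[i, ] <- c(type, L$channels_in[i], L$channels_out[i], shape)
    if (L$kind[i] == "pool") shape <- shape %/% 2L
  }
  plan
}

# Fan-in-scaled (He) random initialisation, driven by R's RNG so that
# set.seed() controls it. Dense layer starts at zero so an untrained
# network outputs the uniform distribution over subjects.
init_weights <- function(spec, seed) {
  set.seed(seed)
  plan <- encoder_plan(spec)
  weights <- list()
  for (i in seq_len(nrow(plan))) {
    type <- plan[i, 1L]
    if (type == 1L) next
    cin <- plan[i, 2L]; cout <- plan[i, 3L]
    if (type == 0L) {
      fan_in <- 27L * cin
      W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout)
    } else {
      n_feat <- if (type == 2L) prod(plan[i, 4:6]) * cin else cin
      W <- matrix(0, n_feat, cout)
    }
    weights[[length(weights) + 1L]] <- list(W = W, b = rep(0, cout))
  }
  weights
}

#' Training configuration for the encoder
#'
#' @param lr_schedule a list of `c(learning_rate, n_iterations)` pairs run in
#'   order; the default mirrors an Adam schedule of 1e-4 then 1e-5.
#' @param batch_size timepoints per Adam step.
#' @param seed integer seed controlling weight init and batch sampling.
#' @param log_every record loss/minibatch accuracy every this many iterations.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr_schedule = list(c(1e-4, 17000L), c(1e-5, 110000L)),
                         batch_size = 32L, seed = 1L, log_every = 50L) {
  rates <- vapply(lr_schedule, `[`, numeric(1), 1L)
  iters <- vapply(lr_schedule, `[`, numeric(1), 2L)
  stopifnot(all(rates > 0), all(iters >= 0), sum(iters) >= 1, batch_size >= 1)
  structure(list(lr_rates = rates, lr_iters = as.integer(iters),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 log_every = as.integer(log_every)),
            class = "train_config")
}

# Stack scans into the (n_voxels x n_timepoints_total) sample matrix the
# C++ trainer consumes, with one integer label per column.
stack_timepoints <- function(scans, subject_ids, input_shape) {
  stopifnot(length(scans) == length(subject_ids))
  cols <- list(); labels <- integer(0); col_subject <- character(0)
  col_time <- integer(0)
  subjects <- sort(unique(subject_ids))
  for (i in seq_along(scans)) {
    a <- volume_data(scans[[i]])
    if (!all(dim(a)[1:3] == input_shape)) {
      stop(sprintf("scan %d spatial shape (%s) does not match encoder input (%s)",
                   i, paste(dim(a)[1:3], collapse = ","),
                   paste(input_shape, collapse = ",")))
    }
    Tn <- dim(a)[4L]
    cols[[i]] <- matrix(a, nrow = prod(input_shape), ncol = Tn)
    labels <- c(labels, rep(match(subject_ids[i], subjects) - 1L, Tn))
    col_subject <- c(col_subject, rep(subject_ids[i], Tn))
    col_time <- c(col_time, seq_len(Tn))
  }
  list(X = do.call(cbind, cols), labels = labels, subjects = subjects,
       col_subject = col_subject, col_time = col_time)
}

#' Train the subject-identification encoder
#'
#' Trains the 3D convolutional network to classify the owning subject from a
#' single fMRI timepoint: each Adam step samples `batch_size` timepoints
#' uniformly (with replacement) over all subject-timepoint pairs and
#' minimises softmax cross-entropy against the one-hot subject identity.
#'
#' @param scans list of [volume4d()] scans, all cropped to the encoder input
#'   shape; one per (subject, session).
#' @param subject_ids character vector, one per scan.
#' @param enc_cfg an [encoder_config()]; `n_subjects` must equal the number
#'   of distinct subject ids.
#' @param tr_cfg a [train_config()].
#' @return a `trained_encoder`: the [build_encoder()] spec, trained weights,
#'   subject label order, and the training log (iteration, learning rate,
#'   minibatch loss and accuracy).
#' @export
train_encoder <- function(scans, subject_ids, enc_cfg, tr_cfg) {
  stopifnot(inherits(enc_cfg, "encoder_config"), inherits(tr_cfg, "train_config"))
  spec <- build_encoder(enc_cfg)
  stacked <- stack_timepoints(scans, subject_ids, enc_cfg$input_shape)
  n_sub <- length(stacked$subjects)
  if (n_sub != enc_cfg$n_subjects) {
    stop(sprintf("encoder configured for %d subjects but %d distinct ids given",
                 enc_cfg$n_subjects, n_sub))
  }
  if (length(stacked$labels) == 0L) stop("empty training set")
  # standardise input intensities over the training set (scalar mean/SD,
  # stored with the model) so optimisation is insensitive to the arbitrary
  # signal units of the scans
  norm <- c(mean = mean(stacked$X), sd = stats::sd(as.vector(stacked$X)))
  if (norm[["sd"]] == 0) stop("training scans are constant")
  weights <- init_weights(spec, tr_cfg$seed)
  fit <- cnn_train_cpp((stacked$X - norm[["mean"]]) / norm[["sd"]],
                       stacked$labels, encoder_plan(spec), weights,
                       tr_cfg$lr_rates, tr_cfg$lr_iters,
                       tr_cfg$batch_size, tr_cfg$seed, tr_cfg$log_every)
  structure(list(spec = spec, weights = fit$weights, log = fit$log,
                 subjects = stacked$subjects, norm = norm,
                 train_config = tr_cfg),
            class = "trained_encoder")
}

# Dense-layer (pre-softmax) outputs for a voxel matrix, n_subjects x n cols.
encoder_logits <- function(enc, X) {
  stopifnot(inherits(enc, "trained_encoder"))
  if (!is.null(enc$norm)) X <- (X - enc$norm[["mean"]]) / enc$norm[["sd"]]
  cnn_forward_cpp(X, encoder_plan(enc$spec), enc$weights)
}

#' Classify a single timepoint
#'
#' Softmax probability over the training subjects for one 3D volume.
#'
#' @param enc a `trained_encoder`.
#' @param vol a 3D array (or 4D with T = 1) matching the encoder input shape.
#' @return named probability vector over training subjects (sums to 1).
#' @export
classify_timepoint <- function(enc, vol) {
  a <- if (inherits(vol, "volume4d")) volume_data(vol) else vol
  shape <- enc$spec$config$input_shape
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L || !all(dim(a) == shape)) {
    stop(sprintf("timepoint shape (%s) does not match encoder input (%s)",
                 paste(dim(a), collapse = ","), paste(shape, collapse = ",")))
  }
  logit <- drop(encoder_logits(enc, matrix(as.numeric(a), ncol = 1L)))
  p <- softmax(logit)
  names(p) <- enc$subjects
  p
}

#' Training accuracy of subject classification
#'
#' Fraction of timepoints whose highest-probability subject equals the true
#' owner; ties resolve to the lowest subject index.
#'
#' @param enc a `trained_encoder`.
#' @param scans list of [volume4d()] scans.
#' @param subject_ids character vector, one per scan; every id must be a
#'   training subject.
#' @return fraction in `[0, 1]`.
#' @export
training_accuracy <- function(enc, scans, subject_ids) {
  stacked <- stack_timepoints(scans, subject_ids, enc$spec$config$input_shape)
  if (!all(stacked$subjects %in% enc$subjects)) {
    stop("scan subject ids outside the encoder's training subjects")
  }
  logits <- encoder_logits(enc, stacked$X)
  pred <- enc$subjects[apply(logits, 2L, which.max)]
  mean(pred == stacked$col_subject)
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("trained subject-identification encoder (%d subjects, %s parameters)\n",
              length(x$subjects), format(x$spec$total_parameters, big.mark = ",")))
  n <- nrow(x$log)
  if (n > 0L) {
    cat(sprintf("final logged iteration %d: loss %.4f, minibatch accuracy %.3f\n",
                x$log$iteration[n], x$log$loss[n], x$log$accuracy[n]))
  }
  invisible(x)
}

#' @export
summary.trained_encoder <- function(object, ...) {
  print(object$spec)
  print(object)
  invisible(object)
}

#' @export
predict.trained_encoder <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  scans <- if (inherits(newdata, "volume4d")) list(newdata) else newdata
  stacked <- stack_timepoints(scans, vapply(scans, function(s) s$subject_id %||% "?",
                                            character(1)),
                              object$spec$config$input_shape)
  logits <- encoder_logits(object, stacked$X)
  probs <- apply(logits, 2L, softmax)
  rownames(probs) <- object$subjects
  if (type == "class") object$subjects[apply(probs, 2L, which.max)] else t(probs)
}

#' @export
plot.trained_encoder <- function(x, ...) {
  graphics::plot(x$log$iteration, x$log$loss, type = "l",
                 xlab = "iteration", ylab = "minibatch loss",
                 main = "encoder training", ...)
  invisible(x)
}

#' Save / load a trained encoder checkpoint
#'
#' The checkpoint directory holds a YAML description of the architecture and
#' training configuration, the weights as an RDS blob, and the training log
#' as CSV.
#'
#' @param enc a `trained_encoder`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_encoder` returns `dir` invisibly; `load_encoder` returns the
#'   `trained_encoder`.
#' @export
save_encoder <- function(enc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- enc$spec$config
  yaml::write_yaml(list(
    input_shape = as.integer(cfg$input_shape), n_subjects = cfg$n_subjects,
    n_blocks = cfg$n_blocks, base_channels = cfg$base_channels,
    n_tail_convs = cfg$n_tail_convs, double_at = cfg$double_at,
    dense_input = cfg$dense_input, subjects = enc$subjects,
    norm_mean = unname(enc$norm["mean"]), norm_sd = unname(enc$norm["sd"])),
    file.path(dir, "encoder.yaml"), precision = 17L)
  saveRDS(enc$weights, file.path(dir, "weights.rds"))
  utils::write.csv(enc$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "encoder.yaml"))
  cfg <- encoder_config(meta$input_shape, meta$n_subjects, meta$n_blocks,
                        meta$base_channels, meta$n_tail_convs,
                        double_at = meta$double_at,
                        dense_input = meta$dense_input)
  norm <- if (!is.null(meta$norm_mean)) {
    c(mean = meta$norm_mean, sd = meta$norm_sd)
  }
  structure(list(spec = build_encoder(cfg),
                 weights = readRDS(file.path(dir, "weights.rds")),
                 log = utils::read.csv(file.path(dir, "training_log.csv")),
                 subjects = unlist(meta$subjects), norm = norm),
            class = "trained_encoder")
}
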