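#' Read / write a cohort subject table
#'
#' The table is a CSV with header `subject_id,group,age,sex`; `group` is
#' `patient` or `control`, `sex` is `m` or `f`.
#'
#' @param path CSV file path.
#' @return a data.frame of class `subject_table`.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_subject_table(tab)
}

#' @rdname read_subject_table
#' @param table a `subject_table`.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("subject_id", "group", "age", "sex")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Validate a data.frame as a subject table
#'
#' @param tab data.frame with columns subject_id, group, age, sex.
#' @return the validated `subject_table`.
#' @export
as_subject_table <- function(tab) {
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(tab))) {
    stop(sprintf("subject table must have columns %s", paste(need, collapse = ", ")))
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id in table")
  if (!all(tab$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  if (!all(tab$sex %in% c("m", "f"))) stop("sex must be 'm' or 'f'")
  if (!all(tab$age > 0)) stop("age must be positive")
  class(tab) <- c("subject_table", "data.frame")
  tab
}

#' Stratified train1 / train2 / test split of a cohort
#'
#' Splits the cohort with exact per-split patient and control counts,
#' balancing sex and age across splits: within each group, subjects are
#' binned into sex-by-age-tertile cells and each cell is dealt out to the
#' splits in proportion to the requested counts (random order within cells,
#' driven by `seed`). Rows are canonically sorted by `subject_id` before any
#' randomness, so the assignment is invariant to input row order.
#'
#' @param table a `subject_table`.
#' @param counts named list mapping split name to `c(n_patients, n_controls)`;
#'   the counts must sum to the cohort's group sizes.
#' @param seed integer seed.
#' @return an object of class `split_spec`: data.frame (subject_id, split)
#'   with the seed as an attribute.
#' @export
stratified_split <- function(table, counts, seed = 1L) {
  table <- as_subject_table(as.data.frame(table))
  splits <- names(counts)
  if (is.null(splits) || any(splits == "")) stop("counts must be a named list")
  want <- do.call(rbind, counts) # splits x (patients, controls)
  have <- c(sum(table$group == "patient"), sum(table$group == "control"))
  if (!all(colSums(want) == have)) {
    stop(sprintf("requested counts (%d patients, %d controls) do not match cohort (%d, %d)",
                 colSums(want)[1], colSums(want)[2], have[1], have[2]))
  }
  if (any(want < 0)) stop("negative split counts")
  table <- table[order(table$subject_id), ]
  set.seed(seed)
  assignment <- character(nrow(table))
  for (gi in 1:2) {
    g <- c("patient", "control")[gi]
    rows <- which(table$group == g)
    if (length(rows) == 0L) next
    quota <- want[, gi]
    sub <- table[rows, , drop = FALSE]
    # sex x age-tertile cells
    tert <- cut(rank(sub$age, ties.method = "first"), breaks = 3L, labels = FALSE)
    cell <- interaction(sub$sex, tert, drop = TRUE)
    for (cl in levels(cell)) {
      members <- rows[cell == cl]
      members <- members[sample.int(length(members))]
      for (m in members) {
        # deal to the split with the largest remaining quota fraction
        frac <- quota / pmax(1, want[, gi])
        pick <- which.max(frac + stats::runif(length(frac)) * 1e-9)
        assignment[m] <- splits[pick]
        quota[pick] <- quota[pick] - 1L
      }
    }
  }
  out <- data.frame(subject_id = table$subject_id, split = assignment,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_spec", "data.frame")
  out
}

#' Read / write a split specification
#'
#' Serialized as CSV `subject_id,split`.
#'
#' @param path CSV file path.
#' @return a `split_spec` data.frame.
#' @export
read_split <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "split") %in% names(out)))
  class(out) <- c("split_spec", "data.frame")
  out
}

#' @rdname read_split
#' @param split a `split_spec`.
#' @export
write_split <- function(split, path) {
  utils::write.csv(as.data.frame(split)[, c("subject_id", "split")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Subject ids belonging to one split
#'
#' @param split a `split_spec`.
#' @param which split name, e.g. `"train1"`.
#' @return character vector of subject ids.
#' @export
split_subjects <- function(split, which) {
  split$subject_id[split$split == which]
}
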