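#' Specification of the celltype-aware train/validation/test split
#'
#' The published split: 75 % of samples train, 20 % of the training pool
#' held out for validation, 25 % of all samples test — stratified per
#' class so that every cell type appears in every partition even though
#' the cohort is unbalanced.
#'
#' @param train_fraction fraction of samples in the training pool.
#' @param val_fraction_of_train fraction of the training pool used for
#'   validation.
#' @param test_fraction fraction of samples in the test set; must equal
#'   `1 - train_fraction`.
#' @param class_aware stratify per class (guarantees every class in
#'   every partition).
#' @param seed integer seed.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.75, val_fraction_of_train = 0.20,
                       test_fraction = 0.25, class_aware = TRUE, seed = 1L) {
  if (abs(train_fraction + test_fraction - 1) > 1e-8) {
    stop_arg("train and test fractions must sum to 1")
  }
  if (train_fraction <= 0 || train_fraction >= 1 ||
      val_fraction_of_train <= 0 || val_fraction_of_train >= 1) {
    stop_arg("fractions must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 test_fraction = test_fraction,
                 class_aware = class_aware, seed = as.integer(seed)),
            class = "split_spec")
}

#' Celltype-aware train/validation/test split
#'
#' Assigns samples to train, validation and test sets with per-class
#' stratification at the configured fractions (rounded per class, at
#' least one sample per partition per class).  Assignment happens at the
#' level of *parent* samples: augmented descendants always follow their
#' parent's partition, so no information leaks from training into
#' validation or test.
#'
#' @param meta `data.frame` with columns `sample_id`, `class_label`,
#'   and optionally `parent_id` (defaults to `sample_id`).
#' @param spec a [split_spec()].
#' @param seed overrides `spec$seed`.
#' @return List with character vectors `train`, `val`, `test` of
#'   `sample_id`s (disjoint, covering all rows).
#' @export
celltype_aware_split <- function(meta, spec = split_spec(), seed = spec$seed) {
  stopifnot(all(c("sample_id", "class_label") %in% names(meta)))
  if (is.null(meta$parent_id)) meta$parent_id <- meta$sample_id
  meta$parent_id <- ifelse(is.na(meta$parent_id), meta$sample_id, meta$parent_id)
  parents <- unique(meta[, c("parent_id", "class_label")])
  if (anyDuplicated(parents$parent_id)) {
    stop_arg("a parent id maps to more than one class")
  }
  counts <- table(parents$class_label)
  if (length(counts) < 2) stop_arg("need at least 2 classes to stratify")
  if (any(counts < 3)) {
    stop_arg("every class needs >= 3 parent samples; too few in: ",
             paste(names(counts)[counts < 3], collapse = ", "))
  }
  assign <- with_seed(seed, {
    out <- list(train = character(), val = character(), test = character())
    for (cl in names(counts)) {
      ids <- sample(parents$parent_id[parents$class_label == cl])
      n <- length(ids)
      n_test <- min(max(1L, round(spec$test_fraction * n)), n - 2L)
      pool <- n - n_test
      n_val <- min(max(1L, round(spec$val_fraction_of_train * pool)), pool - 1L)
      out$test <- c(out$test, ids[seq_len(n_test)])
      out$val <- c(out$val, ids[n_test + seq_len(n_val)])
      out$train <- c(out$train, ids[(n_test + n_val + 1L):n])
    }
    out
  })
  lapply(assign, function(p) meta$sample_id[meta$parent_id %in% p])
}
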