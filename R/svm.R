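#' SVM configuration
#'
#' The published classifier for weighted-centroid features: a support
#' vector machine with a polynomial kernel of degree 2 and coefficient
#' 0, evaluated on random 50/50 train/test splits repeated 300 times.
#' Features are the raw weighted-centroid coordinates in seconds;
#' optional standardization is available but off by default (see
#' `standardize`).
#'
#' @param degree polynomial kernel degree.
#' @param coef0 polynomial kernel constant.
#' @param train_fraction fraction of samples used for training.
#' @param replicates number of independent splits.
#' @param cost soft-margin cost C.
#' @param standardize center and scale features on training statistics
#'   before kernel evaluation.  Off by default: with `coef0 = 0` the
#'   even polynomial kernel cannot separate clusters placed symmetric
#'   about the origin, which is exactly what centering produces for
#'   two-class problems; the reference implementation feeds raw
#'   (positive) centroid coordinates.
#' @param gamma kernel coefficient; `"scale"` (default) uses
#'   `1 / (n_features * var(x))` as in the reference implementation,
#'   or a positive number.
#' @param seed integer seed.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(degree = 2L, coef0 = 0, train_fraction = 0.5,
                       replicates = 300L, cost = 1, standardize = FALSE,
                       gamma = "scale", seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_arg("`train_fraction` must be in (0, 1)")
  }
  if (replicates < 1) stop_arg("`replicates` must be >= 1")
  structure(list(kernel = "polynomial", degree = as.integer(degree),
                 coef0 = coef0, train_fraction = train_fraction,
                 replicates = as.integer(replicates), cost = cost,
                 standardize = standardize, gamma = gamma,
                 seed = as.integer(seed)),
            class = "svm_config")
}

.centroid_xy <- function(centroids) {
  stopifnot(all(c("t1", "t2", "class_label") %in% names(centroids)))
  list(x = as.matrix(centroids[, c("t1", "t2")]),
       y = factor(centroids$class_label))
}

## stratified row indices for the training half
.stratified_half <- function(y, frac) {
  unlist(lapply(levels(y), function(cl) {
    ids <- which(y == cl)
    n_tr <- min(max(1L, round(frac * length(ids))), length(ids) - 1L)
    sample(ids)[seq_len(n_tr)]
  }), use.names = FALSE)
}

#' Fit the polynomial-kernel SVM on centroid features
#'
#' @param centroids `data.frame` with `t1`, `t2`, `class_label`.
#' @param config an [svm_config()].
#' @return A fitted model (class `relaxcell_svm`) usable with
#'   `predict()` and [decision_boundary_map()].
#' @export
fit_svm <- function(centroids, config = svm_config()) {
  d <- .centroid_xy(centroids)
  if (nlevels(droplevels(d$y)) < 2) stop_arg("need >= 2 classes")
  ctr <- if (config$standardize) colMeans(d$x) else c(0, 0)
  scl <- if (config$standardize) apply(d$x, 2, stats::sd) else c(1, 1)
  scl[scl == 0] <- 1
  xs <- scale(d$x, center = ctr, scale = scl)
  gam <- config$gamma
  if (identical(gam, "scale")) {
    v <- stats::var(as.vector(xs)) # total variance, sklearn convention
    gam <- 1 / (ncol(xs) * max(v, 1e-12))
  }
  fit <- e1071::svm(xs, droplevels(d$y), kernel = "polynomial",
                    degree = config$degree, coef0 = config$coef0,
                    cost = config$cost, gamma = gam, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl), class = "relaxcell_svm")
}

#' @export
predict.relaxcell_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  stats::predict(object$fit, xs, ...)
}

#' Train and evaluate the SVM on one random split
#'
#' Splits the centroid table into stratified 50/50 train/test halves,
#' fits the polynomial-kernel SVM on the training half, and returns the
#' accuracy on the held-out half.
#'
#' @param centroids `data.frame` with `t1`, `t2`, `class_label`.
#' @param config an [svm_config()].
#' @param seed split seed.
#' @return Test accuracy in `[0, 1]`.
#' @export
train_svm <- function(centroids, config = svm_config(), seed = config$seed) {
  d <- .centroid_xy(centroids)
  y <- droplevels(d$y)
  if (nlevels(y) < 2) stop_arg("need >= 2 classes")
  tr <- with_seed(seed, .stratified_half(y, config$train_fraction))
  model <- fit_svm(centroids[tr, , drop = FALSE], config)
  pred <- predict(model, d$x[-tr, , drop = FALSE])
  mean(pred == y[-tr])
}

#' Replicate SVM training over many random splits
#'
#' @param centroids `data.frame` with `t1`, `t2`, `class_label`.
#' @param config an [svm_config()]; `config$replicates` splits are run
#'   with per-replicate derived seeds.
#' @return List with `accuracies` (length `replicates`), `mean`, `sd`.
#' @export
run_svm_replicates <- function(centroids, config = svm_config()) {
  acc <- vapply(seq_len(config$replicates), function(r) {
    train_svm(centroids, config, seed = derive_seed(config$seed, "svm", r))
  }, 0)
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc))
}

#' Predicted-class map over a (T1, T2) grid
#'
#' Evaluates a fitted SVM on every point of a rectangular grid, for
#' plotting decision boundaries next to the centroid clouds.
#'
#' @param model a fitted `relaxcell_svm`.
#' @param t1_grid,t2_grid grid coordinates in seconds.
#' @return Character matrix `length(t1_grid) x length(t2_grid)` of
#'   predicted class labels.
#' @export
decision_boundary_map <- function(model, t1_grid, t2_grid) {
  pts <- cbind(t1 = rep(t1_grid, times = length(t2_grid)),
               t2 = rep(t2_grid, each = length(t1_grid)))
  pred <- predict(model, pts)
  matrix(as.character(pred), length(t1_grid), length(t2_grid))
}

#' Exhaustive search over class subsets
#'
#' Enumerates all subsets of `k` classes, scores each by the mean
#' replicate accuracy of the chosen classifier, and returns the ranked
#' table (ties broken by lexicographic subset label).
#'
#' @param centroids `data.frame` with `t1`, `t2`, `class_label`.
#' @param k subset size (>= 2).
#' @param config an [svm_config()]; its `replicates` field sets the
#'   replicate count per subset.
#' @return `data.frame` with columns `classes` (comma-joined subset),
#'   `mean_accuracy`, `sd_accuracy`, ranked by mean accuracy descending.
#' @export
combination_search <- function(centroids, k, config = svm_config(replicates = 10L)) {
  if (k < 2) stop_arg("`k` must be >= 2")
  classes <- sort(unique(as.character(centroids$class_label)))
  if (k > length(classes)) stop_arg("`k` exceeds the number of classes")
  subsets <- utils::combn(classes, k, simplify = FALSE)
  rows <- lapply(subsets, function(ss) {
    sub <- centroids[centroids$class_label %in% ss, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "combo", paste(ss, collapse = ","))
    res <- run_svm_replicates(sub, cfg)
    data.frame(classes = paste(ss, collapse = ","),
               mean_accuracy = res$mean, sd_accuracy = res$sd)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_accuracy, out$classes), , drop = FALSE]
}
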