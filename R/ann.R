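#' VGG-style network architecture description
#'
#' Two published variants, both ending in a softmax head and trained
#' with Adamax for 12 epochs by default:
#' * `"msc"`: seven 3x3 convolutional layers followed by four dense
#'   layers; batch-normalization and 2x2 max-pooling after every other
#'   convolution starting after the first; no dropout.
#' * `"cell_line"`: four 3x3 convolutional layers, each followed by
#'   batch normalization and max pooling, then four dense layers with
#'   25 % dropout to curb overfitting.
#' ReLU activates every convolutional and dense layer.  Only layer
#' counts, activations, optimizer, dropout rate and epoch count are
#' published; kernel sizes, channel and dense widths, learning rate and
#' batch size are package defaults and configurable.
#'
#' @param variant `"msc"` or `"cell_line"`.
#' @param input_size input map side length in pixels (must be divisible
#'   by 16: both variants pool four times).
#' @param base_channels channels of the first convolution; doubled at
#'   every pooling stage.
#' @param dense_widths widths of the three hidden dense layers.
#' @param dropout_rate dropout on hidden dense layers (default 0.25 for
#'   `cell_line`, 0 for `msc`).
#' @param epochs training epochs.
#' @param learning_rate Adamax step size.
#' @param batch_size minibatch size.
#' @return Object of class `ann_architecture`.
#' @export
ann_architecture <- function(variant = c("msc", "cell_line"),
                             input_size = 32L, base_channels = 16L,
                             dense_widths = c(256L, 128L, 64L),
                             dropout_rate = NULL,
                             epochs = 12L, learning_rate = 1e-3,
                             batch_size = 16L) {
  variant <- match.arg(variant)
  if (is.null(dropout_rate)) dropout_rate <- if (variant == "cell_line") 0.25 else 0
  if (dropout_rate < 0 || dropout_rate >= 1) stop_arg("dropout must be in [0, 1)")
  structure(list(variant = variant,
                 conv_layers = if (variant == "msc") 7L else 4L,
                 dense_layers = 4L,
                 input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 dense_widths = as.integer(dense_widths),
                 dropout_rate = dropout_rate,
                 activation = "relu", optimizer = "adamax",
                 output = "softmax",
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size)),
            class = "ann_architecture")
}

#' Construct an initialized network
#'
#' Builds the layer stack of the requested variant with He-initialized
#' weights.  Layer counts are introspectable via the returned model's
#' `counts` field.
#'
#' @param arch an [ann_architecture()].
#' @param n_classes number of output classes (>= 2).
#' @param seed weight-initialization seed.
#' @return Model object of class `relaxcell_ann`.
#' @export
build_ann <- function(arch, n_classes, seed = 1L) {
  stopifnot(inherits(arch, "ann_architecture"))
  if (n_classes < 2) stop_arg("`n_classes` must be >= 2")
  side <- arch$input_size
  if (side < 16L || side %% 16L != 0L) {
    stop_arg("input size must be a positive multiple of 16 (four pooling stages)")
  }
  layers <- list()
  H <- side; Cin <- 1L; Cout <- arch$base_channels
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  pool_here <- function() {
    add(.layer_bn(Cin))
    add(list(type = "pool", H = H, W = H, p = .pool_indices(H, H)))
    H <<- H %/% 2L
    Cout <<- Cin * 2L
  }
  with_seed(seed, {
    if (arch$variant == "msc") {
      ## conv blocks: pool (with normalization) after conv 1, 3, 5, 7
      for (k in seq_len(7)) {
        add(.layer_conv(Cin, Cout, H, H))
        Cin <- Cout
        add(list(type = "relu"))
        if (k %in% c(1L, 3L, 5L, 7L)) pool_here()
      }
    } else {
      for (k in seq_len(4)) {
        add(.layer_conv(Cin, Cout, H, H))
        Cin <- Cout
        add(list(type = "relu"))
        pool_here()
      }
    }
    add(list(type = "flatten", C = Cin, H = H, W = H))
    n_in <- Cin * H * H
    for (wd in arch$dense_widths) {
      add(.layer_dense(n_in, wd))
      add(list(type = "relu"))
      if (arch$dropout_rate > 0) add(list(type = "dropout", rate = arch$dropout_rate))
      n_in <- wd
    }
    add(.layer_dense(n_in, as.integer(n_classes)))
  })
  structure(list(layers = layers, arch = arch, n_classes = as.integer(n_classes),
                 classes = NULL, opt_m = list(), opt_u = list(), opt_t = 0L,
                 counts = list(
                   conv = sum(vapply(layers, function(l) l$type == "conv", TRUE)),
                   dense = sum(vapply(layers, function(l) l$type == "dense", TRUE)),
                   bn = sum(vapply(layers, function(l) l$type == "bn", TRUE)),
                   pool = sum(vapply(layers, function(l) l$type == "pool", TRUE)),
                   dropout = sum(vapply(layers, function(l) l$type == "dropout", TRUE)))),
            class = "relaxcell_ann")
}

## images array (H, W, N) -> activation matrix 1 x (H*W*B) for `sel`
.images_to_batch <- function(images, sel) {
  matrix(images[, , sel, drop = FALSE], nrow = 1L)
}

#' Predict class probabilities / labels with a network
#'
#' @param model a `relaxcell_ann`.
#' @param images array `(H, W, N)` of input maps in `[0, 1]`.
#' @return List with `prob` (`n_classes x N`) and `label` (character if
#'   the model has been trained, otherwise class index).
#' @export
predict_ann <- function(model, images) {
  N <- dim(images)[3]
  prob <- matrix(NA_real_, model$n_classes, N)
  bs <- model$arch$batch_size
  for (start in seq(1L, N, by = bs)) {
    sel <- start:min(start + bs - 1L, N)
    fw <- .forward_pass(model, .images_to_batch(images, sel), length(sel), train = FALSE)
    prob[, sel] <- .softmax(fw$out)
  }
  idx <- max.col(t(prob), ties.method = "first")
  label <- if (!is.null(model$classes)) model$classes[idx] else idx
  list(prob = prob, label = label)
}

.accuracy_on <- function(model, images, truth, sel) {
  if (!length(sel)) return(NA_real_)
  pred <- predict_ann(model, images[, , sel, drop = FALSE])$label
  mean(pred == truth[sel])
}

#' Train a network on spectral maps
#'
#' Performs a celltype-aware train/validation/test split (augmented
#' spectra follow their parent sample), trains the network with Adamax
#' and softmax cross-entropy for `arch$epochs` epochs, logging the
#' cumulative training loss and the validation accuracy per epoch, and
#' evaluates the final test accuracy and confusion matrix.
#' Deterministic given the seed.
#'
#' @param images array `(H, W, N)` of input maps in `[0, 1]`.
#' @param meta `data.frame` with `sample_id`, `class_label` and
#'   optionally `parent_id`, aligned with the third array dimension.
#' @param arch an [ann_architecture()].
#' @param split a [split_spec()].
#' @param seed seed controlling split, initialization and shuffling.
#' @return A `training_report`: per-epoch `cumulative_loss` and
#'   `val_accuracy`, `test_accuracy`, `confusion` (true x predicted
#'   counts), and the partition sizes.
#' @export
train_ann <- function(images, meta, arch = ann_architecture(),
                      split = split_spec(), seed = 1L) {
  stopifnot(dim(images)[3] == nrow(meta))
  classes <- sort(unique(as.character(meta$class_label)))
  truth <- as.character(meta$class_label)
  parts <- celltype_aware_split(meta, split, seed = derive_seed(seed, "split"))
  idx <- lapply(parts, function(ids) which(meta$sample_id %in% ids))
  model <- build_ann(arch, length(classes), seed = derive_seed(seed, "init"))
  model$classes <- classes
  y <- match(truth, classes)
  n_epoch <- arch$epochs
  cum_loss <- numeric(n_epoch)
  val_acc <- numeric(n_epoch)
  model <- with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(n_epoch)) {
      order_tr <- sample(idx$train)
      for (start in seq(1L, length(order_tr), by = arch$batch_size)) {
        sel <- order_tr[start:min(start + arch$batch_size - 1L, length(order_tr))]
        B <- length(sel)
        fw <- .forward_pass(model, .images_to_batch(images, sel), B, train = TRUE)
        model <- fw$model
        prob <- .softmax(fw$out)
        pick <- cbind(y[sel], seq_len(B))
        loss <- -mean(log(pmax(prob[pick], 1e-12)))
        if (!is.finite(loss)) stop_arg("training diverged: non-finite loss")
        cum_loss[ep] <- cum_loss[ep] + loss
        dY <- prob
        dY[pick] <- dY[pick] - 1
        dY <- dY / B
        grads <- .backward_pass(model, fw, dY, B)
        model <- .adamax_step(model, grads, arch$learning_rate)
      }
      val_acc[ep] <- .accuracy_on(model, images, truth, idx$val)
    }
    model
  })
  pred <- predict_ann(model, images[, , idx$test, drop = FALSE])$label
  confusion <- table(factor(truth[idx$test], levels = classes),
                     factor(pred, levels = classes))
  structure(list(cumulative_loss = cum_loss, val_accuracy = val_acc,
                 test_accuracy = mean(pred == truth[idx$test]),
                 confusion = unclass(confusion),
                 n_train = length(idx$train), n_val = length(idx$val),
                 n_test = length(idx$test), classes = classes,
                 model = model, seed = seed),
            class = "training_report")
}

#' Replicate a training task and aggregate the reports
#'
#' Runs `task(seed)` with `n_replicates` independently derived seeds —
#' each training uses a fresh split — and aggregates: mean and std of
#' the test accuracy, element-wise mean epoch curves, and the averaged
#' confusion matrix.
#'
#' @param task function of one argument (an integer seed) returning a
#'   `training_report` (e.g. a closure over [train_ann()]).
#' @param n_replicates number of repetitions.
#' @param seed root seed.
#' @return List with `reports`, `accuracies`, `mean`, `sd`,
#'   `mean_cumulative_loss`, `mean_val_accuracy`, `mean_confusion`.
#' @export
replicate_runs <- function(task, n_replicates = 10L, seed = 1L) {
  reports <- lapply(seq_len(n_replicates), function(r) {
    task(derive_seed(seed, "replicate", r))
  })
  acc <- vapply(reports, `[[`, 0, "test_accuracy")
  conf <- Reduce(`+`, lapply(reports, `[[`, "confusion")) / n_replicates
  list(reports = reports, accuracies = acc,
       mean = mean(acc), sd = stats::sd(acc),
       mean_cumulative_loss = rowMeans(vapply(reports, `[[`,
         numeric(length(reports[[1]]$cumulative_loss)), "cumulative_loss")),
       mean_val_accuracy = rowMeans(vapply(reports, `[[`,
         numeric(length(reports[[1]]$val_accuracy)), "val_accuracy")),
       mean_confusion = conf)
}

#' Resample a spectrum to a square network input map
#'
#' Max-normalizes the (typically cropped) spectrum and resamples it to
#' `size x size` by bilinear interpolation.
#'
#' @param spec a [spectrum2d()].
#' @param size output side length in pixels.
#' @return `size x size` matrix in `[0, 1]` (rows index T1).
#' @export
spectrum_to_map <- function(spec, size = 32L) {
  X <- spec$intensity
  mx <- max(X)
  if (mx > 0) X <- X / mx
  as.matrix(EBImage::resize(EBImage::as.Image(X), w = size, h = size))
}

#' Stack a cohort of spectra into a network input array
#'
#' @param spectra list of [spectrum2d()] (cropped or full-frame).
#' @param size input side length.
#' @return List with `images` (`size x size x N` array) and `meta`
#'   (`data.frame` with `sample_id`, `class_label`, `parent_id`).
#' @export
cohort_to_images <- function(spectra, size = 32L) {
  N <- length(spectra)
  images <- array(0, dim = c(size, size, N))
  meta <- data.frame(sample_id = character(N), class_label = character(N),
                     parent_id = character(N), stringsAsFactors = FALSE)
  for (i in seq_len(N)) {
    images[, , i] <- spectrum_to_map(spectra[[i]], size)
    md <- spectra[[i]]$metadata
    meta$sample_id[i] <- md$sample_id %||% sprintf("sample_%03d", i)
    meta$class_label[i] <- md$class_label %||% md$phenotype %||% NA_character_
    meta$parent_id[i] <- md$parent_id %||% meta$sample_id[i]
  }
  list(images = images, meta = meta)
}
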