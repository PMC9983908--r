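test_that("both architecture variants build with the published layer counts", {
  msc <- build_ann(ann_architecture("msc", input_size = 32), n_classes = 2)
  expect_identical(msc$counts$conv, 7L)
  expect_identical(msc$counts$dense, 4L)
  expect_identical(msc$counts$dropout, 0L)
  expect_identical(msc$counts$pool, 4L)
  cl <- build_ann(ann_architecture("cell_line", input_size = 32), n_classes = 5)
  expect_identical(cl$counts$conv, 4L)
  expect_identical(cl$counts$dense, 4L)
  expect_identical(cl$counts$pool, 4L)
  expect_gt(cl$counts$dropout, 0L)
  drop_layers <- Filter(function(l) l$type == "dropout", cl$layers)
  expect_true(all(vapply(drop_layers, `[[`, 0, "rate") == 0.25))
  # softmax head width equals the class count
  last <- cl$layers[[length(cl$layers)]]
  expect_identical(last$n_out, 5L)
  expect_error(build_ann(ann_architecture("msc", input_size = 20), 2),
               "multiple of 16")
  expect_error(build_ann(ann_architecture("msc"), 1), "n_classes")
  expect_identical(ann_architecture("msc")$epochs, 12L)
})

test_that("backpropagation matches numerical gradients", {
  # the independent oracle for the whole engine: central finite differences
  for (variant in c("msc", "cell_line")) {
    arch <- ann_architecture(variant, input_size = 16, base_channels = 2,
                             dense_widths = c(8L, 6L, 4L), dropout_rate = 0)
    m <- build_ann(arch, 3, seed = 7)
    imgs <- withr::with_seed(1, array(stats::runif(16 * 16 * 4), c(16, 16, 4)))
    y <- c(1L, 2L, 3L, 1L)
    lossfn <- function(model) {
      fw <- relaxcell:::.forward_pass(model, relaxcell:::.images_to_batch(imgs, 1:4), 4, train = TRUE)
      prob <- relaxcell:::.softmax(fw$out)
      -mean(log(prob[cbind(y, 1:4)]))
    }
    fw <- relaxcell:::.forward_pass(m, relaxcell:::.images_to_batch(imgs, 1:4), 4, train = TRUE)
    prob <- relaxcell:::.softmax(fw$out)
    dY <- prob
    dY[cbind(y, 1:4)] <- dY[cbind(y, 1:4)] - 1
    dY <- dY / 4
    gr <- relaxcell:::.backward_pass(m, fw, dY, 4)
    types <- vapply(m$layers, `[[`, "", "type")
    for (i in which(types %in% c("conv", "dense", "bn"))) {
      nms <- if (types[i] == "bn") c("gamma", "beta") else c("W_", "b_")
      for (nm in nms) {
        for (idx in seq_len(min(3, length(m$layers[[i]][[nm]])))) {
          eps <- 1e-5
          mp <- m; mp$layers[[i]][[nm]][idx] <- mp$layers[[i]][[nm]][idx] + eps
          mm <- m; mm$layers[[i]][[nm]][idx] <- mm$layers[[i]][[nm]][idx] - eps
          num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
          ana <- gr[[i]][[nm]][idx]
          expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
        }
      }
    }
  }
})

test_that("an untrained network predicts at chance on balanced classes", {
  k <- 4L
  m <- build_ann(ann_architecture("cell_line", input_size = 16,
                                  base_channels = 2,
                                  dense_widths = c(8L, 6L, 4L)), k, seed = 3)
  m$classes <- LETTERS[1:k]
  imgs <- withr::with_seed(2, array(stats::runif(16 * 16 * 200), c(16, 16, 200)))
  truth <- rep(LETTERS[1:k], 50)
  acc <- mean(predict_ann(m, imgs)$label == truth)
  expect_lt(abs(acc - 1 / k), 0.15)
  # probabilities are a distribution
  pr <- predict_ann(m, imgs[, , 1:5, drop = FALSE])$prob
  expect_equal(colSums(pr), rep(1, 5), tolerance = 1e-9)
})

test_that("training learns a separable task and logs sane reports", {
  dat <- blob_image_cohort(n = 60L)
  rep1 <- train_ann(dat$images, dat$meta,
                    ann_architecture("cell_line", input_size = 32),
                    split_spec(), seed = 5)
  expect_gte(rep1$test_accuracy, 0.95)
  # loss decreases on learnable data
  expect_lt(rep1$cumulative_loss[12], rep1$cumulative_loss[1])
  # confusion matrix conserves the test set
  expect_identical(as.integer(sum(rep1$confusion)), rep1$n_test)
  expect_true(all(rowSums(rep1$confusion) >= 1))  # every class in the test set
  expect_length(rep1$val_accuracy, 12L)
  # determinism: identical seed, identical history
  rep2 <- train_ann(dat$images, dat$meta,
                    ann_architecture("cell_line", input_size = 32),
                    split_spec(), seed = 5)
  expect_identical(rep1$cumulative_loss, rep2$cumulative_loss)
  expect_identical(rep1$test_accuracy, rep2$test_accuracy)
})

test_that("replicate aggregation averages accuracies and confusions", {
  dat <- blob_image_cohort(n = 40L)
  task <- function(seed) {
    train_ann(dat$images, dat$meta,
              ann_architecture("cell_line", input_size = 32,
                               base_channels = 4,
                               dense_widths = c(32L, 16L, 8L)),
              split_spec(), seed = seed)
  }
  agg <- replicate_runs(task, n_replicates = 2L, seed = 9)
  expect_length(agg$accuracies, 2)
  expect_equal(agg$mean, mean(agg$accuracies))
  expect_equal(sum(agg$mean_confusion),
               mean(vapply(agg$reports, `[[`, 0L, "n_test")))
  # n = 1 is a passthrough of the single report
  one <- replicate_runs(task, n_replicates = 1L, seed = 9)
  expect_identical(one$mean, one$reports[[1]]$test_accuracy)
})

test_that("spectra resample to normalized square maps", {
  sp <- blob_spectrum(rbind(c(0.5, 0.05)), id = "m1")
  sp$metadata$class_label <- "A"
  mp <- spectrum_to_map(sp, 32)
  expect_identical(dim(mp), c(32L, 32L))
  expect_lte(max(mp), 1)
  expect_gte(min(mp), 0)
  dat <- cohort_to_images(list(sp, sp), 16)
  expect_identical(dim(dat$images), c(16L, 16L, 2L))
  expect_identical(dat$meta$class_label, c("A", "A"))
})
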