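# Small end-to-end runs use 64x64 fixtures and a 1/16-width network so the
# whole file stays fast.

small_config <- function(epochs = 2, seed = 42, ...) {
  train_config(epochs = epochs, batch_size = 3, seed = seed,
               learning_rate = 2e-3, num_classes = 2,
               input_size = c(64, 64, 3), dropout_rate = 0.2,
               width_multiplier = 1 / 8, ...)
}

small_data <- function(n_per_class = 5, seed = 7) {
  generate_dataset(default_texture_classes(2), n_per_class = n_per_class,
                   size = c(64, 64), seed = seed)
}

test_that("split_dataset is a stratified, deterministic partition", {
  m <- data.frame(image_id = sprintf("im%03d", 1:100),
                  class = rep(c("a", "b"), each = 50))
  sp <- split_dataset(m, train_fraction = 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 30L)
  expect_equal(unname(table(sp$train$class)), c(35L, 35L), ignore_attr = TRUE)
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0L)
  expect_setequal(c(sp$train$image_id, sp$test$image_id), m$image_id)

  sp2 <- split_dataset(m, train_fraction = 0.7, seed = 1)
  expect_identical(sp$train$image_id, sp2$train$image_id)
  sp3 <- split_dataset(m, train_fraction = 0.7, seed = 2)
  expect_false(identical(sp$train$image_id, sp3$train$image_id))

  expect_error(split_dataset(data.frame(image_id = "x", class = "a"),
                             seed = 1), ">= 2 images")
})

test_that("training runs, learns the separable fixtures, and records history", {
  cfg <- small_config(epochs = 5)
  data <- small_data(n_per_class = 6)
  fit <- train_model(cfg, data)
  expect_s3_class(fit, "haarnet_fit")
  expect_equal(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$loss)))
  # loss must come down and accuracy must beat the 0.5 chance level
  expect_lt(fit$history$loss[5], fit$history$loss[1])
  expect_gt(fit$history$train_accuracy[5], 0.5)
  expect_equal(fit$classes, c("classA", "classB"))
  # checkpoint bookkeeping
  expect_true(is.finite(fit$best$accuracy))
  expect_equal(fit$best$accuracy, max(fit$history$test_accuracy))
})

test_that("loss decreases over the first epochs (median over 3 seeds)", {
  data <- small_data(n_per_class = 4)
  deltas <- vapply(c(42, 43, 44), function(s) {
    cfg <- small_config(epochs = 2, seed = s)
    h <- train_model(cfg, data)$history
    h$loss[1] - h$loss[2]
  }, 1)
  expect_gt(median(deltas), 0)
})

test_that("training is reproducible given the seed", {
  cfg <- small_config(epochs = 1)
  data <- small_data(n_per_class = 4)
  f1 <- train_model(cfg, data)
  f2 <- train_model(cfg, data)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params$fc_7, f2$model$params$fc_7)
})

test_that("train/test leakage is rejected and empty training set errors", {
  cfg <- small_config()
  data <- small_data(n_per_class = 3)
  sp <- split_dataset(data, 0.7, 1)
  sp$test <- rbind(sp$test, sp$train[1, ])
  expect_error(train_model(cfg, data, split = sp), "leakage")
  sp2 <- split_dataset(data, 0.7, 1)
  sp2$train <- sp2$train[0, ]
  expect_error(train_model(cfg, data, split = sp2), "empty")
})

test_that("evaluation aggregates patch scores to image level consistently", {
  cfg <- small_config(epochs = 2)
  data <- small_data(n_per_class = 5)
  fit <- train_model(cfg, data)
  ev <- evaluate_model(fit)
  expect_named(ev, c("image", "patch", "predictions", "classes"))
  expect_equal(nrow(ev$predictions), nrow(fit$split$test))
  # cross-module consistency: overall accuracy recomputed from predictions
  expect_equal(ev$image$overall_accuracy,
               mean(ev$predictions$predicted == ev$predictions$class))
  expect_true(all(ev$image$per_class$tp + ev$image$per_class$fn +
                    ev$image$per_class$fp + ev$image$per_class$tn ==
                    nrow(fit$split$test)))
})

test_that("image-level aggregation equals a hand-computed mean over patches", {
  # 3 test images of 96x96 -> 25 patches each at side 32/overlap 0.5
  # (anchors {0,16,...,64}^2)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 5,
                      num_classes = 2, input_size = c(32, 32, 3),
                      width_multiplier = 1 / 16, learning_rate = 1e-3)
  specs <- default_texture_classes(2)
  imgs <- list(generate_image(specs[[1]], c(96, 96), 1),
               generate_image(specs[[2]], c(96, 96), 2),
               generate_image(specs[[1]], c(96, 96), 3))
  test_m <- data.frame(image_id = c("t1", "t2", "t3"),
                       class = c("classA", "classB", "classA"),
                       stringsAsFactors = FALSE)
  test_m$image <- imgs
  # 32x32 train images for a 32-input net
  train_m <- generate_dataset(specs, n_per_class = 3, size = c(32, 32),
                              seed = 9)
  fit <- train_model(cfg, train_m,
                     split = list(train = train_m, test = test_m))
  ev <- evaluate_model(fit)
  # hand-compute: mean of the 9 patch softmax rows per image
  for (i in 1:3) {
    ps <- prepare_patches(imgs[[i]], side = 32, overlap = 0.5,
                          augment = FALSE, normalize = TRUE)
    xs <- array(0, c(32, 32, 3, length(ps$patches)))
    for (k in seq_along(ps$patches)) xs[, , , k] <- ps$patches[[k]]$pixels
    probs <- predict(fit$model, xs)
    expect_equal(nrow(probs), 25L)
    # image-level score = mean of patch scores
    manual <- colMeans(probs)
    pred_manual <- fit$classes[which.max(manual)]
    expect_equal(ev$predictions$predicted[i], pred_manual)
  }
})

test_that("a trivial always-one-class scorer gets accuracy 1/K in the report", {
  classes <- c("a", "b", "c", "d")
  labels <- rep(classes, each = 3)
  scores <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), each = 12), 12, 4,
                   dimnames = list(NULL, classes))
  rep_ <- multiclass_report(labels, scores, classes)
  expect_equal(rep_$overall_accuracy, 0.25)
})

test_that("config validation catches bad fields", {
  expect_error(train_config(train_fraction = 0), "train_fraction")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(optimizer_name = "sgd"), "adam")
  expect_error(train_config(input_size = c(64, 128, 3)), "square")
})
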