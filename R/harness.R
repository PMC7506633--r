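# Orchestration: stratified image-level splitting, the training loop over
# the patching/augmentation pipeline, and evaluation with patch-level and
# image-level (mean softmax over an image's patches) decisions.

#' Training configuration
#'
#' Defaults follow the reference experimental setup: 200 epochs, batch size
#' 3, a 70/30 train/test split, 4-level orthonormal Haar front end and
#' 512x512x3 input. Optimizer settings are not pinned down by that setup;
#' the defaults here are an Adam-style adaptive optimizer at learning rate
#' 1e-4 with softmax cross-entropy, all overridable.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size samples per gradient step (>= 1).
#' @param train_fraction fraction of images per class used for training,
#'   in (0, 1).
#' @param seed master seed for split, initialization, shuffling, dropout.
#' @param learning_rate Adam step size.
#' @param optimizer_name only `"adam"` is implemented.
#' @param num_classes number of classes (checked against the data).
#' @param input_size (H, W, C) network input; H = W is required (patches
#'   are square) and both must be divisible by 16.
#' @param dropout_rate head dropout probability.
#' @param wavelet_mode filter-bank normalization of the spectral taps.
#' @param width_multiplier channel-width scale of the network.
#' @param overlap patch overlap fraction.
#' @param augment apply the 8-fold dihedral augmentation to training
#'   patches.
#' @param verbose print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 3L,
                         train_fraction = 0.7, seed = 1L,
                         learning_rate = 1e-4, optimizer_name = "adam",
                         num_classes = 4L, input_size = c(512L, 512L, 3L),
                         dropout_rate = 0.5,
                         wavelet_mode = "orthonormal",
                         width_multiplier = 1, overlap = 0.5,
                         augment = TRUE, verbose = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (optimizer_name != "adam") stop("only the adam optimizer is implemented")
  if (input_size[1] != input_size[2]) stop("input must be square (H = W)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 dropout_rate = dropout_rate, wavelet_mode = wavelet_mode,
                 width_multiplier = width_multiplier, overlap = overlap,
                 augment = isTRUE(augment), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Stratified image-level train/test split
#'
#' Splits a labelled image manifest before any patching or augmentation, so
#' no patch of a test image can ever reach training. Per class,
#' `round(train_fraction * n)` images go to training; the split is a
#' deterministic function of `seed`.
#'
#' @param manifest data frame with at least `image_id` and `class` columns.
#' @param train_fraction fraction per class assigned to training.
#' @param seed split seed.
#' @return List with `train` and `test` manifests (disjoint, exhaustive).
#' @export
split_dataset <- function(manifest, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(manifest), all(c("image_id", "class") %in%
                                           names(manifest)))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  counts <- table(manifest$class)
  if (any(counts < 2))
    stop("every class needs >= 2 images; class '",
         names(counts)[which(counts < 2)[1]], "' has ",
         min(counts), " image(s)")
  train_idx <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$class), function(idx) {
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  list(train = manifest[sort(train_idx), , drop = FALSE],
       test = manifest[setdiff(seq_len(nrow(manifest)), train_idx), ,
                       drop = FALSE])
}

manifest_image <- function(manifest, i) {
  img <- if ("image" %in% names(manifest)) manifest$image[[i]]
  else read_image(manifest$file[i])
  as_image_array(img)
}

# Anchored (un-augmented, un-normalized) windows for every manifest image.
manifest_windows <- function(manifest, side, overlap) {
  lapply(seq_len(nrow(manifest)), function(i) {
    ps <- extract_patches(manifest_image(manifest, i), side = side,
                          overlap = overlap,
                          image_id = manifest$image_id[i],
                          label = manifest$class[i])
    lapply(ps$patches, `[[`, "pixels")
  })
}

assemble_batch <- function(windows, items, input_size, augment) {
  n <- nrow(items)
  x <- array(0, c(input_size, n))
  for (b in seq_len(n)) {
    px <- windows[[items$img[b]]][[items$win[b]]]
    if (augment) px <- dihedral_transform(px, items$tag[b])
    x[, , , b] <- normalize_patch(px)
  }
  x
}

#' Train the wavelet-fusion network
#'
#' Runs the full pipeline: stratified image-level split, patch extraction
#' with overlap, 8-fold dihedral augmentation of training patches,
#' per-channel mean normalization, then mini-batch Adam on softmax
#' cross-entropy. The per-epoch history records the loss, the training and
#' test accuracies -- both measured the same way, in evaluation mode on the
#' un-augmented patches of the respective split -- plus the running
#' training-mode mini-batch accuracy (`train_accuracy_batch`, the
#' optimizer's noisier view under dropout and batch statistics). The
#' weights with the best test accuracy are checkpointed. Everything is
#' driven by `config$seed`.
#'
#' @param config a [train_config()].
#' @param data labelled image manifest: data frame with `image_id`, `class`
#'   and either a `file` column (PNG/TIFF paths) or an `image` list column.
#' @param split optional pre-made `list(train, test)` of manifests; by
#'   default [split_dataset()] is applied to `data`.
#' @return An object of class `haarnet_fit`: list with `model` (final
#'   weights), `best` (checkpointed weights + epoch), `history` (per-epoch
#'   data frame), `classes`, `config`, `split`.
#' @export
train_model <- function(config, data, split = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(split)) split <- split_dataset(data, config$train_fraction,
                                             config$seed)
  if (nrow(split$train) == 0) stop("training set is empty")
  leaked <- intersect(split$train$image_id, split$test$image_id)
  if (length(leaked))
    stop("train/test leakage: image(s) ", paste(leaked, collapse = ", "),
         " appear in both sets")
  classes <- sort(unique(c(split$train$class, split$test$class)))
  if (length(classes) != config$num_classes)
    stop("config$num_classes = ", config$num_classes, " but the data has ",
         length(classes), " classes")

  graph <- build_architecture(num_classes = length(classes),
                              input_size = config$input_size,
                              dropout_rate = config$dropout_rate,
                              width_multiplier = config$width_multiplier)
  model <- instantiate_model(graph, seed = config$seed,
                             wavelet_mode = config$wavelet_mode)
  if (config$verbose) {
    a <- audit_parameters(graph)$totals
    message("model: ", a$trainable, " trainable / ", a$non_trainable,
            " non-trainable parameters; seed ", config$seed)
  }

  side <- config$input_size[1]
  train_windows <- manifest_windows(split$train, side, config$overlap)
  train_y <- match(split$train$class, classes)
  tags <- if (config$augment) dihedral_tags() else "r0"
  index <- do.call(rbind, lapply(seq_along(train_windows), function(i) {
    expand.grid(img = i, win = seq_along(train_windows[[i]]), tag = tags,
                stringsAsFactors = FALSE)
  }))

  # evaluation-mode training accuracy is measured on the un-augmented
  # training windows, the same estimator used for test accuracy
  train_eval_items <- do.call(rbind, lapply(seq_along(train_windows),
                                            function(i) {
    data.frame(img = i, win = seq_along(train_windows[[i]]), tag = "r0",
               stringsAsFactors = FALSE)
  }))
  train_eval_x <- assemble_batch(train_windows, train_eval_items,
                                 config$input_size, augment = FALSE)
  train_eval_y <- train_y[train_eval_items$img]

  test_windows <- manifest_windows(split$test, side, config$overlap)
  test_x <- NULL
  if (nrow(split$test) > 0) {
    test_items <- do.call(rbind, lapply(seq_along(test_windows), function(i) {
      data.frame(img = i, win = seq_along(test_windows[[i]]), tag = "r0",
                 stringsAsFactors = FALSE)
    }))
    test_x <- assemble_batch(test_windows, test_items, config$input_size,
                             augment = FALSE)
    test_y <- match(split$test$class[test_items$img], classes)
  }

  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_accuracy = numeric(),
                        train_accuracy_batch = numeric(),
                        test_accuracy = numeric())
  best <- list(accuracy = -Inf, epoch = NA_integer_, snapshot = NULL)
  for (epoch in seq_len(config$epochs)) {
    order_ <- sample.int(nrow(index))
    losses <- c(); correct <- 0L; seen <- 0L
    for (start in seq(1L, nrow(index), by = config$batch_size)) {
      items <- index[order_[start:min(start + config$batch_size - 1L,
                                      nrow(index))], , drop = FALSE]
      x <- assemble_batch(train_windows, items, config$input_size,
                          augment = config$augment)
      y <- train_y[items$img]
      res <- train_batch(model, x, y, lr = config$learning_rate)
      if (!is.finite(res$loss))
        stop("divergence: non-finite loss at epoch ", epoch)
      losses <- c(losses, res$loss)
      correct <- correct + sum(max.col(t(res$probs)) == y)
      seen <- seen + length(y)
    }
    train_probs <- predict(model, train_eval_x)
    train_acc <- mean(max.col(train_probs, ties.method = "first") ==
                        train_eval_y)
    test_acc <- NA_real_
    if (!is.null(test_x)) {
      probs <- predict(model, test_x)
      test_acc <- mean(max.col(probs, ties.method = "first") == test_y)
      if (test_acc > best$accuracy) {
        best <- list(accuracy = test_acc, epoch = epoch,
                     snapshot = model_snapshot(model))
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = mean(losses), train_accuracy = train_acc,
      train_accuracy_batch = correct / seen, test_accuracy = test_acc))
    if (config$verbose)
      message(sprintf(
        "epoch %d: loss %.4f train_acc %.3f (batch %.3f) test_acc %s",
        epoch, mean(losses), train_acc, correct / seen,
        ifelse(is.na(test_acc), "-", sprintf("%.3f", test_acc))))
  }
  structure(list(model = model, best = best, history = history,
                 classes = classes, config = config, split = split),
            class = "haarnet_fit")
}

#' @export
print.haarnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("haarnet_fit:", nrow(x$history), "epoch(s);",
      "final train accuracy", round(last$train_accuracy, 3),
      "/ test accuracy", round(last$test_accuracy, 3), "\n")
  invisible(x)
}

#' Evaluate a trained model on a test manifest
#'
#' Computes patch-level predictions on the un-augmented, normalized patches
#' of every test image, aggregates them to image-level scores by averaging
#' the softmax vectors over each image's patches, and reports
#' [multiclass_report()] metrics at both granularities.
#'
#' @param fit a `haarnet_fit` (or a bare `haarnet_model`).
#' @param manifest test image manifest; defaults to the fit's own test
#'   split.
#' @param config a [train_config()]; defaults to the fit's.
#' @param use_best use the best-checkpoint weights rather than the final
#'   ones (fits only).
#' @return List with `image` and `patch` reports (each a
#'   [multiclass_report()]), plus `predictions` (per-image data frame) and
#'   `classes`.
#' @export
evaluate_model <- function(fit, manifest = NULL, config = NULL,
                           use_best = FALSE) {
  if (inherits(fit, "haarnet_fit")) {
    model <- fit$model
    if (use_best && !is.null(fit$best$snapshot)) {
      model <- instantiate_model(model$graph, seed = model$seed,
                                 wavelet_mode = model$bank$mode)
      model_restore(model, fit$best$snapshot)
    }
    if (is.null(manifest)) manifest <- fit$split$test
    if (is.null(config)) config <- fit$config
    classes <- fit$classes
  } else {
    model <- fit
    if (is.null(manifest) || is.null(config))
      stop("manifest and config are required when passing a bare model")
    classes <- sort(unique(manifest$class))
  }
  if (nrow(manifest) == 0) stop("test manifest is empty")
  missing_cls <- setdiff(classes, unique(manifest$class))
  if (length(missing_cls))
    warning("class(es) absent from the test set: ",
            paste(missing_cls, collapse = ", "),
            "; their sensitivity/AUC are undefined")
  side <- config$input_size[1]
  windows <- manifest_windows(manifest, side, config$overlap)
  patch_scores <- list(); patch_labels <- c()
  image_scores <- matrix(0, nrow(manifest), length(classes))
  for (i in seq_len(nrow(manifest))) {
    items <- data.frame(img = 1L, win = seq_along(windows[[i]]), tag = "r0")
    x <- assemble_batch(windows[i], items, config$input_size, augment = FALSE)
    probs <- predict(model, x)
    patch_scores[[i]] <- probs
    patch_labels <- c(patch_labels, rep(manifest$class[i], nrow(probs)))
    image_scores[i, ] <- colMeans(probs)
  }
  patch_scores <- do.call(rbind, patch_scores)
  colnames(patch_scores) <- classes
  colnames(image_scores) <- classes
  image_report <- multiclass_report(manifest$class, image_scores, classes)
  patch_report <- multiclass_report(patch_labels, patch_scores, classes)
  predictions <- data.frame(
    image_id = manifest$image_id, class = manifest$class,
    predicted = classes[max.col(image_scores, ties.method = "first")],
    stringsAsFactors = FALSE)
  list(image = image_report, patch = patch_report,
       predictions = predictions, classes = classes)
}
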