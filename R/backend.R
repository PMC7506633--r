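# CPU reference backend: binds an architecture_graph to concrete weights and
# provides forward, backward and Adam update passes. Convolutions run through
# the compiled im2col/GEMM kernels; everything else is vectorized R.
#
# Conventions:
#   spatial activations  (H, W, C, N) arrays
#   dense activations    (units, N) matrices
#   conv weights         (9*C_in) x F matrices, rows ordered (kr, kc, c)
#   dense weights        N_in x units matrices

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Instantiate an executable model from an architecture graph
#'
#' Allocates and seeds the weights of every layer of `graph` and returns a
#' model object that can run forward passes, gradient updates and
#' prediction on the CPU. Weight initialization is He-normal
#' (`sd = sqrt(2 / fan_in)`) for convolutions and dense layers, zero biases,
#' and unit-scale/zero-shift batch normalization; it is driven entirely by
#' `seed`, so two instantiations with the same seed are identical.
#'
#' The model's parameter counts agree exactly with the closed-form
#' [audit_parameters()] of the same graph, and its forward pass reproduces
#' [forward_shapes()] layer by layer.
#'
#' @param graph an [build_architecture()] result.
#' @param seed integer RNG seed for weight initialization.
#' @param wavelet_mode filter-bank normalization used by the spectral taps
#'   (see [haar_filter_bank()]); the default keeps activation scale stable
#'   across pyramid levels.
#' @return An object of class `haarnet_model` (an environment) with the
#'   graph, parameters and batch-normalization state.
#' @examples
#' g <- build_architecture(num_classes = 2, input_size = c(32, 32, 3),
#'                         width_multiplier = 1 / 16)
#' m <- instantiate_model(g, seed = 1)
#' model_parameter_counts(m)
#' @export
instantiate_model <- function(graph, seed = 1L,
                              wavelet_mode = c("orthonormal", "raw", "average")) {
  stopifnot(inherits(graph, "architecture_graph"))
  wavelet_mode <- match.arg(wavelet_mode)
  shapes <- forward_shapes(graph)
  set.seed(seed)
  params <- list()
  bn_state <- list()
  for (l in graph$layers) {
    if (l$kind == "conv") {
      c_in <- shapes[[l$inputs[1]]][3]
      f <- l$hyper$filters
      params[[l$name]] <- list(
        W = matrix(stats::rnorm(9 * c_in * f, sd = sqrt(2 / (9 * c_in))),
                   9 * c_in, f),
        b = numeric(f)
      )
    } else if (l$kind == "dense") {
      n_in <- prod(shapes[[l$inputs[1]]])
      u <- l$hyper$units
      params[[l$name]] <- list(
        W = matrix(stats::rnorm(n_in * u, sd = sqrt(2 / n_in)), n_in, u),
        b = numeric(u)
      )
    } else if (l$kind == "batchnorm") {
      ch <- shapes[[l$inputs[1]]]
      ch <- ch[length(ch)]
      params[[l$name]] <- list(gamma = rep(1, ch), beta = numeric(ch))
      bn_state[[l$name]] <- list(mean = numeric(ch), var = rep(1, ch))
    }
  }
  model <- new.env(parent = emptyenv())
  model$graph <- graph
  model$shapes <- shapes
  model$params <- params
  model$bn_state <- bn_state
  model$bank <- haar_filter_bank(wavelet_mode)
  model$seed <- as.integer(seed)
  model$opt <- NULL
  class(model) <- "haarnet_model"
  model
}

#' @export
print.haarnet_model <- function(x, ...) {
  cnt <- model_parameter_counts(x)
  cat("haarnet_model on graph with", length(x$graph$layers), "layers;",
      format(cnt["trainable"], big.mark = ","), "trainable /",
      format(cnt["non_trainable"], big.mark = ","),
      "non-trainable parameters\n")
  invisible(x)
}

#' Backend-reported parameter counts
#'
#' Counts the actual allocated weights of a model (trainable: conv/dense
#' weights and biases, batch-norm scale/shift; non-trainable: batch-norm
#' running statistics). Agrees exactly with [audit_parameters()].
#'
#' @param model a [instantiate_model()] result.
#' @return Named numeric vector with `trainable` and `non_trainable`.
#' @export
model_parameter_counts <- function(model) {
  stopifnot(inherits(model, "haarnet_model"))
  tr <- sum(vapply(model$params, function(p) sum(lengths(p)), 1))
  ntr <- sum(vapply(model$bn_state, function(s) sum(lengths(s)), 1))
  c(trainable = tr, non_trainable = ntr)
}

as_batch <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("expected an (H, W, C) image or (H, W, C, N) batch")
  x
}

# nth sample of an (H, W, C, N) batch as an (H, W, C) array.
batch_slice <- function(x, n) {
  d <- dim(x)
  y <- x[, , , n, drop = FALSE]
  dim(y) <- d[1:3]
  y
}

# Wavelet taps for a batch: list level -> (H/2^l, W/2^l, 4C, N)
batch_wavelet_taps <- function(x, levels, bank) {
  d <- dim(x)
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    out[[l]] <- array(0, c(d[1] / 2^l, d[2] / 2^l, 4L * d[3], d[4]))
  }
  for (n in seq_len(d[4])) {
    pyr <- dwt_pyramid(batch_slice(x, n), levels, bank)
    for (l in seq_len(levels)) out[[l]][, , , n] <- pyr[[l]]$data
  }
  out
}

bn_channels_matrix <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3] * d[4])
}

# Forward pass. Returns list(acts, cache); cache holds what backward needs.
model_forward <- function(model, x, training = FALSE, keep_acts = FALSE) {
  x <- as_batch(x)
  graph <- model$graph
  if (!all(dim(x)[1:3] == graph$input_size))
    stop("input is ", paste(dim(x)[1:3], collapse = "x"),
         " but the model expects ", paste(graph$input_size, collapse = "x"))
  wl_levels <- max(vapply(Filter(function(l) l$kind == "wavelet", graph$layers),
                          function(l) l$hyper$level, 1L))
  taps <- batch_wavelet_taps(x, wl_levels, model$bank)
  acts <- list(input = x)
  cache <- list()
  for (l in graph$layers) {
    nm <- l$name
    a_in <- acts[[l$inputs[1]]]
    acts[[nm]] <- switch(
      l$kind,
      input = x,
      wavelet = taps[[l$hyper$level]],
      conv = hn_conv_forward(a_in, model$params[[nm]]$W,
                             model$params[[nm]]$b, l$hyper$stride),
      batchnorm = {
        p <- model$params[[nm]]
        dense_in <- is.matrix(a_in)
        if (training) {
          if (dense_in) {
            mu <- rowMeans(a_in)
            v <- rowMeans(a_in^2) - mu^2
          } else {
            d <- dim(a_in)
            m <- bn_channels_matrix(a_in)
            percn <- matrix(colMeans(m), d[3], d[4])
            mu <- rowMeans(percn)
            percn2 <- matrix(colMeans(m^2), d[3], d[4])
            v <- rowMeans(percn2) - mu^2
          }
          st <- model$bn_state[[nm]]
          st$mean <- BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * mu
          st$var <- BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * v
          model$bn_state[[nm]] <- st
        } else {
          mu <- model$bn_state[[nm]]$mean
          v <- model$bn_state[[nm]]$var
        }
        invstd <- 1 / sqrt(v + BN_EPS)
        if (dense_in) {
          xhat <- (a_in - mu) * invstd
          y <- xhat * p$gamma + p$beta
        } else {
          d <- dim(a_in)
          chcols <- rep_len(seq_len(d[3]), d[3] * d[4])
          m <- bn_channels_matrix(a_in)
          xhat <- (m - rep(mu[chcols], each = d[1] * d[2])) *
            rep(invstd[chcols], each = d[1] * d[2])
          y <- xhat * rep(p$gamma[chcols], each = d[1] * d[2]) +
            rep(p$beta[chcols], each = d[1] * d[2])
          dim(y) <- d
        }
        if (training) cache[[nm]] <- list(xhat = xhat, invstd = invstd)
        y
      },
      relu = {
        y <- a_in
        y[y < 0] <- 0
        y
      },
      avgpool = {
        d <- dim(a_in)
        os <- model$shapes[[nm]]
        out <- array(0, c(os, d[4]))
        for (n in seq_len(d[4]))
          out[, , , n] <- avg_pool(batch_slice(a_in, n), l$hyper$window,
                                   l$hyper$stride, l$hyper$padding)
        out
      },
      concat = {
        ins <- acts[l$inputs]
        chs <- vapply(ins, function(a) dim(a)[3], 1L)
        d1 <- dim(ins[[1]])
        out <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
        at <- 0L
        for (a in ins) {
          out[, , at + seq_len(dim(a)[3]), ] <- a
          at <- at + dim(a)[3]
        }
        out
      },
      flatten = matrix(a_in, prod(dim(a_in)[1:3]), dim(a_in)[4]),
      dense = crossprod(model$params[[nm]]$W, a_in) + model$params[[nm]]$b,
      dropout = {
        rate <- l$hyper$rate
        if (training && rate > 0) {
          mask <- (stats::runif(length(a_in)) >= rate) / (1 - rate)
          dim(mask) <- dim(a_in)
          cache[[nm]] <- mask
          a_in * mask
        } else a_in
      },
      stop("backend cannot execute layer kind: ", l$kind)
    )
  }
  out_name <- graph$layers[[length(graph$layers)]]$name
  list(logits = acts[[out_name]],
       acts = if (keep_acts) acts else NULL,
       cache = cache)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Backward pass from softmax cross-entropy. y: integer class ids 1..K.
# Returns list(loss, probs, grads) with grads matching model$params.
model_backward <- function(model, acts, cache, y) {
  graph <- model$graph
  out_name <- graph$layers[[length(graph$layers)]]$name
  logits <- acts[[out_name]]
  n <- ncol(logits)
  probs <- softmax_cols(logits)
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(n))], 1e-12)))
  donehot <- probs
  donehot[cbind(y, seq_len(n))] <- donehot[cbind(y, seq_len(n))] - 1
  dacts <- list()
  dacts[[out_name]] <- donehot / n
  grads <- list()
  stop_kinds <- c("input", "wavelet")
  for (l in rev(graph$layers)) {
    nm <- l$name
    dy <- dacts[[nm]]
    if (is.null(dy) || l$kind %in% stop_kinds) next
    a_in <- acts[[l$inputs[1]]]
    add_grad <- function(target, g) {
      dacts[[target]] <<- if (is.null(dacts[[target]])) g
      else dacts[[target]] + g
    }
    switch(
      l$kind,
      conv = {
        in_kind <- graph$layers[[l$inputs[1]]]$kind
        need_dx <- !in_kind %in% stop_kinds
        bw <- hn_conv_backward(a_in, model$params[[nm]]$W, dy,
                               l$hyper$stride, need_dx)
        grads[[nm]] <- list(W = bw$dw, b = bw$db)
        if (need_dx) add_grad(l$inputs[1], bw$dx)
      },
      dense = {
        grads[[nm]] <- list(W = a_in %*% t(dy), b = rowSums(dy))
        add_grad(l$inputs[1], model$params[[nm]]$W %*% dy)
      },
      batchnorm = {
        p <- model$params[[nm]]
        cc <- cache[[nm]]
        if (is.matrix(a_in)) {
          dgamma <- rowSums(dy * cc$xhat)
          dbeta <- rowSums(dy)
          dxhat <- dy * p$gamma
          m <- ncol(dy)
          dx <- cc$invstd *
            (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
          add_grad(l$inputs[1], dx)
        } else {
          d <- dim(a_in)
          npix <- d[1] * d[2]
          chcols <- rep_len(seq_len(d[3]), d[3] * d[4])
          dym <- matrix(dy, npix, d[3] * d[4])
          dgamma <- rowsum_channels(dym * cc$xhat, chcols, d[3])
          dbeta <- rowsum_channels(dym, chcols, d[3])
          dxhat <- dym * rep(p$gamma[chcols], each = npix)
          cnt <- npix * d[4]
          mean_dxhat <- rowsum_channels(dxhat, chcols, d[3]) / cnt
          mean_dxx <- rowsum_channels(dxhat * cc$xhat, chcols, d[3]) / cnt
          dx <- rep(cc$invstd[chcols], each = npix) *
            (dxhat - rep(mean_dxhat[chcols], each = npix) -
               cc$xhat * rep(mean_dxx[chcols], each = npix))
          dim(dx) <- d
          add_grad(l$inputs[1], dx)
        }
        grads[[nm]] <- list(gamma = dgamma, beta = dbeta)
      },
      relu = {
        dx <- dy
        dx[acts[[nm]] <= 0] <- 0
        add_grad(l$inputs[1], dx)
      },
      avgpool = add_grad(l$inputs[1],
                         pool_backward(dy, dim(a_in), l$hyper$window,
                                       l$hyper$stride, l$hyper$padding)),
      concat = {
        at <- 0L
        for (inp in l$inputs) {
          ch <- dim(acts[[inp]])[3]
          add_grad(inp, dacts[[nm]][, , at + seq_len(ch), , drop = FALSE])
          at <- at + ch
        }
      },
      flatten = {
        dx <- dy
        dim(dx) <- dim(a_in)
        add_grad(l$inputs[1], dx)
      },
      dropout = {
        mask <- cache[[nm]]
        add_grad(l$inputs[1], if (is.null(mask)) dy else dy * mask)
      },
      stop("no backward rule for layer kind: ", l$kind)
    )
    dacts[[nm]] <- NULL  # free
  }
  list(loss = loss, probs = probs, grads = grads)
}

# Sum columns of m grouped by channel id (chcols), returning length-C vector.
rowsum_channels <- function(m, chcols, C) {
  s <- colSums(m)
  as.numeric(rowsum(s, chcols, reorder = TRUE))
}

# Backward of avg_pool (mean over in-bounds pixels, same conventions as
# avg_pool). dy: (Ho, Wo, C, N); returns (H, W, C, N).
pool_backward <- function(dy, in_dim, window, stride, padding) {
  d <- dim(dy)
  dx <- array(0, in_dim)
  if (padding == "same") {
    beg_r <- max((d[1] - 1L) * stride + window - in_dim[1], 0L) %/% 2L
    beg_c <- max((d[2] - 1L) * stride + window - in_dim[2], 0L) %/% 2L
  } else beg_r <- beg_c <- 0L
  for (i in seq_len(d[1])) {
    r0 <- (i - 1L) * stride + 1L - beg_r
    rows <- max(r0, 1L):min(r0 + window - 1L, in_dim[1])
    for (j in seq_len(d[2])) {
      c0 <- (j - 1L) * stride + 1L - beg_c
      cols <- max(c0, 1L):min(c0 + window - 1L, in_dim[2])
      cnt <- length(rows) * length(cols)
      contrib <- c(dy[i, j, , , drop = FALSE]) / cnt  # per (c, n)
      block <- array(rep(contrib, each = cnt), c(length(rows), length(cols),
                                                 d[3], d[4]))
      dx[rows, cols, , ] <- dx[rows, cols, , , drop = FALSE] + block
    }
  }
  dx
}

# One Adam update in place. Returns list(loss, probs).
train_batch <- function(model, x, y, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  fwd <- model_forward(model, x, training = TRUE, keep_acts = TRUE)
  bwd <- model_backward(model, fwd$acts, fwd$cache, y)
  if (!is.finite(bwd$loss)) return(list(loss = bwd$loss, probs = bwd$probs))
  if (is.null(model$opt)) {
    model$opt <- list(t = 0L,
                      m = rapply(model$params, function(p) p * 0, how = "replace"),
                      v = rapply(model$params, function(p) p * 0, how = "replace"))
  }
  opt <- model$opt
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(bwd$grads)) {
    for (pn in names(bwd$grads[[nm]])) {
      g <- bwd$grads[[nm]][[pn]]
      m <- beta1 * opt$m[[nm]][[pn]] + (1 - beta1) * g
      v <- beta2 * opt$v[[nm]][[pn]] + (1 - beta2) * g^2
      opt$m[[nm]][[pn]] <- m
      opt$v[[nm]][[pn]] <- v
      model$params[[nm]][[pn]] <- model$params[[nm]][[pn]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  model$opt <- opt
  list(loss = bwd$loss, probs = bwd$probs)
}

#' Predict class probabilities
#'
#' Runs the model in evaluation mode (batch normalization uses running
#' statistics, dropout is inactive) and applies a softmax to the classifier
#' logits.
#'
#' @param object a `haarnet_model`.
#' @param x an (H, W, C) image or (H, W, C, N) batch matching the model's
#'   input size.
#' @param batch_size samples per forward chunk.
#' @param ... unused.
#' @return N x num_classes matrix of class probabilities (rows sum to 1).
#' @export
predict.haarnet_model <- function(object, x, batch_size = 8L, ...) {
  x <- as_batch(x)
  n <- dim(x)[4]
  k <- object$graph$num_classes
  probs <- matrix(0, n, k)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- model_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(softmax_cols(fwd$logits))
  }
  probs
}

# Deep-copy the trainable/non-trainable state (for best-checkpoint keeping).
model_snapshot <- function(model) {
  list(params = model$params, bn_state = model$bn_state)
}

model_restore <- function(model, snapshot) {
  model$params <- snapshot$params
  model$bn_state <- snapshot$bn_state
  invisible(model)
}
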