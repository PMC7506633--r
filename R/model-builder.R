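#' @useDynLib haarnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_layer <- function(name, kind, inputs = character(), hyper = list()) {
  list(name = name, kind = kind, inputs = inputs, hyper = hyper)
}

# Base (width_multiplier = 1) conv/dense widths of the reference network.
conv_defs <- function() {
  # name, input, base filters, stride
  defs <- rbind(
    c("conv_1",   "wavelet_l1", 64,  1),
    c("conv_1_2", "relu_1",     64,  2),
    c("conv_a",   "wavelet_l2", 128, 1),
    c("conv_2",   "concate_1",  128, 1),
    c("conv_b",   "wavelet_l3", 64,  1),
    c("conv_2_2", "relu_2",     128, 2),
    c("conv_b_2", "relu_b",     128, 1),
    c("conv_c",   "wavelet_l4", 256, 1),
    c("conv_3",   "concate_2",  256, 1),
    c("conv_c_2", "relu_c",     256, 1),
    c("conv_3_2", "relu_3",     256, 2),
    c("conv_c_3", "relu_c_2",   256, 1),
    c("conv_4",   "concate_3",  256, 1),
    c("conv_4_2", "relu_4",     256, 2),
    c("conv_5_1", "relu_4_2",   128, 1)
  )
  data.frame(name = defs[, 1], input = defs[, 2],
             filters = as.integer(defs[, 3]), stride = as.integer(defs[, 4]),
             stringsAsFactors = FALSE)
}

scale_width <- function(base, width_multiplier) {
  scaled <- base * width_multiplier
  rounded <- as.integer(round(scaled))
  if (any(abs(scaled - rounded) > 1e-8))
    warning("width_multiplier ", width_multiplier,
            " produces non-integer channel counts; rounding applied")
  pmax(rounded, 1L)
}

#' Build the spectral-spatial fusion architecture graph
#'
#' Declares the reference wavelet-fusion CNN as a named, topologically
#' ordered layer graph. The spectral branch is a parameter-free 4-level Haar
#' pyramid whose levels 1-4 are consumed by `conv_1`, `conv_a`, `conv_b` and
#' `conv_c`; spatial and spectral feature maps are fused at three
#' concatenation points (`concate_1..3`) at matched resolutions. All
#' convolutions are 3x3 with "same" padding and are followed by batch
#' normalization and ReLU; downsampling on the spatial trunk happens only at
#' the four stride-2 convolutions (`conv_1_2`, `conv_2_2`, `conv_3_2`,
#' `conv_4_2`). The head is avgpool (2x2, stride 1, same), flatten, then two
#' dense-2048 + BN + ReLU + dropout blocks and a final dense classifier.
#'
#' At `width_multiplier = 1`, `num_classes = 4` and input 512x512x3 the graph
#' reproduces the reference layer table exactly (76,289,732 trainable and
#' 13,440 non-trainable parameters).
#'
#' @param num_classes integer >= 2; units of the final dense layer.
#' @param input_size integer vector (H, W, C); H and W must be divisible
#'   by 16 (four dyadic decompositions).
#' @param dropout_rate dropout probability in `[0, 1)` for the two head
#'   dropout layers.
#' @param width_multiplier positive scale on every conv filter count and on
#'   the 2048-unit dense widths (the classifier width is never scaled).
#' @return An object of class `architecture_graph`: list with `layers`
#'   (ordered list of layer specs), `num_classes`, `input_size`,
#'   `width_multiplier`, `dropout_rate`.
#' @examples
#' g <- build_architecture(num_classes = 4)
#' audit_parameters(g)
#' @seealso [audit_parameters()], [forward_shapes()], [instantiate_model()]
#' @export
build_architecture <- function(num_classes = 4L,
                               input_size = c(512L, 512L, 3L),
                               dropout_rate = 0.5,
                               width_multiplier = 1) {
  num_classes <- as.integer(num_classes)
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L) stop("input_size must be (H, W, C)")
  if (any(input_size[1:2] %% 16L != 0L))
    stop("input H and W must be divisible by 16 (got ",
         input_size[1], " x ", input_size[2], ")")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (width_multiplier <= 0) stop("width_multiplier must be > 0")

  cd <- conv_defs()
  cd$filters <- scale_width(cd$filters, width_multiplier)
  fc_units <- scale_width(2048L, width_multiplier)
  conv <- function(name) {
    r <- cd[cd$name == name, ]
    new_layer(name, "conv", r$input,
              list(filters = r$filters, kernel = 3L, stride = r$stride,
                   padding = "same"))
  }
  bn <- function(name, input) new_layer(name, "batchnorm", input)
  relu <- function(name, input) new_layer(name, "relu", input)

  layers <- list(
    new_layer("input", "input"),
    new_layer("wavelet_l1", "wavelet", "input", list(level = 1L)),
    new_layer("wavelet_l2", "wavelet", "input", list(level = 2L)),
    new_layer("wavelet_l3", "wavelet", "input", list(level = 3L)),
    new_layer("wavelet_l4", "wavelet", "input", list(level = 4L)),
    conv("conv_1"), bn("norm_1", "conv_1"), relu("relu_1", "norm_1"),
    conv("conv_1_2"),
    conv("conv_a"),
    bn("norm_1_2", "conv_1_2"), bn("norm_a", "conv_a"),
    relu("relu_1_2", "norm_1_2"), relu("relu_a", "norm_a"),
    new_layer("concate_1", "concat", c("relu_1_2", "relu_a")),
    conv("conv_2"),
    conv("conv_b"),
    bn("norm_2", "conv_2"), bn("norm_b", "conv_b"),
    relu("relu_2", "norm_2"), relu("relu_b", "norm_b"),
    conv("conv_2_2"), conv("conv_b_2"),
    bn("norm_2_2", "conv_2_2"), bn("norm_b_2", "conv_b_2"),
    conv("conv_c"),
    relu("relu_2_2", "norm_2_2"), relu("relu_b_2", "norm_b_2"),
    bn("norm_c", "conv_c"),
    new_layer("concate_2", "concat", c("relu_2_2", "relu_b_2")),
    relu("relu_c", "norm_c"),
    conv("conv_3"), conv("conv_c_2"),
    bn("norm_3", "conv_3"), bn("norm_c_2", "conv_c_2"),
    relu("relu_3", "norm_3"), relu("relu_c_2", "norm_c_2"),
    conv("conv_3_2"), conv("conv_c_3"),
    bn("norm_3_2", "conv_3_2"), bn("norm_c_3", "conv_c_3"),
    relu("relu_3_2", "norm_3_2"), relu("relu_c_3", "norm_c_3"),
    new_layer("concate_3", "concat", c("relu_3_2", "relu_c_3")),
    conv("conv_4"),
    bn("norm_4", "conv_4"),           # between conv_4 and relu_4
    relu("relu_4", "norm_4"),
    conv("conv_4_2"),
    bn("norm_4_2", "conv_4_2"), relu("relu_4_2", "norm_4_2"),
    conv("conv_5_1"),
    bn("norm_5_1", "conv_5_1"), relu("relu_5_1", "norm_5_1"),
    new_layer("pool_5_1", "avgpool", "relu_5_1",
              list(window = 2L, stride = 1L, padding = "same")),
    new_layer("flat_5_1", "flatten", "pool_5_1"),
    new_layer("fc_5", "dense", "flat_5_1", list(units = fc_units)),
    bn("norm_5", "fc_5"), relu("relu_5", "norm_5"),
    new_layer("drop_5", "dropout", "relu_5", list(rate = dropout_rate)),
    new_layer("fc_6", "dense", "drop_5", list(units = fc_units)),
    bn("norm_6", "fc_6"), relu("relu_6", "norm_6"),
    new_layer("drop_6", "dropout", "relu_6", list(rate = dropout_rate)),
    new_layer("fc_7", "dense", "drop_6", list(units = num_classes))
  )
  names(layers) <- vapply(layers, `[[`, "", "name")
  validate_graph_order(layers)
  structure(
    list(layers = layers, num_classes = num_classes, input_size = input_size,
         dropout_rate = dropout_rate, width_multiplier = width_multiplier),
    class = "architecture_graph"
  )
}

validate_graph_order <- function(layers) {
  nm <- names(layers)
  if (anyDuplicated(nm)) stop("duplicate layer name: ", nm[duplicated(nm)][1])
  seen <- character()
  for (l in layers) {
    missing <- setdiff(l$inputs, seen)
    if (length(missing))
      stop("layer ", l$name, " consumes ", missing[1],
           " before it is defined (graph must be topologically ordered)")
    seen <- c(seen, l$name)
  }
  invisible(TRUE)
}

#' @export
print.architecture_graph <- function(x, ...) {
  cat("architecture_graph: ", length(x$layers), " layers, input ",
      paste(x$input_size, collapse = "x"),
      ", classes ", x$num_classes,
      ", width x", x$width_multiplier, "\n", sep = "")
  a <- audit_parameters(x)
  cat("parameters:", format(a$totals$trainable, big.mark = ","), "trainable,",
      format(a$totals$non_trainable, big.mark = ","), "non-trainable\n")
  invisible(x)
}

#' Closed-form shape propagation through an architecture graph
#'
#' Propagates symbolic output shapes layer by layer: a wavelet tap at level
#' `l` maps (H, W, C) to (H/2^l, W/2^l, 4C); convolutions use "same" padding
#' so the spatial size is `ceiling(size / stride)`; concatenation requires
#' matching spatial sizes and sums channels.
#'
#' @param graph an [build_architecture()] result.
#' @return Named list mapping each layer name to its output shape (length-3
#'   integer vector for spatial layers, length-1 for flattened/dense layers).
#' @export
forward_shapes <- function(graph) {
  stopifnot(inherits(graph, "architecture_graph"))
  shapes <- list()
  for (l in graph$layers) {
    ins <- shapes[l$inputs]
    shapes[[l$name]] <- switch(
      l$kind,
      input = graph$input_size,
      wavelet = {
        s <- graph$input_size
        f <- 2L^l$hyper$level
        if (any(s[1:2] %% f != 0L))
          stop("input not divisible by 2^", l$hyper$level)
        c(s[1] %/% f, s[2] %/% f, 4L * s[3])
      },
      conv = {
        s <- ins[[1]]
        c(ceiling(s[1] / l$hyper$stride), ceiling(s[2] / l$hyper$stride),
          l$hyper$filters)
      },
      batchnorm = ins[[1]],
      relu = ins[[1]],
      dropout = ins[[1]],
      avgpool = {
        s <- ins[[1]]
        if (l$hyper$padding == "same") {
          c(ceiling(s[1] / l$hyper$stride), ceiling(s[2] / l$hyper$stride), s[3])
        } else {
          c((s[1] - l$hyper$window) %/% l$hyper$stride + 1L,
            (s[2] - l$hyper$window) %/% l$hyper$stride + 1L, s[3])
        }
      },
      concat = {
        sp <- lapply(ins, function(s) s[1:2])
        if (!all(vapply(sp, identical, TRUE, sp[[1]])))
          stop("concat ", l$name, ": spatial size mismatch between ",
               l$inputs[1], " (", paste(ins[[1]][1:2], collapse = "x"),
               ") and ", l$inputs[2], " (",
               paste(ins[[2]][1:2], collapse = "x"), ")")
        c(ins[[1]][1:2], sum(vapply(ins, function(s) s[3], 1L)))
      },
      flatten = prod(ins[[1]]),
      dense = l$hyper$units,
      stop("unknown layer kind: ", l$kind)
    )
    shapes[[l$name]] <- as.integer(shapes[[l$name]])
  }
  shapes
}

#' Closed-form parameter audit of an architecture graph
#'
#' Counts trainable and non-trainable parameters per layer without
#' instantiating any weights: a 3x3 convolution holds `(9 C_in + 1) C_out`
#' trainable parameters, a dense layer `(N_in + 1) N_out`, and batch
#' normalization `2C` trainable (scale/shift) plus `2C` non-trainable
#' (running mean/variance); every other kind is parameter-free.
#'
#' @inheritParams forward_shapes
#' @return An object of class `parameter_audit`: list with `per_layer` (data
#'   frame: name, kind, trainable, non_trainable) and `totals`.
#' @export
audit_parameters <- function(graph) {
  stopifnot(inherits(graph, "architecture_graph"))
  shapes <- forward_shapes(graph)
  rows <- lapply(graph$layers, function(l) {
    tr <- ntr <- 0
    if (l$kind == "conv") {
      c_in <- shapes[[l$inputs[1]]][3]
      tr <- (9 * c_in + 1) * l$hyper$filters
    } else if (l$kind == "dense") {
      n_in <- prod(shapes[[l$inputs[1]]])
      tr <- (n_in + 1) * l$hyper$units
    } else if (l$kind == "batchnorm") {
      ch <- shapes[[l$inputs[1]]]
      ch <- ch[length(ch)]
      tr <- 2 * ch
      ntr <- 2 * ch
    } else if (!l$kind %in%
               c("input", "wavelet", "relu", "avgpool", "concat", "flatten",
                 "dropout")) {
      stop("cannot audit unknown layer kind: ", l$kind)
    }
    data.frame(name = l$name, kind = l$kind, trainable = tr,
               non_trainable = ntr, stringsAsFactors = FALSE)
  })
  per_layer <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(
    list(per_layer = per_layer,
         totals = list(trainable = sum(per_layer$trainable),
                       non_trainable = sum(per_layer$non_trainable))),
    class = "parameter_audit"
  )
}

#' @export
print.parameter_audit <- function(x, ...) {
  print(x$per_layer)
  cat("totals:", format(x$totals$trainable, big.mark = ","), "trainable,",
      format(x$totals$non_trainable, big.mark = ","), "non-trainable\n")
  invisible(x)
}

#' Average pooling over 2D feature maps
#'
#' Mean over each window position. With `"same"` padding the output spatial
#' size is `ceiling(size / stride)` and window positions that overhang the
#' input average only the in-bounds pixels (padding never contributes to the
#' mean); with `"valid"` only fully contained windows are taken.
#'
#' In `"average"` filter-bank mode the LL subband of [dwt_level()] equals
#' `avg_pool(x, 2, 2, "valid")` exactly: the wavelet front end subsumes the
#' pooling operator while also emitting detail channels.
#'
#' @param x numeric H x W (matrix) or H x W x C array.
#' @param window pooling window side, >= 1.
#' @param stride step between window anchors, >= 1.
#' @param padding `"valid"` or `"same"`.
#' @return Pooled array (H' x W' x C), or matrix if the input was a matrix.
#' @examples
#' avg_pool(matrix(c(1, 3, 2, 4), 2, 2), 2, 2, "valid")  # 2.5
#' @export
avg_pool <- function(x, window = 2L, stride = 2L,
                     padding = c("valid", "same")) {
  padding <- match.arg(padding)
  was_matrix <- is.matrix(x)
  x <- as_image_array(x, "feature_map")
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1L || stride < 1L) stop("window and stride must be >= 1")
  d <- dim(x)
  if (padding == "valid") {
    if (window > d[1] || window > d[2])
      stop("window ", window, " larger than input extent ",
           d[1], " x ", d[2])
    ho <- (d[1] - window) %/% stride + 1L
    wo <- (d[2] - window) %/% stride + 1L
    beg_r <- beg_c <- 0L
  } else {
    ho <- as.integer(ceiling(d[1] / stride))
    wo <- as.integer(ceiling(d[2] / stride))
    beg_r <- max((ho - 1L) * stride + window - d[1], 0L) %/% 2L
    beg_c <- max((wo - 1L) * stride + window - d[2], 0L) %/% 2L
  }
  out <- array(0, c(ho, wo, d[3]))
  for (i in seq_len(ho)) {
    r0 <- (i - 1L) * stride + 1L - beg_r
    rows <- max(r0, 1L):min(r0 + window - 1L, d[1])
    for (j in seq_len(wo)) {
      c0 <- (j - 1L) * stride + 1L - beg_c
      cols <- max(c0, 1L):min(c0 + window - 1L, d[2])
      block <- x[rows, cols, , drop = FALSE]
      out[i, j, ] <- colMeans(matrix(block, length(rows) * length(cols), d[3]))
    }
  }
  if (was_matrix && d[3] == 1L) out <- matrix(out, ho, wo)
  out
}

#' Export an architecture graph as a JSON manifest
#'
#' @inheritParams forward_shapes
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_architecture <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "architecture_graph"))
  manifest <- list(
    input_size = graph$input_size,
    num_classes = graph$num_classes,
    width_multiplier = graph$width_multiplier,
    layers = lapply(unname(graph$layers), function(l)
      list(name = l$name, kind = l$kind, inputs = as.list(l$inputs),
           hyper = l$hyper))
  )
  js <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a parameter audit as CSV
#'
#' Writes one row per layer with its output shape and parameter counts,
#' mirroring the columns of the reference layer table.
#'
#' @param audit a [audit_parameters()] result.
#' @param graph the graph the audit came from (for shapes and connectivity).
#' @param path CSV file to write.
#' @return The data frame written, invisibly.
#' @export
export_audit <- function(audit, graph, path) {
  stopifnot(inherits(audit, "parameter_audit"))
  shapes <- forward_shapes(graph)
  df <- audit$per_layer
  df$output_shape <- vapply(df$name, function(n)
    paste(shapes[[n]], collapse = "x"), "")
  df$connected_to <- vapply(graph$layers[df$name], function(l)
    paste(l$inputs, collapse = ","), "")
  df$parameters <- df$trainable + df$non_trainable
  df <- df[, c("name", "kind", "output_shape", "parameters",
               "trainable", "non_trainable", "connected_to")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
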