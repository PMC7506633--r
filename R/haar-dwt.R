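#' Haar 2x2 filter bank
#'
#' Constructs the four separable 2D Haar analysis kernels (approximation `LL`
#' and the `LH`, `HL`, `HH` details) as 2x2 matrices, under one of three
#' normalization conventions:
#'
#' * `"raw"`: entries in \{-1, +1\}. One decomposition level multiplies the
#'   approximation of a constant image by 4.
#' * `"orthonormal"`: raw kernels scaled by 1/2. The four flattened kernels
#'   are orthonormal, so a single level conserves the sum of squares
#'   (Parseval identity).
#' * `"average"`: as `"orthonormal"` except `w_ll` is rescaled to entries
#'   1/4, making the approximation band exactly equal to 2x2 stride-2
#'   average pooling.
#'
#' @param mode character; one of `"orthonormal"` (default), `"raw"`,
#'   `"average"`.
#' @return An object of class `haar_filter_bank`: a list with 2x2 matrices
#'   `w_ll`, `w_lh`, `w_hl`, `w_hh` and the `mode` string.
#' @examples
#' bank <- haar_filter_bank("raw")
#' bank$w_ll  # all ones
#' @export
haar_filter_bank <- function(mode = c("orthonormal", "raw", "average")) {
  mode <- match.arg(mode)
  w_ll <- matrix(c( 1,  1,
                    1,  1), 2, 2, byrow = TRUE)
  w_lh <- matrix(c(-1, -1,
                    1,  1), 2, 2, byrow = TRUE)
  w_hl <- matrix(c(-1,  1,
                   -1,  1), 2, 2, byrow = TRUE)
  w_hh <- matrix(c( 1, -1,
                   -1,  1), 2, 2, byrow = TRUE)
  scale <- switch(mode, raw = 1, orthonormal = 0.5, average = 0.5)
  bank <- list(
    w_ll = if (mode == "average") w_ll / 4 else w_ll * scale,
    w_lh = w_lh * scale,
    w_hl = w_hl * scale,
    w_hh = w_hh * scale,
    mode = mode
  )
  class(bank) <- "haar_filter_bank"
  bank
}

#' @export
print.haar_filter_bank <- function(x, ...) {
  cat("Haar 2x2 filter bank, mode =", x$mode, "\n")
  for (nm in c("w_ll", "w_lh", "w_hl", "w_hh")) {
    cat(nm, ":\n")
    print(x[[nm]])
  }
  invisible(x)
}

subband_names <- c("LL", "LH", "HL", "HH")

# Promote a matrix to an (H, W, 1) array; validate finiteness.
as_image_array <- function(image, what = "image") {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (!is.array(image) || length(dim(image)) != 3L)
    stop(what, " must be an H x W x C array or an H x W matrix")
  if (any(dim(image) == 0L)) stop(what, " is empty")
  if (!all(is.finite(image))) stop(what, " contains non-finite values")
  image
}

#' Single-level 2D Haar decomposition
#'
#' Applies the four 2x2 Haar kernels as stride-2 valid correlations over
#' non-overlapping 2x2 blocks (top-left anchored), per input channel. This is
#' the wavelet-as-pooling operator: one level halves the spatial resolution
#' and expands each channel into four subband channels.
#'
#' @param image numeric H x W x C array (or H x W matrix); H and W must be
#'   even.
#' @param bank a [haar_filter_bank()].
#' @return An object of class `subband_stack`: list with `data`, an
#'   (H/2) x (W/2) x 4C array whose channels are blocked per input channel in
#'   the fixed order LL, LH, HL, HH; `level`; `mode`; and `channel_order`, a
#'   data frame mapping each output channel to its source channel and
#'   subband.
#' @examples
#' x <- matrix(c(1, 3, 2, 4), 2, 2)  # block [[1,2],[3,4]]
#' dwt_level(x, haar_filter_bank("raw"))$data[1, 1, ]  # 10 4 2 0
#' @seealso [dwt_pyramid()], [subband_energy()]
#' @export
dwt_level <- function(image, bank = haar_filter_bank()) {
  stopifnot(inherits(bank, "haar_filter_bank"))
  image <- as_image_array(image)
  d <- dim(image)
  if (d[1] %% 2L != 0L)
    stop("image height (rows = ", d[1], ") must be even for one Haar level")
  if (d[2] %% 2L != 0L)
    stop("image width (cols = ", d[2], ") must be even for one Haar level")
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L; C <- d[3]

  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  x11 <- image[i1, j1, , drop = FALSE]
  x12 <- image[i1, j2, , drop = FALSE]
  x21 <- image[i2, j1, , drop = FALSE]
  x22 <- image[i2, j2, , drop = FALSE]

  kernels <- list(bank$w_ll, bank$w_lh, bank$w_hl, bank$w_hh)
  out <- array(0, dim = c(h2, w2, 4L * C))
  for (q in 1:4) {
    k <- kernels[[q]]
    sb <- k[1, 1] * x11 + k[1, 2] * x12 + k[2, 1] * x21 + k[2, 2] * x22
    out[, , (seq_len(C) - 1L) * 4L + q] <- sb
  }
  channel_order <- data.frame(
    channel = seq_len(4L * C),
    source_channel = rep(seq_len(C), each = 4L),
    subband = rep(subband_names, C),
    stringsAsFactors = FALSE
  )
  structure(
    list(data = out, level = 1L, mode = bank$mode, channel_order = channel_order),
    class = "subband_stack"
  )
}

# Indices of the LL channels in a 4C subband stack.
ll_channels <- function(n_channels) seq.int(1L, n_channels, 4L)

#' Multilevel Haar wavelet pyramid
#'
#' Repeatedly applies [dwt_level()]: level 1 decomposes the input image, and
#' each further level decomposes the LL (approximation) channels of the level
#' before it, so level `l` has spatial size `input / 2^l` and `4 * C`
#' channels throughout.
#'
#' @inheritParams dwt_level
#' @param levels integer >= 1; both image dimensions must be divisible by
#'   `2^levels`.
#' @return An object of class `wavelet_pyramid`: a list of `subband_stack`s
#'   with `$level` set to 1..`levels`.
#' @examples
#' img <- array(runif(16 * 16 * 3), c(16, 16, 3))
#' p <- dwt_pyramid(img, levels = 3)
#' vapply(p, function(s) dim(s$data)[1], 1)  # 8 4 2
#' @export
dwt_pyramid <- function(image, levels, bank = haar_filter_bank()) {
  image <- as_image_array(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  d <- dim(image)
  feasible <- min(max_dyadic_levels(d[1]), max_dyadic_levels(d[2]))
  if (d[1] %% 2L^levels != 0L || d[2] %% 2L^levels != 0L)
    stop("image of size ", d[1], " x ", d[2], " supports at most ", feasible,
         " decomposition level(s); ", levels, " requested")
  out <- vector("list", levels)
  current <- image
  for (l in seq_len(levels)) {
    stack <- dwt_level(current, bank)
    stack$level <- l
    out[[l]] <- stack
    current <- stack$data[, , ll_channels(dim(stack$data)[3]), drop = FALSE]
  }
  structure(out, class = "wavelet_pyramid")
}

max_dyadic_levels <- function(n) {
  l <- 0L
  while (n %% 2L == 0L && n > 0L) { n <- n %/% 2L; l <- l + 1L }
  l
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("Haar wavelet pyramid,", length(x), "level(s), mode =", x[[1]]$mode, "\n")
  for (s in x) {
    d <- dim(s$data)
    cat("  level", s$level, ":", d[1], "x", d[2], "x", d[3], "\n")
  }
  invisible(x)
}

#' Per-subband energy of a decomposition level
#'
#' Sum of squared coefficients for every subband channel of a
#' `subband_stack`. In orthonormal mode the energies of one level sum to the
#' energy of the signal that was decomposed, which makes subband energy a
#' convenient scale-resolved texture statistic.
#'
#' @param stack a `subband_stack` from [dwt_level()] or one element of a
#'   [dwt_pyramid()].
#' @return Named nonnegative numeric vector, one entry per subband channel
#'   (names like `"ch1.LL"`).
#' @export
subband_energy <- function(stack) {
  if (!inherits(stack, "subband_stack")) stop("stack must be a subband_stack")
  d <- dim(stack$data)
  e <- colSums(matrix(stack$data^2, d[1] * d[2], d[3]))
  names(e) <- paste0("ch", stack$channel_order$source_channel, ".",
                     stack$channel_order$subband)
  e
}
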