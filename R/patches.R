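# Deterministic patching and 8-fold dihedral augmentation with label
# inheritance: the preprocessing applied to every histology image before it
# enters the network.

new_patch <- function(pixels, label, image_id, row_off, col_off,
                      transform_tag = "r0") {
  structure(list(pixels = pixels, label = label,
                 origin = list(image_id = image_id, row = row_off,
                               col = col_off),
                 transform_tag = transform_tag),
            class = "haarnet_patch")
}

patch_set <- function(patches, provenance) {
  structure(list(patches = patches, provenance = provenance),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set with", length(x$patches), "patch(es)\n")
  print(utils::head(x$provenance))
  invisible(x)
}

#' Bilinear image resize
#'
#' Separable bilinear interpolation with edge clamping, used when a source
#' image (or a clipped border window) is smaller than the requested patch
#' side.
#'
#' @param image H x W x C array or H x W matrix.
#' @param out_h,out_w target dimensions.
#' @return Resized array with the input's channel count.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  image <- as_image_array(image)
  d <- dim(image)
  # map output pixel centers onto input pixel centers
  src_r <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  src_c <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  r0 <- pmin(pmax(floor(src_r), 1), d[1]); r1 <- pmin(r0 + 1, d[1])
  c0 <- pmin(pmax(floor(src_c), 1), d[2]); c1 <- pmin(c0 + 1, d[2])
  wr <- pmin(pmax(src_r - r0, 0), 1); wc <- pmin(pmax(src_c - c0, 0), 1)
  Wr <- matrix(wr, out_h, out_w)                     # varies down rows
  Wc <- matrix(rep(wc, each = out_h), out_h, out_w)  # varies across cols
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    x <- image[, , ch]
    top <- x[r0, c0, drop = FALSE] * (1 - Wc) + x[r0, c1, drop = FALSE] * Wc
    bot <- x[r1, c0, drop = FALSE] * (1 - Wc) + x[r1, c1, drop = FALSE] * Wc
    out[, , ch] <- top * (1 - Wr) + bot * Wr
  }
  out
}

patch_anchors <- function(extent, side, stride) {
  if (extent < side) return(NULL)  # whole-axis fallback
  seq.int(0L, extent - side, by = stride)
}

#' Extract overlapping patches from an image
#'
#' Slides a `side` x `side` window over the image with stride
#' `side * (1 - overlap)` (50% overlap by default), keeping anchored full
#' windows only; partial border windows beyond the anchor grid are
#' discarded. If the image is smaller than `side` along an axis, the whole
#' extent of that axis is taken as a single window and the resulting crop is
#' rescaled to `side` x `side` by bilinear interpolation, so small sources
#' (e.g. 700x460 slides against a 512 window) still yield one full-size
#' patch.
#'
#' @param image H x W x C numeric array (or matrix).
#' @param side patch side in pixels (>= 2).
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param image_id identifier recorded in each patch's origin.
#' @param label class label inherited by every patch.
#' @return A `patch_set`: list of patches plus a provenance data frame
#'   (image_id, row_off, col_off, transform_tag, label); offsets are 0-based
#'   multiples of the stride (-1 marks a rescaled whole-axis window).
#' @examples
#' ps <- extract_patches(array(runif(1024 * 1024 * 3), c(1024, 1024, 3)),
#'                       side = 512)
#' nrow(ps$provenance)  # 9 patches at anchors {0, 256, 512}^2
#' @export
extract_patches <- function(image, side = 512L, overlap = 0.5,
                            image_id = "image", label = NA_character_) {
  image <- as_image_array(image)
  side <- as.integer(side)
  if (side < 2L) stop("side must be >= 2")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stride <- as.integer(round(side * (1 - overlap)))
  if (stride < 1L) stop("overlap too large: stride would be < 1 pixel")
  d <- dim(image)
  row_anchors <- patch_anchors(d[1], side, stride)
  col_anchors <- patch_anchors(d[2], side, stride)
  whole_rows <- is.null(row_anchors)
  whole_cols <- is.null(col_anchors)
  if (whole_rows) row_anchors <- 0L
  if (whole_cols) col_anchors <- 0L
  patches <- list()
  for (r in row_anchors) {
    for (cc in col_anchors) {
      rows <- if (whole_rows) seq_len(d[1]) else (r + 1L):(r + side)
      cols <- if (whole_cols) seq_len(d[2]) else (cc + 1L):(cc + side)
      crop <- image[rows, cols, , drop = FALSE]
      if (any(dim(crop)[1:2] != side)) crop <- resize_bilinear(crop, side, side)
      patches[[length(patches) + 1L]] <-
        new_patch(crop, label, image_id,
                  if (whole_rows) -1L else r, if (whole_cols) -1L else cc)
    }
  }
  patch_set(patches, provenance_frame(patches))
}

provenance_frame <- function(patches) {
  data.frame(
    image_id = vapply(patches, function(p) as.character(p$origin$image_id), ""),
    row_off = vapply(patches, function(p) as.integer(p$origin$row), 1L),
    col_off = vapply(patches, function(p) as.integer(p$origin$col), 1L),
    transform_tag = vapply(patches, function(p) p$transform_tag, ""),
    label = vapply(patches, function(p) as.character(p$label), ""),
    stringsAsFactors = FALSE
  )
}

#' Per-channel zero-mean normalization
#'
#' Subtracts each color channel's own mean, so every emitted channel has
#' mean exactly 0. Accepts a patch object or a raw array.
#'
#' @param patch a `haarnet_patch` or an H x W x C array.
#' @return The same type as the input, normalized.
#' @export
normalize_patch <- function(patch) {
  if (inherits(patch, "haarnet_patch")) {
    patch$pixels <- normalize_patch(patch$pixels)
    return(patch)
  }
  x <- as_image_array(patch, "patch")
  d <- dim(x)
  mu <- colMeans(matrix(x, d[1] * d[2], d[3]))
  x - rep(mu, each = d[1] * d[2])
}

rotate90_ccw <- function(x) {
  # (i, j) -> (W + 1 - j, i): column j becomes row W+1-j
  d <- dim(x)
  y <- aperm(x, c(2, 1, 3))
  y[d[2]:1, , , drop = FALSE]
}

mirror_vertical <- function(x) {
  # flip across the horizontal axis: top row <-> bottom row
  x[dim(x)[1]:1, , , drop = FALSE]
}

#' Apply one of the eight dihedral symmetry transforms
#'
#' @param x H x W x C array (square for rotations to preserve shape).
#' @param tag one of `"r0"`, `"r90"`, `"r180"`, `"r270"` (counterclockwise
#'   rotations) optionally suffixed `"m"` (vertical mirror, top row swapped
#'   with bottom row, applied after the rotation).
#' @return Transformed array.
#' @export
dihedral_transform <- function(x, tag) {
  x <- as_image_array(x, "patch")
  mirrored <- grepl("m$", tag)
  rot <- sub("m$", "", tag)
  k <- match(rot, c("r0", "r90", "r180", "r270")) - 1L
  if (is.na(k)) stop("unknown transform tag: ", tag)
  for (i in seq_len(k)) x <- rotate90_ccw(x)
  if (mirrored) x <- mirror_vertical(x)
  x
}

#' All eight transform tags, in emission order
#' @return Character vector of length 8.
#' @export
dihedral_tags <- function() {
  c("r0", "r90", "r180", "r270", "r0m", "r90m", "r180m", "r270m")
}

#' 8-fold rotation/mirror augmentation of a patch
#'
#' Produces the orbit of the patch under the four 90-degree rotations
#' composed with an optional vertical mirror -- the full dihedral symmetry
#' group of the square. Every output inherits the source label; the
#' transform tag is recorded per output in the fixed order
#' `r0, r90, r180, r270, r0m, r90m, r180m, r270m`.
#'
#' @param patch a `haarnet_patch` with square pixels.
#' @return List of 8 `haarnet_patch` objects.
#' @export
augment_patch <- function(patch) {
  stopifnot(inherits(patch, "haarnet_patch"))
  d <- dim(patch$pixels)
  if (d[1] != d[2])
    stop("augmentation requires a square patch, got ", d[1], " x ", d[2])
  lapply(dihedral_tags(), function(tag) {
    out <- patch
    out$pixels <- dihedral_transform(patch$pixels, tag)
    out$transform_tag <- tag
    out
  })
}

#' Full patching + augmentation + normalization pipeline for one image
#'
#' Extracts anchored overlapping patches, optionally expands each into its 8
#' dihedral variants, and normalizes every emitted patch to per-channel zero
#' mean (normalization happens last, so the zero-mean postcondition holds on
#' every output).
#'
#' @inheritParams extract_patches
#' @param augment if `TRUE`, apply [augment_patch()] to every window.
#' @param normalize if `TRUE`, apply [normalize_patch()] to every output.
#' @return A `patch_set`.
#' @export
prepare_patches <- function(image, side = 512L, overlap = 0.5,
                            image_id = "image", label = NA_character_,
                            augment = TRUE, normalize = TRUE) {
  ps <- extract_patches(image, side, overlap, image_id, label)
  patches <- if (augment) {
    do.call(c, lapply(ps$patches, augment_patch))
  } else ps$patches
  if (normalize) patches <- lapply(patches, normalize_patch)
  patch_set(patches, provenance_frame(patches))
}
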