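# Raster I/O and dataset-directory scanning. PNG is read/written through
# the png package; TIFF reading is available when the tiff package is
# installed.

#' Read an RGB raster image
#'
#' Reads PNG or TIFF into an H x W x 3 array in `[0, 1]`: grayscale images
#' are replicated to three channels and an alpha channel is dropped.
#'
#' @param path image file (.png, .tif, .tiff).
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)")
  )
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as PNG
#'
#' Values are clipped to `[0, 1]` before encoding.
#'
#' @param image H x W x C array.
#' @param path output .png path.
#' @export
write_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}

#' Build an image manifest from a class-labelled directory tree
#'
#' Scans `root/<class>/[<magnification>/]image.(png|tif|tiff)` and returns
#' one row per image. A single level of optional magnification
#' subdirectories (e.g. 40X/100X/200X/400X) is recorded when present.
#'
#' @param root dataset root directory.
#' @return Data frame with `image_id`, `class`, `file` and (if present)
#'   `magnification`.
#' @export
dataset_manifest <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- list.dirs(root, recursive = FALSE)
  if (!length(classes)) stop("no class subdirectories under ", root)
  rows <- lapply(classes, function(cd) {
    files <- list.files(cd, pattern = "\\.(png|tif|tiff)$", recursive = TRUE,
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(files)) return(NULL)
    rel <- substring(files, nchar(cd) + 2L)
    mag <- ifelse(dirname(rel) == ".", NA_character_, dirname(rel))
    data.frame(
      image_id = paste0(basename(cd), "/", rel),
      class = basename(cd),
      file = files,
      magnification = mag,
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) stop("no PNG/TIFF images found under ", root)
  if (all(is.na(manifest$magnification))) manifest$magnification <- NULL
  manifest
}

#' Export wavelet pyramid coefficients
#'
#' Writes each level's coefficient tensor as a flat little-endian double
#' binary file (column-major, as stored in R) next to a JSON sidecar
#' recording shape, level, mode and channel order, plus optional per-subband
#' PNG previews rescaled to `[0, 1]`.
#'
#' @param pyramid a [dwt_pyramid()] result.
#' @param prefix output path prefix.
#' @param previews also write per-subband preview PNGs.
#' @return Character vector of files written, invisibly.
#' @export
export_pyramid <- function(pyramid, prefix, previews = FALSE) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  written <- character()
  for (s in pyramid) {
    base <- sprintf("%s_level%d", prefix, s$level)
    bin <- paste0(base, ".bin")
    con <- file(bin, "wb")
    writeBin(as.numeric(s$data), con, size = 8, endian = "little")
    close(con)
    sidecar <- paste0(base, ".json")
    jsonlite::write_json(list(shape = dim(s$data), level = s$level,
                              mode = s$mode, channel_order = s$channel_order,
                              storage = "float64 little-endian column-major"),
                         sidecar, auto_unbox = TRUE, digits = NA)
    written <- c(written, bin, sidecar)
    if (previews) {
      for (k in seq_len(dim(s$data)[3])) {
        sb <- s$data[, , k]
        rng <- range(sb)
        sb <- if (diff(rng) > 0) (sb - rng[1]) / diff(rng) else sb * 0
        f <- sprintf("%s_%s_ch%d.png", base, s$channel_order$subband[k],
                     s$channel_order$source_channel[k])
        png::writePNG(sb, f)
        written <- c(written, f)
      }
    }
  }
  invisible(written)
}
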