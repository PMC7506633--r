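# Seeded generator of class-separable histology-like RGB images. The
# fixtures emulate only the statistical hooks the classifier exploits --
# class-dependent nucleus-like spot density, periodic texture frequency and
# color mixture -- not histological appearance.

#' Texture class specification for synthetic images
#'
#' @param class_name class identifier.
#' @param spot_density expected nucleus-like spots per 10^4 pixels.
#' @param spot_radius length-2 vector (mean, sd) of spot radius in pixels.
#' @param base_color RGB triple in `[0, 1]` (background stain color).
#' @param texture_freq periodic texture frequency in cycles per 100 pixels.
#' @param texture_amp amplitude of the periodic texture (intensity units).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return An object of class `texture_class_spec`.
#' @export
texture_class_spec <- function(class_name, spot_density = 15,
                               spot_radius = c(5, 1),
                               base_color = c(0.85, 0.7, 0.82),
                               texture_freq = 4, texture_amp = 0.1,
                               noise_sd = 0.02) {
  stopifnot(length(spot_radius) == 2, length(base_color) == 3)
  if (spot_density < 0 || spot_radius[1] <= 0 || texture_freq <= 0 ||
      texture_amp < 0 || noise_sd < 0)
    stop("densities, radii, frequencies must be positive; amplitudes nonnegative")
  if (any(base_color < 0 | base_color > 1))
    stop("base_color must lie in [0, 1]")
  structure(list(class_name = as.character(class_name),
                 spot_density = spot_density, spot_radius = spot_radius,
                 base_color = base_color, texture_freq = texture_freq,
                 texture_amp = texture_amp, noise_sd = noise_sd),
            class = "texture_class_spec")
}

# Relative per-channel absorption of the dark spots (nuclei stain darker and
# bluer than the background).
SPOT_CHANNEL_WEIGHT <- c(0.6, 0.7, 0.35)

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic histology-like image
#'
#' Composes, in order: a constant base color field; an oriented sinusoidal
#' texture (random orientation and phase) of the spec's frequency and
#' amplitude; Poisson-placed Gaussian "nucleus" spots that darken the image
#' with a blue-shifted absorption profile; and i.i.d. Gaussian noise. The
#' result is clipped to `[0, 1]`. Identical `spec`, `size` and `seed`
#' reproduce the image bit for bit, and the caller's RNG state is left
#' untouched.
#'
#' @param spec a [texture_class_spec()].
#' @param size length-2 integer (H, W), each >= 32.
#' @param seed integer seed.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
generate_image <- function(spec, size = c(256L, 256L), seed = 1L) {
  stopifnot(inherits(spec, "texture_class_spec"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop("size must be (H, W) with both sides >= 32")
  h <- size[1]; w <- size[2]
  with_local_seed(seed, {
    img <- array(rep(spec$base_color, each = h * w), c(h, w, 3L))

    # oriented periodic texture
    theta <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    rowc <- matrix(seq_len(h), h, w)
    colc <- matrix(seq_len(w), h, w, byrow = TRUE)
    tex <- spec$texture_amp *
      sin(2 * pi * spec$texture_freq / 100 *
            (rowc * cos(theta) + colc * sin(theta)) + phase)
    img <- img + array(rep(tex, 3L), c(h, w, 3L))

    # nucleus-like dark spots
    n_spots <- stats::rpois(1, spec$spot_density * h * w / 1e4)
    if (n_spots > 0) {
      cy <- stats::runif(n_spots, 1, h)
      cx <- stats::runif(n_spots, 1, w)
      rad <- pmax(stats::rnorm(n_spots, spec$spot_radius[1],
                               spec$spot_radius[2]), 0.5)
      depth <- stats::runif(n_spots, 0.35, 0.6)
      for (s in seq_len(n_spots)) {
        ext <- ceiling(3 * rad[s])
        rows <- max(1, floor(cy[s] - ext)):min(h, ceiling(cy[s] + ext))
        cols <- max(1, floor(cx[s] - ext)):min(w, ceiling(cx[s] + ext))
        d2 <- outer((rows - cy[s])^2, (cols - cx[s])^2, "+")
        bump <- depth[s] * exp(-d2 / (2 * rad[s]^2))
        for (ch in 1:3)
          img[rows, cols, ch] <- img[rows, cols, ch] -
            SPOT_CHANNEL_WEIGHT[ch] * bump
      }
    }

    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(h * w * 3L, 0, spec$noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
    img
  })
}

#' Built-in texture classes
#'
#' Two (benign-like vs malignant-like) or four (normal / benign / in-situ /
#' invasive -like) fixture classes. Classes are separated jointly by spot
#' density and texture frequency -- multi-scale statistics that survive
#' per-channel mean subtraction -- while base colors differ only mildly.
#'
#' @param n_classes 2 or 4.
#' @return Named list of [texture_class_spec()]s.
#' @export
default_texture_classes <- function(n_classes = 2L) {
  specs <- list(
    texture_class_spec("classA", spot_density = 8, spot_radius = c(6, 1),
                       base_color = c(0.88, 0.74, 0.84), texture_freq = 2,
                       texture_amp = 0.12, noise_sd = 0.02),
    texture_class_spec("classB", spot_density = 30, spot_radius = c(4, 0.8),
                       base_color = c(0.80, 0.62, 0.78), texture_freq = 8,
                       texture_amp = 0.12, noise_sd = 0.02),
    texture_class_spec("classC", spot_density = 16, spot_radius = c(5, 1),
                       base_color = c(0.84, 0.68, 0.80), texture_freq = 4,
                       texture_amp = 0.12, noise_sd = 0.02),
    texture_class_spec("classD", spot_density = 45, spot_radius = c(3, 0.6),
                       base_color = c(0.76, 0.58, 0.76), texture_freq = 16,
                       texture_amp = 0.12, noise_sd = 0.02)
  )
  if (!n_classes %in% c(2L, 4L)) stop("n_classes must be 2 or 4")
  specs <- specs[seq_len(n_classes)]
  names(specs) <- vapply(specs, `[[`, "", "class_name")
  specs
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` images per class with per-image child seeds derived
#' deterministically from the master seed. Images are returned in memory
#' (list column) or written as PNGs under `dir/<class>/` when `dir` is
#' given.
#'
#' @param class_specs list of [texture_class_spec()]s with distinct names.
#' @param n_per_class images per class.
#' @param size length-2 (H, W).
#' @param seed master seed.
#' @param dir optional output directory; created if missing.
#' @return A manifest data frame with columns `image_id`, `class`, `seed`
#'   and either `file` (paths) or `image` (list of arrays), plus attribute
#'   `"size"`.
#' @export
generate_dataset <- function(class_specs, n_per_class, size = c(256L, 256L),
                             seed = 1L, dir = NULL) {
  if (length(class_specs) < 2L) stop("need at least 2 classes")
  cls_names <- vapply(class_specs, `[[`, "", "class_name")
  if (anyDuplicated(cls_names))
    stop("duplicate class name: ", cls_names[duplicated(cls_names)][1])
  n_total <- length(class_specs) * n_per_class
  child_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                  n_total))
  manifest <- data.frame(
    image_id = sprintf("%s_%03d", rep(cls_names, each = n_per_class),
                       rep(seq_len(n_per_class), length(class_specs))),
    class = rep(cls_names, each = n_per_class),
    seed = child_seeds,
    stringsAsFactors = FALSE
  )
  images <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    images[[i]] <- generate_image(
      class_specs[[match(manifest$class[i], cls_names)]], size,
      manifest$seed[i])
  }
  if (is.null(dir)) {
    manifest$image <- images
  } else {
    files <- character(n_total)
    for (i in seq_len(n_total)) {
      cls_dir <- file.path(dir, manifest$class[i])
      dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
      files[i] <- file.path(cls_dir, paste0(manifest$image_id[i], ".png"))
      png::writePNG(images[[i]], files[i])
    }
    manifest$file <- files
  }
  attr(manifest, "size") <- size
  manifest
}
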