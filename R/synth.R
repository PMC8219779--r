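#' Configuration for the synthetic radiograph generator
#'
#' Builds the parameter set for [generate_dataset()]. The generator emulates
#' expert-marked radiographs: a structured grayscale background with inserted
#' elliptical lesion regions whose mean intensity differs from the background
#' they replace, paired with an exact binary mask (1 = lesion).
#'
#' All randomness flows from `seed`: image `i` is drawn from a stream seeded
#' with `seed + i`, so identical configurations yield byte-identical datasets
#' and individual images are reproducible in isolation.
#'
#' @param n_images number of images to generate.
#' @param image_size pixels per side of the square image (>= 7).
#' @param lesion_probability fraction of images containing at least one
#'   lesion, in `[0, 1]`. Default 1: every image in the study carries a
#'   lesion, as in a curated positive series.
#' @param lesion_count_range integer `c(min, max)` lesions per positive image.
#' @param lesion_axis_range ellipse semi-axis range in pixels; default
#'   `NULL` means 10%--24% of `image_size`.
#' @param intensity_shift additive lesion contrast in gray levels (signed),
#'   applied to lesion pixels before noise.
#' @param background_kind `"blobs"` (vertical gradient plus smooth Gaussian
#'   blobs, the default), `"gradient"` (vertical gradient only) or `"flat"`
#'   (constant 128, useful for oracle tests).
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise in gray
#'   levels; the final image is rounded and clipped to `[0, 255]`.
#' @param seed integer master seed.
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()], [split_train_test()], [write_fixture_set()]
#' @export
synth_config <- function(n_images,
                         image_size = 512L,
                         lesion_probability = 1,
                         lesion_count_range = c(1L, 2L),
                         lesion_axis_range = NULL,
                         intensity_shift = 80,
                         background_kind = c("blobs", "gradient", "flat"),
                         noise_sd = 8,
                         seed = 1L) {
  background_kind <- match.arg(background_kind)
  if (length(n_images) != 1L || !is.finite(n_images) || n_images < 1)
    stop("'n_images' must be a positive integer")
  if (length(image_size) != 1L || !is.finite(image_size) || image_size < 7)
    stop("'image_size' must be an integer >= 7")
  if (lesion_probability < 0 || lesion_probability > 1)
    stop("'lesion_probability' must be in [0, 1]")
  if (is.null(lesion_axis_range))
    lesion_axis_range <- c(max(1, round(0.10 * image_size)),
                           max(1, round(0.24 * image_size)))
  if (any(lesion_axis_range < 1) || lesion_axis_range[1] > lesion_axis_range[2])
    stop("'lesion_axis_range' must be an ordered pair of pixels >= 1")
  if (lesion_count_range[1] < 1 || lesion_count_range[1] > lesion_count_range[2])
    stop("'lesion_count_range' must be an ordered pair of integers >= 1")
  structure(list(
    n_images = as.integer(n_images),
    image_size = as.integer(image_size),
    lesion_probability = lesion_probability,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_axis_range = lesion_axis_range,
    intensity_shift = intensity_shift,
    background_kind = background_kind,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic radiograph configuration\n")
  cat(sprintf("  %d images of %dx%d, background '%s'\n",
              x$n_images, x$image_size, x$image_size, x$background_kind))
  cat(sprintf("  lesion probability %.2f, %d-%d lesions, semi-axes %g-%g px\n",
              x$lesion_probability, x$lesion_count_range[1],
              x$lesion_count_range[2], x$lesion_axis_range[1],
              x$lesion_axis_range[2]))
  cat(sprintf("  contrast %+g gray levels, noise sd %g, seed %d\n",
              x$intensity_shift, x$noise_sd, x$seed))
  invisible(x)
}

# Background field before noise, as a double matrix in gray levels.
# Consumes the current RNG stream (blob placement only).
synth_background <- function(size, kind) {
  switch(kind,
    flat = matrix(128, size, size),
    gradient = matrix(rep(seq(60, 190, length.out = size), each = size),
                      size, size, byrow = FALSE),
    blobs = {
      bg <- matrix(rep(seq(60, 190, length.out = size), each = size),
                   size, size, byrow = FALSE)
      n_blob <- sample(4:8, 1L)
      rows <- seq_len(size)
      for (b in seq_len(n_blob)) {
        cr <- runif(1, 1, size); cc <- runif(1, 1, size)
        sd_b <- runif(1, 0.06, 0.15) * size
        amp <- runif(1, -15, 15)
        bg <- bg + amp * outer(exp(-((rows - cr)^2) / (2 * sd_b^2)),
                               exp(-((rows - cc)^2) / (2 * sd_b^2)))
      }
      bg
    },
    stop("unknown background kind: ", kind))
}

# Filled axis-aligned ellipse as a logical matrix (exact rasterization:
# a pixel belongs to the lesion iff its center satisfies the ellipse
# inequality). Row 0 = top, column 0 = left, but R matrices are 1-based;
# centers are in 1-based pixel coordinates.
ellipse_mask <- function(size, center_row, center_col, semi_row, semi_col) {
  rows <- seq_len(size)
  dr2 <- ((rows - center_row) / semi_row)^2
  dc2 <- ((rows - center_col) / semi_col)^2
  outer(dr2, dc2, `+`) <= 1
}

#' Generate a seeded synthetic dataset of images and lesion masks
#'
#' Produces `config$n_images` labeled images. A positive image's mask is the
#' exact union of the rendered lesion ellipses; negative images carry an
#' all-zero mask. Lesion pixels differ from the background they replace by
#' `intensity_shift` gray levels before noise is added.
#'
#' @param config a [synth_config()] object.
#' @return a list of labeled images, each a list with elements `pixels`
#'   (integer matrix in `[0, 255]`), `mask` (integer 0/1 matrix of identical
#'   dimensions) and `id` (string). Class `labeled_dataset`.
#' @examples
#' ds <- generate_dataset(synth_config(n_images = 2, image_size = 64, seed = 7))
#' dim(ds[[1]]$pixels)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  size <- config$image_size
  out <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    set.seed(config$seed + i)
    positive <- runif(1) < config$lesion_probability
    bg <- synth_background(size, config$background_kind)
    mask <- matrix(0L, size, size)
    if (positive) {
      n_les <- sample(seq(config$lesion_count_range[1],
                          config$lesion_count_range[2]), 1L)
      for (l in seq_len(n_les)) {
        amax <- min(config$lesion_axis_range[2], (size - 3) / 2)
        a <- runif(1, min(config$lesion_axis_range[1], amax), amax)
        b <- runif(1, min(config$lesion_axis_range[1], amax), amax)
        cr <- runif(1, 1 + a, size - a)
        cc <- runif(1, 1 + b, size - b)
        mask[ellipse_mask(size, cr, cc, a, b)] <- 1L
      }
    }
    px <- bg + config$intensity_shift * mask
    if (config$noise_sd > 0)
      px <- px + rnorm(size * size, sd = config$noise_sd)
    px <- matrix(as.integer(pmin(255, pmax(0, round(px)))), size, size)
    out[[i]] <- list(pixels = px, mask = mask,
                     id = sprintf("img_%04d", i))
  }
  structure(out, class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  npos <- sum(vapply(x, function(im) any(im$mask != 0L), logical(1)))
  side <- if (length(x)) nrow(x[[1]]$pixels) else NA_integer_
  cat(sprintf("Labeled image dataset: %d images (%d positive), %dx%d pixels\n",
              length(x), npos, side, side))
  invisible(x)
}

#' Split a dataset into training and test sets
#'
#' Seeded random partition: `round(n * train_fraction)` items go to the
#' training set, the remainder to the test set (e.g. 1000 images at fraction
#' 0.8 give the 800/200 study split).
#'
#' @param dataset a list of labeled images (see [generate_dataset()]).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
split_train_test <- function(dataset, train_fraction, seed = 1L) {
  n <- length(dataset)
  if (n == 0L) stop("cannot split an empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be strictly between 0 and 1")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(n * train_fraction)
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[setdiff(seq_len(n), seq_len(n_train))])
  list(train = structure(dataset[idx_train], class = "labeled_dataset"),
       test = structure(dataset[idx_test], class = "labeled_dataset"))
}

#' Write a dataset to disk as PNG files plus a manifest
#'
#' Writes one 8-bit grayscale PNG per image and per mask (mask pixels are 0 or
#' 255) and a manifest CSV with header `id,image,mask,is_positive`.
#'
#' @param dataset a `labeled_dataset`.
#' @param directory output directory (created if missing).
#' @return path of the written manifest CSV, invisibly.
#' @export
write_fixture_set <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  rows <- lapply(dataset, function(im) {
    img_path <- file.path(directory, paste0(im$id, ".png"))
    mask_path <- file.path(directory, paste0(im$id, "_mask.png"))
    png::writePNG(im$pixels / 255, img_path)
    png::writePNG(im$mask * 1.0, mask_path)
    data.frame(id = im$id, image = img_path, mask = mask_path,
               is_positive = as.integer(any(im$mask != 0L)))
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Read a dataset written by [write_fixture_set()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `labeled_dataset`.
#' @export
read_fixture_set <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  out <- lapply(seq_len(nrow(man)), function(i) {
    px <- round(png::readPNG(resolve(man$image[i])) * 255)
    mk <- round(png::readPNG(resolve(man$mask[i])) * 255)
    list(pixels = matrix(as.integer(px), nrow(px), ncol(px)),
         mask = matrix(as.integer(mk > 127), nrow(mk), ncol(mk)),
         id = man$id[i])
  })
  structure(out, class = "labeled_dataset")
}
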