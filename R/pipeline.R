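#' Preprocessing configuration for the dataset pipeline
#'
#' Controls patch cropping, resizing, normalization and augmentation of
#' training samples. Defaults follow the training protocol for full-size
#' field images: patches cropped with side lengths between 150 and 600
#' pixels, resized to 256 x 256 and normalized to [0, 1].
#'
#' @param target_size output side length in pixels after resizing (>= 32).
#' @param crop_min,crop_max bounds on patch side lengths in pixels; height
#'   and width are sampled independently, so rectangular patches are allowed.
#' @param augmentations character subset of \code{c("hflip", "vflip",
#'   "rot90", "hist_eq", "brightness")}; each is applied independently with
#'   probability 0.5 at augmentation time.
#' @param brightness_range multiplicative brightness factor range for the
#'   \code{"brightness"} augmentation (clipped to [0, 255]).
#' @param seed integer seed used by \code{\link{crop_patches}}.
#' @return an object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(target_size = 256L, crop_min = 150L,
                              crop_max = 600L,
                              augmentations = c("hflip", "vflip", "rot90",
                                                "hist_eq", "brightness"),
                              brightness_range = c(0.7, 1.3), seed = 1L) {
  if (crop_min > crop_max)
    stop("preprocess_config: crop_min must be <= crop_max", call. = FALSE)
  if (target_size < 32L)
    stop("preprocess_config: target_size must be >= 32", call. = FALSE)
  bad <- setdiff(augmentations,
                 c("hflip", "vflip", "rot90", "hist_eq", "brightness"))
  if (length(bad))
    stop("preprocess_config: unknown augmentations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(target_size = as.integer(target_size),
                 crop_min = as.integer(crop_min),
                 crop_max = as.integer(crop_max),
                 augmentations = augmentations,
                 brightness_range = brightness_range,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Read and write 8-bit RGB images and class masks as PNG
#'
#' Images are stored as standard 8-bit RGB PNG. Masks are single-channel
#' 8-bit PNG whose pixel values are the raw labels 0/1/2 (they look almost
#' black in a viewer; use \code{\link{mask_overlay}} for visualization).
#' Crop boxes and pixel coordinates throughout the package are 0-based and
#' half-open.
#'
#' @param path file path.
#' @param pixels H x W x 3 integer array in 0..255.
#' @param mask H x W integer matrix with values 0/1/2.
#' @return \code{read_image_png}: H x W x 3 integer array;
#'   \code{read_mask_png}: H x W integer matrix. Writers return the path,
#'   invisibly.
#' @name png_io
NULL

#' @rdname png_io
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' @rdname png_io
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  if (!all(m %in% 0:2))
    stop("mask PNG contains labels outside {0, 1, 2}", call. = FALSE)
  m
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Crop random patches from an image/mask pair
#'
#' Patch side lengths are drawn uniformly (independently for height and
#' width) in \code{[crop_min, min(crop_max, image dim)]} and positioned
#' uniformly inside the image; image and mask are cropped with the same box.
#'
#' @param image H x W x 3 integer array.
#' @param mask H x W integer matrix with labels 0/1/2, or \code{NULL}.
#' @param config a \code{\link{preprocess_config}}; its \code{seed} seeds
#'   the draw, so fixed seeds give identical crop boxes.
#' @param n_patches number of patches (>= 1).
#' @param source_id id string recorded in each sample.
#' @return list of samples; each sample is a list with \code{image},
#'   \code{mask}, \code{source_id} and \code{crop_box} (row0, col0, height,
#'   width; 0-based, half-open).
#' @export
crop_patches <- function(image, mask = NULL, config, n_patches,
                         source_id = "source") {
  stopifnot(inherits(config, "preprocess_config"))
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < config$crop_min || W < config$crop_min)
    stop("image smaller than crop_min in at least one dimension",
         call. = FALSE)
  if (n_patches < 1) stop("n_patches must be >= 1", call. = FALSE)
  if (!is.null(mask) && !all(dim(mask) == c(H, W)))
    stop("mask dimensions must match the image", call. = FALSE)
  set.seed(config$seed)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  out <- vector("list", n_patches)
  for (p in seq_len(n_patches)) {
    ph <- pick(config$crop_min, min(config$crop_max, H))
    pw <- pick(config$crop_min, min(config$crop_max, W))
    r0 <- pick(0L, H - ph)
    c0 <- pick(0L, W - pw)
    rows <- (r0 + 1):(r0 + ph); cols <- (c0 + 1):(c0 + pw)
    out[[p]] <- list(
      image = image[rows, cols, , drop = FALSE],
      mask = if (!is.null(mask)) mask[rows, cols, drop = FALSE],
      source_id = source_id,
      crop_box = c(row0 = r0, col0 = c0, height = ph, width = pw)
    )
  }
  out
}

## nearest-neighbor resize of a label matrix (labels stay categorical)
resize_mask_nearest <- function(mask, Ho, Wo) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(H, pmax(1, floor((seq_len(Ho) - 0.5) * H / Ho) + 1L))
  ci <- pmin(W, pmax(1, floor((seq_len(Wo) - 0.5) * W / Wo) + 1L))
  mask[ri, ci, drop = FALSE]
}

## bilinear resize of an H x W x C numeric array
resize_bilinear <- function(x, Ho, Wo) {
  d <- dim(x)
  .cpp_resize_bilinear(as.double(x), d[1], d[2], d[3],
                       as.integer(Ho), as.integer(Wo))
}

#' Convert a sample to model-ready form
#'
#' Resizes the image to \code{target_size} x \code{target_size} with
#' bilinear interpolation, divides intensities by 255 into [0, 1], and
#' resizes the mask (when present) with nearest-neighbor interpolation so
#' labels remain in \{0, 1, 2\}.
#'
#' @param sample a sample as produced by \code{\link{crop_patches}} (any
#'   list with \code{image} and optionally \code{mask} works).
#' @param config a \code{\link{preprocess_config}}.
#' @return list with \code{x} (target x target x 3 double array in [0, 1]),
#'   \code{mask} (target x target integer matrix or \code{NULL}) and
#'   \code{source_id}.
#' @export
preprocess_sample <- function(sample, config) {
  stopifnot(inherits(config, "preprocess_config"))
  if (!is.null(sample$mask) && !all(sample$mask %in% 0:2))
    stop("mask contains labels outside {0, 1, 2}", call. = FALSE)
  ts <- config$target_size
  x <- resize_bilinear(sample$image, ts, ts) / 255
  m <- if (!is.null(sample$mask)) resize_mask_nearest(sample$mask, ts, ts)
  list(x = x, mask = m, source_id = sample$source_id)
}

## histogram equalization on the value channel of HSV, preserving hue;
## image is an H x W x 3 integer array in 0..255
equalize_value_channel <- function(image) {
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  v8 <- as.integer(round(hsv[3, ] * 255))
  cdf <- cumsum(tabulate(v8 + 1L, nbins = 256L))
  cdf_min <- cdf[which(cdf > 0)[1]]
  v_new <- if (cdf[256] > cdf_min) {
    lut <- round((cdf - cdf_min) / (cdf[256] - cdf_min) * 255)
    pmin(255, pmax(0, lut[v8 + 1L])) / 255
  } else hsv[3, ] # constant-value image: equalization is the identity
  ## numeric HSV -> RGB (avoids string color round-trips)
  h6 <- hsv[1, ] * 6
  s <- hsv[2, ]
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v_new * (1 - s)
  q <- v_new * (1 - s * f)
  t <- v_new * (1 - s * (1 - f))
  r <- ifelse(i == 0, v_new, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v_new)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v_new, ifelse(i == 2, v_new,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v_new, ifelse(i == 4, v_new, q)))))
  array(as.integer(round(c(r, g, b) * 255)), dim = d)
}

## rotate an H x W x C array (or H x W matrix) counter-clockwise by k*90 deg
rot90_array <- function(x, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(x)
  is_mat <- is.matrix(x)
  if (is_mat) x <- array(x, dim = c(dim(x), 1))
  for (n in seq_len(k)) {
    d <- dim(x)
    ## counter-clockwise: new[i, j] = old[j, W + 1 - i]
    x <- aperm(x, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  if (is_mat) x[, , 1] else x
}

#' Augment a training sample
#'
#' Each augmentation listed in the configuration is applied independently
#' with probability 0.5 (identity when every draw declines). Geometric
#' transforms (horizontal/vertical flip, rotation by a random multiple of
#' 90 degrees) are applied identically to image and mask, so per-class pixel
#' counts are preserved; photometric transforms (histogram equalization on
#' the HSV value channel, multiplicative brightness with clipping to
#' [0, 255]) touch the image only. Equalization is applied before
#' brightness. Randomness comes from the current RNG state; seed the
#' session (or use \code{force}) for reproducibility.
#'
#' @param sample list with \code{image} (H x W x 3 integer array) and
#'   \code{mask} (H x W integer matrix); a mask is required since
#'   augmentation is a training-time operation.
#' @param config a \code{\link{preprocess_config}}.
#' @param force optional character vector of augmentation names to apply
#'   unconditionally (probability draws are skipped; \code{rot90} then uses
#'   a single 90-degree turn and \code{brightness} the upper range bound);
#'   used for deterministic testing.
#' @return the augmented sample (same structure as the input).
#' @export
augment_sample <- function(sample, config, force = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  if (is.null(sample$mask))
    stop("augment_sample: sample must carry a mask", call. = FALSE)
  img <- sample$image
  mask <- sample$mask
  want <- function(a) {
    if (!is.null(force)) return(a %in% force)
    a %in% config$augmentations && stats::runif(1) < 0.5
  }
  if (want("hflip")) {
    img <- img[, dim(img)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (want("vflip")) {
    img <- img[dim(img)[1]:1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  if (want("rot90")) {
    k <- if (!is.null(force)) 1L else sample(1:3, 1)
    img <- rot90_array(img, k)
    mask <- rot90_array(mask, k)
  }
  if (want("hist_eq")) img <- equalize_value_channel(img)
  if (want("brightness")) {
    f <- if (!is.null(force)) config$brightness_range[2]
         else .runif1(config$brightness_range)
    img <- array(as.integer(pmin(255, pmax(0, round(img * f)))), dim = dim(img))
  }
  list(image = img, mask = mask, source_id = sample$source_id)
}
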