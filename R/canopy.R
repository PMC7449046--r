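#' Scene configuration for the synthetic canopy generator
#'
#' Describes one procedural rice-canopy scene: canvas size, grain-filling
#' stage (which fixes the default class colors), organ counts and geometry,
#' illumination perturbations and the random seed. The generator renders
#' leaves as curved tapered blades (quadratic Bezier spines with a width
#' profile) and panicles as clusters of overlapping small ellipses
#' ("grains"), on a low-frequency soil/water mottle background, and returns
#' the exact 3-class ground-truth mask alongside the image.
#'
#' Stages follow the grain-filling color regimes: \code{"GG"} green panicle
#' with green leaf (early), \code{"YG"} yellow panicle with green leaf
#' (middle), \code{"YY"} yellow panicle with yellow leaf (late).
#'
#' @param height,width canvas size in pixels (>= 32).
#' @param stage one of \code{"GG"}, \code{"YG"}, \code{"YY"}.
#' @param n_leaves,n_panicles integer ranges \code{c(min, max)} for the
#'   number of organs drawn.
#' @param leaf_length range of blade length as a fraction of
#'   \code{min(height, width)}.
#' @param leaf_width range of blade base width in pixels.
#' @param leaf_curvature range of the perpendicular offset of the Bezier
#'   control point, as a fraction of blade length (dimensionless).
#' @param grain_count range of grains per panicle cluster.
#' @param grain_radius range of grain semi-axis in pixels.
#' @param panicle_extent range of panicle axis length in pixels.
#' @param color_model optional list overriding the stage defaults; see
#'   \code{\link{stage_colors}} for the structure (per-class mean RGB in
#'   8-bit units plus a per-channel spread).
#' @param brightness_range multiplicative global brightness range applied to
#'   the image only.
#' @param shadow_fraction approximate fraction of pixels covered by cast
#'   shadows (elliptical multiplicative darkening of the image only).
#' @param shadow_factor range of the multiplicative darkening inside shadows.
#' @param mottle_amplitude amplitude (8-bit units) of the low-frequency
#'   background mottle.
#' @param panicles_on_top if \code{TRUE} (default) panicles are drawn after
#'   leaves and occlude them, as panicles overtop the canopy during grain
#'   filling.
#' @param seed integer seed; identical configurations and seeds produce
#'   bit-identical scenes.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(height = 128, width = 128, stage = c("YG", "GG", "YY"),
                         n_leaves = c(9L, 16L), n_panicles = c(3L, 7L),
                         leaf_length = c(0.4, 0.9), leaf_width = c(4, 8),
                         leaf_curvature = c(-0.25, 0.25),
                         grain_count = c(25L, 60L), grain_radius = c(1.5, 3.5),
                         panicle_extent = c(15, 30),
                         color_model = NULL,
                         brightness_range = c(0.85, 1.15),
                         shadow_fraction = 0.15, shadow_factor = c(0.4, 0.7),
                         mottle_amplitude = 18,
                         panicles_on_top = TRUE, seed = 1L) {
  stage <- match.arg(stage)
  cfg <- list(
    height = as.integer(height), width = as.integer(width), stage = stage,
    n_leaves = as.integer(rep(n_leaves, length.out = 2)),
    n_panicles = as.integer(rep(n_panicles, length.out = 2)),
    leaf_length = leaf_length, leaf_width = leaf_width,
    leaf_curvature = leaf_curvature,
    grain_count = as.integer(rep(grain_count, length.out = 2)),
    grain_radius = grain_radius, panicle_extent = panicle_extent,
    color_model = if (is.null(color_model)) stage_colors(stage) else color_model,
    brightness_range = brightness_range,
    shadow_fraction = shadow_fraction, shadow_factor = shadow_factor,
    mottle_amplitude = mottle_amplitude,
    panicles_on_top = isTRUE(panicles_on_top), seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$height < 32L || cfg$width < 32L)
    stop("scene_config: canvas must be at least 32x32 pixels", call. = FALSE)
  if (cfg$shadow_fraction < 0 || cfg$shadow_fraction > 1)
    stop("scene_config: shadow_fraction must lie in [0, 1]", call. = FALSE)
  for (nm in c("n_leaves", "n_panicles", "grain_count"))
    if (any(cfg[[nm]] < 0) || cfg[[nm]][1] > cfg[[nm]][2])
      stop("scene_config: ", nm, " must be a nondecreasing nonnegative range",
           call. = FALSE)
  for (nm in c("leaf_length", "leaf_width", "grain_radius", "panicle_extent"))
    if (any(cfg[[nm]] <= 0))
      stop("scene_config: ", nm, " must be strictly positive", call. = FALSE)
  cm <- cfg$color_model
  for (cls in c("background", "leaf", "panicle")) {
    mu <- cm[[cls]]$mean
    if (length(mu) != 3 || any(mu < 0) || any(mu > 255))
      stop("scene_config: color mean for '", cls,
           "' must be 3 values in [0, 255]", call. = FALSE)
    if (any(cm[[cls]]$spread < 0))
      stop("scene_config: color spread must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

#' Default class color model per grain-filling stage
#'
#' Mean RGB (8-bit) and per-channel spread for background, leaf and panicle
#' pixels at each stage. The stages define only the qualitative color
#' regimes (GG green/green, YG yellow/green, YY yellow/yellow); the numeric
#' hues here are plausible field values chosen once for the generator and
#' documented in the methods vignette. The spread controls class color
#' overlap: near 0 the class distributions are disjoint (easy tasks), large
#' values overlap (hard tasks).
#'
#' @param stage one of \code{"GG"}, \code{"YG"}, \code{"YY"}.
#' @param spread per-channel standard deviation in 8-bit units.
#' @return list with entries \code{background}, \code{leaf}, \code{panicle},
#'   each a list \code{(mean, spread)}.
#' @export
stage_colors <- function(stage = c("YG", "GG", "YY"), spread = 12) {
  stage <- match.arg(stage)
  leaf_green <- c(70, 130, 55)
  leaf_yellow <- c(175, 160, 70)
  pan_green <- c(130, 160, 95)
  pan_yellow <- c(200, 170, 80)
  leaf <- switch(stage, GG = leaf_green, YG = leaf_green, YY = leaf_yellow)
  pan <- switch(stage, GG = pan_green, YG = pan_yellow, YY = pan_yellow)
  list(
    background = list(mean = c(105, 95, 80), spread = spread),
    leaf = list(mean = leaf, spread = spread),
    panicle = list(mean = pan, spread = spread)
  )
}

#' Class labels used throughout the package
#'
#' Pixel labels follow the network's output channel order: 0 = background,
#' 1 = leaf, 2 = panicle.
#' @return named integer vector.
#' @export
class_labels <- function() c(background = 0L, leaf = 1L, panicle = 2L)

## quadratic Bezier spine sampled at n points; p* are c(row, col)
.bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  list(r = b[, 1], c = b[, 2], t = t)
}

## pixel indices (1-based, column-major in an H x W matrix) of a tapered
## blade around a sampled spine: pixel included if its distance to some
## spine point is below that point's half-width
.blade_pixels <- function(H, W, sp, width) {
  hw <- pmax(0.6, width * (1 - sp$t)^0.7 / 2) # taper toward the tip
  r0 <- max(1, floor(min(sp$r - hw))); r1 <- min(H, ceiling(max(sp$r + hw)))
  c0 <- max(1, floor(min(sp$c - hw))); c1 <- min(W, ceiling(max(sp$c + hw)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
  inside <- rep(FALSE, length(pr))
  for (q in seq_along(sp$r)) { # spine points are few; pixels vectorized
    d2 <- (pr - sp$r[q])^2 + (pc - sp$c[q])^2
    inside <- inside | d2 <= hw[q]^2
  }
  (pc[inside] - 1L) * H + pr[inside]
}

## pixel indices of a filled rotated ellipse
.ellipse_pixels <- function(H, W, center, radii, angle) {
  ca <- cos(angle); sa <- sin(angle)
  rmax <- max(radii)
  r0 <- max(1, floor(center[1] - rmax)); r1 <- min(H, ceiling(center[1] + rmax))
  c0 <- max(1, floor(center[2] - rmax)); c1 <- min(W, ceiling(center[2] + rmax))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  pr <- rep(rr, times = length(cc)) - center[1]
  pc <- rep(cc, each = length(rr)) - center[2]
  u <- pr * ca + pc * sa
  v <- -pr * sa + pc * ca
  inside <- (u / radii[1])^2 + (v / radii[2])^2 <= 1
  ((rep(cc, each = length(rr)))[inside] - 1L) * H +
    (rep(rr, times = length(cc)))[inside]
}

.runif1 <- function(range) stats::runif(1, range[1], range[2])

## uniform integer draw from a range, safe for degenerate ranges
.sample_range <- function(range) {
  if (range[1] >= range[2]) range[1] else sample(range[1]:range[2], 1)
}

#' Generate one synthetic canopy scene with its ground-truth mask
#'
#' Renders the configured scene and returns the 8-bit RGB image, the exact
#' 3-class mask, and the generator's own bookkeeping of per-class pixel
#' counts (maintained incrementally while drawing, so it can serve as an
#' independent oracle for mask-based counting). Brightness and shadows
#' perturb the image only, never the mask; organs drawn later occlude
#' earlier ones consistently in image and mask.
#'
#' @param config a \code{\link{scene_config}}.
#' @param id optional image id string.
#' @return list of class \code{canopy_scene} with elements \code{image}
#'   (list: \code{pixels} H x W x 3 integer array in 0..255, \code{id}),
#'   \code{mask} (H x W integer matrix with values 0/1/2), \code{counts}
#'   (named per-class pixel counts), \code{stage} and \code{seed}.
#' @export
generate_scene <- function(config, id = NULL) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  H <- config$height; W <- config$width
  cm <- config$color_model
  set.seed(config$seed)

  img <- array(0, dim = c(H, W, 3))
  mask <- matrix(0L, H, W)
  counts <- c(background = as.numeric(H) * W, leaf = 0, panicle = 0)

  ## background: per-channel base + shared low-frequency mottle + fine noise
  gh <- max(2L, H %/% 16L); gw <- max(2L, W %/% 16L)
  coarse <- array(stats::rnorm(gh * gw, 0, config$mottle_amplitude),
                  dim = c(gh, gw, 1))
  mottle <- .cpp_resize_bilinear(coarse, gh, gw, 1L, H, W)[, , 1]
  for (ch in 1:3)
    img[, , ch] <- cm$background$mean[ch] + mottle +
      stats::rnorm(H * W, 0, cm$background$spread)

  paint <- function(idx, cls, base_col, spread) {
    if (!length(idx)) return(invisible(NULL))
    old <- tabulate(mask[idx] + 1L, nbins = 3L)
    counts <<- counts - old
    counts[cls + 1L] <<- counts[cls + 1L] + length(idx)
    mask[idx] <<- cls
    for (ch in 1:3)
      img[idx + (ch - 1L) * H * W] <<-
        base_col[ch] + stats::rnorm(length(idx), 0, spread * 0.6)
    invisible(NULL)
  }

  draw_leaf <- function() {
    len <- .runif1(config$leaf_length) * min(H, W)
    p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    th <- stats::runif(1, 0, 2 * pi)
    p2 <- p0 + len * c(cos(th), sin(th))
    mid <- (p0 + p2) / 2
    curv <- .runif1(config$leaf_curvature) * len
    p1 <- mid + curv * c(-sin(th), cos(th))
    sp <- .bezier(p0, p1, p2, max(8L, ceiling(len * 1.5)))
    wd <- .runif1(config$leaf_width)
    col <- cm$leaf$mean + stats::rnorm(3, 0, cm$leaf$spread)
    paint(.blade_pixels(H, W, sp, wd), 1L, col, cm$leaf$spread)
  }

  draw_panicle <- function() {
    ext <- .runif1(config$panicle_extent)
    ctr <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    th <- stats::runif(1, 0, 2 * pi)
    droop <- stats::runif(1, 0.1, 0.5)
    ng <- .sample_range(config$grain_count)
    base_col <- cm$panicle$mean + stats::rnorm(3, 0, cm$panicle$spread)
    tg <- stats::runif(ng)
    axis_r <- ctr[1] + tg * ext * cos(th) + droop * (tg * ext)^2 / ext
    axis_c <- ctr[2] + tg * ext * sin(th)
    lat <- 1 + 3 * tg # lateral scatter widens toward the tip
    gr <- axis_r + stats::rnorm(ng, 0, lat)
    gc <- axis_c + stats::rnorm(ng, 0, lat)
    for (g in seq_len(ng)) {
      rad <- .runif1(config$grain_radius)
      idx <- .ellipse_pixels(H, W, c(gr[g], gc[g]),
                             c(rad, rad * stats::runif(1, 0.5, 0.9)),
                             stats::runif(1, 0, pi))
      ## grain-level color jitter gives the granular texture
      paint(idx, 2L, base_col + stats::rnorm(3, 0, cm$panicle$spread * 0.8),
            cm$panicle$spread * 0.5)
    }
  }

  n_l <- if (config$n_leaves[2] > 0) .sample_range(config$n_leaves) else 0L
  n_p <- if (config$n_panicles[2] > 0)
    .sample_range(config$n_panicles) else 0L
  if (config$panicles_on_top) {
    for (i in seq_len(n_l)) draw_leaf()
    for (i in seq_len(n_p)) draw_panicle()
  } else {
    for (i in seq_len(n_p)) draw_panicle()
    for (i in seq_len(n_l)) draw_leaf()
  }

  ## cast shadows: multiplicative darkening of the image only
  if (config$shadow_fraction > 0) {
    target <- config$shadow_fraction * H * W
    shaded <- 0
    while (shaded < target) {
      ctr <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      radii <- c(.runif1(c(0.08, 0.25)) * H, .runif1(c(0.08, 0.25)) * W)
      idx <- .ellipse_pixels(H, W, ctr, radii, stats::runif(1, 0, pi))
      if (!length(idx)) next
      f <- .runif1(config$shadow_factor)
      for (ch in 1:3) img[idx + (ch - 1L) * H * W] <-
          img[idx + (ch - 1L) * H * W] * f
      shaded <- shaded + length(idx)
    }
  }

  img <- img * .runif1(config$brightness_range)
  img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = c(H, W, 3))

  if (is.null(id)) id <- sprintf("scene_%s_%d", config$stage, config$seed)
  structure(list(
    image = list(pixels = img, id = id),
    mask = mask,
    counts = counts,
    stage = config$stage,
    seed = config$seed
  ), class = "canopy_scene")
}

## deterministic per-image seed derivation (counter-based, below 2^31)
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65521 * 31357 + index * 2654435.0) %%
               2147483647)
}

#' Generate a reproducible synthetic canopy dataset
#'
#' Produces \code{n_images} scenes whose per-image seeds are derived
#' deterministically from the master seed with a counter-based scheme, so
#' datasets are order-independent and reproducible.
#'
#' @param config a \code{\link{scene_config}} (its \code{seed} field is
#'   ignored in favor of the derived per-image seeds).
#' @param n_images number of scenes (>= 1).
#' @param seed master seed.
#' @return list of class \code{canopy_dataset}: \code{scenes} (list of
#'   \code{canopy_scene}) and \code{metadata} (data.frame with image_id,
#'   stage, seed).
#' @export
generate_dataset <- function(config, n_images, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, i)
    ci <- config
    ci$seed <- si
    scenes[[i]] <- generate_scene(ci, id = sprintf("img_%04d", i))
  }
  metadata <- data.frame(
    image_id = vapply(scenes, function(s) s$image$id, character(1)),
    stage = config$stage,
    seed = vapply(scenes, function(s) s$seed, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(scenes = scenes, metadata = metadata),
            class = "canopy_dataset")
}

#' Write a synthetic dataset to disk as PNG images, masks and metadata
#'
#' Images are 8-bit RGB PNG; masks are single-channel PNG with pixel values
#' 0/1/2; optional overlays use the conventional palette black = background,
#' blue = leaf, green = panicle.
#'
#' @param dataset a \code{canopy_dataset}.
#' @param dir output directory (created if missing); \code{images/},
#'   \code{masks/}, optionally \code{overlays/}, and \code{metadata.csv}
#'   are written inside it.
#' @param overlay also write color overlays.
#' @return invisibly, the metadata data.frame augmented with file paths.
#' @export
write_dataset <- function(dataset, dir, overlay = FALSE) {
  stopifnot(inherits(dataset, "canopy_dataset"))
  for (d in c("images", "masks", if (overlay) "overlays"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  md <- dataset$metadata
  md$image_path <- file.path("images", paste0(md$image_id, ".png"))
  md$mask_path <- file.path("masks", paste0(md$image_id, ".png"))
  for (i in seq_along(dataset$scenes)) {
    s <- dataset$scenes[[i]]
    write_image_png(s$image$pixels, file.path(dir, md$image_path[i]))
    write_mask_png(s$mask, file.path(dir, md$mask_path[i]))
    if (overlay)
      write_image_png(mask_overlay(s$mask),
                      file.path(dir, "overlays", paste0(md$image_id[i], ".png")))
  }
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(md)
}

#' Color overlay of a class mask
#'
#' @param mask H x W integer matrix with labels 0/1/2.
#' @return H x W x 3 integer array: black = background, blue = leaf,
#'   green = panicle.
#' @export
mask_overlay <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0L, dim = c(H, W, 3))
  out[, , 3][mask == 1L] <- 255L # leaf -> blue
  out[, , 2][mask == 2L] <- 255L # panicle -> green
  out
}
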