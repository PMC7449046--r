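test_that("identical configuration and seed give bit-identical scenes", {
  cfg <- tiny_scene_config(seed = 7L)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$counts, s2$counts)
})

test_that("an empty scene is all background", {
  cfg <- tiny_scene_config(n_leaves = c(0L, 0L), n_panicles = c(0L, 0L))
  s <- generate_scene(cfg)
  expect_true(all(s$mask == 0L))
  expect_equal(unname(s$counts), c(64 * 64, 0, 0))
})

test_that("populated scenes contain all three classes with positive counts", {
  cfg <- scene_config(height = 256, width = 256, n_leaves = c(5L, 10L),
                      n_panicles = c(3L, 6L), seed = 3L)
  s <- generate_scene(cfg)
  tab <- tabulate(s$mask + 1L, nbins = 3L)
  expect_true(all(tab > 0))
  expect_setequal(sort(unique(as.vector(s$mask))), 0:2)
})

test_that("the incremental bookkeeping equals direct mask counting", {
  for (seed in c(2L, 9L, 31L)) {
    s <- generate_scene(tiny_scene_config(seed = seed))
    expect_equal(unname(s$counts), tabulate(s$mask + 1L, nbins = 3L))
  }
})

test_that("image and mask have consistent shapes and 8-bit range", {
  s <- generate_scene(tiny_scene_config(seed = 5L))
  expect_equal(dim(s$image$pixels), c(64, 64, 3))
  expect_equal(dim(s$mask), c(64, 64))
  expect_true(all(s$image$pixels >= 0 & s$image$pixels <= 255))
  expect_type(s$image$pixels, "integer")
})

test_that("dataset generation is reproducible and images are distinct", {
  cfg <- tiny_scene_config()
  d1 <- generate_dataset(cfg, 3, seed = 1L)
  d2 <- generate_dataset(cfg, 3, seed = 1L)
  for (i in 1:3)
    expect_identical(d1$scenes[[i]]$image$pixels, d2$scenes[[i]]$image$pixels)
  ## pairwise distinct
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sum(d1$scenes[[i]]$image$pixels !=
                    d1$scenes[[j]]$image$pixels), 0)
  ## a singleton dataset equals generate_scene with the derived seed
  d3 <- generate_dataset(cfg, 1, seed = 1L)
  cfg1 <- cfg
  cfg1$seed <- lprseg:::derive_seed(1L, 1L)
  expect_identical(d3$scenes[[1]]$mask, generate_scene(cfg1)$mask)
  expect_error(generate_dataset(cfg, 0), "n_images")
})

test_that("stage color regimes put leaf hue in the configured bands", {
  mean_hue <- function(scene, cls) {
    px <- scene$image$pixels
    idx <- which(scene$mask == cls)
    rgb <- rbind(px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
    h <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1, ]
    mean(h) * 360
  }
  ## YY: leaf is yellow (hue around 30-75 degrees)
  syy <- generate_scene(tiny_scene_config(seed = 11L, stage = "YY",
                                          shadow_fraction = 0))
  expect_gt(sum(syy$mask == 1L), 0)
  hyy <- mean_hue(syy, 1L)
  expect_true(hyy > 30 && hyy < 75)
  ## YG: leaf is green (hue around 75-160 degrees)
  syg <- generate_scene(tiny_scene_config(seed = 11L, stage = "YG",
                                          shadow_fraction = 0))
  hyg <- mean_hue(syg, 1L)
  expect_true(hyg > 75 && hyg < 160)
})

test_that("brightness and shadows perturb the image but never the mask", {
  base <- tiny_scene_config(seed = 13L, shadow_fraction = 0,
                            brightness_range = c(1, 1))
  pert <- tiny_scene_config(seed = 13L, shadow_fraction = 0.3,
                            brightness_range = c(0.7, 0.7))
  s0 <- generate_scene(base)
  s1 <- generate_scene(pert)
  expect_identical(s0$mask, s1$mask)
  expect_gt(sum(s0$image$pixels != s1$image$pixels), 0)
})

test_that("geometric augmentation preserves per-class pixel counts", {
  s <- generate_scene(tiny_scene_config(seed = 17L))
  cfg <- preprocess_config(crop_min = 32L, crop_max = 64L)
  sample_ <- list(image = s$image$pixels, mask = s$mask, source_id = "x")
  for (aug in c("hflip", "vflip", "rot90")) {
    out <- augment_sample(sample_, cfg, force = aug)
    expect_equal(tabulate(out$mask + 1L, 3), tabulate(s$mask + 1L, 3))
  }
})

test_that("class color separability is controlled by the spread", {
  tight <- stage_colors("YG", spread = 0.01)
  loose <- stage_colors("YG", spread = 60)
  class_range <- function(s, cls) {
    sc <- generate_scene(tiny_scene_config(
      seed = 21L, color_model = s, shadow_fraction = 0,
      brightness_range = c(1, 1), mottle_amplitude = if (cls == 0) 0 else 0))
    px <- sc$image$pixels[, , 2] # green channel separates leaf from panicle
    range(px[sc$mask == cls])
  }
  ## with spread -> 0 the green-channel distributions are disjoint
  lr <- class_range(tight, 1L)
  pr <- class_range(tight, 2L)
  expect_true(lr[1] > pr[2] || pr[1] > lr[2])
  ## with large spread they overlap
  lr2 <- class_range(loose, 1L)
  pr2 <- class_range(loose, 2L)
  expect_true(max(lr2[1], pr2[1]) < min(lr2[2], pr2[2]))
})

test_that("scene configuration invariants are enforced", {
  expect_error(scene_config(height = 16), "32x32")
  expect_error(scene_config(shadow_fraction = 1.5), "shadow_fraction")
  expect_error(scene_config(n_leaves = c(5L, 2L)), "n_leaves")
  expect_error(scene_config(leaf_width = c(0, 3)), "leaf_width")
  bad <- stage_colors("YG")
  bad$leaf$mean <- c(300, 0, 0)
  expect_error(scene_config(color_model = bad), "color mean")
})

test_that("datasets round-trip through PNG files and metadata", {
  d <- generate_dataset(tiny_scene_config(), 2, seed = 4L)
  dir <- tempfile("ds")
  md <- write_dataset(d, dir, overlay = TRUE)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  img <- read_image_png(file.path(dir, md$image_path[1]))
  msk <- read_mask_png(file.path(dir, md$mask_path[1]))
  expect_identical(img, d$scenes[[1]]$image$pixels)
  expect_identical(msk, d$scenes[[1]]$mask)
  ov <- read_image_png(file.path(dir, "overlays", paste0(md$image_id[1], ".png")))
  ## palette: leaf pixels blue, panicle pixels green, background black
  expect_true(all(ov[, , 3][d$scenes[[1]]$mask == 1L] == 255L))
  expect_true(all(ov[, , 2][d$scenes[[1]]$mask == 2L] == 255L))
  expect_true(all(ov[, , 1] == 0L))
  unlink(dir, recursive = TRUE)
})
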