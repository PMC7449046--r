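test_that("LPR is the leaf/panicle pixel quotient", {
  mask <- matrix(0L, 20, 20)
  mask[1:300] <- 1L
  mask[301:400] <- 2L
  rec <- compute_lpr(mask, image_id = "a")
  expect_equal(rec$L, 300)
  expect_equal(rec$P, 100)
  expect_equal(rec$lpr, 3.0)
  expect_equal(rec$L + rec$P + rec$background_count, 400)
})

test_that("P = 0 flags the ratio missing unless strict", {
  mask <- matrix(0L, 4, 4)
  rec <- compute_lpr(mask)
  expect_equal(rec$L, 0)
  expect_equal(rec$P, 0)
  expect_true(is.na(rec$lpr))
  expect_error(compute_lpr(mask, strict = TRUE), "undefined")
  expect_error(compute_lpr(matrix(4L, 2, 2)), "labels")
})

test_that("LPR reproduces the generator's own bookkeeping exactly", {
  for (seed in c(1L, 23L)) {
    s <- generate_scene(scene_config(seed = seed))
    rec <- compute_lpr(s$mask, image_id = s$image$id)
    expect_equal(rec$L, unname(s$counts["leaf"]))
    expect_equal(rec$P, unname(s$counts["panicle"]))
    if (rec$P > 0)
      expect_equal(rec$lpr, unname(s$counts["leaf"] / s$counts["panicle"]))
  }
})

test_that("LPR is invariant to pixel permutation and 2x upscaling", {
  s <- generate_scene(tiny_scene_config(seed = 2L))
  rec <- compute_lpr(s$mask)
  set.seed(1)
  perm <- matrix(as.vector(s$mask)[sample(length(s$mask))], 64, 64)
  expect_equal(compute_lpr(perm)$lpr, rec$lpr)
  up <- s$mask[rep(1:64, each = 2), rep(1:64, each = 2)]
  rec2 <- compute_lpr(up)
  expect_equal(rec2$L, 4 * rec$L)
  expect_equal(rec2$P, 4 * rec$P)
  expect_equal(rec2$lpr, rec$lpr)
})

test_that("relabeling background to leaf strictly increases LPR", {
  s <- generate_scene(tiny_scene_config(seed = 3L))
  stopifnot(sum(s$mask == 2L) > 0)
  rec <- compute_lpr(s$mask)
  more <- s$mask
  bg <- which(more == 0L)[1:50]
  more[bg] <- 1L
  expect_gt(compute_lpr(more)$lpr, rec$lpr)
})

test_that("summaries group records and exclude undefined ratios", {
  recs <- rbind(
    compute_lpr({m <- matrix(0L, 4, 4); m[1:2] <- 1L; m[3] <- 2L; m},
                metadata = list(stage = "GG"), image_id = "a"),
    compute_lpr({m <- matrix(0L, 4, 4); m[1:4] <- 1L; m[5] <- 2L; m},
                metadata = list(stage = "GG"), image_id = "b"),
    compute_lpr(matrix(0L, 4, 4), metadata = list(stage = "YY"),
                image_id = "c")
  )
  expect_error(summarize_lpr(recs[3, ], "stage"), "undefined")
  sm <- summarize_lpr(recs, "stage")
  expect_equal(nrow(sm), 1)
  expect_equal(sm$n, 2)
  expect_equal(sm$mean, 3)
  expect_equal(attr(sm, "n_undefined"), 1)
  one <- summarize_lpr(recs[1, ], "stage")
  expect_true(is.na(one$sd))
  ## constant groups: means exact, sd zero
  recs2 <- do.call(rbind, lapply(1:4, function(i) {
    m <- matrix(0L, 4, 4); m[1:ifelse(i <= 2, 2, 4)] <- 1L; m[16] <- 2L
    compute_lpr(m, metadata = list(g = ifelse(i <= 2, "lo", "hi")),
                image_id = as.character(i))
  }))
  sm2 <- summarize_lpr(recs2, "g")
  expect_equal(sort(sm2$mean), c(2, 4))
  expect_equal(sm2$sd, c(0, 0))
})

test_that("identical groups share one letter in the ranges test", {
  vals <- c(2.0, 2.1, 1.9, 2.05)
  recs <- data.frame(lpr = rep(vals, 3),
                     grp = rep(c("a", "b", "c"), each = 4))
  r <- ssr_test(recs, "grp")
  expect_equal(length(unique(r$means$letters)), 1)
})

test_that("well-separated groups receive distinct letters", {
  set.seed(1)
  recs <- data.frame(
    lpr = c(rnorm(10, 2.0, 0.1), rnorm(10, 5.0, 0.1)),
    grp = rep(c("low", "high"), each = 10)
  )
  r <- ssr_test(recs, "grp", alpha = 0.05)
  expect_equal(r$means$group, c("high", "low")) # sorted descending
  expect_length(intersect(strsplit(r$means$letters[1], "")[[1]],
                          strsplit(r$means$letters[2], "")[[1]]), 0)
})

test_that("pairwise decisions agree with a permutation oracle", {
  set.seed(2)
  ## clearly separated and clearly overlapping 3-group cases
  sep <- data.frame(lpr = c(rnorm(8, 1, 0.2), rnorm(8, 3, 0.2),
                            rnorm(8, 6, 0.2)),
                    grp = rep(c("a", "b", "c"), each = 8))
  ovl <- data.frame(lpr = c(rnorm(8, 2, 0.5), rnorm(8, 2.05, 0.5),
                            rnorm(8, 1.95, 0.5)),
                    grp = rep(c("a", "b", "c"), each = 8))
  for (case in list(list(d = sep, expect_sig = TRUE),
                    list(d = ovl, expect_sig = FALSE))) {
    r <- ssr_test(case$d, "grp")
    groups <- r$means$group
    for (i in 1:2) for (j in (i + 1):3) {
      x <- case$d$lpr[case$d$grp == groups[i]]
      y <- case$d$lpr[case$d$grp == groups[j]]
      pperm <- perm_test_two_groups(x, y, n_perm = 10000)
      ssr_sig <- !r$nonsig[i, j]
      if (case$expect_sig) {
        expect_true(ssr_sig)
        expect_lt(pperm, 0.05)
      } else {
        expect_false(ssr_sig)
        expect_gt(pperm, 0.05)
      }
    }
  }
})

test_that("the ranges test validates its inputs", {
  recs <- data.frame(lpr = rnorm(5), grp = "a")
  expect_error(ssr_test(recs, "grp"), "2 groups")
  recs2 <- data.frame(lpr = rnorm(4), grp = c("a", "a", "b", "c"))
  expect_error(ssr_test(recs2, "grp"), "at least 2 defined")
})

test_that("a U-shaped daily leaf-visibility pattern is recovered in LPR", {
  ## five times of day; leaf-visible fraction high in morning/evening, low
  ## at noon (leaves shade each other least at low solar angles)
  leaf_counts <- list(dawn = c(14L, 18L), mid_morning = c(10L, 13L),
                      noon = c(6L, 8L), mid_afternoon = c(10L, 13L),
                      dusk = c(14L, 18L))
  recs <- do.call(rbind, lapply(names(leaf_counts), function(tod) {
    cfg <- scene_config(n_leaves = leaf_counts[[tod]],
                        n_panicles = c(4L, 6L))
    ds <- generate_dataset(cfg, 12, seed = match(tod, names(leaf_counts)))
    do.call(rbind, lapply(ds$scenes, function(s)
      compute_lpr(s$mask, metadata = list(tod = tod),
                  image_id = paste(tod, s$seed))))
  }))
  sm <- summarize_lpr(recs, "tod")
  means <- setNames(sm$mean, sm$group)
  expect_gt(means["dawn"], means["mid_morning"])
  expect_gt(means["mid_morning"], means["noon"])
  expect_lt(means["noon"], means["mid_afternoon"])
  expect_lt(means["mid_afternoon"], means["dusk"])
})

test_that("group mean LPR tracks the configured organ-count ratios", {
  cfg_lo <- scene_config(n_leaves = c(5L, 7L), n_panicles = c(5L, 7L))
  cfg_hi <- scene_config(n_leaves = c(16L, 20L), n_panicles = c(3L, 4L))
  lo <- generate_dataset(cfg_lo, 15, seed = 10)
  hi <- generate_dataset(cfg_hi, 15, seed = 11)
  mean_lpr <- function(ds) {
    v <- vapply(ds$scenes, function(s) {
      r <- compute_lpr(s$mask)
      if (is.na(r$lpr)) NA_real_ else r$lpr
    }, 1)
    mean(v, na.rm = TRUE)
  }
  expect_gt(mean_lpr(hi), 2 * mean_lpr(lo))
})
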