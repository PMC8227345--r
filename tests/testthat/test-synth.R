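test_that("rendering is fully determined by the seed", {
  cfg <- synth_config(image_shape = c(64, 64), count_range = c(10, 20),
                      rng_seed = 21)
  a <- render_sample(cfg)
  b <- render_sample(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations$points, b$annotations$points)

  other <- render_sample(synth_config(image_shape = c(64, 64),
                                      count_range = c(10, 20), rng_seed = 22))
  expect_false(identical(a$image, other$image))
})

test_that("empty count range yields a blank noisy image with no points", {
  s <- render_sample(synth_config(image_shape = c(32, 32),
                                  count_range = c(0, 0), rng_seed = 5))
  expect_equal(n_points(s$annotations), 0L)
  expect_true(all(abs(s$image - 0.08) < 0.25))  # background + noise only
})

test_that("non-adhering grains keep their centers apart", {
  s <- render_sample(synth_config(image_shape = c(128, 128),
                                  count_range = c(30, 30),
                                  adhesion_prob = 0, rng_seed = 9))
  expect_equal(n_points(s$annotations), 30L)
  pts <- s$annotations$points
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  minors <- s$minors
  sep <- outer(minors, minors, "+")
  expect_true(all(d > sep))
  expect_false(any(s$adhered))
})

test_that("each rendered grain is one connected bright component", {
  # noise-free, non-adhering render: a 4-connected flood fill over the
  # thresholded image must find exactly N components. Near-circular
  # grains, so the effective-radius spacing guarantee bounds the true
  # ellipse extent (elongated grains may still tip-touch).
  s <- render_sample(synth_config(image_shape = c(96, 96),
                                  count_range = c(12, 12),
                                  shape_class = "short_oval",
                                  adhesion_prob = 0, noise_sd = 0,
                                  rng_seed = 31))
  bin <- s$image > 0.3
  lab <- matrix(0L, nrow(bin), ncol(bin))
  comp <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      if (lab[p] != 0L || !bin[p]) next
      lab[p] <- comp
      r <- (p - 1L) %% nrow(bin) + 1L; cc <- (p - 1L) %/% nrow(bin) + 1L
      if (r > 1L) queue <- c(queue, p - 1L)
      if (r < nrow(bin)) queue <- c(queue, p + 1L)
      if (cc > 1L) queue <- c(queue, p - nrow(bin))
      if (cc < ncol(bin)) queue <- c(queue, p + nrow(bin))
    }
  }
  expect_equal(max(lab), 12L)
})

test_that("adhering grains are flagged and allowed to touch", {
  s <- render_sample(synth_config(image_shape = c(128, 128),
                                  count_range = c(25, 25),
                                  adhesion_prob = 0.8, rng_seed = 13))
  expect_gt(sum(s$adhered), 0L)
  expect_equal(length(s$adhered), n_points(s$annotations))
})

test_that("oblique perspective warps points together with the image", {
  base <- synth_config(image_shape = c(96, 96), count_range = c(10, 10),
                       perspective = "top_far", rng_seed = 17)
  obl <- base; obl$perspective <- "oblique"
  so <- render_sample(obl)
  expect_equal(n_points(so$annotations), 10L)
  pts <- so$annotations$points
  h <- 96
  expect_true(all(pts[, 2] >= 0 & pts[, 2] < h))
  # grain pixels should sit near the warped annotations: each point must
  # fall on or next to bright image content
  bright <- so$image > 0.3
  on_grain <- sapply(seq_len(nrow(pts)), function(i) {
    r <- round(pts[i, 2]) + 1; cc <- round(pts[i, 1]) + 1
    any(bright[max(1, r - 2):min(h, r + 2), max(1, cc - 2):min(96, cc + 2)])
  })
  expect_true(all(on_grain))
})

test_that("ten-crop produces 10 half-size crops whose quadrants partition", {
  s <- render_sample(synth_config(image_shape = c(64, 64),
                                  count_range = c(25, 25), rng_seed = 3))
  crops <- ten_crop(s, seed = 1)
  expect_length(crops, 10L)
  for (cr in crops) expect_equal(dim(cr$image), c(32L, 32L))
  quad_counts <- sum(sapply(crops[1:4], function(cr) n_points(cr$annotations)))
  expect_equal(quad_counts, n_points(s$annotations))
  # crop annotations are re-based into crop coordinates
  for (cr in crops) {
    if (n_points(cr$annotations) == 0L) next
    expect_true(all(cr$annotations$points >= 0 & cr$annotations$points < 32))
  }
})

test_that("boundary points follow the half-open crop convention", {
  s <- list(image = matrix(0, 8, 8),
            annotations = point_annotations(cbind(4, 4), c(8, 8)),
            adhered = FALSE, config = NULL)
  class(s) <- "seed_sample"
  crops <- ten_crop(s, seed = 1)
  # point (4, 4) sits on the quadrant boundary: left/top inclusive puts it
  # in the bottom-right quadrant only
  counts <- sapply(crops[1:4], function(cr) n_points(cr$annotations))
  expect_equal(counts, c(0L, 0L, 0L, 1L))
})

test_that("build_dataset is deterministic and writes a readable manifest", {
  cfg <- synth_config(image_shape = c(48, 48), count_range = c(5, 10),
                      rng_seed = 77)
  a <- build_dataset(cfg, 3)
  b <- build_dataset(cfg, 3)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  # per-sample streams differ
  expect_false(identical(a[[1]]$image, a[[2]]$image))

  dir <- withr::local_tempdir()
  build_dataset(cfg, 3, dir = dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 3L)
  expect_true(all(file.exists(file.path(dir, manifest$image_path))))
  ann <- read_annotations(file.path(dir, manifest$annotation_path[1]))
  expect_equal(n_points(ann), manifest$count[1])
})
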