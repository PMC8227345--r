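test_that("counts are map totals at any scale", {
  set.seed(61)
  ann <- random_annotations(14, 64, 64, margin = 4)
  dm <- generate_density_map(ann, kernel_spec())
  expect_equal(count_from_density(dm), 14, tolerance = 2e-5 * 14)
  expect_equal(count_from_density(downsample_density(dm, 4)),
               count_from_density(dm), tolerance = 1e-12)
  expect_equal(count_from_density(matrix(0, 5, 5)), 0)
})

test_that("MAE and MSE match hand arithmetic and the loop oracle", {
  pairs <- cbind(c(10, 20), c(10, 20))
  expect_equal(count_mae(pairs), 0)
  expect_equal(count_mse(pairs), 0)
  pairs <- cbind(c(10, 20), c(12, 17))
  expect_equal(count_mae(pairs), 2.5)
  expect_equal(count_mse(pairs), 6.5)

  set.seed(62)
  y <- runif(1000, 0, 100); yh <- y + rnorm(1000, 0, 5)
  mae_loop <- 0; mse_loop <- 0
  for (i in seq_along(y)) {
    mae_loop <- mae_loop + abs(y[i] - yh[i])
    mse_loop <- mse_loop + (y[i] - yh[i])^2
  }
  expect_equal(count_mae(cbind(y, yh)), mae_loop / 1000, tolerance = 1e-9)
  expect_equal(count_mse(cbind(y, yh)), mse_loop / 1000, tolerance = 1e-9)
})

test_that("MSE dominates squared MAE (Jensen)", {
  set.seed(63)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    y <- runif(n, 1, 200); yh <- y + rnorm(n, 0, runif(1, 0.1, 10))
    pairs <- cbind(y, yh)
    expect_gte(count_mse(pairs), count_mae(pairs)^2 - 1e-12)
  }
})

test_that("count-ratio accuracy is 100 iff every rounded count is right", {
  exact <- cbind(c(10, 25), c(10.4, 24.6))  # rounds to truth
  expect_equal(count_accuracy(exact), 100)
  off <- cbind(c(10, 25), c(11, 25))
  expect_lt(count_accuracy(off), 100)
  # degrades smoothly and is clamped at zero
  expect_equal(count_accuracy(cbind(10, 40)), 0)
  expect_equal(count_accuracy(cbind(0, 0.2)), 100)  # zero-count image
  expect_equal(count_accuracy(cbind(0, 3)), 0)
})

test_that("detection finds isolated Gaussian peaks and ignores empty maps", {
  ann <- point_annotations(cbind(12, 20), c(41, 41))
  dm <- generate_density_map(ann, kernel_spec("fixed", sigma_fixed = 2))
  det <- detect_grains(dm, match_spec(min_separation = 3))
  expect_equal(nrow(det), 1L)
  expect_equal(unname(det[1, c("x", "y")]), c(12, 20))

  # two kernels 10 sigma apart stay separate
  ann2 <- point_annotations(cbind(c(10, 30), c(20, 20)), c(41, 41))
  dm2 <- generate_density_map(ann2, kernel_spec("fixed", sigma_fixed = 2))
  det2 <- detect_grains(dm2, match_spec(min_separation = 3))
  expect_equal(nrow(det2), 2L)
  expect_setequal(round(det2[, "x"]), c(10, 30))

  expect_equal(nrow(detect_grains(density_map(matrix(0, 8, 8)))), 0L)
})

test_that("detections on a scale-4 map come back in source coordinates", {
  ann <- point_annotations(cbind(33.5, 17.5), c(64, 64))
  dm <- generate_density_map(ann, kernel_spec("fixed", sigma_fixed = 4))
  down <- downsample_density(dm, 4)
  det <- detect_grains(down, match_spec(min_separation = 5))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det[1, "x"] - 33.5), 4)
  expect_lt(abs(det[1, "y"] - 17.5), 4)
})

test_that("greedy matching reports TP, FP and FN correctly", {
  truth <- point_annotations(cbind(c(5, 15, 25), c(5, 5, 5)), c(32, 32))
  perfect <- match_detections(truth$points, truth, radius = 1)
  expect_equal(c(perfect$tp, perfect$fp, perfect$fn), c(3L, 0L, 0L))
  expect_equal(perfect$accuracy, 100)

  none <- match_detections(matrix(numeric(0), 0, 2), truth, radius = 1)
  expect_equal(c(none$tp, none$fn), c(0L, 3L))

  # one detection just outside the radius: both an FP and an FN
  far <- match_detections(cbind(5 + 2.001, 5), truth, radius = 2)
  expect_equal(far$fp, 1L)
  expect_equal(far$fn, 3L)

  # one-to-one: two detections cannot claim the same truth
  dup <- match_detections(cbind(c(5, 5.5), c(5, 5)), truth, radius = 2)
  expect_equal(dup$tp, 1L)
  expect_equal(dup$fp, 1L)
})

test_that("ground-truth detection recovers grains from generator layouts", {
  for (seed in c(70, 71, 72)) {
    s <- render_sample(synth_config(image_shape = c(96, 96),
                                    count_range = c(20, 20),
                                    adhesion_prob = 0, rng_seed = seed))
    # kernels narrow relative to the generator's spacing guarantee:
    # every grain is a separate peak
    dm <- generate_density_map(s$annotations,
                               kernel_spec("fixed", sigma_fixed = 1.5))
    det <- detect_grains(dm, match_spec(min_separation = 2))
    m <- match_detections(det, s$annotations, radius = 3)
    expect_equal(c(m$tp, m$fp, m$fn), c(20L, 0L, 0L))

    # the adaptive kernel may merge a close pair whose remaining
    # neighbours are distant (sigma averages over m neighbours), but it
    # must never invent grains
    dm_a <- generate_density_map(s$annotations, kernel_spec())
    det_a <- detect_grains(dm_a, match_spec(min_separation = 2))
    sig <- adaptive_sigmas(s$annotations, kernel_spec())
    m_a <- match_detections(det_a, s$annotations, radius = mean(sig))
    expect_equal(m_a$fp, 0L)
    expect_gte(m_a$tp, 16L)
  }
})

test_that("evaluation on ground-truth densities is a fixed point", {
  samples <- tiny_sample_set(4, seed = 71, size = 48L, counts = c(5L, 9L))
  pairs <- t(sapply(samples, function(s) {
    gt <- generate_density_map(s$annotations, kernel_spec())
    c(n_points(s$annotations), count_from_density(gt))
  }))
  expect_equal(count_mae(pairs), 0, tolerance = 1e-6)
  expect_equal(count_accuracy(pairs), 100)
})

test_that("evaluation reports write CSV and JSON", {
  samples <- tiny_sample_set(3, seed = 72, size = 32L, counts = c(2L, 5L))
  m <- build_model(model_config("mcnn"), seed = 73)
  ev <- evaluate_model(m, samples)
  expect_true(ev$mae >= 0 && ev$mse >= 0)
  expect_true(ev$acc >= 0 && ev$acc <= 100)
  expect_equal(nrow(ev$per_image), 3L)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, csv, js, extra = list(note = 1))
  expect_equal(jsonlite::fromJSON(js)$mae, ev$mae)
  expect_equal(nrow(utils::read.csv(csv)), 3L)
})
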