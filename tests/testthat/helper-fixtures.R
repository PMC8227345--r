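# shared fixtures and independent oracles

# brute-force O(N^2) mean distance to the m nearest neighbours, written
# independently of the package's implementation
oracle_mean_neighbor_distance <- function(pts, m) {
  n <- nrow(pts)
  sapply(seq_len(n), function(i) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- c(d, sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2))
    }
    mean(sort(d)[seq_len(min(m, n - 1))])
  })
}

# elementwise loop version of the squared-Euclidean density loss
oracle_density_loss <- function(pred, target) {
  tot <- 0
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred)))
      tot <- tot + (pred[i, j] - target[i, j])^2
  tot
}

random_annotations <- function(n, h = 64, w = 64, margin = 2) {
  point_annotations(
    cbind(runif(n, margin, w - 1 - margin), runif(n, margin, h - 1 - margin)),
    c(h, w))
}

tiny_sample_set <- function(n_imgs, seed, size = 48L, counts = c(4L, 8L),
                            adhesion = 0) {
  cfg <- synth_config(image_shape = c(size, size), count_range = counts,
                      adhesion_prob = adhesion, rng_seed = seed)
  build_dataset(cfg, n_imgs)
}

# one place to keep the trained acceptance-scale models so several tests
# can interrogate the same run
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_mcnn_run <- function() {
  if (!is.null(.acceptance_cache$c6)) return(.acceptance_cache$c6)
  cfg <- synth_config(image_shape = c(96L, 96L), count_range = c(10L, 30L),
                      adhesion_prob = 0.2, rng_seed = 1L)
  samples <- build_dataset(cfg, 32L)
  model <- build_model(model_config("mcnn"), seed = 2L)
  fit <- train_model(model, samples,
                     train_config(epochs = 100L, learning_rate = 1e-3,
                                  optimizer = "adam", rng_seed = 3L))
  .acceptance_cache$c6 <- list(model = model, fit = fit, samples = samples)
  .acceptance_cache$c6
}
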