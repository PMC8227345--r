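#' Count-class bins for the prior classifier
#'
#' Strictly increasing integer edges define `length(edges) + 1` half-open
#' bins covering `[0, Inf)`: counts below `edges[1]` fall in class 0,
#' counts in `[edges[j], edges[j+1])` in class j, and counts at or above
#' the last edge in the final class.
#'
#' @param edges strictly increasing integer thresholds (at least one).
#' @return An object of class `count_class_bins`.
#' @examples
#' bins <- count_class_bins(c(10, 20))
#' count_to_class(c(0, 10, 500), bins)  # 0 1 2
#' @export
count_class_bins <- function(edges) {
  edges <- as.integer(edges)
  if (length(edges) < 1L) stop("need at least one edge (two bins)")
  if (any(diff(edges) <= 0L)) stop("edges must be strictly increasing")
  structure(list(edges = edges, n_classes = length(edges) + 1L),
            class = "count_class_bins")
}

#' Map grain counts to count-class labels
#'
#' @param count nonnegative integer count(s).
#' @param bins a [count_class_bins()].
#' @return Integer class label(s) in `0 .. length(edges)` (0-based).
#' @export
count_to_class <- function(count, bins) {
  stopifnot(inherits(bins, "count_class_bins"))
  if (any(count < 0)) stop("counts must be >= 0")
  findInterval(count, bins$edges)
}

#' Quantile-based default bins for a dataset
#'
#' Splits the observed counts of a sample list into `n_classes` roughly
#' equally populated bins.
#'
#' @param samples list of `seed_sample` objects.
#' @param n_classes number of bins (>= 2).
#' @return A [count_class_bins()].
#' @export
bins_from_samples <- function(samples, n_classes = 5L) {
  counts <- vapply(samples, function(s) n_points(s$annotations), numeric(1))
  qs <- stats::quantile(counts, probs = seq_len(n_classes - 1L) / n_classes,
                        type = 1)
  edges <- sort(unique(as.integer(ceiling(qs))))
  if (length(edges) == 0L) edges <- as.integer(max(counts) + 1L)
  count_class_bins(edges)
}

#' Cross-entropy loss of the count-class prior
#'
#' Mean categorical cross-entropy over the batch:
#' `Lc = -(1/N) sum_i log softmax(logits_i)[label_i]`.
#'
#' @param logits numeric vector (one item) or N x M matrix of unnormalized
#'   class scores.
#' @param labels 0-based class labels, length N.
#' @return Nonnegative scalar loss.
#' @examples
#' prior_loss(rep(0, 5), 2L)  # log(5)
#' @export
prior_loss <- function(logits, labels) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits))
    stop("one label per row of logits required")
  if (any(labels < 0L | labels >= ncol(logits)))
    stop("labels must lie in [0, n_classes)")
  lse <- apply(logits, 1L, function(z) {
    m <- max(z)
    m + log(sum(exp(z - m)))
  })
  picked <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - picked)
}

#' Euclidean density loss
#'
#' Mean over the batch of the squared Euclidean norm of the per-pixel
#' difference between predicted and target density maps:
#' `Ld = (1/N) sum_i || F_i - D_i ||^2`.
#'
#' @param pred predicted map (matrix or [density_map()]) or list of them.
#' @param target ground-truth map(s) of matching shape.
#' @return Nonnegative scalar; 0 iff `pred` equals `target`.
#' @export
density_loss <- function(pred, target) {
  as_list <- function(x) {
    if (inherits(x, "density_map")) list(x$values)
    else if (is.matrix(x)) list(x)
    else lapply(x, function(e) if (inherits(e, "density_map")) e$values else e)
  }
  p <- as_list(pred); t <- as_list(target)
  if (length(p) != length(t)) stop("pred and target batches differ in length")
  terms <- mapply(function(pi, ti) {
    if (!all(dim(pi) == dim(ti))) stop("pred/target shapes differ")
    sum((pi - ti)^2)
  }, p, t)
  mean(terms)
}

#' Combined multi-task loss
#'
#' `L = lambda * Lc + Ld`: the density loss plus the lambda-weighted
#' count-class cross-entropy.
#'
#' @param lc classification loss.
#' @param ld density loss.
#' @param lambda nonnegative weight.
#' @return Scalar total loss.
#' @export
total_loss <- function(lc, ld, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  lambda * lc + ld
}

#' Training configuration
#'
#' @param epochs number of passes over the dataset.
#' @param batch_size images per optimization step (variable-size images
#'   require size-compatible batches; the default of 1 always works).
#' @param learning_rate optimizer step size.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param momentum SGD momentum coefficient.
#' @param lambda weight of the prior loss; ignored by the plain MCNN.
#' @param rng_seed seed controlling shuffling (weight initialization is
#'   seeded in [build_model()]).
#' @param stage `"joint"` trains everything together; `"prior_first"`
#'   first fits the prior classifier alone (density gradients off) for
#'   `prior_epochs`, then continues jointly.
#' @param prior_epochs epochs of the optional prior-only phase.
#' @param shuffle reshuffle sample order each epoch.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 1L,
                         learning_rate = 1e-5, optimizer = c("sgd", "adam"),
                         momentum = 0.9, lambda = 1e-4, rng_seed = 1L,
                         stage = c("joint", "prior_first"),
                         prior_epochs = 20L, shuffle = TRUE, verbose = 0L) {
  optimizer <- match.arg(optimizer)
  stage <- match.arg(stage)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, lambda >= 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         momentum = momentum, lambda = lambda,
         rng_seed = as.integer(rng_seed), stage = stage,
         prior_epochs = as.integer(prior_epochs), shuffle = shuffle,
         verbose = as.integer(verbose)),
    class = "train_config"
  )
}

#' Train a density-map counting network
#'
#' Ground-truth density maps are generated from each sample's annotations
#' with `kernel`, then block-sum downsampled x4 for the MCNN (whose output
#' is at 1/4 resolution) or kept at full resolution for the improved
#' network, so predicted map sums are counts at either scale. The improved
#' network also receives 0-based count-class labels from `bins`.
#'
#' Training is deterministic given the model's and the configuration's
#' seeds under single-threaded execution. A non-finite loss aborts with
#' the offending epoch.
#'
#' @param model a [build_model()] network (modified in place).
#' @param samples list of `seed_sample` objects (from [render_sample()] /
#'   [build_dataset()] or assembled from images + annotations).
#' @param config a [train_config()].
#' @param kernel a [kernel_spec()] for ground-truth generation.
#' @param bins a [count_class_bins()]; defaults to quantile bins of the
#'   training counts ([bins_from_samples()]).
#' @return A list of class `train_result`: `model`, `log` (data frame with
#'   epoch, loss, ld, lc, mae, mse), `bins`, `kernel`.
#' @export
train_model <- function(model, samples, config = train_config(),
                        kernel = kernel_spec(), bins = NULL) {
  stopifnot(inherits(model, "seedcount_model"),
            inherits(config, "train_config"), length(samples) >= 1L)
  kind <- model$config$kind
  images <- lapply(samples, function(s) .check_input_image(model, s$image))
  counts <- vapply(samples, function(s) n_points(s$annotations), numeric(1))
  targets <- lapply(samples, function(s) {
    gt <- generate_density_map(s$annotations, kernel)
    if (kind == "mcnn") gt <- downsample_density(gt, 4L)
    gt$values
  })
  if (kind == "improved") {
    # count-class labels feed the prior branch; the plain MCNN has none
    if (is.null(bins)) bins <- bins_from_samples(samples, model$config$n_classes)
    if (bins$n_classes != model$config$n_classes)
      stop("bins define ", bins$n_classes, " classes but the model expects ",
           model$config$n_classes,
           " (too few distinct counts for quantile bins?)")
    labels <- as.integer(count_to_class(counts, bins))
  } else {
    labels <- integer(length(samples))
  }

  opt <- list(kind = config$optimizer, lr = config$learning_rate,
              momentum = config$momentum)
  n <- length(samples)
  log_rows <- vector("list", config$epochs)

  .with_seed(config$rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      lambda_e <- config$lambda
      if (kind == "improved" && config$stage == "prior_first" &&
          epoch <= config$prior_epochs) {
        # prior-only phase: emphasize the classifier while the density
        # head idles near zero output
        lambda_e <- max(config$lambda, 1)
      }
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- ep_ld <- ep_lc <- 0
      preds <- numeric(n)
      b0 <- 1L
      while (b0 <= n) {
        b1 <- min(b0 + config$batch_size - 1L, n)
        idx <- ord[b0:b1]
        res <- net_train_batch(model$ptr, images[idx], targets[idx],
                               labels[idx], lambda_e, opt)
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_ld <- ep_ld + res$ld * length(idx)
        ep_lc <- ep_lc + res$lc * length(idx)
        preds[idx] <- res$pred_counts
        b0 <- b1 + 1L
      }
      ep_loss <- ep_loss / n; ep_ld <- ep_ld / n; ep_lc <- ep_lc / n
      if (!is.finite(ep_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      err <- preds - counts
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, loss = ep_loss, ld = ep_ld, lc = ep_lc,
        mae = mean(abs(err)), mse = mean(err^2))
      if (config$verbose > 0L && epoch %% config$verbose == 0L)
        message(sprintf("epoch %4d  loss %.5g  mae %.3f  mse %.3f",
                        epoch, ep_loss, mean(abs(err)), mean(err^2)))
    }
  })

  structure(list(model = model, log = do.call(rbind, log_rows),
                 bins = bins, kernel = kernel),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "<train_result> %d epochs: loss %.5g, train MAE %.3f, train MSE %.3f\n",
    last$epoch, last$loss, last$mae, last$mse))
  invisible(x)
}

#' Write a per-epoch training log as CSV
#' @param result a [train_model()] result.
#' @param path output CSV path (columns epoch, loss, ld, lc, mae, mse).
#' @return `path`, invisibly.
#' @export
write_train_log <- function(result, path) {
  stopifnot(inherits(result, "train_result"))
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}
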