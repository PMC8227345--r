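#' Network architecture configuration
#'
#' Describes either the plain MCNN density regressor or the improved
#' multi-task network.
#'
#' The MCNN runs three parallel convolutional columns with large (L),
#' medium (M) and small (S) receptive fields over the same image — four
#' convolutions per column, 2x2 max pools after the first two, ReLU
#' activations — and merges the concatenated column outputs with a
#' learnable 1x1 convolution into a single-channel density map at 1/4 the
#' input resolution. Columns with larger kernels carry fewer channels to
#' keep the parameter count balanced. Default channel plan:
#' L 9x9/16, 7x7/32, 7x7/16, 7x7/8; M 7x7/20, 5x5/40, 5x5/20, 5x5/10;
#' S 5x5/24, 3x3/48, 3x3/24, 3x3/12.
#'
#' The improved network replaces the columns with three identical
#' 7x7/20, 5x5/40, 5x5/20, 5x5/10 columns (PReLU), adds a count-level
#' prior branch — four convolutions with pools after the first two,
#' spatial pyramid pooling over 1+4+16 blocks, and three fully connected
#' layers ending in `n_classes` count-bin logits — and fuses the prior
#' branch's last convolutional feature map into the density head: two 3x3
#' fusion convolutions (24, 32 channels), two stride-2 transposed
#' convolutions (16, 18 channels) that restore full input resolution, and
#' a final 1x1 convolution with ReLU so densities are nonnegative.
#'
#' @param kind `"mcnn"` or `"improved"`.
#' @param n_classes number of count bins M for the prior classifier (>= 2).
#' @param lambda weight of the classification loss in the total loss
#'   `L = lambda * Lc + Ld`.
#' @param columns optional list of three column specs, each
#'   `list(kernels =, channels =, pool_after =)`; defaults as above.
#' @param prior optional prior-branch spec
#'   (`kernels`, `channels`, `pool_after`, `spp_levels`, `fc`).
#' @param head optional head spec (`fusion_channels`, `deconv_channels`).
#' @param init_sd standard deviation of the centered normal weight
#'   initialization.
#' @return An object of class `model_config`.
#' @examples
#' model_config("mcnn")
#' model_config("improved", n_classes = 5)
#' @export
model_config <- function(kind = c("mcnn", "improved"), n_classes = 5L,
                         lambda = 1e-4, columns = NULL, prior = NULL,
                         head = NULL, init_sd = 0.01) {
  kind <- match.arg(kind)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(columns)) {
    columns <- if (kind == "mcnn") list(
      L = list(kernels = c(9L, 7L, 7L, 7L), channels = c(16L, 32L, 16L, 8L),
               pool_after = c(1L, 2L)),
      M = list(kernels = c(7L, 5L, 5L, 5L), channels = c(20L, 40L, 20L, 10L),
               pool_after = c(1L, 2L)),
      S = list(kernels = c(5L, 3L, 3L, 3L), channels = c(24L, 48L, 24L, 12L),
               pool_after = c(1L, 2L))
    ) else {
      one <- list(kernels = c(7L, 5L, 5L, 5L), channels = c(20L, 40L, 20L, 10L),
                  pool_after = c(1L, 2L))
      list(L = one, M = one, S = one)
    }
  }
  for (cs in columns) {
    if (length(cs$kernels) != 4L || length(cs$channels) != 4L)
      stop("each column must have exactly 4 convolutional layers")
    if (any(cs$kernels %% 2L == 0L)) stop("kernels must be odd")
    if (any(cs$channels < 1L)) stop("channels must be >= 1")
  }
  if (is.null(prior)) prior <- list(
    kernels = c(5L, 5L, 5L, 5L), channels = c(16L, 32L, 16L, 8L),
    pool_after = c(1L, 2L), spp_levels = c(1L, 2L, 4L), fc = c(512L, 256L)
  )
  if (is.null(head)) head <- list(fusion_channels = c(24L, 32L),
                                  deconv_channels = c(16L, 18L))
  structure(
    list(kind = kind, n_classes = as.integer(n_classes), lambda = lambda,
         columns = columns, prior = prior, head = head, init_sd = init_sd),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s, %d count classes, lambda %g\n",
              x$kind, x$n_classes, x$lambda))
  invisible(x)
}

#' Build a network from a configuration
#'
#' Initializes all weights from a centered normal (sd `init_sd`), biases at
#' zero, deterministically from `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return An object of class `seedcount_model` holding the native network
#'   and its configuration.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  cfg <- list(init_sd = config$init_sd, columns = unname(config$columns))
  if (config$kind == "improved") {
    cfg$prior <- c(config$prior, list(n_classes = config$n_classes))
    cfg$head <- config$head
  }
  ptr <- net_create(config$kind, cfg, as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "seedcount_model")
}

#' @export
print.seedcount_model <- function(x, ...) {
  cat(sprintf("<seedcount_model> %s, %s parameters\n", x$config$kind,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

.check_input_image <- function(model, image) {
  image <- .as_gray(image)
  h <- nrow(image); w <- ncol(image)
  if (h %% 4L != 0L || w %% 4L != 0L)
    stop(sprintf(paste0("input %dx%d: both sides must be divisible by 4 ",
                        "(two stride-2 pools); pad the image first"), h, w))
  if (model$config$kind == "improved" && (h < 16L || w < 16L))
    stop("improved network needs inputs of at least 16x16 px ",
         "(so the pooled feature map can form the 4x4 pyramid blocks)")
  image
}

# accept grayscale matrix or H x W x C array (RGB averaged to luma)
.as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    ch <- dim(image)[3L]
    if (ch >= 3L)
      return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
    return(image[, , 1L])
  }
  stop("image must be a matrix or an H x W x C array")
}

#' Run a network forward on one image
#'
#' @param object a [build_model()] network.
#' @param image grayscale matrix (or RGB array) with values in `[0, 1]`,
#'   both sides divisible by 4; the improved network additionally needs
#'   at least 16 px per side.
#' @param ... unused.
#' @return A list with `density` (a [density_map()]: scale 4 at 1/4
#'   resolution for the MCNN, scale 1 at full resolution for the improved
#'   network) and, for the improved network, `logits` (length
#'   `n_classes`) and `probs` (its softmax).
#' @export
predict.seedcount_model <- function(object, image, ...) {
  image <- .check_input_image(object, image)
  out <- net_forward_cpp(object$ptr, image)
  scale <- if (object$config$kind == "mcnn") 4L else 1L
  res <- list(density = density_map(pmax(out$density, 0), scale = scale))
  if (!is.null(out$logits)) {
    res$logits <- out$logits
    res$probs <- .softmax(out$logits)
  }
  res
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Count-bin prior forward pass
#'
#' Classifier head of the improved network: returns the count-bin logits
#' together with the prior branch's last convolutional feature map (the
#' features that the density head consumes).
#'
#' @param model an improved-kind [build_model()] network.
#' @param image input image as in [predict.seedcount_model()].
#' @return List with `logits`, `probs` and `density` as in `predict`.
#' @export
prior_forward <- function(model, image) {
  stopifnot(inherits(model, "seedcount_model"))
  if (model$config$kind != "improved")
    stop("prior_forward requires an improved-kind model")
  predict(model, image)
}

#' Spatial pyramid pooling
#'
#' Per channel, the maximum over each block of the 1x1, 2x2 and 4x4
#' partitions of the spatial grid (floor-boundary blocks that tile the
#' grid exactly): 21 values per channel by default, independent of the
#' input's spatial size.
#'
#' @param x numeric matrix (one channel) or H x W x C array.
#' @param levels pyramid levels; default `c(1, 2, 4)`.
#' @return Numeric vector of length `sum(levels^2) * C`, channel-major:
#'   for each channel, all levels in order, blocks within a level in
#'   column-major order.
#' @examples
#' spp_pool(matrix(2, 8, 8))  # 21 values, all 2
#' @export
spp_pool <- function(x, levels = c(1L, 2L, 4L)) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a matrix or a 3-d array")
  if (min(d[1L], d[2L]) < max(levels))
    stop(sprintf("spatial size %dx%d cannot form %d blocks per side",
                 d[1L], d[2L], max(levels)))
  spp_pool_cpp(as.numeric(x), d[1L], d[2L], d[3L], as.integer(levels))
}

#' Exact learnable-parameter count
#'
#' @param model a [build_model()] network.
#' @return Number of scalar learnable parameters (weights, biases, PReLU
#'   slopes).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seedcount_model"))
  net_param_count(model$ptr)
}

#' Extract all network parameters
#' @param model a [build_model()] network.
#' @return Named list of numeric matrices, one per parameter tensor.
#' @export
model_parameters <- function(model) {
  stopifnot(inherits(model, "seedcount_model"))
  net_get_params(model$ptr)
}

#' Overwrite network parameters (by name)
#' @param model a [build_model()] network.
#' @param values named list as returned by [model_parameters()]; tensors
#'   not named are left untouched.
#' @return `model`, invisibly (the native network is modified in place).
#' @export
set_model_parameters <- function(model, values) {
  stopifnot(inherits(model, "seedcount_model"))
  net_set_params(model$ptr, values)
  invisible(model)
}

#' Save a model checkpoint
#'
#' Writes the parameters together with a JSON sidecar recording the
#' architecture configuration and seeds.
#'
#' @param model a [build_model()] network.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seedcount_model"))
  saveRDS(list(config = model$config, seed = model$seed,
               params = model_parameters(model)), path)
  sidecar <- list(kind = model$config$kind,
                  n_classes = model$config$n_classes,
                  lambda = model$config$lambda, seed = model$seed,
                  n_parameters = count_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return A `seedcount_model` with the stored parameters.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config, seed = obj$seed)
  set_model_parameters(model, obj$params)
  model
}
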