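#' Gaussian kernel specification for density-map generation
#'
#' In `"fixed"` mode every annotation is smoothed with the same bandwidth
#' `sigma_fixed`. In `"adaptive"` mode (the geometry-adaptive kernel) each
#' annotation i gets its own bandwidth `sigma_i = beta * dbar_i`, where
#' `dbar_i` is the mean Euclidean distance from point i to its `neighbors_m`
#' nearest annotated neighbours, so densely packed (small, adhering) grains
#' get narrow kernels and sparse grains wide ones.
#'
#' @param mode `"adaptive"` or `"fixed"`.
#' @param sigma_fixed bandwidth in pixels (> 0), required for fixed mode;
#'   in adaptive mode it serves as the fallback bandwidth for single-point
#'   images.
#' @param beta dimensionless proportionality factor between the neighbour
#'   distance and sigma; 0.3 gives the best density maps for rice grains.
#' @param neighbors_m number of nearest neighbours averaged (>= 1).
#' @param truncation_sigmas kernel support cutoff: each Gaussian is evaluated
#'   within `truncation_sigmas * sigma` pixels of its center and zero beyond.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec()                       # adaptive, beta = 0.3, m = 3
#' kernel_spec("fixed", sigma_fixed = 2)
#' @export
kernel_spec <- function(mode = c("adaptive", "fixed"), sigma_fixed = NULL,
                        beta = 0.3, neighbors_m = 3L,
                        truncation_sigmas = 4.0) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(sigma_fixed) || !is.numeric(sigma_fixed) || sigma_fixed <= 0)
      stop("fixed mode requires sigma_fixed > 0")
  } else {
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
      stop("adaptive mode requires beta > 0")
    if (neighbors_m < 1L) stop("neighbors_m must be >= 1")
  }
  if (truncation_sigmas <= 0) stop("truncation_sigmas must be > 0")
  structure(
    list(mode = mode, sigma_fixed = sigma_fixed, beta = beta,
         neighbors_m = as.integer(neighbors_m),
         truncation_sigmas = truncation_sigmas),
    class = "kernel_spec"
  )
}

#' Mean distance to the m nearest annotated neighbours
#'
#' For each annotation point, the mean Euclidean distance to its
#' `min(m, N - 1)` nearest other points, in input order. This is the local
#' grain-spacing estimate that drives the adaptive kernel bandwidth.
#'
#' @param ann a [point_annotations] object.
#' @param m number of neighbours (>= 1).
#' @return Numeric vector of length `n_points(ann)`; `NA` for the single
#'   point of a one-point image (no neighbour exists); empty for an empty
#'   annotation list.
#' @examples
#' ann <- point_annotations(cbind(c(0, 3, 6), c(0, 0, 0)), c(16, 16))
#' mean_neighbor_distance(ann, m = 1)  # 3 3 3
#' @export
mean_neighbor_distance <- function(ann, m = 3L) {
  stopifnot(inherits(ann, "point_annotations"))
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  n <- n_points(ann)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(NA_real_)
  d <- as.matrix(stats::dist(ann$points))
  k <- min(m, n - 1L)
  vapply(seq_len(n), function(i) {
    di <- sort(d[i, -i], partial = k)[seq_len(k)]
    mean(di)
  }, numeric(1))
}

#' Per-point adaptive kernel bandwidths
#'
#' `sigma_i = beta * dbar_i` with `dbar_i` from [mean_neighbor_distance()].
#' A single-point image has no neighbour distance; its sigma falls back to
#' `sigma_fixed` when set, else to `min(0.1 * min(image_shape), 15)` pixels.
#'
#' @param ann a [point_annotations] object.
#' @param spec an adaptive-mode [kernel_spec].
#' @return Numeric vector of positive bandwidths, one per point.
#' @export
adaptive_sigmas <- function(ann, spec = kernel_spec()) {
  stopifnot(inherits(ann, "point_annotations"), inherits(spec, "kernel_spec"))
  if (spec$mode != "adaptive") stop("adaptive_sigmas requires an adaptive kernel_spec")
  n <- n_points(ann)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(.fallback_sigma(ann, spec))
  dbar <- mean_neighbor_distance(ann, spec$neighbors_m)
  sig <- spec$beta * dbar
  # coincident duplicate points give dbar 0; keep sigma positive
  sig[sig <= 0] <- .fallback_sigma(ann, spec)
  sig
}

.fallback_sigma <- function(ann, spec) {
  if (!is.null(spec$sigma_fixed)) return(spec$sigma_fixed)
  min(0.1 * min(ann$image_shape), 15)
}

#' Ground-truth density map from point annotations
#'
#' Places one discretely renormalized truncated Gaussian per annotation:
#' the kernel is evaluated at pixel centers within
#' `truncation_sigmas * sigma` of the point, clipped at the image border,
#' and divided by its own sum, so each grain contributes exactly unit mass
#' and the map total equals the grain count.
#'
#' @param ann a [point_annotations] object.
#' @param spec a [kernel_spec]; adaptive by default.
#' @return A `density_map` object (see [density_map()]) at scale 1 with
#'   `sum(values) == n_points(ann)` up to floating-point rounding.
#' @examples
#' ann <- point_annotations(cbind(8, 8), c(17, 17))
#' dm <- generate_density_map(ann, kernel_spec("fixed", sigma_fixed = 2))
#' sum(dm$values)  # 1
#' @export
generate_density_map <- function(ann, spec = kernel_spec()) {
  stopifnot(inherits(ann, "point_annotations"), inherits(spec, "kernel_spec"))
  h <- ann$image_shape[1L]; w <- ann$image_shape[2L]
  vals <- matrix(0, h, w)
  n <- n_points(ann)
  if (n == 0L)
    return(density_map(vals, scale = 1L, image_id = ann$image_id))
  sig <- if (spec$mode == "fixed") rep(spec$sigma_fixed, n)
         else adaptive_sigmas(ann, spec)
  for (i in seq_len(n)) {
    x <- ann$points[i, 1L]; y <- ann$points[i, 2L]; s <- sig[i]
    r <- ceiling(spec$truncation_sigmas * s)
    # pixel-center coordinates are 0-based; peak lands on the nearest pixel
    cx0 <- max(0L, floor(x - r)); cx1 <- min(w - 1L, ceiling(x + r))
    cy0 <- max(0L, floor(y - r)); cy1 <- min(h - 1L, ceiling(y + r))
    xs <- cx0:cx1; ys <- cy0:cy1
    dx2 <- (xs - x)^2; dy2 <- (ys - y)^2
    g <- exp(-(outer(dy2, dx2, "+")) / (2 * s^2))
    g[outer(dy2, dx2, "+") > (spec$truncation_sigmas * s)^2] <- 0
    tot <- sum(g)
    if (tot <= 0) { # degenerate: deposit the whole mass on the nearest pixel
      vals[round(y) + 1L, round(x) + 1L] <- vals[round(y) + 1L, round(x) + 1L] + 1
      next
    }
    vals[ys + 1L, xs + 1L] <- vals[ys + 1L, xs + 1L] + g / tot
  }
  density_map(vals, scale = 1L, image_id = ann$image_id)
}

#' Density map container
#'
#' A nonnegative grid whose total mass equals the (possibly fractional)
#' grain count it encodes. `scale` records the ratio of source-image
#' resolution to grid resolution (1 for full resolution, 4 for the MCNN's
#' quarter-resolution output).
#'
#' @param values nonnegative numeric matrix.
#' @param scale integer in `{1, 2, 4}`.
#' @param image_id source image identifier.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, scale = 1L, image_id = "image") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0)) stop("density values must be nonnegative")
  scale <- as.integer(scale)
  if (!scale %in% c(1L, 2L, 4L)) stop("scale must be 1, 2 or 4")
  structure(list(values = values, scale = scale,
                 image_id = as.character(image_id)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> '%s': %dx%d grid, scale %d, mass %.4f\n",
              x$image_id, nrow(x$values), ncol(x$values), x$scale,
              sum(x$values)))
  invisible(x)
}

#' @export
as.matrix.density_map <- function(x, ...) x$values

#' Count-preserving block-sum downsampling
#'
#' Sums non-overlapping `factor x factor` blocks, so the map total (the
#' count) is preserved exactly while the grid shrinks to the network output
#' resolution.
#'
#' @param map a [density_map()].
#' @param factor 2 or 4; must divide both grid dimensions.
#' @return A `density_map` with `scale = map$scale * factor`.
#' @export
downsample_density <- function(map, factor) {
  stopifnot(inherits(map, "density_map"))
  factor <- as.integer(factor)
  if (!factor %in% c(2L, 4L)) stop("factor must be 2 or 4")
  v <- map$values
  h <- nrow(v); w <- ncol(v)
  if (h %% factor != 0L || w %% factor != 0L)
    stop(sprintf(
      "grid %dx%d is not divisible by %d; pad the map (or source image) first",
      h, w, factor))
  ho <- h %/% factor; wo <- w %/% factor
  # fold rows then columns
  v1 <- rowsum(v, rep(seq_len(ho), each = factor))
  out <- t(rowsum(t(v1), rep(seq_len(wo), each = factor)))
  dimnames(out) <- NULL
  new_scale <- map$scale * factor
  if (!new_scale %in% c(1L, 2L, 4L))
    stop("resulting scale ", new_scale, " exceeds the supported range")
  density_map(out, scale = new_scale, image_id = map$image_id)
}

#' Write a density map to disk
#'
#' Stores the grid, scale and image id in R's portable serialized array
#' container (`.rds`).
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  saveRDS(list(values = map$values, scale = map$scale,
               image_id = map$image_id), path)
  invisible(path)
}

#' Read a density map written by [write_density()]
#' @param path input path.
#' @return A [density_map()].
#' @export
read_density <- function(path) {
  obj <- readRDS(path)
  density_map(obj$values, obj$scale, obj$image_id)
}

#' Render a density map as a PNG heat map
#'
#' Inspection aid: normalizes the map to its maximum and writes an
#' inferno-like false-color PNG.
#'
#' @param map a [density_map()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
density_png <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  mx <- max(v)
  if (mx > 0) v <- v / mx
  pal <- grDevices::colorRamp(c("black", "darkred", "orange", "yellow", "white"))
  rgbv <- pal(as.vector(v)) / 255
  arr <- array(rgbv, dim = c(nrow(v), ncol(v), 3L))
  png::writePNG(arr, path)
  invisible(path)
}
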