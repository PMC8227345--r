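#' Configuration of the synthetic seed-image generator
#'
#' Emulates the structure of bench-top rice photographs: bright grains
#' (filled rotated ellipses with a darker split line along the major axis)
#' on a dark background, at one of three shape classes and three viewing
#' conditions, with optional grain adhesion (touching/overlapping grains)
#' and additive sensor noise. Each grain contributes exactly one annotation
#' at its (possibly warped) center.
#'
#' Shape-class defaults (major-axis mean in px / minor-to-major axis ratio):
#' elongated 16 / 0.35, short_oval 11 / 0.75, long_oval 13 / 0.55 —
#' long thin indica-like grains, short broad japonica-like grains, and an
#' intermediate oval, respectively.
#'
#' Viewing conditions: `top_far` shrinks all grains (scale 0.75), `top_near`
#' enlarges them (scale 1.15), `oblique` applies a fixed projective warp to
#' the rendered image and its annotation points.
#'
#' @param image_shape `c(height, width)` in pixels (even values recommended
#'   so crops and pooling tile exactly).
#' @param count_range `c(min, max)` grains per image, drawn uniformly.
#' @param shape_class `"elongated"`, `"short_oval"` or `"long_oval"`.
#' @param axis_major `c(mean, sd)` of the grain major axis in px; `NULL`
#'   uses the shape-class default.
#' @param axis_ratio `c(mean, sd)` of the minor/major axis ratio; `NULL`
#'   uses the shape-class default.
#' @param adhesion_prob probability that a grain is deliberately placed
#'   tangent to / overlapping an earlier grain.
#' @param max_overlap_frac maximum fractional overlap of effective radii for
#'   adhering grains, in `[0, 1]`.
#' @param perspective `"top_far"`, `"top_near"` or `"oblique"`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensities live in `[0, 1]`).
#' @param rng_seed integer seed; the sample is fully determined by it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_shape = c(192L, 192L),
                         count_range = c(20L, 60L),
                         shape_class = c("elongated", "short_oval", "long_oval"),
                         axis_major = NULL, axis_ratio = NULL,
                         adhesion_prob = 0.15, max_overlap_frac = 0.3,
                         perspective = c("top_far", "top_near", "oblique"),
                         noise_sd = 0.02, rng_seed = 1L) {
  shape_class <- match.arg(shape_class)
  perspective <- match.arg(perspective)
  defaults <- list(
    elongated  = list(major = c(16, 2.0), ratio = c(0.35, 0.05)),
    short_oval = list(major = c(11, 1.5), ratio = c(0.75, 0.06)),
    long_oval  = list(major = c(13, 1.8), ratio = c(0.55, 0.05))
  )[[shape_class]]
  if (is.null(axis_major)) axis_major <- defaults$major
  if (is.null(axis_ratio)) axis_ratio <- defaults$ratio
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            length(count_range) == 2L, count_range[1L] >= 0L,
            count_range[2L] >= count_range[1L],
            adhesion_prob >= 0, adhesion_prob <= 1,
            max_overlap_frac >= 0, max_overlap_frac <= 1,
            axis_major[2L] >= 0, axis_ratio[2L] >= 0, noise_sd >= 0)
  structure(
    list(image_shape = as.integer(image_shape),
         count_range = as.integer(count_range),
         shape_class = shape_class,
         axis_major = as.numeric(axis_major),
         axis_ratio = as.numeric(axis_ratio),
         adhesion_prob = adhesion_prob,
         max_overlap_frac = max_overlap_frac,
         perspective = perspective,
         noise_sd = noise_sd,
         rng_seed = as.integer(rng_seed)),
    class = "synth_config"
  )
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one synthetic seed sample
#'
#' Draws `N ~ Uniform(count_range)` grains sequentially. A non-adhering
#' grain is rejection-placed so its center keeps clear of every earlier
#' grain (center distance above the sum of effective radii); with
#' probability `adhesion_prob` a grain is instead placed tangent to or
#' overlapping a random earlier grain (overlap up to `max_overlap_frac` of
#' the summed effective radii) and both grains are flagged as adhering.
#' If a placement cannot be found within a bounded number of retries the
#' grain is dropped, so the annotation list always matches what was drawn.
#'
#' @param config a [synth_config()].
#' @return An object of class `seed_sample`: list with `image` (h x w
#'   matrix in `[0, 1]`), `annotations` ([point_annotations]), `adhered`
#'   (logical per grain), `count_class` (`NA` until assigned by
#'   [count_to_class()]), and `config`.
#' @examples
#' s <- render_sample(synth_config(image_shape = c(64, 64),
#'                                 count_range = c(5, 5), rng_seed = 7))
#' n_points(s$annotations)  # 5
#' @export
render_sample <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$rng_seed, .render_sample_impl(config))
}

.render_sample_impl <- function(config) {
  h <- config$image_shape[1L]; w <- config$image_shape[2L]
  persp_scale <- switch(config$perspective,
                        top_far = 0.75, top_near = 1.15, oblique = 1.0)
  n_target <- if (config$count_range[1L] == config$count_range[2L])
    config$count_range[1L]
  else sample(config$count_range[1L]:config$count_range[2L], 1L)

  img <- matrix(0.08, h, w)
  centers <- matrix(numeric(0), ncol = 2L)   # (x, y)
  radii <- numeric(0)                        # effective radius sqrt(a*b)
  minors <- numeric(0)
  adhered <- logical(0)

  i <- 0L
  while (i < n_target) {
    i <- i + 1L
    major <- max(3, rnorm(1, config$axis_major[1L], config$axis_major[2L])) * persp_scale
    ratio <- min(0.95, max(0.15, rnorm(1, config$axis_ratio[1L], config$axis_ratio[2L])))
    a <- major / 2; b <- a * ratio
    reff <- sqrt(a * b)
    theta <- runif(1, 0, pi)
    margin <- a + 1
    if (2 * margin >= min(h, w)) { i <- i; next } # grain larger than frame
    placed <- FALSE
    adhere_this <- nrow(centers) > 0L && runif(1) < config$adhesion_prob
    for (try in seq_len(60L)) {
      if (adhere_this) {
        j <- sample.int(nrow(centers), 1L)
        u <- runif(1)
        dctr <- (reff + radii[j]) * (1 - u * config$max_overlap_frac)
        ang <- runif(1, 0, 2 * pi)
        cx <- centers[j, 1L] + dctr * cos(ang)
        cy <- centers[j, 2L] + dctr * sin(ang)
        if (cx < margin || cx > w - 1 - margin ||
            cy < margin || cy > h - 1 - margin) next
        # must not crash into grains other than the chosen partner
        if (nrow(centers) > 1L) {
          others <- setdiff(seq_len(nrow(centers)), j)
          dd <- sqrt((centers[others, 1L] - cx)^2 + (centers[others, 2L] - cy)^2)
          if (any(dd < (radii[others] + reff) * 0.9)) next
        }
        placed <- TRUE
      } else {
        cx <- runif(1, margin, w - 1 - margin)
        cy <- runif(1, margin, h - 1 - margin)
        if (nrow(centers) > 0L) {
          dd <- sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)
          if (any(dd < (radii + reff) * 1.05)) next
        }
        placed <- TRUE
      }
      if (placed) break
    }
    if (!placed) next  # dropped; fewer grains than targeted
    img <- .draw_grain(img, cx, cy, a, b, theta)
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, reff)
    minors <- c(minors, b)
    if (adhere_this) {
      adhered[j] <- TRUE
      adhered <- c(adhered, TRUE)
    } else adhered <- c(adhered, FALSE)
  }

  if (config$perspective == "oblique" && nrow(centers) > 0L) {
    warped <- .oblique_warp(img, centers)
    img <- warped$image
    centers <- warped$points
  } else if (config$perspective == "oblique") {
    img <- .oblique_warp(img, centers)$image
  }

  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
  img <- pmin(pmax(img, 0), 1)

  ann <- point_annotations(centers, c(h, w),
                           image_id = sprintf("synth_%d", config$rng_seed))
  structure(
    list(image = img, annotations = ann, adhered = adhered,
         count_class = NA_integer_, minors = minors, config = config),
    class = "seed_sample"
  )
}

# filled rotated ellipse with a dark split line along the major axis
.draw_grain <- function(img, cx, cy, a, b, theta) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(a) + 1L
  xs <- max(0L, floor(cx - r)):min(w - 1L, ceiling(cx + r))
  ys <- max(0L, floor(cy - r)):min(h - 1L, ceiling(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a     # along major axis
  v <- (-dx * sin(theta) + dy * cos(theta)) / b    # along minor axis
  inside <- (u^2 + v^2) <= 1
  base <- runif(1, 0.65, 0.85)
  shade <- base * (1 - 0.35 * exp(-(v / 0.25)^2)) * (1 - 0.15 * abs(u))
  patch <- img[ys + 1L, xs + 1L]
  patch[inside] <- pmax(patch[inside], shade[inside])
  img[ys + 1L, xs + 1L] <- patch
  img
}

# fixed projective warp: rows farther down the frame shrink toward the
# principal point, approximating an oblique top view
.oblique_warp <- function(img, points, p = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(p)) p <- 0.35 / h
  # forward map: (x, y) -> ((x - cx)/(1 + p y) + cx', y/(1 + p y))
  cx <- (w - 1) / 2
  fwd <- function(x, y) {
    d <- 1 + p * y
    cbind(cx + (x - cx) / d, y / d)
  }
  # inverse for image resampling: y = y'/(1 - p y'), x = cx + (x' - cx) * d
  out <- matrix(0.08, h, w)
  yy <- 0:(h - 1); xx <- 0:(w - 1)
  ysrc <- yy / (1 - p * yy)
  valid_y <- ysrc >= 0 & ysrc <= h - 1
  for (j in seq_along(xx)) {
    d <- 1 + p * ysrc
    xsrc <- cx + (xx[j] - cx) * d
    ok <- valid_y & xsrc >= 0 & xsrc <= w - 1
    out[ok, j] <- img[cbind(round(ysrc[ok]) + 1L, round(xsrc[ok]) + 1L)]
  }
  pts <- if (nrow(points) > 0L) fwd(points[, 1L], points[, 2L]) else points
  list(image = out, points = pts)
}

#' @export
print.seed_sample <- function(x, ...) {
  cat(sprintf("<seed_sample> %dx%d image, %d grains (%d adhering)\n",
              nrow(x$image), ncol(x$image), n_points(x$annotations),
              sum(x$adhered)))
  invisible(x)
}

#' Quarter-size ten-crop augmentation
#'
#' Splits a sample into 10 crops of half height x half width (one quarter
#' of the original area): the 4 quadrants, the center crop, and 5
#' random-offset crops. Crop membership of a point is half-open
#' (`[x0, x0 + w/2)` x `[y0, y0 + h/2)`, left/top edges inclusive), so the
#' four quadrants partition the annotations exactly.
#'
#' @param sample a `seed_sample` (or any list with `image` and
#'   `annotations`).
#' @param seed seed for the 5 random crop offsets.
#' @return List of 10 `seed_sample` objects with re-based annotations.
#' @export
ten_crop <- function(sample, seed = 0L) {
  img <- sample$image
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("image must be at least 2x2")
  h2 <- h %/% 2L; w2 <- w %/% 2L
  origins <- rbind(
    c(0L, 0L), c(0L, w2), c(h2, 0L), c(h2, w2),          # quadrants
    c((h - h2) %/% 2L, (w - w2) %/% 2L)                  # center
  )
  rand <- .with_seed(seed, cbind(sample.int(h - h2 + 1L, 5L, replace = TRUE) - 1L,
                                 sample.int(w - w2 + 1L, 5L, replace = TRUE) - 1L))
  origins <- rbind(origins, rand)
  lapply(seq_len(nrow(origins)), function(i) {
    y0 <- origins[i, 1L]; x0 <- origins[i, 2L]
    .crop_sample(sample, y0, x0, h2, w2, i)
  })
}

.crop_sample <- function(sample, y0, x0, hc, wc, tag) {
  img <- sample$image[(y0 + 1L):(y0 + hc), (x0 + 1L):(x0 + wc), drop = FALSE]
  pts <- sample$annotations$points
  keep <- if (nrow(pts) > 0L)
    pts[, 1L] >= x0 & pts[, 1L] < x0 + wc & pts[, 2L] >= y0 & pts[, 2L] < y0 + hc
  else logical(0)
  newpts <- pts[keep, , drop = FALSE]
  if (nrow(newpts) > 0L) {
    newpts[, 1L] <- newpts[, 1L] - x0
    newpts[, 2L] <- newpts[, 2L] - y0
  }
  ann <- point_annotations(newpts, c(hc, wc),
                           image_id = paste0(sample$annotations$image_id, "_crop", tag))
  structure(
    list(image = img, annotations = ann,
         adhered = if (length(sample$adhered)) sample$adhered[keep] else logical(0),
         count_class = NA_integer_, config = sample$config),
    class = "seed_sample"
  )
}

#' Build a deterministic synthetic dataset
#'
#' Renders `n_per_config` samples per configuration; sample k of
#' configuration j uses an RNG stream derived from
#' `(config$rng_seed, k)` so generation is reproducible (and would remain
#' so under parallel generation). With `dir` set, images are written as
#' PNG, annotations as JSON, and a `manifest.csv`
#' (`image_path, annotation_path, count`) indexes the dataset.
#'
#' @param configs a [synth_config()] or list of them.
#' @param n_per_config samples per configuration (>= 1).
#' @param dir optional output directory.
#' @return Invisibly (if `dir` given) or visibly, the list of
#'   `seed_sample` objects.
#' @export
build_dataset <- function(configs, n_per_config = 1L, dir = NULL) {
  if (inherits(configs, "synth_config")) configs <- list(configs)
  stopifnot(n_per_config >= 1L)
  samples <- list()
  for (cfg in configs) {
    for (k in seq_len(n_per_config)) {
      cfg_k <- cfg
      cfg_k$rng_seed <- as.integer((as.double(cfg$rng_seed) * 10007 + k) %% 2147483647)
      samples[[length(samples) + 1L]] <- render_sample(cfg_k)
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      ip <- file.path(dir, sprintf("sample_%04d.png", i))
      ap <- file.path(dir, sprintf("sample_%04d.json", i))
      png::writePNG(s$image, ip)
      write_annotations(s$annotations, ap)
      data.frame(image_path = basename(ip), annotation_path = basename(ap),
                 count = n_points(s$annotations))
    })
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    return(invisible(samples))
  }
  samples
}
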