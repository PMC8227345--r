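#' Count encoded by a density map
#'
#' The (fractional) count is the total mass of the map; density maps are
#' count-normalized at every scale, so no scale correction applies.
#' Rounding to whole grains is a separate, explicit step.
#'
#' @param map a [density_map()] or plain matrix.
#' @return Nonnegative scalar.
#' @export
count_from_density <- function(map) {
  v <- if (inherits(map, "density_map")) map$values else map
  sum(v)
}

.as_pairs <- function(pairs) {
  p <- as.matrix(pairs)
  if (ncol(p) != 2L) stop("pairs must have two columns (true, predicted)")
  storage.mode(p) <- "double"
  p
}

#' Mean absolute counting error
#'
#' `MAE = (1/n) sum_i |y_i - yhat_i|` over per-image (true, predicted)
#' count pairs; fractional predictions are used as-is.
#'
#' @param pairs two-column matrix or data frame: true count, predicted
#'   count.
#' @return Nonnegative scalar in grains.
#' @export
count_mae <- function(pairs) {
  p <- .as_pairs(pairs)
  mean(abs(p[, 1L] - p[, 2L]))
}

#' Mean squared counting error
#'
#' `MSE = (1/n) sum_i (y_i - yhat_i)^2` — the mean of squared errors, not
#' its square root.
#'
#' @inheritParams count_mae
#' @return Nonnegative scalar in grains squared.
#' @export
count_mse <- function(pairs) {
  p <- .as_pairs(pairs)
  mean((p[, 1L] - p[, 2L])^2)
}

#' Count-ratio accuracy
#'
#' Per image, `100 * max(0, 1 - |round(yhat) - y| / y)` (an image with a
#' zero true count scores 100 iff the rounded prediction is also zero);
#' the reported ACC is the mean over images. Predictions are rounded
#' half-up to whole grains before comparison.
#'
#' @inheritParams count_mae
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
count_accuracy <- function(pairs) {
  p <- .as_pairs(pairs)
  y <- p[, 1L]; yh <- floor(p[, 2L] + 0.5)
  acc <- ifelse(y > 0, pmax(0, 1 - abs(yh - y) / y),
                as.numeric(yh == 0))
  100 * mean(acc)
}

#' Detection matching specification
#'
#' @param peak_threshold minimum density value for a local maximum to
#'   count as a detection, as a fraction of the per-map maximum (in
#'   `(0, 1]`).
#' @param match_radius maximum center distance (source-image px) for a
#'   detection to match a ground-truth point; `NULL` defers to the
#'   caller's per-image choice (mean adaptive sigma).
#' @param min_separation non-maximum-suppression radius in source px.
#' @return An object of class `match_spec`.
#' @export
match_spec <- function(peak_threshold = 0.05, match_radius = NULL,
                       min_separation = 2) {
  stopifnot(peak_threshold > 0, peak_threshold <= 1, min_separation > 0,
            is.null(match_radius) || match_radius > 0)
  structure(list(peak_threshold = peak_threshold,
                 match_radius = match_radius,
                 min_separation = min_separation),
            class = "match_spec")
}

#' Grain detections from a density map
#'
#' Local maxima (8-neighborhood) above `peak_threshold * max(map)`,
#' non-maximum-suppressed at `min_separation`, returned in descending
#' peak order as (x, y) source-image pixel coordinates (grid coordinates
#' are mapped back through the map's `scale`).
#'
#' @param map a [density_map()].
#' @param spec a [match_spec()].
#' @return Numeric matrix with columns `x`, `y`, `peak`; zero rows for an
#'   all-zero map.
#' @export
detect_grains <- function(map, spec = match_spec()) {
  stopifnot(inherits(map, "density_map"), inherits(spec, "match_spec"))
  v <- map$values
  empty <- matrix(numeric(0), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "peak")))
  mx <- max(v)
  if (mx <= 0) return(empty)
  thr <- spec$peak_threshold * mx
  h <- nrow(v); w <- ncol(v)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- v
  is_max <- v >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
    # strict inequality against earlier neighbors, non-strict against
    # later ones: exactly one winner per tied plateau pair
    if (dy < 0L || (dy == 0L && dx < 0L)) is_max <- is_max & (v > nb)
    else is_max <- is_max & (v >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  peaks <- v[idx]
  ord <- order(peaks, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; peaks <- peaks[ord]
  # grid -> source-image coordinates (pixel centers)
  s <- map$scale
  xs <- (idx[, 2L] - 1L + 0.5) * s - 0.5
  ys <- (idx[, 1L] - 1L + 0.5) * s - 0.5
  keep <- rep(TRUE, length(peaks))
  for (i in seq_along(peaks)) {
    if (!keep[i]) next
    if (i < length(peaks)) {
      j <- (i + 1L):length(peaks)
      d2 <- (xs[j] - xs[i])^2 + (ys[j] - ys[i])^2
      keep[j][d2 < spec$min_separation^2] <- FALSE
    }
  }
  cbind(x = xs[keep], y = ys[keep], peak = peaks[keep])
}

#' Greedy one-to-one matching of detections against ground truth
#'
#' Candidate pairs within `radius` are matched greedily by ascending
#' distance, each detection and each truth point used at most once.
#' TP = matched pairs, FP = unmatched detections, FN = unmatched truths.
#' True negatives are not defined for point detection, so the
#' detection-level accuracy is reported as `TP / (TP + FP + FN)`; the
#' package's default image-level ACC is the count-ratio accuracy
#' ([count_accuracy()]).
#'
#' @param detections matrix with columns `x`, `y` ([detect_grains()]
#'   output is accepted).
#' @param truth a [point_annotations] object.
#' @param radius maximum matching distance in px.
#' @return List with `tp`, `fp`, `fn`, `accuracy` (percent),
#'   `matched_truth` (logical per truth point).
#' @export
match_detections <- function(detections, truth, radius) {
  stopifnot(inherits(truth, "point_annotations"), radius > 0)
  det <- if (is.null(dim(detections))) matrix(detections, ncol = 2L)
         else as.matrix(detections)[, 1:2, drop = FALSE]
  nt <- n_points(truth); nd <- nrow(det)
  matched_t <- logical(nt); matched_d <- logical(nd)
  if (nt > 0L && nd > 0L) {
    dx <- outer(det[, 1L], truth$points[, 1L], "-")
    dy <- outer(det[, 2L], truth$points[, 2L], "-")
    dmat <- sqrt(dx^2 + dy^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        d <- cand[r, 1L]; t <- cand[r, 2L]
        if (!matched_d[d] && !matched_t[t]) {
          matched_d[d] <- TRUE; matched_t[t] <- TRUE
        }
      }
    }
  }
  tp <- sum(matched_t); fp <- nd - sum(matched_d); fn <- nt - tp
  acc <- if (tp + fp + fn > 0L) 100 * tp / (tp + fp + fn) else 100
  list(tp = tp, fp = fp, fn = fn, accuracy = acc, matched_truth = matched_t)
}

#' Evaluate a model on a sample set
#'
#' Predicts a density map per image, takes its mass as the predicted
#' count, and aggregates MAE, MSE and count-ratio ACC.
#'
#' @param model a [build_model()] network.
#' @param samples list of `seed_sample` objects.
#' @return An object of class `eval_result`: `mae`, `mse`, `acc` and
#'   `per_image` (data frame of true/predicted counts).
#' @export
evaluate_model <- function(model, samples) {
  stopifnot(inherits(model, "seedcount_model"), length(samples) >= 1L)
  per <- lapply(samples, function(s) {
    pred <- predict(model, s$image)
    data.frame(true = n_points(s$annotations),
               predicted = count_from_density(pred$density))
  })
  per <- do.call(rbind, per)
  structure(list(mae = count_mae(per), mse = count_mse(per),
                 acc = count_accuracy(per), per_image = per),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d images: MAE %.3f  MSE %.3f  ACC %.2f%%\n",
              nrow(x$per_image), x$mae, x$mse, x$acc))
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-image counts as CSV plus a JSON summary (mae, mse, acc, and any
#' extra fields passed in `extra`).
#'
#' @param result an [evaluate_model()] result.
#' @param csv_path per-image CSV path.
#' @param json_path summary JSON path.
#' @param extra optional named list merged into the JSON summary.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(result, csv_path, json_path, extra = list()) {
  stopifnot(inherits(result, "eval_result"))
  utils::write.csv(result$per_image, csv_path, row.names = FALSE)
  summary <- c(list(mae = result$mae, mse = result$mse, acc = result$acc),
               extra)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Counting accuracy on adhering vs all grains
#'
#' Uses the synthetic generator's per-grain adhesion flags. Grain-level
#' recall on the adhering subset: detections from the predicted density
#' map are matched one-to-one against all ground-truth points, and the
#' matched fraction of flagged (conglutinated) grains is averaged over
#' images that contain any. The all-grain figure is the count-ratio ACC
#' over the full set.
#'
#' @param model a [build_model()] network.
#' @param samples `seed_sample` list with `adhered` flags.
#' @param spec a [match_spec()]; a `NULL` `match_radius` defaults per
#'   image to the mean adaptive sigma of its annotations.
#' @param kernel [kernel_spec()] used for the per-image default radius.
#' @return List with `acc_conglutinated` and `acc_all` (percent), plus
#'   `eval` (the underlying [evaluate_model()] result).
#' @export
adhesion_report <- function(model, samples, spec = match_spec(),
                            kernel = kernel_spec()) {
  stopifnot(inherits(model, "seedcount_model"))
  ev <- evaluate_model(model, samples)
  rec <- vapply(samples, function(s) {
    if (!any(s$adhered)) return(NA_real_)
    pred <- predict(model, s$image)
    radius <- spec$match_radius
    if (is.null(radius)) {
      sig <- adaptive_sigmas(s$annotations, kernel)
      radius <- max(2, mean(sig) / kernel$beta * 0.5)
    }
    det <- detect_grains(pred$density, spec)
    m <- match_detections(det, s$annotations, radius)
    mean(m$matched_truth[s$adhered])
  }, numeric(1))
  acc_cong <- if (all(is.na(rec))) NA_real_ else 100 * mean(rec, na.rm = TRUE)
  list(acc_conglutinated = acc_cong, acc_all = ev$acc, eval = ev)
}
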