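#' Point annotations for a seed image
#'
#' One annotation per grain: the (x, y) pixel coordinates of its center,
#' 0-based and pixel-center anchored, with x the column and y the row.
#' Every point must lie within `[0, width) x [0, height)`; the list may be
#' empty.
#'
#' @param points numeric matrix or data frame with two columns (x, y), one
#'   row per grain; may have zero rows.
#' @param image_shape integer vector `c(height, width)` in pixels.
#' @param image_id character identifier of the source image.
#' @return An object of class `point_annotations`: a list with elements
#'   `points` (n x 2 numeric matrix, columns `x`, `y`), `image_shape`
#'   and `image_id`.
#' @examples
#' ann <- point_annotations(cbind(c(3, 10), c(4, 12)), image_shape = c(32, 32))
#' n_points(ann)
#' @export
point_annotations <- function(points, image_shape, image_id = "image") {
  if (is.null(points) || length(points) == 0L) {
    pts <- matrix(numeric(0), ncol = 2L)
  } else {
    pts <- as.matrix(points)
    if (ncol(pts) != 2L) stop("'points' must have two columns (x, y)")
    storage.mode(pts) <- "double"
  }
  colnames(pts) <- c("x", "y")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0L))
    stop("'image_shape' must be positive c(height, width)")
  if (nrow(pts) > 0L) {
    if (anyNA(pts)) stop("annotation coordinates must not contain NA/NaN")
    h <- image_shape[1L]; w <- image_shape[2L]
    if (any(pts[, 1L] < 0 | pts[, 1L] >= w | pts[, 2L] < 0 | pts[, 2L] >= h))
      stop("all points must lie within [0, width) x [0, height)")
  }
  structure(
    list(points = pts, image_shape = image_shape,
         image_id = as.character(image_id)),
    class = "point_annotations"
  )
}

#' Number of annotated grains
#' @param ann a [point_annotations] object.
#' @return Integer count of annotation points.
#' @export
n_points <- function(ann) {
  stopifnot(inherits(ann, "point_annotations"))
  nrow(ann$points)
}

#' @export
print.point_annotations <- function(x, ...) {
  cat(sprintf("<point_annotations> '%s': %d points on %dx%d image\n",
              x$image_id, n_points(x), x$image_shape[1L], x$image_shape[2L]))
  invisible(x)
}

#' Read point annotations from JSON or CSV
#'
#' Two dialects are accepted. JSON:
#' `{"image": "...", "image_shape": [h, w], "points": [[x, y], ...]}`.
#' CSV: a two-column file with header `x,y`; the image shape is not part of
#' this dialect and must be supplied via `image_shape`.
#'
#' @param path file path; dialect chosen by extension (`.json` / `.csv`).
#' @param image_shape `c(height, width)`, required for CSV, overrides the
#'   stored shape for JSON when given.
#' @param image_id optional identifier; defaults to the stored one (JSON) or
#'   the file name (CSV).
#' @return A [point_annotations] object.
#' @export
read_annotations <- function(path, image_shape = NULL, image_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    pts <- obj$points
    if (is.null(pts) || length(pts) == 0L) pts <- matrix(numeric(0), ncol = 2L)
    if (is.null(image_shape)) image_shape <- obj$image_shape
    if (is.null(image_id)) image_id <- if (!is.null(obj$image)) obj$image else "image"
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop("CSV annotations need columns 'x' and 'y'")
    pts <- as.matrix(df[, c("x", "y")])
    if (is.null(image_id)) image_id <- basename(path)
  } else stop("unsupported annotation format: ", ext)
  if (is.null(image_shape))
    stop("'image_shape' must be given when the file does not store it")
  point_annotations(pts, image_shape, image_id)
}

#' Write point annotations as JSON
#'
#' @param ann a [point_annotations] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "point_annotations"))
  obj <- list(
    image = ann$image_id,
    image_shape = ann$image_shape,
    points = if (n_points(ann) > 0L) unname(ann$points) else matrix(numeric(0), 0, 2)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
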