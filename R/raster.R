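#' Plan a fixed-target raster scan
#'
#' Describes the serpentine grid scan of a fixed-target chip: the stage
#' stops on an `n_slow` x `n_fast` grid of positions spaced `step`
#' micrometres apart and records `images_per_stop` still images at each
#' stop. The plan can be given either as explicit step counts or as a
#' window size plus step, in which case `n = floor(window/step) + 1`
#' positions fit along each axis.
#'
#' @param n_fast,n_slow Explicit numbers of stops along the fast (in-row)
#'   and slow (row) axes.
#' @param window_mm Alternative to explicit counts: numeric length-2
#'   `(width, height)` of the scan window in mm (fast axis first).
#' @param step_um Motor step size in micrometres (default 50).
#' @param images_per_stop Still images collected per stop (default 1).
#' @return A `scan_plan` object with elements `n_fast`, `n_slow`,
#'   `step_um`, `images_per_stop` and `n_images`.
#' @examples
#' plan_scan(n_fast = 175, n_slow = 208)$n_images  # 36400
#' @export
plan_scan <- function(n_fast = NULL, n_slow = NULL, window_mm = NULL,
                      step_um = 50, images_per_stop = 1) {
  if (images_per_stop < 1) stop("images_per_stop must be >= 1")
  if (is.null(n_fast) != is.null(n_slow))
    stop("give both n_fast and n_slow, or neither")
  if (is.null(n_fast)) {
    if (is.null(window_mm) || length(window_mm) != 2)
      stop("window mode needs window_mm = c(width, height) in mm")
    if (step_um <= 0) stop("step size must be positive")
    window_um <- window_mm * 1000
    n <- floor(window_um / step_um) + 1
    if (any(window_um < step_um))
      warning("step larger than window; plan collapses to a single row/column")
    n_fast <- max(1, n[1])
    n_slow <- max(1, n[2])
  }
  if (n_fast < 1 || n_slow < 1) stop("grid dimensions must be >= 1")
  plan <- list(n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
               step_um = step_um, images_per_stop = as.integer(images_per_stop),
               n_images = as.integer(n_fast) * as.integer(n_slow) *
                 as.integer(images_per_stop))
  class(plan) <- "scan_plan"
  plan
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("scan plan %d x %d stops, %g um step, %d image(s)/stop -> %d images\n",
              x$n_fast, x$n_slow, x$step_um, x$images_per_stop, x$n_images))
  invisible(x)
}

#' Grid position of an image in a serpentine scan
#'
#' The stage traverses the grid boustrophedon: even rows (0, 2, ...) run
#' left to right along the fast axis, odd rows right to left. Image ids
#' are 0-based and increase along the traversal; with multiple images per
#' stop, consecutive ids share a position.
#'
#' @param plan A [plan_scan()] object.
#' @param image_id Integer vector of 0-based image ids.
#' @return Integer matrix with columns `row` (slow axis) and `col`
#'   (fast axis), 0-based.
#' @export
serpentine_position <- function(plan, image_id) {
  stopifnot(inherits(plan, "scan_plan"))
  if (any(image_id < 0 | image_id >= plan$n_images))
    stop("image_id outside plan: ", paste(utils::head(
      image_id[image_id < 0 | image_id >= plan$n_images]), collapse = ", "))
  stop_id <- image_id %/% plan$images_per_stop
  row <- stop_id %/% plan$n_fast
  along <- stop_id %% plan$n_fast
  col <- ifelse(row %% 2 == 0, along, plan$n_fast - 1 - along)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Indexing hit rate as a percentage
#'
#' `100 * n_indexed / n_total`, rounded to one decimal with
#' round-half-to-even (the rounding used throughout reporting).
#'
#' @param n_indexed Number of images with at least one indexed lattice.
#' @param n_total Number of collected images.
#' @return Hit rate in percent, one decimal.
#' @examples
#' hit_rate_percent(8424, 36400)  # 23.1
#' @export
hit_rate_percent <- function(n_indexed, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  round(100 * n_indexed / n_total, 1)
}

#' Hit-rate and lattice-multiplicity accounting for a run
#'
#' Counts indexed images, computes the hit rate against the planned image
#' total, and produces the lattice census: how many images carry exactly
#' one, two, or three-or-more indexed lattices, and the total lattice
#' count.
#'
#' @param plan A [plan_scan()].
#' @param images List of image records (see [image_record()]).
#' @return A list with `n_images` (planned), `n_collected`, `n_indexed`,
#'   `hit_rate` (%, one decimal), `census` (named vector: single, double,
#'   triple_plus) and `n_lattices`.
#' @export
hit_statistics <- function(plan, images) {
  stopifnot(inherits(plan, "scan_plan"))
  ids <- vapply(images, function(im) im$image_id, numeric(1))
  if (any(ids < 0 | ids >= plan$n_images))
    stop("image id outside plan: ", ids[which(ids < 0 | ids >= plan$n_images)[1]])
  nlat <- vapply(images, function(im) length(im$lattices), integer(1))
  census <- c(single = sum(nlat == 1), double = sum(nlat == 2),
              triple_plus = sum(nlat >= 3))
  list(n_images = plan$n_images,
       n_collected = length(images),
       n_indexed = sum(nlat >= 1),
       hit_rate = hit_rate_percent(sum(nlat >= 1), plan$n_images),
       census = census,
       n_lattices = sum(nlat))
}

#' Per-position lattice-count map of a chip
#'
#' Lays the indexed-lattice count of each image onto the scan grid using
#' the serpentine traversal, giving the spatial hit map of the chip.
#'
#' @inheritParams hit_statistics
#' @return Integer matrix `n_slow` x `n_fast`; entry = number of indexed
#'   lattices at that position (0 for misses and uncollected positions).
#'   With several images per stop, counts accumulate.
#' @export
hit_map <- function(plan, images) {
  stopifnot(inherits(plan, "scan_plan"))
  m <- matrix(0L, nrow = plan$n_slow, ncol = plan$n_fast)
  ids <- vapply(images, function(im) im$image_id, numeric(1))
  if (anyDuplicated(ids)) stop("duplicate image ids in run")
  pos <- serpentine_position(plan, ids)
  if (plan$images_per_stop == 1 && anyDuplicated(pos) )
    stop("duplicate grid position in run")
  nlat <- vapply(images, function(im) length(im$lattices), integer(1))
  for (i in seq_along(images))
    m[pos[i, "row"] + 1, pos[i, "col"] + 1] <-
      m[pos[i, "row"] + 1, pos[i, "col"] + 1] + nlat[i]
  m
}
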