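#' Per-image rejection criteria
#'
#' The three per-image outlier filters applied to indexed stills before
#' merging: a minimum spot count, a worst acceptable per-image resolution,
#' and a maximum fractional deviation of any refined cell length from the
#' run-average cell.
#'
#' @param min_spots Reject images with fewer found spots (default 75;
#'   small-cell samples typically use a lower value because fewer
#'   reflections fall on the detector).
#' @param worst_d Reject images whose per-image resolution estimate is
#'   worse (larger d) than this, in Angstrom (default 2.8).
#' @param cell_tolerance Maximum fractional deviation of a, b or c from
#'   the run average (default 0.035, i.e. 3.5%).
#' @param resolution_rank Order statistic used for the per-image
#'   resolution: the d-spacing of the rank-th highest-resolution
#'   observation (default 5, a robust choice that ignores a few spurious
#'   high-resolution spots).
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(min_spots = 75, worst_d = 2.8,
                               cell_tolerance = 0.035, resolution_rank = 5) {
  if (worst_d <= 0) stop("worst_d must be positive")
  if (cell_tolerance < 0) stop("cell_tolerance must be >= 0")
  if (min_spots < 0) stop("min_spots must be >= 0")
  if (resolution_rank < 1) stop("resolution_rank must be >= 1")
  obj <- list(min_spots = min_spots, worst_d = worst_d,
              cell_tolerance = cell_tolerance,
              resolution_rank = as.integer(resolution_rank))
  class(obj) <- "rejection_criteria"
  obj
}

#' Run-average unit cell
#'
#' Arithmetic mean of each cell parameter over every indexed lattice of
#' every image, with the crystal-system constraints of the symmetry group
#' re-imposed afterwards (symmetry-tied lengths, e.g. a and b in a
#' hexagonal cell, are averaged jointly). Computed once, over all indexed
#' images, before any rejection.
#'
#' @param images List of [image_record()]s.
#' @param group A [symmetry_group()] supplying the crystal system.
#' @return A [unit_cell()].
#' @export
average_cell <- function(images, group) {
  stopifnot(inherits(group, "symmetry_group"))
  cells <- unlist(lapply(images, function(im)
    lapply(im$lattices, function(l) l$cell)), recursive = FALSE)
  if (length(cells) == 0) stop("no indexed lattices to average")
  average_cell_list(cells, group$crystal_system)
}

#' Per-image resolution estimate
#'
#' The d-spacing of the rank-th highest-resolution (smallest-d)
#' observation across all lattices of the image, computed against a
#' common reference cell so per-lattice cell jitter does not move the
#' estimate. If the image has fewer than `rank` observations the weakest
#' (largest-d) available observation is returned and the result carries
#' attribute `short = TRUE`.
#'
#' @param image An [image_record()] with at least one observation.
#' @param cell Reference [unit_cell()] (usually [average_cell()]).
#' @param rank Order statistic (>= 1).
#' @return d in Angstrom, attribute `short` flagging rank shortfall.
#' @export
image_resolution <- function(image, cell, rank = 5) {
  obs <- do.call(rbind, lapply(image$lattices, function(l) l$obs[, c("h", "k", "l")]))
  if (is.null(obs) || nrow(obs) == 0) stop("image has no observations")
  d <- sort(d_spacing(cell, obs))
  if (nrow(obs) >= rank) {
    structure(d[rank], short = FALSE)
  } else {
    structure(d[length(d)], short = TRUE)
  }
}

# Per-image maximum fractional deviation of any cell length of any
# lattice from the reference cell (a, b, c only; angles are
# symmetry-fixed for the supported crystal systems).
cell_deviation <- function(image, ref_cell) {
  refs <- c(ref_cell$a, ref_cell$b, ref_cell$c)
  devs <- vapply(image$lattices, function(l)
    max(abs(c(l$cell$a, l$cell$b, l$cell$c) - refs) / refs), numeric(1))
  if (length(devs) == 0) NA_real_ else max(devs)
}

#' Apply the per-image outlier filters
#'
#' An image is rejected when it fails at least one criterion: spot count
#' below `min_spots`, per-image resolution worse than `worst_d`, or any
#' cell length of any of its lattices deviating from the run-average cell
#' by more than `cell_tolerance` (a multi-lattice image is rejected as a
#' whole if any lattice fails). Per-criterion counts are non-exclusive —
#' an image failing two criteria increments both — while the total counts
#' unique images.
#'
#' @param images List of indexed [image_record()]s (>= 1).
#' @param criteria A [rejection_criteria()].
#' @param group A [symmetry_group()] (for cell averaging constraints).
#' @return An object of class `rejection_report`: a list with `n_input`,
#'   `n_rejected_spots`, `n_rejected_resolution`, `n_rejected_cell`,
#'   `n_rejected_total`, `surviving_ids`, the `average_cell` used, and
#'   `flags` (per-image logical data frame).
#' @export
apply_filters <- function(images, criteria, group) {
  stopifnot(inherits(criteria, "rejection_criteria"))
  if (length(images) == 0) stop("empty image list")
  ref <- average_cell(images, group)
  pd <- rejection_plot_data(images, criteria, group, ref_cell = ref)
  fail_spots <- pd$spot_count < criteria$min_spots
  fail_res <- pd$resolution > criteria$worst_d
  fail_cell <- !is.na(pd$cell_deviation) &
    pd$cell_deviation > criteria$cell_tolerance
  rejected <- fail_spots | fail_res | fail_cell
  report <- list(
    n_input = length(images),
    n_rejected_spots = sum(fail_spots),
    n_rejected_resolution = sum(fail_res),
    n_rejected_cell = sum(fail_cell),
    n_rejected_total = sum(rejected),
    surviving_ids = pd$image_id[!rejected],
    average_cell = ref,
    flags = data.frame(image_id = pd$image_id,
                       fail_spots = fail_spots,
                       fail_resolution = fail_res,
                       fail_cell = fail_cell,
                       rejected = rejected))
  class(report) <- "rejection_report"
  report
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf(
    "rejection report: %d images in, %d rejected (%d spots, %d resolution, %d cell), %d surviving\n",
    x$n_input, x$n_rejected_total, x$n_rejected_spots,
    x$n_rejected_resolution, x$n_rejected_cell, length(x$surviving_ids)))
  invisible(x)
}

#' Per-image series behind the rejection decision
#'
#' One row per input image with the exact numbers the filters act on —
#' spot count, per-image resolution and maximum fractional cell
#' deviation — plus the thresholds, ready for plotting or export.
#'
#' @inheritParams apply_filters
#' @param ref_cell Optional precomputed reference cell; computed from the
#'   images when omitted.
#' @return Data frame with columns `image_id`, `spot_count`, `resolution`,
#'   `resolution_short` (order-statistic shortfall flag),
#'   `cell_deviation`, and attributes `thresholds` and `average_cell`.
#' @export
rejection_plot_data <- function(images, criteria, group, ref_cell = NULL) {
  if (length(images) == 0) stop("empty image list")
  if (is.null(ref_cell)) ref_cell <- average_cell(images, group)
  res <- lapply(images, function(im) {
    if (length(im$lattices) == 0) return(structure(Inf, short = NA))
    image_resolution(im, ref_cell, criteria$resolution_rank)
  })
  out <- data.frame(
    image_id = vapply(images, function(im) im$image_id, integer(1)),
    spot_count = vapply(images, function(im) im$spot_count, integer(1)),
    resolution = vapply(res, as.numeric, numeric(1)),
    resolution_short = vapply(res, function(r) attr(r, "short"), logical(1)),
    cell_deviation = vapply(images, cell_deviation, numeric(1),
                            ref_cell = ref_cell))
  attr(out, "thresholds") <- criteria
  attr(out, "average_cell") <- ref_cell
  out
}
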