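#' Construct one still-image record
#'
#' One record per collected still image: its position on the raster grid,
#' the number of diffraction spots found by spot finding (pre-indexing),
#' and zero or more indexed lattices each carrying a refined cell and an
#' observation list. An image with no lattices is a non-hit.
#'
#' @param image_id 0-based integer id, increasing along the scan traversal.
#' @param grid_xy Integer pair `(row, col)`, 0-based; row is the slow axis.
#' @param spot_count Number of found spots (>= 0).
#' @param lattices List of [lattice_record()] objects (possibly empty).
#' @return An object of class `image_record`.
#' @export
image_record <- function(image_id, grid_xy, spot_count, lattices = list()) {
  if (image_id < 0) stop("image_id must be >= 0")
  if (length(grid_xy) != 2 || any(grid_xy < 0))
    stop("grid_xy must be two non-negative integers")
  if (spot_count < 0) stop("spot_count must be >= 0")
  lat_ids <- vapply(lattices, function(l) l$lattice_id, numeric(1))
  if (anyDuplicated(lat_ids)) stop("lattice ids must be unique within an image")
  obj <- list(image_id = as.integer(image_id),
              grid_xy = as.integer(grid_xy),
              spot_count = as.integer(spot_count),
              lattices = lattices)
  class(obj) <- "image_record"
  obj
}

#' Construct one indexed-lattice record
#'
#' @param lattice_id Integer >= 1, unique within its image.
#' @param cell Refined [unit_cell()] for this lattice.
#' @param obs Data frame of integrated observations with columns
#'   `h, k, l` (as indexed, not ASU-mapped), `I` (intensity, may be
#'   negative) and `sigI` (> 0).
#' @return An object of class `lattice_record`.
#' @export
lattice_record <- function(lattice_id, cell, obs) {
  if (lattice_id < 1) stop("lattice_id must be >= 1")
  stopifnot(inherits(cell, "unit_cell"))
  req <- c("h", "k", "l", "I", "sigI")
  if (!all(req %in% names(obs))) stop("observations need columns h,k,l,I,sigI")
  if (nrow(obs) == 0) stop("observation list must be non-empty")
  bad <- which(!(obs$sigI > 0))
  if (length(bad) > 0)
    stop("observation ", bad[1], ": sigI must be > 0")
  obj <- list(lattice_id = as.integer(lattice_id), cell = cell,
              obs = obs[, req])
  class(obj) <- "lattice_record"
  obj
}

#' Run metadata pair
#'
#' Every collection run is described by two JSON documents: beamline
#' metadata (wavelength, beam and step size, exposure, detector distance,
#' flux) and sample metadata (unit cell, symmetry, protein name, reference
#' model, experimental intent, principal investigator). Only `cell` and
#' `symmetry` in the sample document are interpreted by the pipeline; the
#' rest is carried through for provenance.
#'
#' @param beamline Named list of beamline fields.
#' @param sample Named list of sample fields; must contain `cell`
#'   (six numbers) and `symmetry` (a name accepted by [space_group()], or
#'   a parsed [symmetry_group()]).
#' @return An object of class `run_metadata` with `beamline`, `sample`,
#'   and parsed `cell` / `group`.
#' @export
run_metadata <- function(beamline, sample) {
  if (is.null(sample$cell) || is.null(sample$symmetry))
    stop("sample metadata must contain 'cell' and 'symmetry'")
  cellv <- as.numeric(unlist(sample$cell))
  if (length(cellv) != 6) stop("sample cell must have six parameters")
  cell <- unit_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  group <- if (inherits(sample$symmetry, "symmetry_group")) sample$symmetry
           else space_group(sample$symmetry)
  obj <- list(beamline = beamline, sample = sample, cell = cell, group = group)
  class(obj) <- "run_metadata"
  obj
}

images_format_version <- "1.0"

lattice_to_json_list <- function(lat) {
  list(lattice_id = lat$lattice_id,
       cell = as.numeric(cell_parameters(lat$cell)),
       obs = list(h = lat$obs$h, k = lat$obs$k, l = lat$obs$l,
                  I = lat$obs$I, sigI = lat$obs$sigI))
}

#' Write a run to disk
#'
#' Creates `metadata_beamline.json`, `metadata_sample.json` and
#' `images.jsonl` (one JSON object per line per image) under `path`.
#' Numeric values are written at full precision so that
#' [read_run()] is an exact round-trip inverse.
#'
#' @param path Output directory (created if missing).
#' @param metadata A [run_metadata()].
#' @param images List of [image_record()] objects.
#' @return `path`, invisibly.
#' @export
write_run <- function(path, metadata, images) {
  stopifnot(inherits(metadata, "run_metadata"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sample <- metadata$sample
  sample$symmetry <- if (inherits(sample$symmetry, "symmetry_group"))
    sample$symmetry$name else sample$symmetry
  jsonlite::write_json(metadata$beamline,
                       file.path(path, "metadata_beamline.json"),
                       auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(sample, file.path(path, "metadata_sample.json"),
                       auto_unbox = TRUE, digits = I(17))
  con <- file(file.path(path, "images.jsonl"), open = "w")
  on.exit(close(con))
  for (im in images) {
    line <- jsonlite::toJSON(
      list(format_version = images_format_version,
           image_id = im$image_id,
           grid_xy = im$grid_xy,
           spot_count = im$spot_count,
           lattices = lapply(im$lattices, lattice_to_json_list)),
      auto_unbox = TRUE, digits = I(17))
    writeLines(line, con)
  }
  invisible(path)
}

parse_image_line <- function(line, lineno) {
  rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e)
                    stop("images.jsonl line ", lineno, ": malformed JSON (",
                         conditionMessage(e), ")", call. = FALSE))
  for (f in c("image_id", "grid_xy", "spot_count"))
    if (is.null(rec[[f]]))
      stop("images.jsonl line ", lineno, ": missing field '", f, "'",
           call. = FALSE)
  lats <- rec$lattices
  lat_list <- list()
  if (length(lats) > 0) {
    # jsonlite may simplify a list of records to a data frame
    if (is.data.frame(lats)) lats <- split(lats, seq_len(nrow(lats)))
    lat_list <- lapply(seq_along(lats), function(i) {
      lt <- lats[[i]]
      if (is.data.frame(lt) && nrow(lt) == 1) lt <- as.list(lt)
      cellv <- as.numeric(unlist(lt$cell))
      obs <- lt$obs
      if (is.data.frame(obs)) obs <- as.list(obs)
      obs_df <- tryCatch(
        data.frame(h = as.integer(unlist(obs$h)), k = as.integer(unlist(obs$k)),
                   l = as.integer(unlist(obs$l)), I = as.numeric(unlist(obs$I)),
                   sigI = as.numeric(unlist(obs$sigI))),
        error = function(e)
          stop("images.jsonl line ", lineno, ", lattice ", i,
               ": malformed observation table", call. = FALSE))
      bad <- which(!(obs_df$sigI > 0))
      if (length(bad) > 0)
        stop("images.jsonl line ", lineno, ", lattice ", i, ", observation ",
             bad[1], ": field 'sigI' must be > 0", call. = FALSE)
      lattice_record(unlist(lt$lattice_id),
                     unit_cell(cellv[1], cellv[2], cellv[3],
                               cellv[4], cellv[5], cellv[6]),
                     obs_df)
    })
  }
  image_record(rec$image_id, rec$grid_xy, rec$spot_count, lat_list)
}

#' Read a run from disk
#'
#' Reads the two metadata documents and the full image stream written by
#' [write_run()], validating record invariants. Malformed lines are
#' reported with their line number and offending field. For batchwise
#' (constant-memory) access use [open_image_stream()].
#'
#' @param path Run directory.
#' @return List with `metadata` (a [run_metadata()]) and `images`
#'   (list of [image_record()]s, in image_id order).
#' @export
read_run <- function(path) {
  meta <- read_run_metadata(path)
  stream <- open_image_stream(file.path(path, "images.jsonl"),
                              batch_size = 4096L)
  on.exit(try(stream$close(), silent = TRUE))
  images <- list()
  repeat {
    b <- stream$next_batch()
    if (is.null(b)) break
    images <- c(images, b)
  }
  stream$close()
  ids <- vapply(images, function(im) im$image_id, integer(1))
  images <- images[order(ids)]
  list(metadata = meta, images = images)
}

#' @rdname read_run
#' @export
read_run_metadata <- function(path) {
  bl_path <- file.path(path, "metadata_beamline.json")
  sm_path <- file.path(path, "metadata_sample.json")
  if (!file.exists(bl_path)) stop("missing metadata_beamline.json in ", path)
  if (!file.exists(sm_path)) stop("missing metadata_sample.json in ", path)
  run_metadata(jsonlite::fromJSON(bl_path, simplifyVector = TRUE),
               jsonlite::fromJSON(sm_path, simplifyVector = TRUE))
}

#' Open a batchwise reader over an image file
#'
#' Returns a small stream object reading `batch_size` images at a time,
#' so a full chip scan never needs to be held in memory at once.
#'
#' @param path Path to an `images.jsonl` file.
#' @param batch_size Images per batch (>= 1).
#' @return List with functions `next_batch()` (returns a list of
#'   [image_record()]s, or `NULL` at end of file) and `close()`.
#' @export
open_image_stream <- function(path, batch_size = 256L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (!file.exists(path)) stop("no such image file: ", path)
  con <- file(path, open = "r")
  lineno <- 0L
  list(
    next_batch = function() {
      lines <- readLines(con, n = batch_size)
      if (length(lines) == 0) return(NULL)
      out <- vector("list", length(lines))
      for (i in seq_along(lines)) {
        out[[i]] <- parse_image_line(lines[i], lineno + i)
      }
      lineno <<- lineno + length(lines)
      out
    },
    close = function() close(con)
  )
}

#' Split a sequence into ordered batches
#'
#' Mirrors the batchwise triggering of the analysis pipeline, which acts
#' on fixed-size batches of images as they land: order is preserved and
#' every batch is full except possibly the last.
#'
#' @param x A list or vector (e.g. of image records or image ids).
#' @param batch_size Batch size (>= 1).
#' @return List of consecutive chunks of `x`.
#' @examples
#' length(batch_stream(seq_len(36400), 256))  # 143
#' @export
batch_stream <- function(x, batch_size) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  n <- length(x)
  if (n == 0) return(list())
  starts <- seq(1, n, by = batch_size)
  lapply(starts, function(s) x[s:min(s + batch_size - 1, n)])
}

# ---- merged-reflection output ---------------------------------------------

merged_columns <- function(set) {
  if (all(c("F", "sigF") %in% names(set))) c("F", "sigF")
  else if (all(c("I_full", "sigI_full") %in% names(set))) c("I_full", "sigI_full")
  else stop("merged table needs columns F/sigF or I_full/sigI_full")
}

#' Write merged reflections
#'
#' Writes a merged-reflection table either as fixed-width hkl text
#' (columns `h k l value sigma`, two decimals, SHELX-style widths, one
#' header comment line) or as a minimal mmCIF `_refln` loop. Intensity
#' tables (columns `I_full`, `sigI_full`) and amplitude tables (`F`,
#' `sigF`) are both accepted.
#'
#' @param set Data frame keyed by canonical `h, k, l` (a merged set from
#'   [merge_stills()] or an amplitude table from [truncate_set()]).
#' @param path Output file.
#' @param format `"hkl"` (fixed-width text) or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_merged <- function(set, path, format = c("hkl", "mmcif")) {
  format <- match.arg(format)
  if (nrow(set) == 0) stop("refusing to write an empty merged set")
  vc <- merged_columns(set)
  ord <- order(set$h, set$k, set$l)
  set <- set[ord, , drop = FALSE]
  if (format == "hkl") {
    lines <- c(
      sprintf("#   h   k   l %7s %7s", vc[1], vc[2]),
      sprintf("%5d%5d%5d%10.2f%10.2f", set$h, set$k, set$l,
              set[[vc[1]]], set[[vc[2]]]))
    writeLines(lines, path)
  } else {
    tag <- if (vc[1] == "F") c("_refln.F_meas_au", "_refln.F_meas_sigma_au")
           else c("_refln.intensity_meas", "_refln.intensity_sigma")
    lines <- c(
      "data_meshmerge",
      "loop_",
      "_refln.index_h",
      "_refln.index_k",
      "_refln.index_l",
      tag,
      sprintf("%d %d %d %.2f %.2f", set$h, set$k, set$l,
              set[[vc[1]]], set[[vc[2]]]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read fixed-width hkl text written by [write_merged()]
#'
#' @param path Input file.
#' @return Data frame with `h, k, l` and the two value columns named in
#'   the header.
#' @export
read_hkl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty hkl file")
  header <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  df <- utils::read.table(text = body, col.names = header)
  df$h <- as.integer(df$h); df$k <- as.integer(df$k); df$l <- as.integer(df$l)
  df
}
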