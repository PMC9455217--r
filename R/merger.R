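# Flatten the observations of a set of images into one data.table with
# ASU-mapped indices. One row per observation; `lat` is a run-global
# lattice key, `img_pos` the 0-based position of the image in the input
# order (used for the half-dataset split).
obs_table <- function(images, group, cell) {
  parts <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    for (lt in im$lattices) {
      parts[[length(parts) + 1]] <- data.table::data.table(
        img_pos = i - 1L,
        image_id = im$image_id,
        lat = paste0(im$image_id, ":", lt$lattice_id),
        h = lt$obs$h, k = lt$obs$k, l = lt$obs$l,
        I = lt$obs$I, sigI = lt$obs$sigI)
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) stop("no observations in input images")
  dt <- data.table::rbindlist(parts)
  asu <- map_to_asu(group, as.matrix(dt[, c("h", "k", "l")]))
  dt[, c("h", "k", "l") := list(asu[, 1], asu[, 2], asu[, 3])]
  dt[, d := d_spacing(cell, asu)]
  dt
}

# Union-find over lattices connected by shared unique reflections;
# returns an integer component id per lattice (named).
lattice_components <- function(dt) {
  lats <- unique(dt$lat)
  parent <- seq_along(lats)
  names(parent) <- lats
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(dt$h, dt$k, dt$l)
  lat_idx <- match(dt$lat, lats)
  for (grp in split(lat_idx, key)) {
    grp <- unique(grp)
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (j in grp[-1]) parent[find(j)] <- r
    }
  }
  comp <- vapply(seq_along(lats), find, numeric(1))
  stats::setNames(match(comp, unique(comp)), lats)
}

#' Determine per-lattice linear scales
#'
#' Bulk scaling of still intensities by one multiplicative factor per
#' lattice. The algorithm alternates between (a) merging all observations
#' with the current scales into a reference set and (b) refitting each
#' lattice's scale by least squares against that reference,
#' `k_i = sum(I_obs * I_ref) / sum(I_ref^2)`, until the largest relative
#' scale change falls below `tol`. Scales are renormalised to mean 1
#' (per connected component if the observation graph is disconnected).
#' No per-image B factor or partiality model is fitted; this is the
#' linear-scale Monte-Carlo approximation appropriate for high-redundancy
#' still data.
#'
#' @param images List of (surviving) [image_record()]s.
#' @param group A [symmetry_group()].
#' @param cell Reference [unit_cell()].
#' @param tol Convergence tolerance on the maximum relative scale change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 50).
#' @return An object of class `scale_set`: data frame with `lat`
#'   (image_id:lattice_id key), `image_id`, `k`, plus attributes
#'   `iterations`, `residual` (final max relative change) and
#'   `components`.
#' @export
scale_images <- function(images, group, cell, tol = 1e-6, max_iter = 50) {
  dt <- obs_table(images, group, cell)
  lats <- unique(dt$lat)
  comp <- lattice_components(dt)
  n_comp <- max(comp)
  if (length(lats) > 1 && n_comp == length(lats))
    stop("no two lattices share a unique reflection; scaling is undetermined")
  if (n_comp > 1)
    warning("observation graph has ", n_comp,
            " disconnected components; scales normalised per component")
  k <- stats::setNames(rep(1, length(lats)), lats)
  iter <- 0L
  resid <- Inf
  I <- dt$I; sigI <- dt$sigI
  lat_idx <- match(dt$lat, lats)
  key <- paste(dt$h, dt$k, dt$l)
  key_f <- factor(key)
  while (iter < max_iter) {
    iter <- iter + 1L
    ki <- k[lat_idx]
    w <- (ki / sigI)^2
    Is <- I / ki
    ref_num <- rowsum(w * Is, key_f)
    ref_den <- rowsum(w, key_f)
    Iref_all <- (ref_num / ref_den)[key_f]
    num <- rowsum(I * Iref_all, lat_idx)
    den <- rowsum(Iref_all^2, lat_idx)
    k_new <- as.numeric(num / den)
    bad <- !is.finite(k_new) | k_new <= 0
    k_new[bad] <- k[bad]
    # renormalise to mean 1 within each connected component
    for (cid in seq_len(n_comp)) {
      sel <- comp[lats] == cid
      k_new[sel] <- k_new[sel] / mean(k_new[sel])
    }
    resid <- max(abs(k_new - k) / k)
    k <- stats::setNames(k_new, lats)
    if (resid < tol) break
  }
  img_of_lat <- dt$image_id[match(lats, dt$lat)]
  out <- data.frame(lat = lats, image_id = img_of_lat, k = as.numeric(k))
  attr(out, "iterations") <- iter
  attr(out, "residual") <- resid
  attr(out, "components") <- n_comp
  class(out) <- c("scale_set", "data.frame")
  out
}

#' Merge scaled still observations into a unique-reflection table
#'
#' Observations are mapped to the asymmetric unit, divided by their
#' lattice scale, and combined per unique reflection by an
#' inverse-variance weighted mean (weights `1/(sigI/k)^2`). Negative
#' intensities are merged as-is; positivity is the job of the
#' French-Wilson step. Two half-dataset merges are computed from the
#' image-parity split: images at even positions of the input (surviving)
#' order form half 1, odd positions half 2, with all lattices of an image
#' staying in the same half.
#'
#' @param images List of surviving [image_record()]s, in surviving order.
#' @param scales A [scale_images()] result covering all lattices (or
#'   `NULL` for unit scales).
#' @param group A [symmetry_group()].
#' @param cell Reference [unit_cell()].
#' @param half_split Half-dataset assignment rule; only `"parity"` is
#'   implemented.
#' @return A `merged_set`: data frame with columns `h, k, l` (canonical),
#'   `d`, `centric`, `I_full`, `sigI_full`, `n_obs`, `I_half1`,
#'   `I_half2`, `n_half1`, `n_half2` (half columns `NA` where a half has
#'   no observation), plus attributes `cell`, `group`, `n_images`,
#'   `scales`.
#' @export
merge_stills <- function(images, scales, group, cell, half_split = "parity") {
  half_split <- match.arg(half_split, "parity")
  if (length(images) == 0) stop("empty image list")
  dt <- obs_table(images, group, cell)
  if (is.null(scales)) {
    dt[, scl := 1]
  } else {
    stopifnot(inherits(scales, "scale_set"))
    m <- match(dt$lat, scales$lat)
    if (anyNA(m)) stop("scales do not cover all lattices")
    dt[, scl := scales$k[m]]
  }
  dt[, half := img_pos %% 2L + 1L]
  dt[, w := (scl / sigI)^2]
  dt[, Is := I / scl]
  full <- dt[, list(d = d[1],
                    I_full = sum(w * Is) / sum(w),
                    sigI_full = 1 / sqrt(sum(w)),
                    n_obs = .N), by = c("h", "k", "l")]
  halves <- dt[, list(I_half = sum(w * Is) / sum(w), n_half = .N),
               by = c("h", "k", "l", "half")]
  h1 <- halves[half == 1L, c("h", "k", "l", "I_half", "n_half")]
  h2 <- halves[half == 2L, c("h", "k", "l", "I_half", "n_half")]
  data.table::setnames(h1, c("I_half", "n_half"), c("I_half1", "n_half1"))
  data.table::setnames(h2, c("I_half", "n_half"), c("I_half2", "n_half2"))
  out <- merge(merge(full, h1, by = c("h", "k", "l"), all.x = TRUE),
               h2, by = c("h", "k", "l"), all.x = TRUE)
  out[is.na(n_half1), n_half1 := 0L]
  out[is.na(n_half2), n_half2 := 0L]
  out <- as.data.frame(out)
  out$centric <- is_centric(group, out)
  out <- out[order(-out$d, out$h, out$k, out$l), ]
  rownames(out) <- NULL
  attr(out, "cell") <- cell
  attr(out, "group") <- group
  attr(out, "n_images") <- length(images)
  attr(out, "scales") <- scales
  class(out) <- c("merged_set", "data.frame")
  out
}

#' Mean multiplicity of a merged set
#'
#' Average number of observations contributing to each unique reflection
#' (the data redundancy), overall and — when a shell binning is given —
#' per resolution shell.
#'
#' @param set A `merged_set` from [merge_stills()].
#' @param shells Optional [bin_shells()] result.
#' @return List with `overall` and, if shells were given, a data frame
#'   `per_shell`.
#' @export
multiplicity_summary <- function(set, shells = NULL) {
  if (nrow(set) == 0) stop("empty merged set")
  out <- list(overall = mean(set$n_obs))
  if (!is.null(shells)) {
    sh <- shells$assignment
    per <- vapply(split(set$n_obs, sh), mean, numeric(1))
    out$per_shell <- data.frame(shell = as.integer(names(per)),
                                multiplicity = as.numeric(per))
  }
  out
}
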