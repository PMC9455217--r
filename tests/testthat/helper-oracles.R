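# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: orbits are generated by explicit
# per-element arithmetic, absences come from textbook reflection-condition
# rules, and quadrature oracles use dense trapezoid integration.

# Full orbit of one reflection under the point group plus Friedel
# inversion, via explicit elementwise matrix application.
orbit_oracle <- function(group, hkl) {
  out <- list()
  for (R in group$rotations) {
    m <- c(
      hkl[1] * R[1, 1] + hkl[2] * R[2, 1] + hkl[3] * R[3, 1],
      hkl[1] * R[1, 2] + hkl[2] * R[2, 2] + hkl[3] * R[3, 2],
      hkl[1] * R[1, 3] + hkl[2] * R[2, 3] + hkl[3] * R[3, 3])
    out[[length(out) + 1]] <- m
    out[[length(out) + 1]] <- -m
  }
  mat <- unique(do.call(rbind, out))
  mat[order(mat[, 1], mat[, 2], mat[, 3]), , drop = FALSE]
}

# Canonical representative = lexicographic maximum of the orbit.
canonical_oracle <- function(group, hkl) {
  orb <- orbit_oracle(group, hkl)
  orb[nrow(orb), ]
}

# Reflection-condition rules for the built-in groups (screw axes only).
absence_rule_oracle <- function(group_name, hkl) {
  h <- hkl[1]; k <- hkl[2]; l <- hkl[3]
  axis_h <- k == 0 && l == 0
  axis_k <- h == 0 && l == 0
  axis_l <- h == 0 && k == 0
  switch(normalize_name(group_name),
    P1 = FALSE,
    P21 = axis_k && k %% 2 != 0,
    P212121 = (axis_h && h %% 2 != 0) || (axis_k && k %% 2 != 0) ||
      (axis_l && l %% 2 != 0),
    P43212 = (axis_l && l %% 4 != 0) || (axis_h && h %% 2 != 0) ||
      (axis_k && k %% 2 != 0),
    P6422 = axis_l && l %% 3 != 0,
    stop("no rule oracle for ", group_name))
}

normalize_name <- function(name) toupper(gsub("[ _()]", "", name))

# Brute-force unique-reflection count: scan a box, keep d-range, group by
# orbit via the oracle canonical form, optionally drop rule-based absences.
unique_count_oracle <- function(cell, group, d_max, d_min,
                                exclude_absent = TRUE, box = 6) {
  seen <- character(0)
  for (h in -box:box) for (k in -box:box) for (l in -box:box) {
    if (h == 0 && k == 0 && l == 0) next
    d <- d_spacing(cell, c(h, k, l))
    if (d < d_min - 1e-9 || d > d_max + 1e-9) next
    if (exclude_absent && absence_rule_oracle(group$name, c(h, k, l))) next
    can <- canonical_oracle(group, c(h, k, l))
    seen <- union(seen, paste(can, collapse = ","))
  }
  length(seen)
}

# Dense-trapezoid posterior-moment oracle for the intensity-to-amplitude
# conversion over J in [0, I + 10*sigI]. The acentric case integrates in J
# directly; the centric prior's integrable J^(-1/2) singularity is removed
# by substituting t = sqrt(J) (dJ = 2t dt), which a uniform trapezoid grid
# then handles at full order.
i_to_f_oracle <- function(I, sigI, Sigma, centric, n = 1e6) {
  upper <- I + 10 * sigI
  stopifnot(upper > 0)
  if (!centric) {
    J <- seq(0, upper, length.out = n)
    lg <- -(I - J)^2 / (2 * sigI^2) - J / Sigma
    g <- exp(lg - max(lg))
    z <- pracma::trapz(J, g)
    Fm <- pracma::trapz(J, sqrt(J) * g) / z
    Ej <- pracma::trapz(J, J * g) / z
  } else {
    t <- seq(0, sqrt(upper), length.out = n)
    lg <- -(I - t^2)^2 / (2 * sigI^2) - t^2 / (2 * Sigma)
    g <- exp(lg - max(lg))  # prior density in t is flat after substitution
    z <- pracma::trapz(t, g)
    Fm <- pracma::trapz(t, t * g) / z
    Ej <- pracma::trapz(t, t^2 * g) / z
  }
  list(F = Fm, sigF = sqrt(max(Ej - Fm^2, 0)))
}

as_hkl_mat <- function(df) {
  m <- unname(as.matrix(df[, c("h", "k", "l")]))
  storage.mode(m) <- "integer"
  m
}

# Small toy image builders used by several files.
toy_obs <- function(hkl, I, sigI = rep(1, length(I))) {
  data.frame(h = sapply(hkl, `[`, 1), k = sapply(hkl, `[`, 2),
             l = sapply(hkl, `[`, 3), I = I, sigI = sigI)
}

toy_image <- function(id, cell, obs, spot_count = 100, grid = c(0, id),
                      lattice_ids = 1) {
  if (is.data.frame(obs)) obs <- list(obs)
  lats <- lapply(seq_along(obs), function(i)
    lattice_record(lattice_ids[min(i, length(lattice_ids))], cell, obs[[i]]))
  image_record(id, grid, spot_count, lats)
}

# Shared small simulated run for the cheaper end-to-end checks.
small_clean_config <- function(seed = 7, ...) {
  defaults <- list(cell = unit_cell(15, 18, 20), group = space_group("P212121"),
                   d_min = 2.5, wilson_B = 5, plan = plan_scan(20, 20),
                   hit_rate = 0.3, obs_fraction = 1, scale_sigma = 0,
                   noise_sigma = 0, cell_jitter = 0, outlier_fraction = 0,
                   multi2_fraction = 0.1, multi3_fraction = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

indexed_images <- function(run) {
  Filter(function(im) length(im$lattices) > 0, run$images)
}

images_by_id <- function(images, ids) {
  images[vapply(images, function(im) im$image_id, integer(1)) %in% ids]
}

# Minimal generic CIF loop reader used as a parse oracle for the mmCIF
# writer: returns a data frame of the first loop_ block.
parse_cif_loop <- function(path) {
  lines <- trimws(readLines(path))
  start <- which(lines == "loop_")[1]
  tags <- character(0)
  i <- start + 1
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, lines[i])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body)]
  df <- utils::read.table(text = body, col.names = tags)
  df
}
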