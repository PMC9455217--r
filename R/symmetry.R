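#' Construct a symmetry group for reflection data
#'
#' Holds the point-group rotation operators of a space group together with
#' the fractional translation attached to each operator (screw components),
#' which is what reciprocal-space bookkeeping needs: orbit generation,
#' asymmetric-unit mapping, systematic-absence tests and centricity.
#'
#' Operators act on fractional coordinates as `x' = R x + t`; a reflection
#' transforms as the row vector `h' = h R`, and the phase shift picked up is
#' `2*pi* h.t`.
#'
#' @param name Hermann-Mauguin style label (free text).
#' @param rotations List of 3x3 integer matrices; must contain the identity
#'   and be closed under multiplication.
#' @param translations List (same length) of numeric length-3 fractional
#'   translations in [0, 1).
#' @param laue_class Label for the Laue class (e.g. `"mmm"`, `"6/mmm"`).
#' @param crystal_system One of `"triclinic"`, `"monoclinic"`,
#'   `"orthorhombic"`, `"tetragonal"`, `"hexagonal"`, `"cubic"`; controls
#'   which cell constraints are re-imposed when averaging cells.
#' @return An object of class `symmetry_group`.
#' @seealso [space_group()] for the built-in catalogue,
#'   [read_symmetry_config()] to load a group from JSON.
#' @export
symmetry_group <- function(name, rotations, translations, laue_class,
                           crystal_system = "triclinic") {
  if (length(rotations) != length(translations))
    stop("rotations and translations must have equal length")
  rotations <- lapply(rotations, function(R) {
    R <- matrix(as.numeric(R), 3, 3)
    if (any(R != round(R))) stop("rotation operators must be integer matrices")
    R
  })
  translations <- lapply(translations, function(t) {
    t <- as.numeric(t)
    if (length(t) != 3) stop("translations must have three components")
    t %% 1
  })
  keys <- vapply(rotations, function(R) paste(R, collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("duplicate rotation operators")
  if (!any(keys == paste(diag(3), collapse = ",")))
    stop("identity operator missing")
  for (i in seq_along(rotations)) for (j in seq_along(rotations)) {
    prod_key <- paste(rotations[[i]] %*% rotations[[j]], collapse = ",")
    if (!prod_key %in% keys)
      stop("rotation operators are not closed under multiplication")
  }
  obj <- list(name = name, rotations = rotations, translations = translations,
              laue_class = laue_class, crystal_system = crystal_system,
              order = length(rotations))
  class(obj) <- "symmetry_group"
  obj
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("symmetry group %s  (%d operators, Laue class %s, %s)\n",
              x$name, x$order, x$laue_class, x$crystal_system))
  invisible(x)
}

# ---- built-in catalogue ----------------------------------------------------
# Rotation parts + screw translations for the space groups this pipeline is
# used with. Matrices are written row-wise; the operator list of each group
# was cross-checked against reference space-group tables.

sg_table <- function() {
  m <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  I3 <- diag(3)
  list(
    P1 = list(
      hm = "P 1", laue = "-1", system = "triclinic",
      rot = list(I3),
      tr = list(c(0, 0, 0))
    ),
    P21 = list(
      hm = "P 21", laue = "2/m", system = "monoclinic",
      rot = list(I3, m(-1, 0, 0, 0, 1, 0, 0, 0, -1)),
      tr = list(c(0, 0, 0), c(0, 1 / 2, 0))
    ),
    P212121 = list(
      hm = "P 21 21 21", laue = "mmm", system = "orthorhombic",
      rot = list(
        I3,
        m(-1, 0, 0, 0, -1, 0, 0, 0, 1),
        m(1, 0, 0, 0, -1, 0, 0, 0, -1),
        m(-1, 0, 0, 0, 1, 0, 0, 0, -1)),
      tr = list(
        c(0, 0, 0),
        c(1 / 2, 0, 1 / 2),
        c(1 / 2, 1 / 2, 0),
        c(0, 1 / 2, 1 / 2))
    ),
    P43212 = list(
      hm = "P 43 21 2", laue = "4/mmm", system = "tetragonal",
      rot = list(
        I3,
        m(0, -1, 0, 1, 0, 0, 0, 0, 1),
        m(-1, 0, 0, 0, -1, 0, 0, 0, 1),
        m(0, 1, 0, -1, 0, 0, 0, 0, 1),
        m(1, 0, 0, 0, -1, 0, 0, 0, -1),
        m(0, -1, 0, -1, 0, 0, 0, 0, -1),
        m(-1, 0, 0, 0, 1, 0, 0, 0, -1),
        m(0, 1, 0, 1, 0, 0, 0, 0, -1)),
      tr = list(
        c(0, 0, 0),
        c(1 / 2, 1 / 2, 3 / 4),
        c(0, 0, 1 / 2),
        c(1 / 2, 1 / 2, 1 / 4),
        c(1 / 2, 1 / 2, 1 / 4),
        c(0, 0, 1 / 2),
        c(1 / 2, 1 / 2, 3 / 4),
        c(0, 0, 0))
    ),
    P6422 = list(
      hm = "P 64 2 2", laue = "6/mmm", system = "hexagonal",
      rot = list(
        I3,
        m(1, -1, 0, 1, 0, 0, 0, 0, 1),
        m(0, -1, 0, 1, -1, 0, 0, 0, 1),
        m(-1, 0, 0, 0, -1, 0, 0, 0, 1),
        m(-1, 1, 0, -1, 0, 0, 0, 0, 1),
        m(0, 1, 0, -1, 1, 0, 0, 0, 1),
        m(0, -1, 0, -1, 0, 0, 0, 0, -1),
        m(-1, 0, 0, -1, 1, 0, 0, 0, -1),
        m(-1, 1, 0, 0, 1, 0, 0, 0, -1),
        m(0, 1, 0, 1, 0, 0, 0, 0, -1),
        m(1, 0, 0, 1, -1, 0, 0, 0, -1),
        m(1, -1, 0, 0, -1, 0, 0, 0, -1)),
      tr = list(
        c(0, 0, 0),
        c(0, 0, 2 / 3),
        c(0, 0, 1 / 3),
        c(0, 0, 0),
        c(0, 0, 2 / 3),
        c(0, 0, 1 / 3),
        c(0, 0, 1 / 3),
        c(0, 0, 2 / 3),
        c(0, 0, 0),
        c(0, 0, 1 / 3),
        c(0, 0, 2 / 3),
        c(0, 0, 0))
    )
  )
}

normalize_sg_name <- function(name) {
  toupper(gsub("[ _()]", "", name))
}

#' Built-in space groups
#'
#' Returns one of the shipped symmetry groups. The catalogue covers the
#' space groups this pipeline is routinely run with: P1, P2(1),
#' P2(1)2(1)2(1), P4(3)2(1)2 and P6(4)22. Other groups can be supplied via
#' [read_symmetry_config()].
#'
#' @param name Hermann-Mauguin symbol; spaces and underscores are ignored,
#'   so `"P212121"`, `"P 21 21 21"` and `"P_21_21_21"` are equivalent.
#' @return A [symmetry_group()].
#' @examples
#' space_group("P6422")
#' @export
space_group <- function(name) {
  tab <- sg_table()
  key <- normalize_sg_name(name)
  if (!key %in% names(tab))
    stop("unknown built-in space group '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  e <- tab[[key]]
  symmetry_group(e$hm, e$rot, e$tr, e$laue, e$system)
}

#' Names of the built-in space groups
#' @return Character vector of catalogue keys accepted by [space_group()].
#' @export
space_group_names <- function() names(sg_table())

#' Load a symmetry group from a JSON config
#'
#' The config format is a JSON object with fields `name`, `rotations`
#' (list of 9-integer row-major matrices), `translations` (list of
#' length-3 arrays whose entries are fractions written as strings, e.g.
#' `"1/2"`, or plain numbers), `laue_class` and optionally
#' `crystal_system`.
#'
#' @param path Path to the JSON file.
#' @return A [symmetry_group()].
#' @export
read_symmetry_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("name", "rotations", "translations", "laue_class"))
    if (is.null(cfg[[f]])) stop("symmetry config missing field '", f, "'")
  parse_frac <- function(x) {
    if (is.numeric(x)) return(x)
    parts <- strsplit(as.character(x), "/", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(as.numeric(parts))
    as.numeric(parts[1]) / as.numeric(parts[2])
  }
  rot <- lapply(cfg$rotations, function(r) matrix(unlist(r), 3, 3, byrow = TRUE))
  tr <- lapply(cfg$translations, function(t) vapply(t, parse_frac, numeric(1)))
  symmetry_group(cfg$name, rot, tr, cfg$laue_class,
                 cfg$crystal_system %||% "triclinic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reciprocal-space group actions ---------------------------------------

# All symmetry mates of each row of H (N x 3) including Friedel pairs:
# returns a list of 2*order matrices, each N x 3.
hkl_mates <- function(group, H) {
  mates <- lapply(group$rotations, function(R) H %*% R)
  c(mates, lapply(mates, function(M) -M))
}

#' Map reflections to the asymmetric unit
#'
#' Replaces each reflection by the canonical representative of its orbit
#' under the point group plus Friedel inversion. The canonical member is
#' defined as the orbit member that is maximal under lexicographic
#' (h, k, l) ordering; this is an internal convention (any fixed total
#' order serves merging equally well) and does not follow the reference
#' asymmetric-unit zones of any particular software suite.
#'
#' @param group A [symmetry_group()].
#' @param hkl Length-3 vector, N x 3 matrix, or data frame with `h,k,l`.
#' @return An N x 3 integer matrix of canonical indices (a length-3 vector
#'   if a single reflection was given).
#' @examples
#' map_to_asu(space_group("P212121"), c(-1, 2, -3))  # (1, 2, 3)
#' @export
map_to_asu <- function(group, hkl) {
  stopifnot(inherits(group, "symmetry_group"))
  single <- is.null(dim(hkl)) && !is.data.frame(hkl)
  H <- as_hkl_matrix(hkl)
  mates <- hkl_mates(group, H)
  # lexicographic maximum via a collision-free packed key
  K <- 2 * max(abs(H)) * max(vapply(group$rotations,
                                    function(R) sum(abs(R[, 1])) + sum(abs(R[, 2])) + sum(abs(R[, 3])),
                                    numeric(1))) + 3
  best <- mates[[1]]
  best_key <- (best[, 1] * K + best[, 2]) * K + best[, 3]
  for (M in mates[-1]) {
    key <- (M[, 1] * K + M[, 2]) * K + M[, 3]
    take <- key > best_key
    if (any(take)) {
      best[take, ] <- M[take, , drop = FALSE]
      best_key[take] <- key[take]
    }
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  if (single) best[1, ] else best
}

#' Test reflections for systematic absence
#'
#' A reflection is systematically absent when some operator fixes it
#' (`h R = h`) while the associated translation produces a non-integer
#' phase shift `h.t` — the reciprocal-space signature of screw axes and
#' glide planes.
#'
#' @inheritParams map_to_asu
#' @return Logical vector, one entry per reflection.
#' @examples
#' is_systematically_absent(space_group("P212121"), c(3, 0, 0))  # TRUE
#' @export
is_systematically_absent <- function(group, hkl) {
  stopifnot(inherits(group, "symmetry_group"))
  H <- as_hkl_matrix(hkl)
  absent <- rep(FALSE, nrow(H))
  for (i in seq_len(group$order)) {
    R <- group$rotations[[i]]
    t <- group$translations[[i]]
    fixed <- rowSums(abs(H %*% R - H)) == 0
    phase <- as.numeric(H %*% t)
    shifted <- abs(phase - round(phase)) > 1e-9
    absent <- absent | (fixed & shifted)
  }
  absent
}

#' Test reflections for centricity
#'
#' A reflection is centric when some point-group operator maps it to its
#' Friedel mate (`h R = -h`); centric reflections follow a different
#' intensity distribution, which matters for Wilson statistics and
#' French-Wilson truncation.
#'
#' @inheritParams map_to_asu
#' @return Logical vector.
#' @export
is_centric <- function(group, hkl) {
  stopifnot(inherits(group, "symmetry_group"))
  H <- as_hkl_matrix(hkl)
  centric <- rep(FALSE, nrow(H))
  for (R in group$rotations)
    centric <- centric | rowSums(abs(H %*% R + H)) == 0
  centric
}

#' Orbit multiplicity (epsilon) factors
#'
#' Epsilon is the order of the stabiliser of a reflection in the point
#' group: the number of rotation operators that map it to itself. It
#' weights the expected intensity of zonal/axial reflections in Wilson
#' statistics.
#'
#' @inheritParams map_to_asu
#' @return Integer vector of epsilon factors (>= 1).
#' @export
epsilon_factor <- function(group, hkl) {
  stopifnot(inherits(group, "symmetry_group"))
  H <- as_hkl_matrix(hkl)
  eps <- rep(0L, nrow(H))
  for (R in group$rotations)
    eps <- eps + as.integer(rowSums(abs(H %*% R - H)) == 0)
  eps
}

#' Enumerate the unique reflections in a resolution range
#'
#' Scans the reciprocal lattice inside a bounding box wide enough for
#' `d_min`, keeps reflections with `d` in `[d_min, d_max]`, reduces them to
#' canonical asymmetric-unit representatives and (optionally) drops
#' systematic absences. This provides the denominator for completeness.
#'
#' @param cell A [unit_cell()].
#' @param group A [symmetry_group()].
#' @param d_max Low-resolution limit in Angstrom (may be `Inf`).
#' @param d_min High-resolution limit in Angstrom; must satisfy
#'   `d_max > d_min > 0`.
#' @param exclude_absent Drop systematically absent reflections
#'   (default `TRUE`).
#' @return A data frame with columns `h, k, l, d, centric, epsilon`,
#'   sorted by decreasing `d`.
#' @export
unique_reflections <- function(cell, group, d_max = Inf, d_min,
                               exclude_absent = TRUE) {
  stopifnot(inherits(cell, "unit_cell"), inherits(group, "symmetry_group"))
  if (!is.finite(d_min) || d_min <= 0) stop("d_min must be positive and finite")
  if (d_min >= d_max) stop("d_min must be smaller than d_max")
  hmax <- floor(cell$a / d_min) + 1
  kmax <- floor(cell$b / d_min) + 1
  lmax <- floor(cell$c / d_min) + 1
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- d_spacing(cell, grid)
  keep <- d >= d_min - 1e-9 & d <= d_max + 1e-9
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  asu <- map_to_asu(group, grid)
  is_canon <- rowSums(abs(asu - grid)) == 0
  H <- grid[is_canon, , drop = FALSE]
  d <- d[is_canon]
  if (exclude_absent && nrow(H) > 0) {
    keep <- !is_systematically_absent(group, H)
    H <- H[keep, , drop = FALSE]
    d <- d[keep]
  }
  out <- data.frame(h = as.integer(H[, 1]), k = as.integer(H[, 2]),
                    l = as.integer(H[, 3]), d = d)
  if (nrow(out) > 0) {
    out$centric <- is_centric(group, H)
    out$epsilon <- epsilon_factor(group, H)
  } else {
    out$centric <- logical(0)
    out$epsilon <- integer(0)
  }
  out <- out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
  rownames(out) <- NULL
  out
}
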