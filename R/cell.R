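#' Construct a unit cell
#'
#' A crystallographic unit cell described by its six lattice parameters.
#' Lengths are in Angstrom, angles in degrees. The object carries the
#' direct-space metric tensor and its inverse (the reciprocal metric
#' tensor), which is all that reflection d-spacing calculations need.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180).
#' @return An object of class `unit_cell`: a list with elements
#'   `a, b, c, alpha, beta, gamma`, `volume` (Angstrom^3), `metric`
#'   (3x3 direct metric tensor G) and `recip_metric` (G^-1).
#' @examples
#' uc <- unit_cell(49.41, 69.35, 70.04)
#' uc$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  alpha <- unname(alpha); beta <- unname(beta); gamma <- unname(gamma)
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(ang * pi / 180)
  G <- matrix(c(
    a * a,            a * b * ca[[3]],  a * c * ca[[2]],
    a * b * ca[[3]],  b * b,            b * c * ca[[1]],
    a * c * ca[[2]],  b * c * ca[[1]],  c * c
  ), nrow = 3, byrow = TRUE)
  vol2 <- det(G)
  if (vol2 <= 0)
    stop("unit cell angles are geometrically impossible (non-positive volume)")
  obj <- list(a = a, b = b, c = c,
              alpha = alpha, beta = beta, gamma = gamma,
              volume = sqrt(vol2), metric = G, recip_metric = solve(G))
  class(obj) <- "unit_cell"
  obj
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, ...) {
  sprintf("%.4f %.4f %.4f %.3f %.3f %.3f", x$a, x$b, x$c, x$alpha, x$beta, x$gamma)
}

#' Cell parameters as a numeric vector
#'
#' @param cell A [unit_cell()].
#' @return Named numeric vector `(a, b, c, alpha, beta, gamma)`.
#' @export
cell_parameters <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  c(a = cell$a, b = cell$b, c = cell$c,
    alpha = cell$alpha, beta = cell$beta, gamma = cell$gamma)
}

# Coerce hkl input (length-3 vector, Nx3 matrix, or data.frame with h,k,l)
# to an integer Nx3 matrix; reject the origin (0,0,0), which is not a
# reflection.
as_hkl_matrix <- function(hkl, allow_origin = FALSE) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3) stop("hkl must have three components")
    hkl <- matrix(hkl, nrow = 1)
  }
  if (ncol(hkl) != 3) stop("hkl matrix must have three columns")
  storage.mode(hkl) <- "double"
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  if (!allow_origin && any(rowSums(abs(hkl)) == 0))
    stop("(0,0,0) is not a valid reflection")
  hkl
}

#' Resolution (d-spacing) of reflections
#'
#' Computes d = 1 / sqrt(h' G* h) from the reciprocal metric tensor G* of
#' the cell. Vectorised over rows of `hkl`. Symmetric under Friedel
#' inversion by construction.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an N x 3 matrix / data frame
#'   with columns `h, k, l`. The origin (0,0,0) is rejected.
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(2, 0, 0))  # 5 A
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  H <- as_hkl_matrix(hkl)
  inv_d2 <- rowSums((H %*% cell$recip_metric) * H)
  1 / sqrt(inv_d2)
}

# Average a set of cells parameter-wise and re-impose the lattice
# constraints of the crystal system (e.g. a = b and gamma = 120 for
# hexagonal). `cells` is a list of unit_cell objects.
average_cell_list <- function(cells, system = "triclinic") {
  stopifnot(length(cells) >= 1)
  P <- vapply(cells, cell_parameters, numeric(6))
  m <- rowMeans(P)
  constrain_cell(m[1], m[2], m[3], m[4], m[5], m[6], system)
}

# Re-impose crystal-system constraints on raw parameters; symmetry-tied
# lengths are averaged jointly.
constrain_cell <- function(a, b, c, alpha, beta, gamma, system) {
  switch(system,
    triclinic = unit_cell(a, b, c, alpha, beta, gamma),
    monoclinic = unit_cell(a, b, c, 90, beta, 90),
    orthorhombic = unit_cell(a, b, c, 90, 90, 90),
    tetragonal = {
      ab <- mean(c(a, b))
      unit_cell(ab, ab, c, 90, 90, 90)
    },
    hexagonal = {
      ab <- mean(c(a, b))
      unit_cell(ab, ab, c, 90, 90, 120)
    },
    cubic = {
      abc <- mean(c(a, b, c))
      unit_cell(abc, abc, abc, 90, 90, 90)
    },
    stop("unknown crystal system: ", system)
  )
}
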