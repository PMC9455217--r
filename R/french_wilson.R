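#' Estimate Wilson prior parameters per shell
#'
#' The Wilson prior for true intensities needs one parameter per
#' resolution shell: Sigma, the expected true intensity, estimated as the
#' mean merged intensity of the shell floored at a small positive value
#' (1e-6 of the overall mean magnitude) so that noise-dominated shells
#' with non-positive means still yield a proper prior. Shells with fewer
#' than `min_n` reflections borrow the nearest adequately populated
#' shell's estimate.
#'
#' @param set A `merged_set`.
#' @param shells A [bin_shells()] result for `set`.
#' @param min_n Minimum reflections for a shell to stand on its own
#'   (default 10).
#' @return An object of class `wilson_params`: list with `table`
#'   (data frame `shell, Sigma, n_used, borrowed`) and `binning`.
#' @export
estimate_wilson_params <- function(set, shells, min_n = 10) {
  n_shells <- shells$n_shells
  floor_val <- 1e-6 * max(mean(abs(set$I_full)), .Machine$double.eps)
  Sigma <- rep(NA_real_, n_shells)
  n_used <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    rows <- which(shells$assignment == s)
    n_used[s] <- length(rows)
    if (length(rows) > 0) {
      m <- mean(set$I_full[rows])
      if (m < floor_val) {
        warning("shell ", s, ": non-positive mean intensity; floored")
        m <- floor_val
      }
      Sigma[s] <- m
    }
  }
  borrowed <- rep(FALSE, n_shells)
  strong <- which(n_used >= min_n & !is.na(Sigma))
  if (length(strong) == 0) strong <- which(!is.na(Sigma))
  if (length(strong) == 0) stop("no populated shells to estimate Sigma from")
  for (s in seq_len(n_shells)) {
    if (n_used[s] < min_n || is.na(Sigma[s])) {
      nearest <- strong[which.min(abs(strong - s))]
      Sigma[s] <- Sigma[nearest]
      borrowed[s] <- TRUE
    }
  }
  structure(list(table = data.frame(shell = seq_len(n_shells), Sigma = Sigma,
                                    n_used = n_used, borrowed = borrowed),
                 binning = shells),
            class = "wilson_params")
}

#' Bayesian intensity-to-amplitude conversion
#'
#' Posterior mean and standard deviation of the structure-factor
#' amplitude `F = sqrt(J)` given an observed merged intensity with
#' Gaussian error, `I_obs ~ N(J, sigI^2)` for true intensity `J >= 0`,
#' under the Wilson prior: acentric `P(J) ~ exp(-J/Sigma)`, centric
#' `P(J) ~ J^(-1/2) exp(-J/(2 Sigma))`. The posterior moments are
#' evaluated by Gauss-Legendre quadrature in the amplitude variable
#' `u = sqrt(J)` (which absorbs the centric prior's integrable
#' singularity at J = 0) on `[0, sqrt(max(I,0) + 15 sigI)]`. Negative
#' observed intensities yield a finite positive amplitude, as they
#' should.
#'
#' Vectorised over reflections.
#'
#' @param I Observed merged intensities.
#' @param sigI Intensity standard deviations (> 0).
#' @param Sigma Wilson prior means (> 0), recycled as needed.
#' @param centric Logical vector, recycled.
#' @param n_nodes Quadrature nodes (default 512).
#' @return Data frame with columns `F` and `sigF` (both > 0).
#' @examples
#' i_to_f(10000, 1, 100, FALSE)$F  # ~ 100 in the strong-signal limit
#' @export
i_to_f <- function(I, sigI, Sigma, centric, n_nodes = 512) {
  n <- max(length(I), length(sigI), length(Sigma), length(centric))
  I <- rep_len(I, n); sigI <- rep_len(sigI, n)
  Sigma <- rep_len(Sigma, n); centric <- rep_len(centric, n)
  if (any(sigI <= 0)) stop("sigI must be > 0")
  if (any(Sigma <= 0)) stop("Sigma must be > 0")
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  Fm <- numeric(n); sF <- numeric(n)
  chunk <- 2000L
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    u_max <- sqrt(pmax(I[idx], 0) + 15 * sigI[idx])
    U <- outer(gl$x, u_max)                      # n_nodes x m
    J <- U^2
    loglik <- -sweep(J, 2, I[idx])^2 / rep(2 * sigI[idx]^2, each = n_nodes)
    logprior <- matrix(0, n_nodes, length(idx))
    cen <- centric[idx]
    if (any(!cen))
      logprior[, !cen] <- log(U[, !cen, drop = FALSE]) -
        sweep(J[, !cen, drop = FALSE], 2, Sigma[idx][!cen], `/`)
    if (any(cen))
      logprior[, cen] <- -sweep(J[, cen, drop = FALSE], 2,
                                2 * Sigma[idx][cen], `/`)
    lg <- loglik + logprior
    lg <- sweep(lg, 2, apply(lg, 2, max))
    g <- exp(lg) * gl$w
    z0 <- colSums(g)
    ef <- colSums(g * U) / z0
    ej <- colSums(g * J) / z0
    Fm[idx] <- ef
    sF[idx] <- sqrt(pmax(ej - ef^2, 0))
  }
  data.frame(F = Fm, sigF = sF)
}

#' Convert a merged set to structure-factor amplitudes
#'
#' Applies [i_to_f()] to every unique reflection with the shellwise
#' Wilson prior from [estimate_wilson_params()], using the set's centric
#' flags. Systematically absent reflections, should any appear in the
#' input, are excluded with a message.
#'
#' @param set A `merged_set` from [merge_stills()].
#' @param params A [estimate_wilson_params()] result for the same set.
#' @param group A [symmetry_group()]; defaults to the set's attribute.
#' @param n_nodes Quadrature nodes passed to [i_to_f()].
#' @return Data frame `h, k, l, d, centric, I_full, sigI_full, F, sigF`,
#'   ready for [write_merged()].
#' @export
truncate_set <- function(set, params, group = attr(set, "group"),
                         n_nodes = 512) {
  stopifnot(inherits(params, "wilson_params"))
  if (is.null(group)) stop("group must be supplied or carried by the set")
  if (nrow(set) != length(params$binning$assignment))
    stop("params were estimated on a different set")
  absent <- is_systematically_absent(group, set)
  if (any(absent)) {
    message(sum(absent), " systematically absent reflection(s) excluded")
    keep <- !absent
  } else keep <- rep(TRUE, nrow(set))
  rows <- set[keep, , drop = FALSE]
  Sigma <- params$table$Sigma[params$binning$assignment[keep]]
  centric <- if ("centric" %in% names(rows)) rows$centric
             else is_centric(group, rows)
  fs <- i_to_f(rows$I_full, rows$sigI_full, Sigma, centric, n_nodes)
  out <- data.frame(h = rows$h, k = rows$k, l = rows$l, d = rows$d,
                    centric = centric,
                    I_full = rows$I_full, sigI_full = rows$sigI_full,
                    F = fs$F, sigF = fs$sigF)
  rownames(out) <- NULL
  out
}
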