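#' Configuration for a synthetic still-data run
#'
#' Defines the statistical regime of a simulated fixed-target raster run.
#' The defaults reproduce the regime of a single-chip serial run on a
#' small orthorhombic protein crystal: a 175 x 208 scan at 50 um step,
#' a hit rate near 23%, one to three indexed lattices per hit (15% double,
#' 2.5% triple), lognormal per-lattice scale spread, per-observation
#' Gaussian noise at 10% of the shell mean, 1% unit-cell jitter, and 5%
#' outlier images whose cells are shifted by 7% and whose spot counts
#' fall below any sensible spot-count filter.
#'
#' @param cell True [unit_cell()] (default 49.41, 69.35, 70.04 A,
#'   orthorhombic).
#' @param group A [symmetry_group()] (default P2(1)2(1)2(1)).
#' @param d_min High-resolution limit of simulated reflections (default
#'   1.8 A).
#' @param wilson_B Wilson B factor in A^2 controlling the resolution
#'   falloff of true intensities (default 11.5).
#' @param base_intensity Mean true intensity at zero scattering angle
#'   (arbitrary detector units, default 1000).
#' @param plan A [plan_scan()] (default 175 x 208).
#' @param hit_rate Probability a grid stop yields an indexed image
#'   (default 0.231).
#' @param obs_fraction Fraction of unique reflections observed per
#'   lattice (default 0.1); each sampled reflection is re-expanded to a
#'   random symmetry mate before being recorded, as an integrator would
#'   see it.
#' @param scale_sigma Lognormal sigma of true per-lattice scales
#'   (default 0.3).
#' @param noise_sigma Gaussian noise level as a fraction of the Wilson
#'   mean (default 0.1).
#' @param noise_model `"shell"`: noise sd is `noise_sigma * Sigma(d)`
#'   (constant signal-to-noise across resolution); `"flat"`: sd is
#'   `noise_sigma * base_intensity` regardless of d, so signal-to-noise
#'   decays with resolution as the Wilson falloff — use this to plant a
#'   resolution-dependent signal decay for cutoff studies.
#' @param cell_jitter Fractional sd of per-lattice cell-length jitter
#'   (default 0.01).
#' @param outlier_fraction Fraction of hit images planted as outliers
#'   (default 0.05).
#' @param outlier_cell_shift Fractional cell-length shift of outlier
#'   images (default 0.07; sign drawn per image).
#' @param multi2_fraction,multi3_fraction Probabilities of a hit carrying
#'   two / three lattices (defaults 0.153 and 0.025).
#' @param clutter_mean Poisson mean of unindexed clutter spots added to
#'   the spot count (default 25).
#' @param seed Integer seed; the run is fully deterministic given the
#'   config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(cell = unit_cell(49.41, 69.35, 70.04),
                              group = space_group("P212121"),
                              d_min = 1.8,
                              wilson_B = 11.5,
                              base_intensity = 1000,
                              plan = plan_scan(175, 208),
                              hit_rate = 0.231,
                              obs_fraction = 0.1,
                              scale_sigma = 0.3,
                              noise_sigma = 0.1,
                              noise_model = c("shell", "flat"),
                              cell_jitter = 0.01,
                              outlier_fraction = 0.05,
                              outlier_cell_shift = 0.07,
                              multi2_fraction = 0.153,
                              multi3_fraction = 0.025,
                              clutter_mean = 25,
                              seed = 1) {
  noise_model <- match.arg(noise_model)
  fracs <- c(hit_rate = hit_rate, obs_fraction = obs_fraction,
             outlier_fraction = outlier_fraction,
             multi2_fraction = multi2_fraction,
             multi3_fraction = multi3_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (multi2_fraction + multi3_fraction > 1)
    stop("multi2_fraction + multi3_fraction must be <= 1")
  if (d_min <= 0) stop("d_min must be positive")
  if (obs_fraction <= 0) stop("obs_fraction must be positive")
  if (scale_sigma < 0 || noise_sigma < 0 || cell_jitter < 0)
    stop("sigma parameters must be >= 0")
  stopifnot(inherits(cell, "unit_cell"), inherits(group, "symmetry_group"),
            inherits(plan, "scan_plan"))
  obj <- as.list(environment())
  class(obj) <- "simulation_config"
  obj
}

#' Draw ground-truth reflection intensities
#'
#' Samples one true intensity per unique reflection from Wilson
#' statistics: acentric reflections are exponential with mean
#' `Sigma(d)`, centric reflections are `Sigma(d) * chi-squared(1)`, where
#' `Sigma(d) = base_intensity * exp(-wilson_B / (2 d^2))` is the Wilson
#' falloff (`sin(theta)/lambda = 1/(2d)`).
#'
#' @inheritParams simulation_config
#' @param seed Integer seed (the RNG state is set here).
#' @return Data frame: the [unique_reflections()] table plus columns
#'   `Sigma` and `J` (true intensity).
#' @export
simulate_truth <- function(cell, group, d_min, wilson_B, seed,
                           base_intensity = 1000) {
  set.seed(seed)
  refs <- unique_reflections(cell, group, d_max = Inf, d_min = d_min,
                             exclude_absent = TRUE)
  refs$Sigma <- base_intensity * exp(-wilson_B / (2 * refs$d^2))
  n <- nrow(refs)
  J <- numeric(n)
  ac <- !refs$centric
  J[ac] <- stats::rexp(sum(ac), rate = 1 / refs$Sigma[ac])
  J[!ac] <- refs$Sigma[!ac] * stats::rchisq(sum(!ac), df = 1)
  refs$J <- J
  refs
}

# jitter cell lengths fractionally and re-impose lattice constraints
jitter_cell <- function(cell, frac_sd, shift, system) {
  f <- 1 + stats::rnorm(3, 0, frac_sd)
  constrain_cell(cell$a * f[1] * (1 + shift), cell$b * f[2] * (1 + shift),
                 cell$c * f[3] * (1 + shift),
                 cell$alpha, cell$beta, cell$gamma, system)
}

#' Simulate a full fixed-target run
#'
#' Generates a ground-truth-labelled raster run under a
#' [simulation_config()]. One RNG stream is used with a fixed draw order
#' (truth intensities first, then per image in id order: hit flag,
#' outlier flag, lattice-count draw, then per lattice: scale, cell
#' jitter, observation subset, symmetry-mate expansion, noise; finally
#' the clutter-spot draw), so runs are fully reproducible from the seed.
#'
#' Per image: a Bernoulli(hit_rate) draw decides if the stop is a hit;
#' hits carry 1-3 lattices; each lattice observes an `obs_fraction`
#' subset of the unique reflections, re-expanded to random symmetry
#' mates, with intensity `k * J + N(0, sd^2)` and sigma set to the noise
#' sd (floored at a tiny positive value so sigma > 0 always). Planted
#' outlier images get all cell lengths shifted by `outlier_cell_shift`
#' and a spot count far below the usual spot filter.
#'
#' @param config A [simulation_config()].
#' @return List with `metadata` (a [run_metadata()]), `images` (list of
#'   [image_record()]s covering every grid stop), and `truth` (list:
#'   `reflections` from [simulate_truth()], `labels` per-image data
#'   frame with `image_id, hit, outlier, n_lattices`, `scales` data frame
#'   with `lat, k_true`, and the `config`).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  truth <- simulate_truth(cf$cell, cf$group, cf$d_min, cf$wilson_B, cf$seed,
                          cf$base_intensity)
  n_ref <- nrow(truth)
  refs_m <- as.matrix(truth[, c("h", "k", "l")])
  n_img <- cf$plan$n_images
  sd_floor <- 1e-8 * cf$base_intensity
  n_ops <- cf$group$order
  rot <- cf$group$rotations
  n_take <- max(1L, round(cf$obs_fraction * n_ref))

  images <- vector("list", n_img)
  labels <- data.frame(image_id = seq_len(n_img) - 1L,
                       hit = FALSE, outlier = FALSE, n_lattices = 0L)
  scale_lat <- character(0)
  scale_k <- numeric(0)
  pos <- serpentine_position(cf$plan, seq_len(n_img) - 1L)

  for (i in seq_len(n_img)) {
    id <- i - 1L
    hit <- stats::runif(1) < cf$hit_rate
    if (!hit) {
      spots <- stats::rpois(1, cf$clutter_mean)
      images[[i]] <- image_record(id, pos[i, ], spots, list())
      next
    }
    outlier <- stats::runif(1) < cf$outlier_fraction
    u <- stats::runif(1)
    n_lat <- if (u < cf$multi3_fraction) 3L
             else if (u < cf$multi3_fraction + cf$multi2_fraction) 2L
             else 1L
    shift <- if (outlier) sample(c(-1, 1), 1) * cf$outlier_cell_shift else 0
    lattices <- vector("list", n_lat)
    n_obs_total <- 0L
    for (j in seq_len(n_lat)) {
      k_true <- if (cf$scale_sigma > 0)
        stats::rlnorm(1, 0, cf$scale_sigma) else 1
      lcell <- jitter_cell(cf$cell, cf$cell_jitter, shift,
                           cf$group$crystal_system)
      sel <- if (n_take >= n_ref) seq_len(n_ref)
             else sample.int(n_ref, n_take)
      H <- refs_m[sel, , drop = FALSE]
      op_idx <- sample.int(n_ops, length(sel), replace = TRUE)
      sgn <- sample(c(1, -1), length(sel), replace = TRUE)
      Hm <- H
      for (o in unique(op_idx)) {
        rows <- op_idx == o
        Hm[rows, ] <- H[rows, , drop = FALSE] %*% rot[[o]]
      }
      Hm <- Hm * sgn
      sd_vec <- if (cf$noise_model == "shell")
        cf$noise_sigma * truth$Sigma[sel]
      else rep(cf$noise_sigma * cf$base_intensity, length(sel))
      I_obs <- k_true * truth$J[sel] + stats::rnorm(length(sel), 0, sd_vec)
      sig <- pmax(sd_vec, sd_floor)
      lattices[[j]] <- lattice_record(j, lcell,
        data.frame(h = as.integer(Hm[, 1]), k = as.integer(Hm[, 2]),
                   l = as.integer(Hm[, 3]), I = I_obs, sigI = sig))
      scale_lat <- c(scale_lat, paste0(id, ":", j))
      scale_k <- c(scale_k, k_true)
      n_obs_total <- n_obs_total + length(sel)
    }
    spots <- if (outlier) stats::rpois(1, 20)
             else n_obs_total + stats::rpois(1, cf$clutter_mean)
    images[[i]] <- image_record(id, pos[i, ], spots, lattices)
    labels$hit[i] <- TRUE
    labels$outlier[i] <- outlier
    labels$n_lattices[i] <- n_lat
  }
  meta <- run_metadata(
    beamline = list(wavelength_A = 0.9792, beam_um = c(75, 75),
                    step_um = cf$plan$step_um, exposure_ms = 40,
                    detector_distance_mm = 350, flux = 3e12),
    sample = list(cell = as.numeric(cell_parameters(cf$cell)),
                  symmetry = cf$group$name,
                  protein = "synthetic sample",
                  pdb_model = "none",
                  intent = "simulation",
                  principal_investigator = "simulator"))
  list(metadata = meta, images = images,
       truth = list(reflections = truth, labels = labels,
                    scales = data.frame(lat = scale_lat, k_true = scale_k),
                    config = cf))
}

#' Compare pipeline outputs against the planted ground truth
#'
#' Scores a processed simulated run: outlier-flagging precision and
#' recall, the false-flag rate on clean indexed images, the Pearson
#' correlation of recovered per-lattice scales with the planted ones,
#' and the relative RMS error of merged intensities against the true
#' intensities after a single global scale fit.
#'
#' @param report A [apply_filters()] result on the run's indexed images.
#' @param scales A [scale_images()] result on the surviving images (or
#'   `NULL` to skip the scale score).
#' @param merged A [merge_stills()] result (or `NULL` to skip).
#' @param truth The `truth` element of [simulate_run()].
#' @return List with `outlier_precision`, `outlier_recall`,
#'   `false_flag_rate`, `scale_r`, `intensity_rmse_rel`, `n_planted`,
#'   `n_flagged`.
#' @export
evaluate_recovery <- function(report, scales, merged, truth) {
  stopifnot(inherits(report, "rejection_report"))
  lab <- truth$labels
  if (!all(report$flags$image_id %in% lab$image_id))
    stop("report and truth come from different runs")
  fl <- merge(report$flags, lab, by = "image_id")
  planted <- fl$outlier
  flagged <- fl$rejected
  recall <- if (sum(planted) > 0) sum(flagged & planted) / sum(planted) else NA
  precision <- if (sum(flagged) > 0) sum(flagged & planted) / sum(flagged) else NA
  false_flag <- if (sum(!planted) > 0)
    sum(flagged & !planted) / sum(!planted) else NA
  scale_r <- NA_real_
  if (!is.null(scales)) {
    m <- merge(as.data.frame(scales), truth$scales, by = "lat")
    if (nrow(m) >= 3) scale_r <- stats::cor(m$k, m$k_true)
  }
  rmse <- NA_real_
  if (!is.null(merged)) {
    tr <- merge(as.data.frame(merged)[, c("h", "k", "l", "I_full")],
                truth$reflections[, c("h", "k", "l", "J")],
                by = c("h", "k", "l"))
    cglob <- sum(tr$I_full * tr$J) / sum(tr$J^2)
    rmse <- sqrt(mean((tr$I_full / cglob - tr$J)^2)) / mean(tr$J)
  }
  list(outlier_precision = precision, outlier_recall = recall,
       false_flag_rate = false_flag, scale_r = scale_r,
       intensity_rmse_rel = rmse,
       n_planted = sum(planted), n_flagged = sum(flagged))
}
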