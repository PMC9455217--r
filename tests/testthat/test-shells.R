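# minimal merged-set-like frame for statistics tests
stat_set <- function(I1, I2, d = NULL, centric = FALSE, I_full = NULL) {
  n <- length(I1)
  data.frame(h = seq_len(n), k = 0L, l = 0L,
             d = if (is.null(d)) seq(10, 2, length.out = n) else d,
             centric = rep_len(centric, n),
             I_full = if (is.null(I_full)) (I1 + I2) / 2 else I_full,
             sigI_full = 1,
             n_obs = 2L, I_half1 = I1, I_half2 = I2,
             n_half1 = 1L, n_half2 = 1L)
}

test_that("equal-volume shells split 1/d^3 evenly and cover every reflection", {
  s <- stat_set(1:40, 1:40)
  b <- bin_shells(s, 1)
  expect_true(all(b$assignment == 1))
  # closed-form boundary for two shells over d in [2, 8]
  s2 <- stat_set(1:10, 1:10, d = seq(8, 2, length.out = 10))
  b2 <- bin_shells(s2, 2)
  expect_equal(b2$boundaries$d_min[1], ((1 / 2^3 + 1 / 8^3) / 2)^(-1 / 3))
  # each reflection lies inside its shell
  for (i in seq_len(nrow(s2))) {
    sh <- b2$assignment[i]
    expect_lte(s2$d[i], b2$boundaries$d_max[sh] + 1e-9)
    expect_gte(s2$d[i], b2$boundaries$d_min[sh] - 1e-9)
  }
  expect_error(bin_shells(s, 0), ">= 1")
})

test_that("CC1/2 matches hand-computed Pearson correlations", {
  b1 <- function(s) bin_shells(s, 1)
  ident <- stat_set(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cc_half(ident, b1(ident))$cc_half, 1.0)
  anti <- stat_set(c(1, 2, 3), c(3, 2, 1))
  expect_equal(cc_half(anti, b1(anti))$cc_half, -1.0)
  hand <- stat_set(c(1, 2, 3), c(1, 2, 4))
  expect_equal(cc_half(hand, b1(hand))$cc_half, 0.98198, tolerance = 1e-5)
  expect_equal(cc_half(hand, b1(hand))$cc_half,
               cor(c(1, 2, 3), c(1, 2, 4)))
  # fewer than 3 usable reflections: omitted
  two <- stat_set(c(1, 2), c(1, 2))
  expect_true(is.na(cc_half(two, b1(two))$cc_half))
  # reflections missing a half are excluded
  mixed <- stat_set(c(1, 2, 3, 4), c(1, 2, 4, 9))
  mixed$n_half2[4] <- 0L; mixed$I_half2[4] <- NA
  expect_equal(cc_half(mixed, b1(mixed))$n_used, 3L)
})

test_that("Rsplit matches its definition and is scale-invariant", {
  b1 <- function(s) bin_shells(s, 1)
  ident <- stat_set(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r_split(ident, b1(ident))$r_split, 0)
  one <- stat_set(2, 1)
  expect_equal(r_split(one, b1(one))$r_split, 100 / sqrt(2) / 1.5,
               tolerance = 1e-10)
  expect_equal(round(r_split(one, b1(one))$r_split, 2), 47.14)
  a <- stat_set(c(2, 3, 4), c(1, 5, 3))
  sc <- a; sc$I_half1 <- 7 * sc$I_half1; sc$I_half2 <- 7 * sc$I_half2
  expect_equal(r_split(a, b1(a))$r_split, r_split(sc, b1(sc))$r_split)
  # non-positive denominator is flagged as NA
  neg <- stat_set(c(-1, -2, -3), c(-2, -1, -3))
  expect_true(is.na(r_split(neg, b1(neg))$r_split))
})

test_that("second moments approach the Wilson expectations", {
  b1 <- function(s) bin_shells(s, 1)
  const <- stat_set(rep(4, 5), rep(4, 5))
  expect_equal(second_moment(const, b1(const))$second_moment, 1.0)
  two <- stat_set(c(0, 2), c(0, 2))
  expect_equal(second_moment(two, b1(two))$second_moment, 2.0)
  set.seed(71)
  ac <- stat_set(I1 = rep(1, 1e5), I2 = rep(1, 1e5), I_full = rexp(1e5))
  expect_equal(second_moment(ac, b1(ac))$second_moment, 2.0, tolerance = 0.01)
  cen <- stat_set(I1 = rep(1, 1e5), I2 = rep(1, 1e5),
                  I_full = rchisq(1e5, 1), centric = TRUE)
  expect_equal(second_moment(cen, b1(cen), acentric_only = FALSE)$second_moment,
               3.0, tolerance = 0.02 * 3)
  # centric reflections are excluded by default
  mix <- rbind(ac, cen)
  m_def <- second_moment(mix, bin_shells(mix, 1))$second_moment
  expect_equal(m_def, second_moment(ac, b1(ac))$second_moment, tolerance = 1e-12)
})

test_that("completeness counts observed against enumerated unique reflections", {
  cell <- unit_cell(10, 10, 10)
  g <- space_group("P1")
  refs <- unique_reflections(cell, g, Inf, 5)
  full <- data.frame(refs, I_full = 100, sigI_full = 1, n_obs = 2L,
                     I_half1 = 100, I_half2 = 100, n_half1 = 1L, n_half2 = 1L)
  b <- bin_shells(full, 1)
  expect_equal(shell_completeness(full, b, cell, g)$completeness, 100)
  drop1 <- full[-1, ]
  b2 <- bin_shells(drop1, 1)
  cp <- shell_completeness(drop1, b2, cell, g)
  # dropping 1 of 16 gives 15/16 against the full-range denominator;
  # the data range shrank, so allow the boundary effect explicitly
  expect_equal(cp$n_observed, 15)
  expect_equal(100 * 15 / 16, 93.75)
})

test_that("the shell table assembles consistent statistics with an overall row", {
  cfg <- small_clean_config(seed = 7)
  run <- simulate_run(cfg)
  idx <- indexed_images(run)
  ms <- merge_stills(idx, NULL, cfg$group, cfg$cell)
  st <- shell_table(ms, n_shells = 6)
  expect_equal(nrow(st), 6)
  expect_true(all(st$completeness == 100))
  expect_equal(st$cc_half, rep(1, 6))
  expect_lt(max(st$r_split), 1e-8)
  expect_true(all(st$n_unique_observed <= st$n_unique_theoretical))
  ov <- attr(st, "overall")
  expect_equal(ov$n_unique_observed, nrow(ms))
  expect_equal(ov$completeness, 100)
  expect_equal(sum(st$n_unique_observed), nrow(ms))
})

test_that("the cutoff rule stops at the first failing shell", {
  mk_table <- function(cc, d_min_shells, m2 = NULL, comp = NULL) {
    n <- length(cc)
    tab <- data.frame(
      shell = seq_len(n),
      d_max = c(d_min_shells[1] + 1, utils::head(d_min_shells, -1)),
      d_min = d_min_shells,
      cc_half = cc,
      second_moment = if (is.null(m2)) rep(1.9, n) else m2,
      completeness = if (is.null(comp)) rep(99, n) else comp)
    class(tab) <- c("shell_table", "data.frame")
    tab
  }
  tab <- mk_table(c(0.9, 0.8, 0.6, 0.4), c(3.0, 2.5, 2.0, 1.8))
  cut <- estimate_cutoff(tab, cc_min = 0.5)
  expect_equal(cut$d_cut, 2.0)
  expect_equal(cut$failed_metric, "cc_half")
  # all shells passing: overall d_min
  allpass <- mk_table(c(0.9, 0.8, 0.7, 0.6), c(3.0, 2.5, 2.0, 1.8))
  expect_equal(estimate_cutoff(allpass)$d_cut, 1.8)
  # shells beyond the first failure are ignored even if they pass again
  dip <- mk_table(c(0.9, 0.3, 0.9, 0.8), c(3.0, 2.5, 2.0, 1.8))
  expect_equal(estimate_cutoff(dip)$d_cut, 3.0)
  # first shell failing warns and returns the low-resolution boundary
  bad <- mk_table(c(0.2, 0.1), c(3.0, 2.5))
  expect_warning(cut0 <- estimate_cutoff(bad), "first shell")
  expect_equal(cut0$d_cut, bad$d_max[1])
  # monotonicity: relaxing any threshold never coarsens the cutoff
  tab2 <- mk_table(c(0.9, 0.7, 0.55, 0.4), c(3.0, 2.5, 2.0, 1.8),
                   m2 = c(1.8, 2.0, 2.3, 2.8), comp = c(99, 97, 92, 80))
  base <- estimate_cutoff(tab2, cc_min = 0.6, moment_max = 2.2,
                          completeness_min = 95)
  for (relax in list(c(0.5, 2.2, 95), c(0.6, 2.5, 95), c(0.6, 2.2, 90))) {
    r <- estimate_cutoff(tab2, cc_min = relax[1], moment_max = relax[2],
                         completeness_min = relax[3])
    expect_lte(r$d_cut, base$d_cut)
  }
})

test_that("CC1/2 and Rsplit respond to noise as theory predicts", {
  # decreasing noise drives CC1/2 -> 1 and Rsplit -> 0
  overall <- function(noise, seed) {
    cfg <- small_clean_config(seed = seed, plan = plan_scan(12, 12),
                              hit_rate = 0.6, obs_fraction = 0.8,
                              noise_sigma = noise)
    run <- simulate_run(cfg)
    idx <- indexed_images(run)
    ms <- merge_stills(idx, NULL, cfg$group, cfg$cell)
    b <- bin_shells(ms, 1)
    list(cc = cc_half(ms, b)$cc_half, rs = r_split(ms, b)$r_split,
         ms = ms, truth = run$truth$reflections)
  }
  res <- lapply(c(0.8, 0.2, 0.02), overall, seed = 73)
  ccs <- vapply(res, function(r) r$cc, numeric(1))
  rss <- vapply(res, function(r) r$rs, numeric(1))
  expect_true(all(diff(ccs) > 0))
  expect_true(all(diff(rss) < 0))
  expect_gt(ccs[3], 0.999)
  expect_lt(rss[3], 2)
  # analytic expectation tau^2/(tau^2 + sigma_half^2) within Fisher-z bounds
  r <- res[[2]]
  tr <- merge(as.data.frame(r$ms), r$truth[, c("h", "k", "l", "J")],
              by = c("h", "k", "l"))
  use <- tr$n_half1 >= 1 & tr$n_half2 >= 1
  tau2 <- var(tr$J[use])
  sig2 <- mean(c((tr$I_half1[use] - tr$J[use])^2,
                 (tr$I_half2[use] - tr$J[use])^2))
  pred <- tau2 / (tau2 + sig2)
  n <- sum(use)
  cc_obs <- cc_half(r$ms, bin_shells(r$ms, 1))$cc_half
  expect_lt(abs(atanh(cc_obs) - atanh(pred)), 1.96 / sqrt(n - 3) + 0.05)
})
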