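test_that("unit cell validates parameters and computes metric quantities", {
  uc <- unit_cell(10, 10, 10)
  expect_equal(uc$volume, 1000)
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, alpha = 190), "between 0 and 180")
  # degenerate angle combination: alpha + beta + gamma geometry impossible
  expect_error(unit_cell(10, 10, 10, 10, 10, 170), "impossible")
  hexa <- unit_cell(105.67, 105.67, 99.33, 90, 90, 120)
  expect_equal(hexa$a, hexa$b)
})

test_that("d-spacing matches axis reflections and closed forms", {
  hexa <- unit_cell(105.67, 105.67, 99.33, 90, 90, 120)
  ortho <- unit_cell(49.41, 69.35, 70.04)
  expect_equal(d_spacing(hexa, c(0, 0, 2)), 99.33 / 2)
  expect_equal(d_spacing(ortho, c(2, 0, 0)), 49.41 / 2)
  # hexagonal closed form 1/d^2 = (4/3)(h^2+hk+k^2)/a^2 + l^2/c^2
  hex_d <- function(h, k, l)
    1 / sqrt((4 / 3) * (h^2 + h * k + k^2) / 105.67^2 + l^2 / 99.33^2)
  ortho_d <- function(h, k, l)
    1 / sqrt(h^2 / 49.41^2 + k^2 / 69.35^2 + l^2 / 70.04^2)
  for (hkl in list(c(1, 1, 0), c(2, -1, 3), c(0, 3, 5), c(4, 2, 1))) {
    expect_equal(d_spacing(hexa, hkl), hex_d(hkl[1], hkl[2], hkl[3]),
                 tolerance = 1e-10)
    expect_equal(d_spacing(ortho, hkl), ortho_d(hkl[1], hkl[2], hkl[3]),
                 tolerance = 1e-10)
  }
  # Friedel symmetry
  expect_equal(d_spacing(hexa, c(2, -1, 3)), d_spacing(hexa, c(-2, 1, -3)))
  expect_error(d_spacing(ortho, c(0, 0, 0)), "not a valid reflection")
})

test_that("built-in groups are closed, contain identity, and reject bad input", {
  for (nm in space_group_names()) {
    g <- space_group(nm)
    expect_s3_class(g, "symmetry_group")
    expect_true(g$order >= 1)
  }
  expect_equal(space_group("P 21 21 21")$order, 4)
  expect_equal(space_group("P6422")$order, 12)
  expect_error(space_group("P313131"), "unknown")
  # a non-closed operator set is refused
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(
    symmetry_group("bad", list(diag(3), rot90z),
                   list(c(0, 0, 0), c(0, 0, 0)), "4/m"),
    "not closed")
})

test_that("ASU mapping picks the canonical orbit member and is idempotent", {
  g222 <- space_group("P212121")
  g622 <- space_group("P6422")
  expect_equal(as.integer(map_to_asu(g222, c(-1, 2, -3))), c(1, 2, 3))
  expect_equal(as.integer(map_to_asu(g622, c(-1, 1, 0))), c(1, 0, 0))
  # the canonical choice of (1,0,0) is confirmed by orbit enumeration
  orb <- orbit_oracle(g622, c(-1, 1, 0))
  expect_true(any(apply(orb, 1, function(r) all(r == c(1, 0, 0)))))
  # 24 signed operator images collapse to 6 distinct mates (stabiliser order 4)
  expect_equal(nrow(orb), 6)
  # idempotence and orbit consistency, randomised
  set.seed(11)
  for (nm in space_group_names()) {
    g <- space_group(nm)
    H <- matrix(sample(-6:6, 60, replace = TRUE), ncol = 3)
    H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
    asu <- map_to_asu(g, H)
    expect_equal(map_to_asu(g, asu), asu)
    for (i in seq_len(nrow(H))) {
      expect_equal(as.integer(map_to_asu(g, H[i, ])),
                   as.integer(canonical_oracle(g, H[i, ])))
      # every mate of the orbit maps to the same representative
      orb <- orbit_oracle(g, H[i, ])
      mapped <- map_to_asu(g, orb)
      expect_equal(nrow(unique(mapped)), 1)
    }
  }
  expect_error(map_to_asu(g222, c(0, 0, 0)), "not a valid reflection")
})

test_that("systematic absences follow the screw-axis reflection conditions", {
  expect_true(is_systematically_absent(space_group("P212121"), c(3, 0, 0)))
  expect_false(is_systematically_absent(space_group("P212121"), c(2, 0, 0)))
  set.seed(13)
  for (nm in space_group_names()) {
    g <- space_group(nm)
    H <- rbind(as.matrix(expand.grid(h = -5:5, k = 0, l = 0)),
               as.matrix(expand.grid(h = 0, k = -5:5, l = 0)),
               as.matrix(expand.grid(h = 0, k = 0, l = -5:5)),
               matrix(sample(-6:6, 45, replace = TRUE), ncol = 3))
    H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
    got <- is_systematically_absent(g, H)
    want <- apply(H, 1, function(r) absence_rule_oracle(g$name, r))
    expect_equal(got, unname(want), info = nm)
  }
})

test_that("centricity and epsilon factors behave as the point group dictates", {
  g222 <- space_group("P212121")
  # in 222 all principal zones are centric, general reflections are not
  expect_true(all(is_centric(g222, rbind(c(1, 2, 0), c(0, 2, 3), c(1, 0, 3)))))
  expect_false(is_centric(g222, c(1, 2, 3)))
  # P1 has no centric reflections
  expect_false(any(is_centric(space_group("P1"),
                              matrix(sample(-5:5, 30, replace = TRUE), ncol = 3))))
  # epsilon: axis reflections in 622 sit on the 6-fold
  g622 <- space_group("P6422")
  expect_equal(epsilon_factor(g622, c(0, 0, 6)), 6L)
  expect_equal(epsilon_factor(g622, c(1, 2, 3)), 1L)
  expect_equal(epsilon_factor(g222, c(5, 0, 0)), 2L)
})

test_that("unique reflection enumeration matches brute-force orbit counting", {
  cube <- unit_cell(10, 10, 10)
  p1 <- space_group("P1")
  ur <- unique_reflections(cube, p1, d_max = Inf, d_min = 5)
  expect_equal(nrow(ur), 16)
  expect_error(unique_reflections(cube, p1, d_max = 5, d_min = 5), "smaller")
  # every returned index is canonical, in range, present
  for (nm in c("P212121", "P6422", "P43212")) {
    g <- space_group(nm)
    cell <- switch(nm,
      P6422 = unit_cell(10, 10, 12, 90, 90, 120),
      P43212 = unit_cell(10, 10, 12),
      unit_cell(10, 11, 12))
    ur <- unique_reflections(cell, g, d_max = Inf, d_min = 4)
    expect_true(all(ur$d >= 4 - 1e-9))
    expect_equal(unname(map_to_asu(g, ur)), as_hkl_mat(ur))
    expect_false(any(is_systematically_absent(g, ur)))
    expect_equal(nrow(ur), unique_count_oracle(cell, g, Inf, 4), info = nm)
  }
  # the exclude_absent flag restores the screw-axis reflections
  g <- space_group("P212121")
  cell <- unit_cell(10, 11, 12)
  n_with <- nrow(unique_reflections(cell, g, Inf, 4, exclude_absent = FALSE))
  n_without <- nrow(unique_reflections(cell, g, Inf, 4, exclude_absent = TRUE))
  expect_equal(n_with, unique_count_oracle(cell, g, Inf, 4, exclude_absent = FALSE))
  expect_gt(n_with, n_without)
})

test_that("a symmetry group loads from a JSON config file", {
  cfg <- list(name = "P21 config", laue_class = "2/m",
              crystal_system = "monoclinic",
              rotations = list(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                               c(-1, 0, 0, 0, 1, 0, 0, 0, -1)),
              translations = list(list("0", "0", "0"),
                                  list("0", "1/2", "0")))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  g <- read_symmetry_config(path)
  expect_equal(g$order, 2)
  expect_true(is_systematically_absent(g, c(0, 3, 0)))
  expect_false(is_systematically_absent(g, c(0, 2, 0)))
})
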