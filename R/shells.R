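#' Assign unique reflections to resolution shells
#'
#' Equal-volume binning: shell boundaries are equally spaced in 1/d^3
#' between the resolution limits of the data, so each shell covers the
#' same reciprocal-space volume and holds a comparable number of
#' reflections.
#'
#' @param set A `merged_set` (or any data frame with a `d` column).
#' @param n_shells Number of shells (>= 1, default 20).
#' @return An object of class `shell_binning`: list with `boundaries`
#'   (data frame `shell, d_max, d_min`) and `assignment` (integer shell
#'   index per row of `set`; shell 1 is the lowest-resolution shell).
#' @export
bin_shells <- function(set, n_shells = 20) {
  if (n_shells < 1) stop("n_shells must be >= 1")
  if (nrow(set) == 0) stop("empty reflection set")
  d <- set$d
  s <- 1 / d^3
  edges <- seq(min(s), max(s), length.out = n_shells + 1)
  # findInterval with rightmost.closed keeps the top shell inclusive
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > n_shells] <- n_shells
  boundaries <- data.frame(
    shell = seq_len(n_shells),
    d_max = utils::head(edges, -1)^(-1 / 3),
    d_min = utils::tail(edges, -1)^(-1 / 3))
  structure(list(boundaries = boundaries, assignment = as.integer(idx),
                 n_shells = as.integer(n_shells)),
            class = "shell_binning")
}

usable_half_rows <- function(set) {
  set$n_half1 >= 1 & set$n_half2 >= 1 &
    !is.na(set$I_half1) & !is.na(set$I_half2)
}

per_shell_stat <- function(set, shells, fun, min_n = 1L) {
  n_shells <- shells$n_shells
  out <- rep(NA_real_, n_shells)
  n_used <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    rows <- set[shells$assignment == s, , drop = FALSE]
    n_used[s] <- nrow(rows)
    if (nrow(rows) >= min_n) out[s] <- fun(rows)
  }
  list(value = out, n = n_used)
}

#' Half-dataset correlation CC1/2 per shell
#'
#' Pearson correlation between the two half-dataset merged intensities
#' over the unique reflections of each shell. Reflections missing either
#' half are excluded; shells with fewer than three usable reflections are
#' reported as `NA`.
#'
#' @param set A `merged_set` with half columns.
#' @param shells A [bin_shells()] result.
#' @return Data frame `shell, cc_half, n_used`.
#' @export
cc_half <- function(set, shells) {
  use <- usable_half_rows(set)
  n_shells <- shells$n_shells
  cc <- rep(NA_real_, n_shells)
  n_used <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    rows <- which(shells$assignment == s & use)
    n_used[s] <- length(rows)
    if (length(rows) >= 3) {
      x <- set$I_half1[rows]; y <- set$I_half2[rows]
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        cc[s] <- stats::cor(x, y)
      else if (all(x == y)) cc[s] <- 1
    }
  }
  data.frame(shell = seq_len(n_shells), cc_half = cc, n_used = n_used)
}

#' Half-dataset discrepancy Rsplit per shell
#'
#' `Rsplit = (1/sqrt(2)) * sum|I1 - I2| / (0.5 * sum(I1 + I2))`, in
#' percent, over the usable unique reflections of each shell. Shells with
#' a non-positive denominator are reported as `NA`.
#'
#' @inheritParams cc_half
#' @return Data frame `shell, r_split, n_used`.
#' @export
r_split <- function(set, shells) {
  use <- usable_half_rows(set)
  n_shells <- shells$n_shells
  rs <- rep(NA_real_, n_shells)
  n_used <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    rows <- which(shells$assignment == s & use)
    n_used[s] <- length(rows)
    if (length(rows) >= 1) {
      den <- 0.5 * sum(set$I_half1[rows] + set$I_half2[rows])
      if (den > 0)
        rs[s] <- 100 / sqrt(2) * sum(abs(set$I_half1[rows] - set$I_half2[rows])) / den
    }
  }
  data.frame(shell = seq_len(n_shells), r_split = rs, n_used = n_used)
}

#' Second intensity moment per shell
#'
#' The ratio `<I^2> / <I>^2` of merged intensities, by default over
#' acentric reflections only, for which Wilson statistics give an
#' expectation of 2 (centric reflections give 3); values well above 2
#' indicate noise-dominated or pathological shells. Shells whose mean
#' intensity is not positive are reported as `NA`.
#'
#' @inheritParams cc_half
#' @param acentric_only Use only acentric reflections (default `TRUE`).
#' @return Data frame `shell, second_moment, n_used`.
#' @export
second_moment <- function(set, shells, acentric_only = TRUE) {
  keep <- if (acentric_only && "centric" %in% names(set)) !set$centric
          else rep(TRUE, nrow(set))
  n_shells <- shells$n_shells
  m2 <- rep(NA_real_, n_shells)
  n_used <- integer(n_shells)
  for (s in seq_len(n_shells)) {
    rows <- which(shells$assignment == s & keep)
    n_used[s] <- length(rows)
    if (length(rows) >= 1) {
      mi <- mean(set$I_full[rows])
      if (mi > 0) m2[s] <- mean(set$I_full[rows]^2) / mi^2
    }
  }
  data.frame(shell = seq_len(n_shells), second_moment = m2, n_used = n_used)
}

#' Completeness per shell
#'
#' `100 * n_unique_observed / n_unique_theoretical` per shell, where the
#' theoretical count comes from [unique_reflections()] over the data's
#' resolution range assigned to the same shell boundaries (systematic
#' absences excluded from the denominator).
#'
#' @inheritParams cc_half
#' @param cell A [unit_cell()].
#' @param group A [symmetry_group()].
#' @return Data frame `shell, completeness, n_observed, n_theoretical`.
#' @export
shell_completeness <- function(set, shells, cell, group) {
  b <- shells$boundaries
  theo <- unique_reflections(cell, group,
                             d_max = max(b$d_max) * (1 + 1e-9),
                             d_min = min(b$d_min) * (1 - 1e-9),
                             exclude_absent = TRUE)
  s_theo <- 1 / theo$d^3
  edges <- c(1 / b$d_max^3, 1 / b$d_min[shells$n_shells]^3)
  idx <- findInterval(s_theo, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > shells$n_shells] <- shells$n_shells
  n_theo <- tabulate(idx, nbins = shells$n_shells)
  n_obs <- tabulate(shells$assignment, nbins = shells$n_shells)
  comp <- ifelse(n_theo > 0, 100 * pmin(n_obs, n_theo) / n_theo, NA_real_)
  data.frame(shell = seq_len(shells$n_shells), completeness = comp,
             n_observed = n_obs, n_theoretical = n_theo)
}

#' Full per-shell statistics table
#'
#' Combines completeness, multiplicity, mean I/sigma, CC1/2, Rsplit and
#' the second intensity moment into one table, ordered from low to high
#' resolution, with an overall row (computed over all unique reflections,
#' not averaged over shells) appended as attribute `overall`.
#'
#' @param set A `merged_set` from [merge_stills()].
#' @param n_shells Number of equal-volume shells (default 20).
#' @param cell,group Defaults taken from the merged set's attributes.
#' @return An object of class `shell_table` (data frame, one row per
#'   shell) with columns `shell, d_max, d_min, n_unique_observed,
#'   n_unique_theoretical, completeness, multiplicity, mean_i_sig,
#'   cc_half, r_split, second_moment`; attribute `overall` holds the
#'   overall row and `binning` the shell assignment.
#' @export
shell_table <- function(set, n_shells = 20, cell = attr(set, "cell"),
                        group = attr(set, "group")) {
  if (is.null(cell) || is.null(group))
    stop("cell and group must be supplied or carried by the merged set")
  shells <- bin_shells(set, n_shells)
  comp <- shell_completeness(set, shells, cell, group)
  cc <- cc_half(set, shells)
  rs <- r_split(set, shells)
  m2 <- second_moment(set, shells)
  mult <- per_shell_stat(set, shells, function(r) mean(r$n_obs))
  isig <- per_shell_stat(set, shells, function(r) mean(r$I_full / r$sigI_full))
  out <- data.frame(
    shell = shells$boundaries$shell,
    d_max = shells$boundaries$d_max,
    d_min = shells$boundaries$d_min,
    n_unique_observed = comp$n_observed,
    n_unique_theoretical = comp$n_theoretical,
    completeness = comp$completeness,
    multiplicity = mult$value,
    mean_i_sig = isig$value,
    cc_half = cc$cc_half,
    r_split = rs$r_split,
    second_moment = m2$second_moment)
  one <- bin_shells(set, 1)
  cc1 <- cc_half(set, one); rs1 <- r_split(set, one); m21 <- second_moment(set, one)
  comp1 <- shell_completeness(set, one, cell, group)
  overall <- data.frame(
    d_max = max(set$d), d_min = min(set$d),
    n_unique_observed = nrow(set),
    n_unique_theoretical = comp1$n_theoretical,
    completeness = comp1$completeness,
    multiplicity = mean(set$n_obs),
    mean_i_sig = mean(set$I_full / set$sigI_full),
    cc_half = cc1$cc_half, r_split = rs1$r_split,
    second_moment = m21$second_moment)
  attr(out, "overall") <- overall
  attr(out, "binning") <- shells
  class(out) <- c("shell_table", "data.frame")
  out
}

#' Automated resolution cutoff from shell statistics
#'
#' Scans the shell table from low to high resolution and keeps shells as
#' long as CC1/2 stays at or above `cc_min`, the second moment stays at
#' or below `moment_max`, and completeness stays at or above
#' `completeness_min`. The cutoff is the `d_min` of the last shell before
#' the first failure; shells beyond the first failure are not considered
#' even if they pass again. A metric that is `NA` in a shell (too few
#' reflections to evaluate) does not veto that shell.
#'
#' @param table A [shell_table()].
#' @param cc_min Minimum CC1/2 (default 0.5).
#' @param moment_max Maximum acentric second moment (default 2.5: the
#'   Wilson expectation of 2 plus slack for gradual noise inflation).
#' @param completeness_min Minimum completeness in percent (default 90).
#' @return List with `d_cut` (Angstrom), `last_shell` (index), and
#'   `failed_metric` (name of the metric that ended the scan, or `NA` if
#'   all shells pass). If the first shell already fails, `d_cut` is the
#'   low-resolution boundary and a warning is raised.
#' @export
estimate_cutoff <- function(table, cc_min = 0.5, moment_max = 2.5,
                            completeness_min = 90) {
  stopifnot(inherits(table, "shell_table"))
  tab <- table[order(-table$d_max), , drop = FALSE]
  pass_one <- function(x, ok) is.na(x) | ok(x)
  failed <- NA_character_
  last <- 0L
  for (i in seq_len(nrow(tab))) {
    ok_cc <- pass_one(tab$cc_half[i], function(x) x >= cc_min)
    ok_m2 <- pass_one(tab$second_moment[i], function(x) x <= moment_max)
    ok_cp <- pass_one(tab$completeness[i], function(x) x >= completeness_min)
    if (ok_cc && ok_m2 && ok_cp) {
      last <- i
    } else {
      failed <- if (!ok_cc) "cc_half" else if (!ok_m2) "second_moment"
                else "completeness"
      break
    }
  }
  if (last == 0L) {
    warning("first shell already fails the cutoff criteria (", failed, ")")
    return(list(d_cut = tab$d_max[1], last_shell = 0L, failed_metric = failed))
  }
  list(d_cut = tab$d_min[last], last_shell = last, failed_metric = failed)
}

#' Write a shell table as CSV and JSON
#'
#' @param table A [shell_table()].
#' @param csv_path,json_path Output file paths (either may be `NULL`).
#' @return Invisibly, the table.
#' @export
write_shell_table <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(table), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(shells = as.data.frame(table),
                              overall = attr(table, "overall")),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(table)
}
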