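#' DVH summary of a structure
#'
#' Computes cumulative dose-volume-histogram statistics over the voxels of a
#' mask: `d_max` (single-voxel maximum), `d_mean` (arithmetic mean), `V(x)`
#' (volume receiving at least `x` Gy, closed at the level, in cc and % of
#' the structure volume) and `D(p%)` (the minimum dose received by the
#' hottest `p%` of the structure, by the order-statistic rule: the
#' `ceiling(p/100 * n)`-th largest voxel dose).
#'
#' @param grid a [dose_grid()].
#' @param mask a non-empty [voxel_mask()] on the same header.
#' @param name structure name carried into the summary.
#' @param v_levels numeric vector of dose levels (Gy) for `V(x)`.
#' @param d_levels numeric vector of relative volumes (%, in (0, 100]) for
#'   `D(p%)`.
#' @return An object of class `dvh_summary` with fields `structure`,
#'   `d_max`, `d_mean`, `volume_cc`, `v_at` (data.frame: dose_gy, cc, pct)
#'   and `d_at` (data.frame: pct, dose_gy).
#' @examples
#' h <- grid_header(c(8, 1, 1), spacing = c(2.5, 2.5, 2.5))
#' g <- dose_grid(h, seq(10, 80, by = 10))
#' m <- voxel_mask(h, rep(TRUE, 8))
#' dvh_summary(g, m, v_levels = 60, d_levels = 25)
#' @export
dvh_summary <- function(grid, mask, name = "structure",
                        v_levels = numeric(0), d_levels = numeric(0)) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "voxel_mask"))
  stop_if_geometry_differs(grid$header, mask$header, "dose grid and mask")
  doses <- grid$values[mask$flags]
  n <- length(doses)
  if (n == 0L)
    stop("empty-ROI error: mask selects no voxels", call. = FALSE)
  vox_cc <- prod(grid$header$spacing) / 1000
  v_at <- NULL
  if (length(v_levels)) {
    counts <- vapply(v_levels, function(x) sum(doses >= x), numeric(1))
    v_at <- data.frame(dose_gy = v_levels, cc = counts * vox_cc,
                       pct = 100 * counts / n)
  }
  d_at <- NULL
  if (length(d_levels)) {
    if (any(d_levels <= 0 | d_levels > 100))
      stop("`d_levels` must lie in (0, 100]", call. = FALSE)
    sorted <- sort(doses, decreasing = TRUE)
    k <- pmin(pmax(ceiling(d_levels / 100 * n), 1L), n)
    d_at <- data.frame(pct = d_levels, dose_gy = sorted[k])
  }
  structure(list(structure = name, d_max = max(doses), d_mean = mean(doses),
                 volume_cc = n * vox_cc, v_at = v_at, d_at = d_at),
            class = "dvh_summary")
}

#' @export
print.dvh_summary <- function(x, ...) {
  cat(sprintf("<dvh_summary> %s: %.4g cc, Dmax %.4g Gy, Dmean %.4g Gy\n",
              x$structure, x$volume_cc, x$d_max, x$d_mean))
  if (!is.null(x$v_at))
    for (i in seq_len(nrow(x$v_at)))
      cat(sprintf("  V%g Gy = %.4g cc (%.2f%%)\n",
                  x$v_at$dose_gy[i], x$v_at$cc[i], x$v_at$pct[i]))
  if (!is.null(x$d_at))
    for (i in seq_len(nrow(x$d_at)))
      cat(sprintf("  D%g%% = %.4g Gy\n", x$d_at$pct[i], x$d_at$dose_gy[i]))
  invisible(x)
}

#' Relative mean-dose difference between evaluated and reference (%)
#'
#' `Diff = (Dmean_eval - Dmean_ref) / Dmean_ref * 100`, signed: negative
#' when the evaluated algorithm underestimates the structure mean dose
#' relative to the reference (e.g. an air cavity), positive when it
#' overestimates it (e.g. bone).
#'
#' @param d_mean_eval evaluated (planning-system) mean dose, Gy.
#' @param d_mean_ref reference (Monte Carlo) mean dose, Gy; must be > 0.
#' @return Signed percentage difference.
#' @examples
#' relative_dmean_diff(98.4, 100)   # -1.6
#' relative_dmean_diff(102.3, 100)  # +2.3
#' @export
relative_dmean_diff <- function(d_mean_eval, d_mean_ref) {
  if (!is.numeric(d_mean_ref) || any(d_mean_ref <= 0))
    stop("domain error: reference mean dose must be > 0", call. = FALSE)
  100 * (d_mean_eval - d_mean_ref) / d_mean_ref
}

#' Define an organ-at-risk dose constraint
#'
#' Encodes the usual clinical constraint families: `Dmax < bound Gy`,
#' `Dmean < bound Gy`, `V(dose Gy) < bound cc` and `V(dose Gy) < bound %`.
#' All comparisons are strict (`<`): a value exactly at the bound fails.
#'
#' @param metric one of `"Dmax"`, `"Dmean"`, `"V_at_dose_abs"`,
#'   `"V_at_dose_rel"`.
#' @param bound the constraint bound (> 0): Gy for dose metrics, cc for
#'   `V_at_dose_abs`, % for `V_at_dose_rel`.
#' @param dose_gy the dose level for the `V` metrics (ignored otherwise).
#' @return An object of class `dose_constraint`.
#' @examples
#' constraint("Dmax", 54)              # brainstem-style Dmax < 54 Gy
#' constraint("V_at_dose_abs", 2, 60)  # temporal-lobe-style V60 < 2 cc
#' @export
constraint <- function(metric = c("Dmax", "Dmean", "V_at_dose_abs", "V_at_dose_rel"),
                       bound, dose_gy = NULL) {
  metric <- match.arg(metric)
  if (!is.numeric(bound) || bound <= 0)
    stop("constraint bound must be > 0", call. = FALSE)
  if (metric %in% c("V_at_dose_abs", "V_at_dose_rel") &&
      (is.null(dose_gy) || dose_gy <= 0))
    stop(sprintf("metric '%s' needs a positive `dose_gy` level", metric), call. = FALSE)
  structure(list(metric = metric, bound = bound, dose_gy = dose_gy),
            class = "dose_constraint")
}

#' Check a DVH summary against a constraint
#'
#' @param summary a [dvh_summary()] containing the metric the constraint
#'   needs (for `V` constraints, a `v_at` row at the constraint's dose
#'   level).
#' @param cons a [constraint()].
#' @return `TRUE` (pass) or `FALSE` (fail); strict comparison, so equality
#'   with the bound fails.
#' @export
check_constraint <- function(summary, cons) {
  stopifnot(inherits(summary, "dvh_summary"), inherits(cons, "dose_constraint"))
  value <- switch(cons$metric,
    Dmax = summary$d_max,
    Dmean = summary$d_mean,
    V_at_dose_abs = ,
    V_at_dose_rel = {
      if (is.null(summary$v_at))
        stop("specification error: summary has no V(x) entries", call. = FALSE)
      row <- which(abs(summary$v_at$dose_gy - cons$dose_gy) < 1e-9)
      if (length(row) == 0L)
        stop(sprintf("specification error: summary has no V at %g Gy", cons$dose_gy),
             call. = FALSE)
      if (cons$metric == "V_at_dose_abs") summary$v_at$cc[row[1]]
      else summary$v_at$pct[row[1]]
    })
  value < cons$bound
}

#' Export DVH summaries as a CSV report
#'
#' One row per structure x metric, suitable for spreadsheet review.
#'
#' @param summaries list of [dvh_summary()] objects.
#' @param path output CSV path.
#' @return The report data.frame, invisibly.
#' @export
write_dvh_csv <- function(summaries, path) {
  rows <- list()
  for (s in summaries) {
    rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "Dmax",
                                            level = NA_real_, value = s$d_max, unit = "Gy")
    rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "Dmean",
                                            level = NA_real_, value = s$d_mean, unit = "Gy")
    rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "Volume",
                                            level = NA_real_, value = s$volume_cc, unit = "cc")
    if (!is.null(s$v_at))
      for (i in seq_len(nrow(s$v_at))) {
        rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "V",
                                                level = s$v_at$dose_gy[i],
                                                value = s$v_at$cc[i], unit = "cc")
        rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "V",
                                                level = s$v_at$dose_gy[i],
                                                value = s$v_at$pct[i], unit = "%")
      }
    if (!is.null(s$d_at))
      for (i in seq_len(nrow(s$d_at)))
        rows[[length(rows) + 1L]] <- data.frame(structure = s$structure, metric = "D",
                                                level = s$d_at$pct[i],
                                                value = s$d_at$dose_gy[i], unit = "Gy")
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
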