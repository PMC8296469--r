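#' Gamma evaluation criteria
#'
#' Parameters of the global 3D gamma-index evaluation. Defaults follow the
#' common clinical QA convention: 3% dose difference (of the global
#' reference maximum), 2 mm distance to agreement, and suppression of
#' voxels whose reference dose is below 10% of the reference maximum.
#'
#' @param dose_diff_pct dose-difference criterion, % of the global
#'   reference maximum (> 0).
#' @param dta_mm distance-to-agreement criterion in mm (> 0).
#' @param suppression_pct reference voxels below this % of the reference
#'   maximum are excluded from scoring (> 0).
#' @param search_cap_mm maximum radius of the distance-to-agreement search,
#'   mm; must be at least `dta_mm`. Gamma values whose minimum is not
#'   bracketed inside the cap are reported as the cap-boundary minimum
#'   (at least `search_cap_mm / dta_mm`).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 2, suppression_pct = 10,
                           search_cap_mm = 3 * dta_mm) {
  if (!all(c(dose_diff_pct, dta_mm, suppression_pct, search_cap_mm) > 0))
    stop("all gamma criteria must be > 0", call. = FALSE)
  if (search_cap_mm < dta_mm)
    stop("`search_cap_mm` must be at least `dta_mm`", call. = FALSE)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 suppression_pct = suppression_pct, search_cap_mm = search_cap_mm),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %g%% suppression, search cap %g mm\n",
              x$dose_diff_pct, x$dta_mm, x$suppression_pct, x$search_cap_mm))
  invisible(x)
}

gamma_common <- function(reference, evaluated, criteria, roi, normalization, brute) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  stop_if_geometry_differs(reference$header, evaluated$header,
                           "reference and evaluated dose grids")
  h <- reference$header
  scored <- rep(TRUE, n_voxels(h))
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "voxel_mask"))
    stop_if_geometry_differs(reference$header, roi$header, "dose grid and ROI mask")
    scored <- roi$flags
  }
  norm_max <- if (normalization == "global") max(reference$values)
              else max(reference$values[scored], 0)
  if (norm_max <= 0)
    stop("reference maximum dose must be > 0", call. = FALSE)
  thresh <- criteria$suppression_pct / 100 * norm_max
  scored <- scored & (reference$values >= thresh)
  if (!any(scored))
    stop(sprintf("empty-ROI error: every voxel is below the %g%% suppression level",
                 criteria$suppression_pct), call. = FALSE)
  dd_abs <- criteria$dose_diff_pct / 100 * norm_max
  idx0 <- which(scored) - 1L
  g <- gamma_engine_cpp(reference$values, evaluated$values, h$dims, h$spacing,
                        idx0, dd_abs, criteria$dta_mm, criteria$search_cap_mm,
                        criteria$dta_mm / 10, brute)
  gamma_map <- rep(NA_real_, n_voxels(h))
  gamma_map[scored] <- g
  # the 1e-9 slack only resolves exact-boundary ties (e.g. a uniform
  # dose_diff_pct scaling) that double rounding would otherwise flip
  passing <- sum(g <= 1 + 1e-9)
  structure(list(header = h,
                 gamma_map = gamma_map,
                 analyzed_count = length(g),
                 passing_rate_pct = 100 * passing / length(g),
                 criteria = criteria,
                 normalization = normalization),
            class = "gamma_result")
}

#' Global 3D gamma-index evaluation
#'
#' Compares an evaluated dose distribution against a reference on the same
#' grid. For each scored reference voxel the gamma index is the minimum over
#' candidate positions r of
#' `sqrt(|r - r_ref|^2 / dta^2 + (D_eval(r) - D_ref(r_ref))^2 / dD^2)`,
#' with `dD = dose_diff_pct/100 * max(reference)` (global normalization).
#' Candidate positions form an isotropic lattice of step `dta_mm / 10`
#' truncated to a ball of radius `search_cap_mm`; the evaluated dose is
#' trilinearly interpolated there. Scored voxels are the ROI (all voxels if
#' none is given) minus voxels whose reference dose falls below the
#' suppression level. A voxel passes when gamma <= 1 (the boundary passes);
#' the passing rate is the percentage of scored voxels that pass.
#'
#' The minimization prunes candidates whose distance term alone exceeds the
#' running minimum, which is exact: results are identical to the exhaustive
#' [gamma_bruteforce()] oracle.
#'
#' @param reference reference [dose_grid()] (e.g. a Monte Carlo
#'   recalculation); its maximum sets the global normalization and the
#'   suppression level.
#' @param evaluated evaluated [dose_grid()] (e.g. the planning-system dose);
#'   must share the reference's exact grid header.
#' @param criteria a [gamma_criteria()].
#' @param roi optional [voxel_mask()] restricting scoring to a structure.
#' @param normalization `"global"` (default; reference maximum over the
#'   whole grid) or `"roi"` (reference maximum inside the ROI).
#' @return An object of class `gamma_result`: `gamma_map` (per-voxel gamma,
#'   `NA` where unscored), `analyzed_count`, `passing_rate_pct`, plus the
#'   criteria used.
#' @examples
#' h <- grid_header(c(8, 8, 8))
#' ref <- dose_grid(h, rep(50, 512))
#' compute_gamma(ref, ref)$passing_rate_pct  # identical doses: 100
#' @export
compute_gamma <- function(reference, evaluated, criteria = gamma_criteria(),
                          roi = NULL, normalization = c("global", "roi")) {
  normalization <- match.arg(normalization)
  gamma_common(reference, evaluated, criteria, roi, normalization, brute = FALSE)
}

#' Exhaustive gamma-index oracle
#'
#' Identical contract and search lattice as [compute_gamma()], but the
#' minimization enumerates every lattice candidate with no pruning. It
#' exists as an independent equivalence oracle for the accelerated engine
#' and is limited to grids of at most 32^3 voxels.
#'
#' @inheritParams compute_gamma
#' @return An object of class `gamma_result`.
#' @export
gamma_bruteforce <- function(reference, evaluated, criteria = gamma_criteria(),
                             roi = NULL, normalization = c("global", "roi")) {
  normalization <- match.arg(normalization)
  if (n_voxels(reference$header) > 32768)
    stop("size error: gamma_bruteforce is limited to grids of at most 32^3 voxels",
         call. = FALSE)
  gamma_common(reference, evaluated, criteria, roi, normalization, brute = TRUE)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: %d voxels analyzed, passing rate %.2f%%\n",
              x$criteria$dose_diff_pct, x$criteria$dta_mm,
              x$analyzed_count, x$passing_rate_pct))
  invisible(x)
}

#' Passing rate of a gamma result inside a mask
#'
#' Re-scores an existing gamma map on a sub-ROI. Because the per-voxel gamma
#' value does not depend on the ROI (only the scored set does), this equals
#' running [compute_gamma()] with that ROI directly, at no extra cost.
#'
#' @param result a `gamma_result`.
#' @param mask a [voxel_mask()] on the same grid.
#' @return List with `passing_rate_pct` and `analyzed_count` over the scored
#'   voxels inside `mask`.
#' @export
gamma_rate_in_mask <- function(result, mask) {
  stopifnot(inherits(result, "gamma_result"), inherits(mask, "voxel_mask"))
  stop_if_geometry_differs(result$header, mask$header, "gamma map and mask")
  g <- result$gamma_map[mask$flags & !is.na(result$gamma_map)]
  if (length(g) == 0L)
    stop("empty-ROI error: mask contains no scored voxels", call. = FALSE)
  list(passing_rate_pct = 100 * sum(g <= 1 + 1e-9) / length(g),
       analyzed_count = length(g))
}

#' Export a gamma map as a DGRID v1 file
#'
#' The unit line is written as `Gy` (the DGRID payload slot), with the
#' documented meaning "gamma"; unscored voxels are written as -1.
#'
#' @param result a `gamma_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gamma_map <- function(result, path) {
  stopifnot(inherits(result, "gamma_result"))
  vals <- result$gamma_map
  vals[is.na(vals)] <- -1
  h <- result$header
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DGRID 1",
               sprintf("dims %d %d %d", h$dims[1], h$dims[2], h$dims[3]),
               sprintf("origin %.17g %.17g %.17g", h$origin[1], h$origin[2], h$origin[3]),
               sprintf("spacing %.17g %.17g %.17g", h$spacing[1], h$spacing[2], h$spacing[3]),
               "unit Gy"), con)
  payload <- sprintf("%.17g", vals)
  rows <- split(payload, (seq_along(payload) - 1L) %/% 8L)
  writeLines(vapply(rows, paste, "", collapse = " "), con)
  invisible(path)
}
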