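#' Per-case QA run configuration
#'
#' @param criteria a [gamma_criteria()] (default 3%/2 mm, 10% suppression).
#' @param roles named character vector mapping analysis roles to structure
#'   names; must contain `target`, `air` and `bone`. Additional entries
#'   (e.g. OARs) are scored as well.
#' @param v_levels dose levels (Gy) for DVH `V(x)` metrics.
#' @param d_levels relative volumes (%) for DVH `D(p%)` metrics.
#' @param gamma_star cohort crossing level, % (default 95).
#' @return An object of class `run_config`.
#' @export
run_config <- function(criteria = gamma_criteria(),
                       roles = c(target = "target", air = "air", bone = "bone"),
                       v_levels = numeric(0), d_levels = numeric(0),
                       gamma_star = 95) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  if (!all(c("target", "air", "bone") %in% names(roles)))
    stop("`roles` must name `target`, `air` and `bone` structures", call. = FALSE)
  structure(list(criteria = criteria, roles = roles, v_levels = v_levels,
                 d_levels = d_levels, gamma_star = gamma_star),
            class = "run_config")
}

#' Run the per-case QA analysis
#'
#' Computes the entire-plan gamma passing rate (all non-suppressed voxels),
#' per-structure gamma passing rates, per-structure relative Dmean
#' differences (evaluated vs reference), and the voxelized air/bone
#' volumes. The gamma map is computed once over all non-suppressed voxels
#' and re-scored per structure, which is exactly equivalent to evaluating
#' each ROI separately (the per-voxel gamma does not depend on the ROI).
#'
#' @param reference,evaluated [dose_grid()] objects on one header.
#' @param masks named list of [voxel_mask()] objects containing at least
#'   the structures named by `config$roles`.
#' @param config a [run_config()].
#' @param case_id,algorithm,cohort labels carried into the record.
#' @param keep_gamma_map if `TRUE` the entire-plan `gamma_result` is
#'   attached as attribute `"gamma"`.
#' @return A [case_record()].
#' @export
run_case <- function(reference, evaluated, masks, config = run_config(),
                     case_id = "case", algorithm = "TPS", cohort = NA_character_,
                     keep_gamma_map = FALSE) {
  stopifnot(inherits(config, "run_config"))
  for (role in names(config$roles)) {
    nm <- config$roles[[role]]
    if (!nm %in% names(masks))
      stop(sprintf("configuration error: role '%s' refers to missing structure '%s'",
                   role, nm), call. = FALSE)
  }
  for (nm in names(masks))
    stop_if_geometry_differs(reference$header, masks[[nm]]$header,
                             sprintf("dose grid and mask '%s'", nm))

  g <- compute_gamma(reference, evaluated, config$criteria)
  gamma_pct <- c(entire_plan = g$passing_rate_pct)
  diff_pct <- numeric(0)
  for (role in names(config$roles)) {
    nm <- config$roles[[role]]
    gamma_pct[[role]] <- gamma_rate_in_mask(g, masks[[nm]])$passing_rate_pct
    d_ref <- dvh_summary(reference, masks[[nm]], nm)
    d_eval <- dvh_summary(evaluated, masks[[nm]], nm)
    diff_pct[[role]] <- relative_dmean_diff(d_eval$d_mean, d_ref$d_mean)
  }
  rec <- case_record(case_id, algorithm, gamma_pct, diff_pct,
                     v_air_cc = volume_cc(masks[[config$roles[["air"]]]]),
                     v_bone_cc = volume_cc(masks[[config$roles[["bone"]]]]),
                     cohort = cohort)
  if (keep_gamma_map) attr(rec, "gamma") <- g
  rec
}

#' Run the cohort analysis from a manifest
#'
#' Reads every case of a [generate_cohort()] manifest, runs [run_case()]
#' per algorithm label, and writes the report bundle: `case_records.csv`,
#' `summary.csv`, `scatter_<algorithm>.csv` (volume / rate pairs for
#' plotting), `fits.json` and `run.log`. Unreadable cases are skipped with
#' a warning; fewer than 3 usable cases aborts.
#'
#' @param manifest manifest data.frame or path to `manifest.csv`.
#' @param config a [run_config()].
#' @param out_dir report output directory.
#' @return A `cohort_summary`, invisibly.
#' @export
run_cohort <- function(manifest, config = run_config(), out_dir) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eval_cols <- grep("^evaluated_", names(manifest), value = TRUE)
  if (length(eval_cols) == 0)
    stop("manifest has no evaluated_* dose columns", call. = FALSE)
  records <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      masks <- list(target = read_dgrid(row$target),
                    air = read_dgrid(row$air),
                    bone = read_dgrid(row$bone))
      reference <- read_dgrid(row$reference)
      lapply(eval_cols, function(col) {
        run_case(reference, read_dgrid(row[[col]]), masks, config,
                 case_id = row$case_id, algorithm = sub("^evaluated_", "", col))
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping case %s: %s", row$case_id, conditionMessage(res)),
              call. = FALSE)
      skipped <- c(skipped, row$case_id)
    } else {
      records <- c(records, res)
    }
  }
  n_usable <- length(unique(vapply(records, function(r) r$case_id, "")))
  if (n_usable < 3)
    stop(sprintf("fewer than 3 usable cases (%d); aborting cohort analysis", n_usable),
         call. = FALSE)
  summary <- summarize_cohort(records, gamma_star = config$gamma_star)
  write_cohort_reports(records, summary, config, out_dir, skipped)
  invisible(summary)
}

write_cohort_reports <- function(records, summary, config, out_dir, skipped = character(0)) {
  df <- records_to_df(records)
  utils::write.csv(df, file.path(out_dir, "case_records.csv"), row.names = FALSE)
  utils::write.csv(summary$table, file.path(out_dir, "summary.csv"), row.names = FALSE)
  for (al in names(summary$fits)) {
    sub <- df[df$algorithm == al & df$metric == "gamma_pct" & df$structure %in% c("air", "bone"), ]
    sub$volume_cc <- ifelse(sub$structure == "air", sub$v_air_cc, sub$v_bone_cc)
    utils::write.csv(sub[, c("case_id", "structure", "volume_cc", "value")],
                     file.path(out_dir, sprintf("scatter_%s.csv", gsub("[^A-Za-z0-9]+", "_", al))),
                     row.names = FALSE)
  }
  fits_out <- lapply(summary$fits, function(f) {
    lapply(f, function(x) if (is.null(x)) NULL else unclass(x))
  })
  jsonlite::write_json(list(fits = fits_out, thresholds = summary$thresholds,
                            gamma_star = summary$gamma_star),
                       file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_lines <- c(sprintf("doseQA %s", as.character(utils::packageVersion("doseQA"))),
                 sprintf("criteria: %g%%/%g mm, suppression %g%%, cap %g mm",
                         config$criteria$dose_diff_pct, config$criteria$dta_mm,
                         config$criteria$suppression_pct, config$criteria$search_cap_mm),
                 sprintf("cases analyzed: %d", summary$n_cases),
                 if (length(skipped)) sprintf("cases skipped: %s", paste(skipped, collapse = ", "))
                 else "cases skipped: none")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}

#' Evaluate a synthetic cohort in memory
#'
#' Composes [sample_cohort_plan()], [build_phantom()], [make_dose_pair()]
#' and [run_case()] case by case without persisting dose grids, which is
#' how the package's own cohort-scale experiments are run. Results are
#' identical to generating the cohort on disk and calling [run_cohort()]
#' on its manifest.
#'
#' @param config a [cohort_config()].
#' @param spec_template a [phantom_spec()].
#' @param models named list of [perturbation_model()] objects.
#' @param run_cfg a [run_config()].
#' @param progress print one line per case.
#' @return List with `records` (list of [case_record()]), `summary`
#'   (a `cohort_summary`) and the sampled `plan`.
#' @export
evaluate_synthetic_cohort <- function(config, spec_template = phantom_spec(),
                                      models = list("AAA-like" = aaa_model(),
                                                    "AXB-like" = axb_model()),
                                      run_cfg = run_config(), progress = FALSE) {
  plan <- sample_cohort_plan(config)
  records <- list()
  for (i in seq_len(nrow(plan))) {
    spec <- spec_template
    spec$v_air_cc <- plan$v_air_cc[i]
    spec$v_bone_cc <- plan$v_bone_cc[i]
    ph <- build_phantom(spec, plan$seed[i])
    masks <- list(target = ph$target, air = ph$air, bone = ph$bone)
    for (lab in names(models)) {
      pair <- make_dose_pair(ph, models[[lab]], spec$rx_gy, plan$seed[i],
                             spec$falloff_sigma_mm)
      records[[length(records) + 1L]] <-
        run_case(pair$reference, pair$evaluated, masks, run_cfg,
                 case_id = plan$case_id[i], algorithm = lab)
    }
    if (progress)
      message(sprintf("%s done (v_air %.1f cc, v_bone %.1f cc)",
                      plan$case_id[i], plan$v_air_cc[i], plan$v_bone_cc[i]))
  }
  list(records = records,
       summary = summarize_cohort(records, gamma_star = run_cfg$gamma_star),
       plan = plan)
}
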