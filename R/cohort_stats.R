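#' Fit a log-linear volume / passing-rate relation
#'
#' Ordinary least squares of `gamma = a + b * ln(V)` on (volume, passing
#' rate) pairs, the relation observed between structure volume and the
#' gamma passing rate of heterogeneity-affected structures. Unweighted,
#' natural logarithm. `R^2 = 1 - SS_res / SS_tot`; when every response is
#' identical (`SS_tot = 0`) the fit is a flat line and `R^2` is reported
#' as 0 (no variance to explain).
#'
#' @param volume_cc structure volumes in cc (> 0), length >= 3.
#' @param gamma_pct gamma passing rates (%), same length.
#' @return An object of class `log_linear_fit`: `intercept` (%), `slope`
#'   (% per ln cc), `r_squared`, `n`.
#' @examples
#' fit_log_linear(exp(1:3), c(92, 94, 96))  # a = 90, b = 2, R^2 = 1
#' @export
fit_log_linear <- function(volume_cc, gamma_pct) {
  if (length(volume_cc) != length(gamma_pct))
    stop("`volume_cc` and `gamma_pct` must have equal length", call. = FALSE)
  if (length(volume_cc) < 3L)
    stop("sample-size error: need at least 3 (volume, rate) pairs", call. = FALSE)
  if (any(!is.finite(volume_cc)) || any(volume_cc <= 0))
    stop("domain error: volumes must be finite and > 0", call. = FALSE)
  x <- log(volume_cc)
  if (max(x) - min(x) < 1e-12)
    stop("degenerate-design error: zero variance in ln(volume)", call. = FALSE)
  fit <- stats::lm(gamma_pct ~ x)
  ss_tot <- sum((gamma_pct - mean(gamma_pct))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n = length(x)),
            class = "log_linear_fit")
}

#' @export
print.log_linear_fit <- function(x, ...) {
  cat(sprintf("<log_linear_fit> gamma = %.3f %+.3f ln(V), R^2 = %.3f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Volume at which a fitted relation crosses a passing-rate level
#'
#' Inverts `gamma = a + b ln(V)` at `gamma_star` (default the 95% action
#' level): `V* = exp((gamma_star - a) / b)`. The caller interprets the side:
#' with a positive slope (air-cavity-like), rates fall below `gamma_star`
#' for volumes below `V*`; with a negative slope (bone-like), for volumes
#' above `V*`.
#'
#' @param fit a [fit_log_linear()] result.
#' @param gamma_star passing-rate level in % (default 95).
#' @return Crossing volume in cc.
#' @examples
#' threshold_volume(fit_log_linear(exp(1:3), c(92, 94, 96)))  # exp(2.5)
#' @export
threshold_volume <- function(fit, gamma_star = 95) {
  stopifnot(inherits(fit, "log_linear_fit"))
  if (abs(fit$slope) < 1e-12)
    stop("no-crossing error: fitted slope is zero", call. = FALSE)
  exp((gamma_star - fit$intercept) / fit$slope)
}

#' Paired two-sided t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`
#' (sample SD, n - 1 divisor), with a two-sided p-value from the Student t
#' distribution with n - 1 degrees of freedom. Zero-variance differences
#' are handled explicitly: all-zero differences give `t = 0, p = 1`;
#' identical nonzero differences give an infinite t (reported as
#' `infinite = TRUE`) with `p = 0`.
#'
#' @param x,y paired numeric samples of equal length n >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`, `infinite`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 6))  # t = -3.4641, p = 0.0742
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L)
    stop("sample-size error: paired t-test needs n >= 2", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  m <- mean(d)
  if (sd_d == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, infinite = FALSE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, mean_diff = m, infinite = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = m, infinite = FALSE)
}

#' Build a case record
#'
#' One analyzed case (patient or phantom) under one dose-calculation
#' algorithm label: per-structure gamma passing rates, per-structure
#' relative mean-dose differences, and the voxelized air-cavity and bone
#' volumes inside the target.
#'
#' @param case_id case identifier.
#' @param algorithm algorithm label (e.g. `"AAA-like"`).
#' @param gamma_pct named numeric vector of gamma passing rates (%), one
#'   entry per scored structure (use `"entire_plan"` for the whole-grid
#'   rate); all in `[0, 100]`.
#' @param diff_pct named numeric vector of relative Dmean differences (%).
#' @param v_air_cc,v_bone_cc voxelized volumes in cc (> 0).
#' @param cohort optional cohort label (e.g. `"NPC-like"`).
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, algorithm, gamma_pct, diff_pct,
                        v_air_cc, v_bone_cc, cohort = NA_character_) {
  if (is.null(names(gamma_pct)) || is.null(names(diff_pct)))
    stop("`gamma_pct` and `diff_pct` must be named vectors", call. = FALSE)
  if (any(gamma_pct < 0 | gamma_pct > 100))
    stop("gamma passing rates must lie in [0, 100]", call. = FALSE)
  if (v_air_cc <= 0 || v_bone_cc <= 0)
    stop("analyzed structure volumes must be > 0", call. = FALSE)
  structure(list(case_id = as.character(case_id), algorithm = algorithm,
                 cohort = cohort, gamma_pct = gamma_pct, diff_pct = diff_pct,
                 v_air_cc = v_air_cc, v_bone_cc = v_bone_cc),
            class = "case_record")
}

records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(case_id = r$case_id, algorithm = r$algorithm, cohort = r$cohort,
               structure = c(names(r$gamma_pct), names(r$diff_pct)),
               metric = c(rep("gamma_pct", length(r$gamma_pct)),
                          rep("diff_pct", length(r$diff_pct))),
               value = c(unname(r$gamma_pct), unname(r$diff_pct)),
               v_air_cc = r$v_air_cc, v_bone_cc = r$v_bone_cc)
  }))
}

#' Summarize a cohort of case records
#'
#' Aggregates per-structure statistics (mean, sample SD with n - 1 divisor,
#' n) per algorithm label, runs paired t-tests between the two algorithm
#' labels (pairing on case id), and fits the two log-linear volume
#' relations per algorithm: air-cavity passing rate vs ln(V_air) and bone
#' passing rate vs ln(V_bone). Aggregation is order-independent: records
#' are sorted by case id internally.
#'
#' @param records list of [case_record()] objects; every case id must be
#'   present under both algorithm labels when two labels are given.
#' @param air_structure,bone_structure names of the gamma entries to use for
#'   the volume regressions.
#' @param gamma_star passing-rate level for threshold volumes (default 95).
#' @return An object of class `cohort_summary`: `table` (data.frame of
#'   structure x algorithm x metric with mean/sd/n and paired p), `fits`
#'   (per algorithm: `air`, `bone` [fit_log_linear()] objects),
#'   `thresholds` (per algorithm: crossing volumes in cc or NA when the
#'   fit has no usable crossing), `n_cases`.
#' @export
summarize_cohort <- function(records, air_structure = "air", bone_structure = "bone",
                             gamma_star = 95) {
  if (length(records) < 2L)
    stop("sample-size error: need at least 2 case records", call. = FALSE)
  df <- records_to_df(records)
  algos <- sort(unique(df$algorithm))
  if (length(algos) == 2) {
    ids <- split(df$case_id, df$algorithm)
    missing_a <- setdiff(unique(ids[[2]]), unique(ids[[1]]))
    missing_b <- setdiff(unique(ids[[1]]), unique(ids[[2]]))
    offenders <- union(missing_a, missing_b)
    if (length(offenders))
      stop(sprintf("pairing error: case(s) %s present under only one algorithm label",
                   paste(offenders, collapse = ", ")), call. = FALSE)
  }

  key <- interaction(df$structure, df$metric, df$algorithm, drop = TRUE)
  parts <- split(df, key)
  tab <- do.call(rbind, lapply(parts, function(p) {
    data.frame(structure = p$structure[1], metric = p$metric[1],
               algorithm = p$algorithm[1], mean = mean(p$value),
               sd = stats::sd(p$value), n = nrow(p))
  }))
  rownames(tab) <- NULL

  # paired p-values between the two algorithm labels, per structure x metric
  tab$p_paired <- NA_real_
  if (length(algos) == 2) {
    for (i in seq_len(nrow(tab))) {
      sel <- df$structure == tab$structure[i] & df$metric == tab$metric[i]
      a <- df[sel & df$algorithm == algos[1], ]
      b <- df[sel & df$algorithm == algos[2], ]
      if (nrow(a) >= 2 && nrow(a) == nrow(b)) {
        a <- a[order(a$case_id), ]; b <- b[order(b$case_id), ]
        tab$p_paired[i] <- paired_t_test(a$value, b$value)$p
      }
    }
    tab$significant <- !is.na(tab$p_paired) & tab$p_paired < 0.05
  }

  fits <- list(); thresholds <- list()
  for (al in algos) {
    sub <- df[df$algorithm == al & df$metric == "gamma_pct", ]
    air <- sub[sub$structure == air_structure, ]
    bone <- sub[sub$structure == bone_structure, ]
    f <- list(air = NULL, bone = NULL)
    th <- list(air = NA_real_, bone = NA_real_)
    if (nrow(air) >= 3) {
      f$air <- fit_log_linear(air$v_air_cc, air$value)
      th$air <- tryCatch(threshold_volume(f$air, gamma_star), error = function(e) NA_real_)
    }
    if (nrow(bone) >= 3) {
      f$bone <- fit_log_linear(bone$v_bone_cc, bone$value)
      th$bone <- tryCatch(threshold_volume(f$bone, gamma_star), error = function(e) NA_real_)
    }
    fits[[al]] <- f
    thresholds[[al]] <- th
  }

  structure(list(table = tab, fits = fits, thresholds = thresholds,
                 n_cases = length(unique(df$case_id)), gamma_star = gamma_star),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d case(s)\n", x$n_cases))
  print(x$table, digits = 4)
  for (al in names(x$fits)) {
    f <- x$fits[[al]]
    if (!is.null(f$air))
      cat(sprintf("%s air:  gamma = %.2f %+.2f ln(V), R^2 = %.3f, %g%% crossing %.1f cc\n",
                  al, f$air$intercept, f$air$slope, f$air$r_squared,
                  x$gamma_star, x$thresholds[[al]]$air))
    if (!is.null(f$bone))
      cat(sprintf("%s bone: gamma = %.2f %+.2f ln(V), R^2 = %.3f, %g%% crossing %.1f cc\n",
                  al, f$bone$intercept, f$bone$slope, f$bone$r_squared,
                  x$gamma_star, x$thresholds[[al]]$bone))
  }
  invisible(x)
}
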