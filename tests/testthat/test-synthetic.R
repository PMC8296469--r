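# smaller phantom grid keeps these structural tests fast; the full-size
# study conditions are exercised in the acceptance suite
small_spec <- function(v_air = 8, v_bone = 10) {
  phantom_spec(dims = c(40, 40, 40), target_semiaxes_mm = c(34, 30, 27),
               v_air_cc = v_air, v_bone_cc = v_bone)
}

test_that("phantoms realize the requested volumes and keep air and bone disjoint", {
  spec <- phantom_spec(v_air_cc = 30, v_bone_cc = 41.2)
  ph <- build_phantom(spec, 42)
  expect_gte(volume_cc(ph$air), 28.5)
  expect_lte(volume_cc(ph$air), 31.5)
  expect_equal(sum(ph$air$flags & ph$bone$flags), 0)
  expect_true(all(ph$target$flags[ph$air$flags]))
  expect_true(all(ph$target$flags[ph$bone$flags]))

  ph2 <- build_phantom(spec, 42)
  expect_identical(ph2$air$flags, ph$air$flags)   # determinism
  expect_identical(ph2$bone$flags, ph$bone$flags)

  ph3 <- build_phantom(spec, 43)
  expect_false(identical(ph3$air$flags, ph$air$flags))
})

test_that("infeasible volume requests are geometry errors", {
  expect_error(phantom_spec(v_air_cc = 300, v_bone_cc = 300), "fit inside")
  expect_error(phantom_spec(v_air_cc = 0.5), "at least 1 cc")
})

test_that("the null perturbation model reproduces the true dose exactly", {
  null_model <- perturbation_model(shell_deficit_frac = 0, bone_surplus_base = 0,
                                   background_amp = 0, mc_noise_frac = 0)
  ph <- build_phantom(small_spec(), 7)
  pair <- make_dose_pair(ph, null_model, 70.4, 7)
  expect_identical(pair$reference$values, pair$true$values)
  expect_identical(pair$evaluated$values, pair$true$values)
  g <- compute_gamma(pair$reference, pair$evaluated)
  expect_equal(g$passing_rate_pct, 100)
})

test_that("dose pairs are reproducible and share the reference across models", {
  ph <- build_phantom(small_spec(), 11)
  p1 <- make_dose_pair(ph, aaa_model(), 70.4, 11)
  p2 <- make_dose_pair(ph, aaa_model(), 70.4, 11)
  expect_identical(p1$reference$values, p2$reference$values)
  expect_identical(p1$evaluated$values, p2$evaluated$values)
  p3 <- make_dose_pair(ph, axb_model(), 70.4, 11)
  expect_identical(p1$reference$values, p3$reference$values)
  expect_false(identical(p1$evaluated$values, p3$evaluated$values))
})

test_that("AXB-like errors stay inside the tight bands and pass gamma", {
  spec <- phantom_spec(v_air_cc = 36.7, v_bone_cc = 41.2)
  ph <- build_phantom(spec, 5)
  pair <- make_dose_pair(ph, axb_model(), spec$rx_gy, 5)
  for (roi in list(ph$air, ph$bone)) {
    d_ref <- dvh_summary(pair$reference, roi)$d_mean
    d_ev <- dvh_summary(pair$evaluated, roi)$d_mean
    expect_lte(abs(relative_dmean_diff(d_ev, d_ref)), 1.5)
    expect_gte(compute_gamma(pair$reference, pair$evaluated, roi = roi)$passing_rate_pct, 95)
  }
})

test_that("AAA-like errors have the documented signs: deficit in air, surplus in bone", {
  spec <- phantom_spec(v_air_cc = 36.7, v_bone_cc = 41.2)
  ph <- build_phantom(spec, 6)
  pair <- make_dose_pair(ph, aaa_model(), spec$rx_gy, 6)
  d_air <- relative_dmean_diff(dvh_summary(pair$evaluated, ph$air)$d_mean,
                               dvh_summary(pair$reference, ph$air)$d_mean)
  d_bone <- relative_dmean_diff(dvh_summary(pair$evaluated, ph$bone)$d_mean,
                                dvh_summary(pair$reference, ph$bone)$d_mean)
  expect_lt(d_air, 0)
  expect_gt(d_bone, 0)
})

test_that("raising the MC statistical uncertainty lowers heterogeneity passing rates", {
  spec <- phantom_spec(v_air_cc = 36.7, v_bone_cc = 41.2)
  ph <- build_phantom(spec, 9)
  p05 <- make_dose_pair(ph, aaa_model(), spec$rx_gy, 9)
  p20 <- make_dose_pair(ph, aaa_model(mc_noise_frac = 0.02), spec$rx_gy, 9)
  for (roi in list(ph$air, ph$bone)) {
    r05 <- compute_gamma(p05$reference, p05$evaluated, roi = roi)$passing_rate_pct
    r20 <- compute_gamma(p20$reference, p20$evaluated, roi = roi)$passing_rate_pct
    expect_lt(r20, r05)
  }
})

test_that("cohort plans match the configured lognormal moments", {
  cfg <- cohort_config(n = 40, master_seed = 314)
  plan <- sample_cohort_plan(cfg)
  expect_equal(nrow(plan), 40)
  # sample mean within 3 standard errors of the configured mean
  expect_lt(abs(mean(plan$v_air_cc) - cfg$air_mean_cc), 3 * cfg$air_sd_cc / sqrt(40))
  expect_lt(abs(mean(plan$v_bone_cc) - cfg$bone_mean_cc), 3 * cfg$bone_sd_cc / sqrt(40))
  expect_true(all(plan$v_air_cc >= cfg$min_cc & plan$v_air_cc <= cfg$max_cc))
  expect_identical(plan, sample_cohort_plan(cfg))  # reproducible
  expect_error(cohort_config(n = 2), "sample-size")
})

test_that("generate_cohort writes a reproducible DGRID bundle with a manifest", {
  cfg <- cohort_config(n = 3, air_mean_cc = 8, air_sd_cc = 3,
                       bone_mean_cc = 10, bone_sd_cc = 3, master_seed = 99)
  models <- list("AAA-like" = aaa_model(), "AXB-like" = axb_model())
  out1 <- file.path(withr::local_tempdir(), "cohort1")
  out2 <- file.path(withr::local_tempdir(), "cohort2")
  man1 <- generate_cohort(cfg, small_spec(), models, out1)
  man2 <- generate_cohort(cfg, small_spec(), models, out2)
  expect_equal(nrow(man1), 3)
  expect_true(all(file.exists(man1$reference)))
  expect_true(all(file.exists(man1[["evaluated_AAA_like"]])))
  expect_true(file.exists(file.path(out1, "manifest.csv")))
  expect_true(file.exists(file.path(out1, "config.ini")))
  # byte-identical regeneration (paths aside)
  r1 <- read_dgrid(man1$reference[2]); r2 <- read_dgrid(man2$reference[2])
  expect_identical(r1$values, r2$values)
  expect_identical(readLines(man1[["evaluated_AXB_like"]][1]),
                   readLines(man2[["evaluated_AXB_like"]][1]))
  m1 <- utils::read.csv(file.path(out1, "manifest.csv"))
  m2 <- utils::read.csv(file.path(out2, "manifest.csv"))
  expect_identical(m1$v_air_cc, m2$v_air_cc)
  expect_identical(m1$seed, m2$seed)
})
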