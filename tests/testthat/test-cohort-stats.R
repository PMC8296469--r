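test_that("log-linear fits recover exact lines and match the normal equations", {
  f <- fit_log_linear(exp(1:3), c(92, 94, 96))
  expect_equal(f$intercept, 90)
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)

  f2 <- fit_log_linear(exp(1:3), c(98, 96, 94))
  expect_equal(f2$slope, -2)

  set.seed(21)
  v <- rlnorm(40, 3, 0.8)
  y <- 88 + 3.5 * log(v) + rnorm(40, 0, 2)
  f3 <- fit_log_linear(v, y)
  # closed-form least squares oracle
  x <- log(v)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(f3$slope, b, tolerance = 1e-9)
  expect_equal(f3$intercept, a, tolerance = 1e-9)
  expect_equal(f3$r_squared, r2, tolerance = 1e-9)
})

test_that("log-linear fits are invariant to ordering and duplication", {
  set.seed(31)
  v <- rlnorm(15, 3, 0.6)
  y <- 90 + 2 * log(v) + rnorm(15)
  f <- fit_log_linear(v, y)
  perm <- sample(15)
  f_perm <- fit_log_linear(v[perm], y[perm])
  f_dup <- fit_log_linear(c(v, v), c(y, y))
  expect_equal(f_perm[c("intercept", "slope", "r_squared")],
               f[c("intercept", "slope", "r_squared")])
  expect_equal(f_dup$slope, f$slope)
  expect_equal(f_dup$r_squared, f$r_squared, tolerance = 1e-12)
})

test_that("degenerate regression designs are rejected", {
  expect_error(fit_log_linear(c(1, 2), c(1, 2)), "sample-size")
  expect_error(fit_log_linear(c(1, -2, 3), c(1, 2, 3)), "domain error")
  expect_error(fit_log_linear(c(5, 5, 5), c(1, 2, 3)), "degenerate-design")
})

test_that("threshold volumes invert the fitted relation at the action level", {
  f <- fit_log_linear(exp(1:3), c(92, 94, 96))       # a = 90, b = 2
  expect_equal(threshold_volume(f, 95), exp(2.5))
  f2 <- fit_log_linear(exp(1:3), c(98, 96, 94))      # a = 100, b = -2
  expect_equal(threshold_volume(f2, 95), exp(2.5))
  f3 <- f; f3$slope <- 0
  expect_error(threshold_volume(f3), "no-crossing")
  # on exact-line data the fitted crossing is the analytic crossing
  a <- 80; b <- 6
  v <- exp(seq(1, 4, length.out = 7))
  ff <- fit_log_linear(v, a + b * log(v))
  expect_equal(threshold_volume(ff, 95), exp((95 - a) / b), tolerance = 1e-9)
})

test_that("the paired t-test matches the df=2 closed form and is antisymmetric", {
  r <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$t, -3.4641, tolerance = 1e-4)
  # two-sided p for df = 2: 1 - |t| / sqrt(t^2 + 2)
  expect_equal(r$p, 1 - abs(r$t) / sqrt(r$t^2 + 2), tolerance = 1e-9)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  fwd <- paired_t_test(c(5, 7, 9, 4), c(6, 6, 7, 7))
  rev <- paired_t_test(c(6, 6, 7, 7), c(5, 7, 9, 4))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  const <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(const$infinite); expect_equal(const$p, 0)

  expect_error(paired_t_test(1, 2), "sample-size")
  expect_error(paired_t_test(1:3, 1:2), "equal length")
})

make_rec <- function(id, algo, g_air, g_bone, d_air, d_bone, va = 30, vb = 40) {
  case_record(id, algo,
              gamma_pct = c(entire_plan = 99, air = g_air, bone = g_bone),
              diff_pct = c(air = d_air, bone = d_bone),
              v_air_cc = va, v_bone_cc = vb)
}

test_that("cohort summaries aggregate to spreadsheet arithmetic with paired p-values", {
  recs <- list(
    make_rec("c1", "A", 90, 80, -1, 2, va = 10, vb = 20),
    make_rec("c2", "A", 94, 76, -2, 3, va = 30, vb = 50),
    make_rec("c3", "A", 98, 70, -1.5, 2.5, va = 90, vb = 80),
    make_rec("c1", "B", 99, 99, -0.1, 0.2, va = 10, vb = 20),
    make_rec("c2", "B", 98, 99, -0.2, 0.3, va = 30, vb = 50),
    make_rec("c3", "B", 99, 98, -0.1, 0.4, va = 90, vb = 80))
  s <- summarize_cohort(recs)
  row <- s$table[s$table$structure == "air" & s$table$metric == "gamma_pct" &
                   s$table$algorithm == "A", ]
  expect_equal(row$mean, mean(c(90, 94, 98)))
  expect_equal(row$sd, sd(c(90, 94, 98)))
  expect_equal(row$n, 3)
  expect_equal(row$p_paired, paired_t_test(c(90, 94, 98), c(99, 98, 99))$p)
  fa <- s$fits[["A"]]$air
  expect_equal(fa$slope, fit_log_linear(c(10, 30, 90), c(90, 94, 98))$slope)

  # identical records under both labels: p = 1, sd = 0
  recs2 <- list(make_rec("c1", "A", 90, 80, -1, 2), make_rec("c2", "A", 90, 80, -1, 2),
                make_rec("c1", "B", 90, 80, -1, 2), make_rec("c2", "B", 90, 80, -1, 2))
  s2 <- summarize_cohort(recs2)
  expect_true(all(s2$table$sd == 0))
  expect_true(all(s2$table$p_paired == 1, na.rm = TRUE))
})

test_that("unpaired case ids across algorithm labels are an error naming offenders", {
  recs <- list(make_rec("c1", "A", 90, 80, -1, 2),
               make_rec("c2", "A", 92, 82, -1, 2),
               make_rec("c1", "B", 99, 99, 0, 0),
               make_rec("c9", "B", 98, 98, 0, 0))
  expect_error(summarize_cohort(recs), "pairing error.*c9|c9.*pairing error")
})

test_that("case records validate their fields", {
  expect_error(case_record("c", "A", c(air = 101), c(air = 0), 1, 1), "\\[0, 100\\]")
  expect_error(case_record("c", "A", c(air = 90), c(air = 0), 0, 1), "> 0")
  expect_error(case_record("c", "A", 90, c(air = 0), 1, 1), "named")
})
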