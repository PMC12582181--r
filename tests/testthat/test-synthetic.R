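cfg <- generator_config()

test_that("generated curves hit the 24-h anchors and are deterministic", {
  cv <- gen_time_activity(cfg, "tumor", "low")
  expect_equal(cv$activity[cv$time_h == 24], 10.48, tolerance = 1e-6)
  cv_high <- gen_time_activity(cfg, "tumor", "high")
  expect_equal(cv_high$activity[cv_high$time_h == 24], 0.38,
               tolerance = 1e-6)
  expect_equal(gen_time_activity(cfg, "blood", "low")$activity[2], 0.68,
               tolerance = 1e-6)
  expect_equal(gen_time_activity(cfg, "kidney", "high")$activity[2], 0.47,
               tolerance = 1e-6)
  # same config -> identical curves
  expect_identical(gen_time_activity(cfg, "tumor", "low"),
                   gen_time_activity(cfg, "tumor", "low"))
  bad <- cfg; bad$tissues$tumor$uptake_rate <- 0.001
  expect_error(gen_time_activity(bad, "tumor", "low"), "exceed")
})

test_that("slow-clearance limit approaches uptake-then-physical-decay", {
  slow <- cfg
  slow$tissues$tumor$clearance_rate <- 1e-8
  ch <- ac225_chain()
  lam <- ch$parent$decay_constant
  got <- config_implied_coefficient(slow, "tumor", "low", ch, rbe = 5)
  # closed form for k_c -> 0: TIA -> S (1/lambda - 1/(k_u + lambda))
  p <- slow$tissues$tumor
  s24 <- (exp(-1e-8 * 24) - exp(-p$uptake_rate * 24)) * exp(-lam * 24)
  S <- 10.48 / s24
  tia <- S * (1 / lam - 1 / (p$uptake_rate + lam))
  expect_equal(got, coeff_oracle(tia, alpha_energy_per_decay(ch), 5),
               tolerance = 1e-4)
})

test_that("generated biodistribution obeys the saturation ordering", {
  bd_low <- gen_biodist_study(cfg, "low", cv = 0, n = 1)
  bd_high <- gen_biodist_study(cfg, "high", cv = 0, n = 1)
  for (tt in c(2, 24, 72)) {
    expect_gt(bd_low$pia_g_mean[bd_low$tissue == "tumor" &
                                  bd_low$time_h == tt],
              bd_high$pia_g_mean[bd_high$tissue == "tumor" &
                                   bd_high$time_h == tt])
  }
})

test_that("noise-free tables equal the generating curve; noisy ones match the CV", {
  bd0 <- gen_biodist_study(cfg, "low", cv = 0, n = 3)
  cv_t <- gen_time_activity(cfg, "tumor", "low")
  expect_equal(bd0$pia_g_mean[bd0$tissue == "tumor"], cv_t$activity)
  expect_true(all(bd0$pia_g_sd == 0))
  # empirical CV of single draws across replicate configs ~ 0.30
  set.seed(99)
  draws <- sapply(1:400, function(i) {
    c2 <- generator_config(seed = i)
    bd <- gen_biodist_study(c2, "low", cv = 0.30, n = 1)
    bd$pia_g_mean[bd$tissue == "tumor" & bd$time_h == 24]
  })
  expect_equal(sd(draws) / mean(draws), 0.30, tolerance = 0.10)
  # round trip through the CSV reader
  path <- withr::local_tempfile(fileext = ".csv")
  bd <- gen_biodist_study(cfg, "low")
  write_biodist(bd, path)
  expect_equal(as.data.frame(read_biodist(path)), as.data.frame(bd),
               tolerance = 1e-12)
  # determinism
  expect_identical(gen_biodist_study(cfg, "low"),
                   gen_biodist_study(cfg, "low"))
})

test_that("noise-free generation -> integration -> dose recovers the implied coefficient", {
  bd0 <- gen_biodist_study(cfg, "low", cv = 0, n = 1)
  fit <- dosimetry(bd0[bd0$tissue == "tumor", ],
                   tail_model = "fitted-monoexponential")
  truth <- config_implied_coefficient(cfg, "tumor", "low")
  expect_equal(coef(fit)[["tumor"]], truth, tolerance = 0.02)
})

test_that("internalization defaults match the configured kinetics", {
  s <- gen_internalization(cfg)
  f <- internalized_fraction(s)
  expect_equal(f[s$time_h == 1], 0.09, tolerance = 1e-6,
               ignore_attr = TRUE)
  f24 <- f[s$time_h == 24]
  expect_gt(f24, 0.26); expect_lt(f24, 0.30)
  auc <- auc_internalized_percent(s)
  expect_gt(auc, 15); expect_lt(auc, 25)
  # zero transfer rate -> nothing internalized
  c0 <- cfg
  c0$internalization$frac_1h <- 1e-9
  c0$internalization$frac_24h <- 2e-8
  s0 <- gen_internalization(c0)
  expect_lt(max(internalized_fraction(s0), na.rm = TRUE), 1e-6)
})

test_that("therapy cohorts are deterministic and dose-responsive", {
  ctrl <- gen_therapy_cohort(cfg, 0, n = 10, group = "control")
  expect_identical(ctrl$tumor,
                   gen_therapy_cohort(cfg, 0, n = 10, group = "control")$tumor)
  med <- median_survival(km_fit(ctrl$survival$time_d, ctrl$survival$event))
  expect_gt(med, 20); expect_lt(med, 30)
  treated <- gen_therapy_cohort(cfg, 210, n = 10, group = "treated",
                                seed = cfg$seed + 1)
  cr <- vapply(treated$series,
               function(s) classify_response(s) == "complete_response",
               logical(1))
  expect_gte(mean(cr), 0.9)
  # treated animals never double within the horizon
  expect_true(all(!treated$survival$event))
})
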