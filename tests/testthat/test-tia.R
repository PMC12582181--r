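ac <- nuclide("Ac-225", 9.92, "d")

test_that("undecay_correct applies the physical decay factor pointwise", {
  t <- c(2, 24, 72, 192, 240)
  cv <- time_activity_curve("tumor", t, rep(10, 5), decay_corrected = TRUE)
  phys <- undecay_correct(cv, ac)
  expect_false(phys$decay_corrected)
  expect_equal(phys$activity, 10 * exp(-ac$decay_constant * t))
  # t = 0 unchanged; t = T1/2 halved
  cv0 <- time_activity_curve("x", c(0, ac$half_life_h), c(4, 4),
                             decay_corrected = TRUE)
  expect_equal(undecay_correct(cv0, ac)$activity, c(4, 2))
  expect_error(undecay_correct(phys, ac), "already physical")
})

test_that("single-point curve with physical tail gives A0/lambda", {
  cv <- time_activity_curve("blood", 0, 7)
  r <- integrate_tac(cv, ac, "physical-decay")
  expect_equal(r$tia, 7 / ac$decay_constant)
  expect_equal(r$tail_fraction, 1.0)
})

test_that("densely sampled pure decay integrates to A0/lambda within 1%", {
  a0 <- 12
  t <- seq(0, 10 * ac$half_life_h, length.out = 50)
  cv <- time_activity_curve("tumor", t, a0 * exp(-ac$decay_constant * t))
  for (tm in c("physical-decay", "fitted-monoexponential", "none")) {
    r <- integrate_tac(cv, ac, tm)
    expect_equal(r$tia, a0 / ac$decay_constant, tolerance = 0.01)
  }
})

test_that("uptake-and-clearance curve matches the fine-grid quadrature oracle", {
  t <- c(2, 24, 72, 192, 240)
  a <- 12 * (exp(-0.003 * t) - exp(-0.25 * t)) * exp(-ac$decay_constant * t)
  cv <- time_activity_curve("tumor", t, a)
  r <- integrate_tac(cv, ac, "physical-decay")
  expect_equal(r$tia, tia_oracle(t, a, ac$decay_constant, "physical"),
               tolerance = 0.005)
  r0 <- integrate_tac(cv, ac, "none")
  expect_equal(r0$tia, tia_oracle(t, a, ac$decay_constant, "none"),
               tolerance = 0.005)
})

test_that("TIA is homogeneous and trapezoid-consistent", {
  t <- c(2, 24, 72, 192, 240)
  a <- c(3, 9, 7, 4, 2.5)
  cv <- time_activity_curve("tumor", t, a)
  base <- integrate_tac(cv, ac)$tia
  # degree-1 homogeneity
  expect_equal(integrate_tac(time_activity_curve("tumor", t, 3 * a), ac)$tia,
               3 * base, tolerance = 1e-12)
  # chord point insertion leaves the integral unchanged
  tmid <- 48
  amid <- approx(t, a, xout = tmid)$y
  cv2 <- time_activity_curve("tumor", sort(c(t, tmid)),
                             append(a, amid, after = 2))
  expect_equal(integrate_tac(cv2, ac)$tia, base, tolerance = 1e-12)
})

test_that("tail models are ordered physical >= fitted >= none", {
  t <- c(2, 24, 72, 192, 240)
  a <- 10 * (exp(-0.004 * t) - exp(-0.3 * t)) * exp(-ac$decay_constant * t)
  cv <- time_activity_curve("tumor", t, a)
  tp <- integrate_tac(cv, ac, "physical-decay")$tia
  tf <- integrate_tac(cv, ac, "fitted-monoexponential")$tia
  tn <- integrate_tac(cv, ac, "none")$tia
  expect_true(tp >= tf)
  expect_true(tf >= tn)
})

test_that("fitted tail guards degenerate input and rising tails", {
  one <- time_activity_curve("x", 5, 3)
  expect_error(integrate_tac(one, ac, "fitted-monoexponential"),
               "at least 2 points")
  rising <- time_activity_curve("x", c(2, 24, 72), c(1, 2, 4))
  expect_warning(r <- integrate_tac(rising, ac, "fitted-monoexponential"),
                 "physical-decay")
  expect_equal(r$tail_model, "physical-decay")
  # decay-corrected input must be rejected
  dc <- time_activity_curve("x", c(2, 24), c(1, 1), decay_corrected = TRUE)
  expect_error(integrate_tac(dc, ac), "undecay_correct")
})

test_that("on a pure-decay curve the two tail models agree within 1%", {
  # for a genuinely monoexponential tail, the fitted rate equals the
  # physical one, so the two extrapolating tail models coincide; "none"
  # truncates by exactly the activity remaining past the last sample
  t <- seq(0, 3 * ac$half_life_h, length.out = 20)
  cv <- time_activity_curve("x", t, 5 * exp(-ac$decay_constant * t))
  tp <- integrate_tac(cv, ac, "physical-decay")$tia
  tf <- integrate_tac(cv, ac, "fitted-monoexponential")$tia
  tn <- integrate_tac(cv, ac, "none")$tia
  expect_equal(tf, tp, tolerance = 0.01)
  expect_equal(tp, 5 / ac$decay_constant, tolerance = 0.01)
  expect_equal((tp - tn) / tp, 2^-3, tolerance = 0.02)
})

test_that("biodist_to_tac groups tissues and removes decay correction", {
  bd <- biodist_table(rep(c("tumor", "blood"), each = 2),
                      c(2, 24, 2, 24), c(5, 10, 2, 1),
                      decay_corrected = TRUE)
  curves <- biodist_to_tac(bd, ac)
  expect_named(curves, c("blood", "tumor"))
  expect_false(curves$tumor$decay_corrected)
  expect_equal(curves$tumor$activity,
               c(5, 10) * exp(-ac$decay_constant * c(2, 24)))
})
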