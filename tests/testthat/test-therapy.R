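test_that("complete response is judged on the final volume, inclusive", {
  cr <- tumor_series("a", c(0, 30), c(100, 4.2))
  expect_equal(classify_response(cr), "complete_response")
  no <- tumor_series("b", c(0, 30), c(100, 4.3))
  expect_equal(classify_response(no), "no_complete_response")
  dip <- tumor_series("c", c(0, 20, 60), c(100, 2, 100))
  expect_equal(classify_response(dip), "no_complete_response")
  diam <- tumor_series("d", c(0, 30), c(5, 9), type = "diameter")
  expect_error(classify_response(diam), "volumes")
})

test_that("endpoint_time interpolates doubling crossings", {
  s <- tumor_series("a", c(0, 7, 14), c(100, 150, 250))
  ep <- endpoint_time(s, "doubling")
  expect_equal(ep$time, 10.5)   # hand linear interpolation to 200
  expect_true(ep$event)
  # first-past-threshold alternative
  ep2 <- endpoint_time(s, "doubling", interpolate = FALSE)
  expect_equal(ep2$time, 14)
  # never reached -> censored at last observation
  flat <- tumor_series("b", c(0, 70, 140), c(100, 120, 150))
  epc <- endpoint_time(flat, "doubling")
  expect_equal(epc, list(time = 140, event = FALSE))
  # diameter series crossing exactly at a measurement day
  d <- tumor_series("c", c(0, 10, 20), c(4, 10, 12), type = "diameter")
  epd <- endpoint_time(d, "diameter_10mm")
  expect_equal(epd, list(time = 10, event = TRUE))
  expect_error(endpoint_time(d, "doubling"), "volume series")
})

test_that("doubling time is invariant to volume rescaling", {
  set.seed(11)
  for (i in 1:10) {
    v <- cumprod(c(runif(1, 50, 150), exp(runif(5, 0, 0.6))))
    s1 <- tumor_series("a", seq(0, 25, 5), v)
    s2 <- tumor_series("a", seq(0, 25, 5), 13 * v)
    expect_equal(endpoint_time(s1, "doubling"),
                 endpoint_time(s2, "doubling"))
  }
})

test_that("KM estimator reproduces hand product-limit calculations", {
  # all events at t = 5: S drops 1 -> 0
  f <- km_fit(rep(5, 4), rep(TRUE, 4))
  expect_equal(f$table$surv, 0)
  # events at 1 and 2, censor at 1.5: S = 2/3 on [1, 2), 0 at 2
  f2 <- km_fit(c(1, 1.5, 2), c(TRUE, FALSE, TRUE))
  expect_equal(f2$table$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(f2$table$n_risk, c(3, 2, 1))
  expect_equal(predict(f2, c(0.5, 1.2, 3)), c(1, 2 / 3, 0))
  expect_error(km_fit(c(0, 1), c(TRUE, TRUE)), "> 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(12)
  t <- rexp(40, 1 / 20)
  f <- km_fit(t, rep(TRUE, 40))
  ecdf_surv <- 1 - ecdf(t)(f$table$time)
  expect_equal(f$table$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("KM agrees with the survival package and recovers a known median", {
  set.seed(13)
  m <- 20
  t <- rexp(200, log(2) / m)
  ev <- t < 60                        # administrative censoring at 60
  t[!ev] <- 60
  f <- km_fit(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  expect_equal(f$table$surv[f$table$n_event > 0],
               sf$surv[sf$n.event > 0], tolerance = 1e-10)
  expect_equal(median_survival(f), m, tolerance = 0.15)
})

test_that("median survival is undefined when S stays above 0.5", {
  f <- km_fit(c(10, 25, 140, 140, 140), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  med <- median_survival(f)
  expect_true(is.na(med))
  expect_equal(attr(med, "last_followup"), 140)
  f2 <- km_fit(c(25, 25, 25, 30, 30), rep(TRUE, 5))
  expect_equal(median_survival(f2), 25)
})

test_that("log-rank matches the hand observed-minus-expected table", {
  # 6 animals, no censoring: A = {1, 3, 5}, B = {2, 4, 6}
  time <- c(1, 3, 5, 2, 4, 6)
  group <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, rep(TRUE, 6), group)
  # hand calculation: sum(O-E) = 23/30, var = 1.21222..., chisq = 0.48489
  expect_equal(unname(lr$statistic), 0.48489, tolerance = 1e-4)
  expect_equal(lr$p.value, pchisq(0.48489, 1, lower.tail = FALSE),
               tolerance = 1e-4)
  # symmetric under group swap
  lr2 <- logrank_test(time, rep(TRUE, 6), rev(group))
  expect_equal(lr2$statistic, lr$statistic)
  # identical groups -> chisq ~ 0
  lr3 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                      rep(c("A", "B"), 3))
  expect_lt(unname(lr3$statistic), 1e-10)
  expect_equal(lr3$p.value, 1)
})

test_that("log-rank agrees with survival::survdiff on censored data", {
  set.seed(14)
  for (i in 1:5) {
    t <- c(rexp(15, 1 / 20), rexp(15, 1 / 35))
    ev <- runif(30) < 0.8
    g <- rep(c("a", "b"), each = 15)
    lr <- logrank_test(t, ev, g)
    sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
    expect_equal(unname(lr$statistic), sd$chisq, tolerance = 1e-8)
  }
  expect_warning(logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")),
                 "no events")
})

test_that("survival_records derives endpoints and honors deaths", {
  s1 <- tumor_series("a1", c(0, 7, 14), c(100, 150, 250), group = "g")
  s2 <- tumor_series("a2", c(0, 70, 140), c(100, 120, 150), group = "g")
  rec <- survival_records(list(s1, s2))
  expect_equal(rec$time_d, c(10.5, 140))
  expect_equal(rec$event, c(TRUE, FALSE))
  expect_equal(rec$reason, c("doubling", "censored"))
  # a death from another cause before the endpoint is an event
  rec2 <- survival_records(list(s1, s2), deaths = c(a2 = 60))
  expect_equal(rec2$time_d, c(10.5, 60))
  expect_equal(rec2$reason, c("doubling", "death"))
})
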