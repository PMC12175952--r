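# Derived resistances, smoothing, baseline adjustment, cohort curves,
# stability detection, alerts and endpoint statistics.

test_that("derived resistances follow their defining ratios and missing-data contract", {
  expect_equal(compute_tpr(50, 5), 10)
  # cohort-mean arithmetic: ratio of printed means differs from the printed
  # mean of per-patient ratios, which is expected (Jensen-type gap)
  expect_equal(compute_tpr(52.9, 4.88), 10.8402, tolerance = 1e-4)
  expect_true(abs(compute_tpr(52.9, 4.88) - 11.7) > 0.5)
  expect_true(is.na(compute_tpr(NA, 5)) && is.na(compute_tpr(50, NA)))
  expect_error(compute_tpr(50, 0), "positive")

  expect_equal(compute_tsr(120, 60, 5), 16)       # MAP 80 / 5
  expect_equal(compute_tsr(83.6 * 1.5, 83.6 * 0.75, 5.2),
               16.0769, tolerance = 1e-3)          # MAP 83.6 by construction
  expect_equal(compute_tsr(90, 90, 6), 15)         # degenerate pulse pressure
  expect_error(compute_tsr(60, 120, 5), "diastolic")
  # direct MAP column overrides the estimate
  expect_equal(compute_tsr(120, 60, 5, map = 90), 18)

  expect_equal(compute_pvr(50, 10, 5), 8)
  expect_equal(compute_pvr(50, 0, 5), compute_tpr(50, 5))
  expect_equal(compute_pvr(52.9, 10.3, 4.88), 8.7295, tolerance = 1e-4)
  expect_warning(out <- compute_pvr(c(50, 20), c(10, 25), c(5, 5)),
                 "pawp >= mpap")
  expect_true(is.na(out[2]) && out[1] == 8)
  # PVR never exceeds TPR for positive wedge pressure
  set.seed(1)
  mp <- runif(50, 30, 80); co <- runif(50, 3, 7); pw <- runif(50, 1, 20)
  expect_true(all(compute_pvr(mp, pw, co) <= compute_tpr(mp, co)))
})

test_that("trailing 3-day average respects the calendar and the 2-of-3 rule", {
  r <- rolling_3day(0:2, c(10, 11, 12))
  expect_equal(r$value[3], 11)
  expect_true(is.na(r$value[1]))                 # single value in window
  expect_equal(r$value[2], 10.5)                 # two of three present
  const <- rolling_3day(0:9, rep(7, 10))
  expect_true(all(const$value[-1] == 7))         # smoothing fixed point
  gap <- rolling_3day(c(0, 2), c(10, 12))        # day 1 missing entirely
  expect_equal(gap$value[3], 11)
  miss <- rolling_3day(0:2, c(10, NA, 12))
  expect_equal(miss$value[3], 11)
  one <- rolling_3day(c(0, 1, 2, 3), c(10, NA, NA, 12))
  expect_true(is.na(one$value[4]))               # only 1 of 3 present
})

test_that("baseline adjustment centers on the pre-drug window in both modes", {
  p <- make_patient(rep(12, 30), drug_start = 10)
  adj <- baseline_adjust(p, "tpr", "start", "absolute")
  expect_true(all(abs(adj$value[!is.na(adj$value)]) < 1e-12))
  expect_equal(attr(adj, "baseline"), 12 / 5)
  expect_equal(adj$rel_day[1], -10)

  # baseline TPR 12 WU, on-drug 9.6 WU -> -2.4 WU; percent -20%
  p2 <- make_patient(c(rep(60, 10), rep(48, 20)), co = 5, drug_start = 10)
  a2 <- baseline_adjust(p2, "tpr", "start", "absolute")
  expect_equal(a2$value[a2$rel_day == 15], -2.4)
  pc <- baseline_adjust(p2, "tpr", "start", "percent")
  expect_equal(pc$value[pc$rel_day == 15], -20)
  # 12 -> 9.56 corresponds to -20.33%
  p3 <- make_patient(c(rep(60, 10), rep(9.56 * 5, 20)), drug_start = 10)
  p3c <- baseline_adjust(p3, "tpr", "start", "percent")
  expect_equal(p3c$value[p3c$rel_day == 15], 100 * (9.56 / 12 - 1))

  # adding a constant to the whole series leaves the adjusted series as is
  p4 <- make_patient(c(rep(60, 10), rep(48, 20)) + 35, drug_start = 10)
  a4 <- baseline_adjust(p4, "tpr", "start", "absolute")
  expect_equal(a4$value, a2$value)

  expect_error(baseline_adjust(make_patient(c(60, NA, NA, NA, 60, 60, 60),
                                            drug_start = 3), "tpr"),
               "insufficient baseline")
})

test_that("cohort curves aggregate with t-intervals and patient-count rules", {
  p1 <- make_patient(c(rep(10, 10), rep(11, 20)), co = 1, drug_start = 10)
  p2 <- make_patient(c(rep(20, 10), rep(23, 20)), co = 1, drug_start = 10,
                     id = "T2")
  cv <- cohort_curve(list(p1, p2), "tpr", "start", "absolute")
  on_drug <- cv[cv$rel_day >= 3, ]
  expect_true(all(on_drug$mean == 2))             # mean of +1 and +3
  expect_true(all(on_drug$n == 2))
  expect_true(all(on_drug$ci_lo <= on_drug$mean &
                    on_drug$mean <= on_drug$ci_hi))
  # identical patients give a zero-width interval
  cvz <- cohort_curve(list(p1, make_patient(c(rep(10, 10), rep(11, 20)),
                                            co = 1, drug_start = 10,
                                            id = "T3")), "tpr")
  expect_true(all(abs(cvz$ci_hi - cvz$ci_lo) < 1e-12))
  # all-zero adjusted input: mean 0, CI [0,0]
  cz <- cohort_curve(list(make_patient(rep(5, 30), drug_start = 10),
                          make_patient(rep(8, 30), drug_start = 10,
                                       id = "T4")), "tpr")
  expect_true(all(cz$mean == 0 & cz$ci_lo == 0 & cz$ci_hi == 0))
  # a single contributing patient emits nothing
  expect_error(cohort_curve(list(p1), "tpr", min_patients = 2),
               "minimum patient count")
})

test_that("stability detector matches its definition and the brute-force scan", {
  # constant series from day 0: seven zero-changes complete on day 7
  st <- stability_time(0:20, rep(5, 21))
  expect_identical(st, list(time = 7, event = TRUE))
  # all daily changes 0.2: never qualifies
  drift <- cumsum(c(5, rep(0.2, 20)))
  expect_false(stability_time(0:20, drift)$event)
  # mixed changes: first window with >= 6 of 7 below 0.15
  chg <- c(0.3, 0.1, 0.1, 0.05, 0.1, 0.1, 0.2, 0.1)
  v <- cumsum(c(5, chg))
  got <- stability_time(0:8, v)
  orc <- brute_stability(0:8, v)
  expect_identical(got, orc)
  expect_true(got$event)
  # series shorter than w + 1 days is censored at its end
  short <- stability_time(0:5, rep(1, 6))
  expect_false(short$event)
  expect_identical(short$time, 5)
  # randomized equivalence with the exhaustive scan (with missing days)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    day <- sort(sample(0:(n + 10), n))
    val <- cumsum(rnorm(n, 0, 0.2))
    expect_identical(stability_time(day, val), brute_stability(day, val))
  }
})

test_that("Kaplan-Meier medians equal the hand-computed product-limit estimate", {
  all28 <- km_summary(rep(28, 6), rep(1, 6))
  expect_equal(all28$median, 28)
  none <- km_summary(c(10, 20, 30), c(0, 0, 0))
  expect_true(none$all_censored)
  expect_true(is.na(none$median))
  # hand computation: S(1)=4/5, S(2)=3/5, S(4)=3/10 -> median at t=4
  mix <- km_summary(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
  expect_equal(mix$median, 4)
  expect_identical(mix$n_events, 3L)
  expect_error(km_summary(c(0, 1), c(1, 1)), "positive")
})

test_that("withdrawal alert fires at the configured fractional mPAP rise", {
  # baseline mPAP 50; after stop the raw series jumps to 55, so the 3-day
  # average crosses the 10% level (55.0) two days later
  mp <- c(rep(50, 20), rep(55, 10))
  p <- make_patient(mp, drug_start = 10, drug_stop = 19)
  a <- withdrawal_alert(p, 0.10)
  expect_equal(a$baseline, 50)
  expect_equal(a$alert_level, 55)
  expect_equal(a$day, 22)        # first day the smoothed series reaches 55
  # never reaches the level: no alert
  p2 <- make_patient(c(rep(50, 20), rep(53, 10)), drug_start = 10,
                     drug_stop = 19)
  expect_true(is.na(withdrawal_alert(p2, 0.10)$day))
  # degenerate threshold 0: first smoothed day at or above baseline
  a0 <- withdrawal_alert(p2, 0)
  expect_equal(a0$day, 20)
})

test_that("paired endpoint statistics reproduce hand computations", {
  e <- endpoint_change(c(10, 12), c(8, 10), "paired-t")
  expect_equal(e$change, -2)
  expect_true(e$degenerate)                      # zero-variance differences
  expect_true(is.na(e$p_value))
  # textbook three-pair computation, checked to 1e-12:
  # diffs -1,-1,-4: mean -2, sd sqrt(3), t = -2, df 2
  b <- c(10, 12, 14); f <- c(9, 11, 10)
  h <- endpoint_change(b, f, "paired-t")
  expect_equal(h$change, -2, tolerance = 1e-12)
  expect_equal(h$p_value, 2 * pt(-2, 2), tolerance = 1e-12)
  half <- qt(0.975, 2) * sqrt(3) / sqrt(3)
  expect_equal(h$ci_lo, -2 - half, tolerance = 1e-12)
  expect_equal(h$ci_hi, -2 + half, tolerance = 1e-12)
  # geometric mean ratio: both pairs halve -> ratio 0.5 exactly
  g <- endpoint_change(c(100, 400), c(50, 200), "log-paired-t")
  expect_equal(g$change, 0.5)
  expect_true(g$degenerate)
  # identical vectors: change 0 / ratio 1
  i1 <- endpoint_change(c(5, 7, 9), c(5, 7, 9), "paired-t")
  expect_equal(i1$change, 0)
  i2 <- endpoint_change(c(5, 7, 9), c(5, 7, 9), "log-paired-t")
  expect_equal(i2$change, 1)
  # signed-rank route returns a Hodges-Lehmann shift of the right sign
  w <- endpoint_change(c(10, 12, 14, 16), c(8, 11, 12, 13), "wilcoxon")
  expect_lt(w$change, 0)
  expect_error(endpoint_change(1:3, 1:4), "paired")
})

test_that("exposure-response joins patients and recovers monotone rank structure", {
  auc <- c(A = 1000, B = 2000, C = 4000, D = 8000)
  eff <- c(A = -5, B = -10, C = -15, D = -20)   # perfectly monotone
  dose <- c(A = 100, B = 200, C = 300, D = 400)
  er <- exposure_response(dose, auc, eff)
  expect_equal(er$rho, -1)
  expect_identical(er$n, 4L)
  const <- exposure_response(dose, auc, c(A = -5, B = -5, C = -5, D = -5))
  expect_true(is.na(const$rho))
  expect_match(const$note, "constant")
  few <- exposure_response(dose[1:2], auc[1:2], eff[1:2])
  expect_true(is.na(few$rho))
  expect_match(few$note, "fewer than 3")
})
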