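test_that("tricube local-linear smoothing reproduces constants and lines", {
  day <- seq(0, 100, by = 7)
  cst <- smoothCurve(day, rep(4.2, length(day)), span_days = 30)
  expect_true(all(abs(cst$value - 4.2) < 1e-9))
  lin <- smoothCurve(day, 2 * day, span_days = 30)
  expect_true(all(abs(lin$value - 2 * lin$day) < 1e-7))
})

test_that("smoothing is linear in value and translation-equivariant in day", {
  set.seed(21)
  day <- sort(sample(0:120, 18))
  y <- sin(day / 15) + rnorm(18, 0, 0.1)
  s0 <- smoothCurve(day, y, span_days = 40)
  sa <- smoothCurve(day, 3 * y + 2, span_days = 40)
  expect_equal(sa$value, 3 * s0$value + 2, tolerance = 1e-9)
  sh <- smoothCurve(day + 500, y, span_days = 40)
  expect_equal(sh$value, s0$value, tolerance = 1e-9)
  expect_equal(sh$day, s0$day + 500)
  expect_error(smoothCurve(1:2, 1:2), "at least 3")
  expect_error(smoothCurve(day, y, span_days = 40, grid_days = -5),
               "no extrapolation")
})

test_that("span controls the bias-variance tradeoff on fast oscillation", {
  set.seed(22)
  day <- 0:120
  truth <- sin(day / 6)
  y <- truth + rnorm(121, 0, 0.05)
  rmse <- function(span) {
    f <- smoothCurve(day, y, span_days = span)
    sqrt(mean((f$value - truth)^2))
  }
  expect_lt(rmse(8), rmse(60))
})

test_that("rise detection follows the nadir-relative sustained rule", {
  day <- seq(0, 70, by = 7)
  expect_true(is.na(detectRise(day, rep(10, length(day)))))
  # sustained +50% step is detected at the step
  v <- c(rep(10, 5), rep(15, 6))
  det <- detectRise(day, v, interpolate = FALSE)
  expect_equal(det, day[6])
  # unsustained single-draw spike is not detected
  vs <- c(rep(10, 5), 15, rep(10, 5))
  expect_true(is.na(detectRise(day, vs)))
  # monotone in threshold: higher threshold never detects earlier
  set.seed(23)
  for (i in 1:20) {
    vv <- cumsum(c(10, rnorm(10, 0.5, 2)))
    vv <- pmax(vv, 1)
    d1 <- detectRise(day, vv, threshold = 0.2, interpolate = FALSE)
    d2 <- detectRise(day, vv, threshold = 0.5, interpolate = FALSE)
    if (!is.na(d2)) {
      expect_false(is.na(d1))
      expect_lte(d1, d2)
    }
  }
})

test_that("lead time arithmetic and event invariances hold", {
  tr <- simulateTrajectory(trajectorySpec(fc_lead_days = 35, seed = 31))
  lt <- leadTime(tr)
  expect_true(lt$detected)
  expect_equal(lt$lead_days, lt$pd_day - lt$detection_day)
  # adding non-PD events does not change the lead time
  tr2 <- tr
  tr2@events <- rbind(events(tr), data.frame(day = c(3, 50),
                                             type = c("surgery",
                                                      "regimen_change")))
  tr2@events <- tr2@events[order(tr2@events$day), ]
  lt2 <- leadTime(tr2)
  expect_equal(lt2$lead_days, lt$lead_days)
  # no PD event is an error
  tr3 <- tr
  tr3@events <- data.frame(day = 3L, type = "surgery")
  expect_error(leadTime(tr3), "no PD event")
  # flat Fc: no detection, no lead
  t0 <- simulateTrajectory(trajectorySpec(
    fc_gain = 0, noise = list(fc = 0, cea = 0, burden = 0), seed = 32))
  lt0 <- leadTime(t0)
  expect_false(lt0$detected)
  expect_true(is.na(lt0$lead_days))
})

test_that("programmed leads are recovered within one draw interval", {
  errs <- vapply(1:25, function(s) {
    tr <- simulateTrajectory(trajectorySpec(fc_lead_days = 35), seed = s)
    lt <- leadTime(tr)
    if (!lt$detected) return(NA_real_)
    lt$lead_days - 35
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 7, na.rm = TRUE), 0.9)
})

test_that("trend concordance ranks identical, opposite and flat curves", {
  day <- 0:50
  a <- data.frame(day = day, value = sin(day / 8))
  b <- data.frame(day = day, value = -sin(day / 8))
  expect_equal(trendConcordance(a, a), 1)
  expect_equal(trendConcordance(a, b), -1)
  flat <- data.frame(day = day, value = rep(1, 51))
  expect_equal(trendConcordance(a, flat), 0)
  expect_error(trendConcordance(a, data.frame(day = 200:205, value = 1:6)),
               "common grid")
})
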