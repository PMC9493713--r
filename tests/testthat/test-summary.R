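test_that("gape_series matches the chord closed form", {
  # closed jaws: constant baseline
  n <- 10
  up <- matrix(rep(c(3, 0.2, 0), each = n), n)
  lo <- matrix(rep(c(3, -0.2, 0), each = n), n)
  expect_equal(gape_series(up, lo), rep(0.4, n))
  # jaw tip 3 cm from the hinge rotated -30 deg: chord 2 * 3 * sin(15 deg)
  hinge <- c(0, 0, 0)
  tip <- c(3, 0, 0)
  up1 <- matrix(rep(tip, each = 2), 2)
  R <- rot_axis_angle(c(0, 0, 1), -30 * pi / 180)
  lo1 <- rbind(tip, as.numeric(R %*% tip))
  g <- gape_series(up1, lo1)
  expect_equal(g[1], 0)
  expect_equal(g[2], 2 * 3 * sin(15 * pi / 180), tolerance = 1e-12)
})

test_that("detect_events finds onset, peak and close on a triangular pulse", {
  gape <- c(rep(0, 10), seq(0, 1, length.out = 21), seq(1, 0,
                                                        length.out = 21)[-1],
            rep(0, 10))
  ev <- detect_events(gape, fps = 100, threshold = 0.05)
  expect_equal(ev$peak_gape_frame, 31L)
  # symmetric pulse: onset and close symmetric about the apex
  expect_equal(ev$peak_gape_frame - ev$onset_frame,
               ev$jaw_close_frame - ev$peak_gape_frame)
  # plateaued maximum: first frame of the plateau
  gape2 <- c(rep(0, 5), seq(0, 1, length.out = 11), rep(1, 5),
             seq(1, 0, length.out = 11), rep(0, 5))
  ev2 <- detect_events(gape2, fps = 100, threshold = 0.05)
  expect_equal(ev2$peak_gape_frame, 16L)
  # no excursion: an error
  expect_error(detect_events(rep(1, 50), fps = 100, threshold = 0.05),
               "no strike")
  expect_error(detect_events(gape, fps = 100, threshold = 0.7), "threshold")
})

test_that("the detector is invariant to time shifts and amplitude scaling", {
  pulse <- function(pad) c(rep(0, pad), sin(seq(0, pi, length.out = 51)),
                           rep(0, 60 - pad))
  e1 <- detect_events(pulse(10), fps = 100, threshold = 0.05)
  e2 <- detect_events(pulse(25), fps = 100, threshold = 0.05)
  expect_equal(e2$onset_frame - e1$onset_frame, 15L)
  expect_equal(e1$duration_ms, e2$duration_ms)
  e3 <- detect_events(10 * pulse(10), fps = 100, threshold = 0.05)
  expect_equal(e3$onset_frame, e1$onset_frame)
  expect_equal(e3$duration_ms, e1$duration_ms)
})

test_that("channel peaks use the first-frame tie-break and peak-gape timing", {
  gape <- c(0, 1, 2, 3, 2, 1, 0, 0)
  ch <- list(jaw = c(0, -1, -2, -2, -1, 0, 0, 0),
             elev_max = c(0, 0.5, 1, 1, 0.5, 0, 0, 0))
  ev <- detect_events(gape, channels = ch, fps = 1000, threshold = 0.1)
  p <- ev$peaks
  expect_equal(p$frame[p$channel == "jaw"], 3L)       # first of the tie
  expect_equal(p$frame[p$channel == "elev_max"], 3L)  # maximum for _max
  expect_equal(p$time_re_peak_gape_ms[p$channel == "jaw"], -1)
})

test_that("align_and_average matches hand arithmetic", {
  # identical trials: mean equals the trial, sem 0
  tr <- list(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))
  avg <- align_and_average(tr, c(3, 3), fps = 100)
  expect_equal(avg$mean, c(0, 1, 2, 1, 0))
  expect_equal(avg$sem, rep(0, 5))
  expect_equal(avg$time_ms[3], 0)
  # two constant trials at +1 and -1: mean 0, sem = sd/sqrt(2) = 1
  tr2 <- list(rep(1, 5), rep(-1, 5))
  avg2 <- align_and_average(tr2, c(3, 3), fps = 100)
  expect_equal(avg2$mean, rep(0, 5))
  expect_equal(avg2$sem, rep(1, 5))
  # single trial: sem is NA
  avg3 <- align_and_average(list(1:5), 2, fps = 100)
  expect_true(all(is.na(avg3$sem)))
  expect_equal(avg3$n, rep(1, 5))
  # unequal lengths: per-time-point counts, no extrapolation
  avg4 <- align_and_average(list(c(0, 1, 2), c(0, 1, 2, 3, 4)), c(2, 2), 100)
  expect_equal(avg4$n, c(2, 2, 2, 1, 1))
})

test_that("summarize_trials reports mean and s.e.m. per variable", {
  one <- data.frame(gape_deg = -11.6, dur_ms = 465)
  s1 <- summarize_trials(one)
  expect_equal(s1$mean, c(-11.6, 465))
  expect_equal(s1$sem, c(0, 0))
  expect_true(attr(s1, "single_trial"))
  reps <- data.frame(gape_deg = rep(-11.6, 10), dur_ms = rep(465, 10))
  expect_equal(summarize_trials(reps)$sem, c(0, 0))
  two <- data.frame(v = c(1, 3))
  expect_equal(summarize_trials(two)$sem, stats::sd(c(1, 3)) / sqrt(2))
})

test_that("body_length_regression matches the closed-form normal equations", {
  # perfectly collinear
  rec <- data.frame(body_length_mm = c(100, 200, 300),
                    time_to_peak_gape_ms = c(10, 20, 30))
  fit <- body_length_regression(rec)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.1)
  # constant response: zero slope, zero r^2
  rec2 <- data.frame(body_length_mm = c(100, 200, 300),
                     time_to_peak_gape_ms = c(15, 15, 15))
  fit2 <- body_length_regression(rec2)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$r_squared, 0)
  # 5-point hand-computable table against the normal equations
  x <- c(120, 250, 400, 560, 800)
  y <- c(35, 60, 48, 100, 140)
  rec3 <- data.frame(body_length_mm = x, time_to_peak_gape_ms = y)
  fit3 <- body_length_regression(rec3)
  slope_hand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  intercept_hand <- mean(y) - slope_hand * mean(x)
  expect_equal(fit3$slope, slope_hand, tolerance = 1e-12)
  expect_equal(fit3$intercept, intercept_hand, tolerance = 1e-12)
  r2_hand <- stats::cor(x, y)^2
  expect_equal(fit3$r_squared, r2_hand, tolerance = 1e-12)
  # degenerate predictor
  rec4 <- data.frame(body_length_mm = c(100, 100, 100),
                     time_to_peak_gape_ms = c(1, 2, 3))
  expect_error(body_length_regression(rec4), "constant")
})

test_that("peak_value returns extrema and unbiased quadratic vertices", {
  x <- c(5, 3, 1, 3, 5)
  expect_equal(peak_value(x), 1)
  expect_equal(peak_value(-x, maximum = TRUE), -1)
  # exact parabola: the fitted vertex reproduces the analytic minimum
  tt <- seq(-3, 3, by = 0.25)
  par <- 2 + (tt - 0.1)^2
  expect_equal(peak_value(par, fit_halfwidth = 5), 2, tolerance = 1e-9)
  expect_equal(peak_value(par, fit_halfwidth = 0), min(par))
})
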