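test_that("freeze_bone holds the bone's pose relative to the neurocranium", {
  rig <- default_rig()
  sim <- simulate_strike(rig, quick_cfg())
  poses <- sim$truth$poses
  t0 <- 40; N <- 20
  frozen <- freeze_bone(poses, "lower_jaw", "neurocranium", t0, N)
  inv <- strikekin:::invert_transform
  for (f in c(t0, t0 + 7, t0 + N)) {
    expected <- poses$neurocranium$transforms[[f]] %*%
      inv(poses$neurocranium$transforms[[t0]]) %*%
      poses$lower_jaw$transforms[[t0]]
    expect_lt(max(abs(frozen$lower_jaw$transforms[[f]] - expected)), 1e-10)
  }
  # outside the window and other bodies: untouched
  expect_identical(frozen$lower_jaw$transforms[[t0 + N + 1]],
                   poses$lower_jaw$transforms[[t0 + N + 1]])
  expect_identical(frozen$ceratohyal_R, poses$ceratohyal_R)
  # a bone already stationary relative to the neurocranium is unchanged
  frozen2 <- freeze_bone(poses, "upper_jaw", "neurocranium", t0, N)
  for (f in t0:(t0 + N))
    expect_lt(max(abs(frozen2$upper_jaw$transforms[[f]] -
                        poses$upper_jaw$transforms[[f]])), 1e-10)
})

test_that("the two-plate geometry yields RCVC 0.5/0.5 against the oracle", {
  w <- make_plate_world()
  cfg <- freeze_window_config(10, list(roof = "roof", floor = "floor"))
  res <- rcvc_series(w$def, w$poses, cfg)
  expect_true(all(!res$degenerate))
  expect_equal(res$rcvc_roof, rep(0.5, nrow(res)), tolerance = 0.02)
  expect_equal(res$rcvc_floor, rep(0.5, nrow(res)), tolerance = 0.02)
  # brute-force freeze-and-measure oracle at one window, via the independent
  # hull-volume oracle and hand-frozen locator positions
  t0 <- 5; t1 <- 15
  world_at <- function(f, freeze = NULL) {
    out <- NULL
    for (i in seq_len(nrow(w$def$locators))) {
      b <- w$def$locators$body[i]
      fr <- if (!is.null(freeze) && b == freeze) t0 else f
      p <- as.numeric(w$def$locators[i, c("x", "y", "z")])
      T <- w$poses[[b]]$transforms[[fr]]
      out <- rbind(out, as.numeric(T[1:3, 1:3] %*% p + T[1:3, 4]))
    }
    out
  }
  dv_full <- hull_volume_brute(world_at(t1)) - hull_volume_brute(world_at(t0))
  dv_roof <- hull_volume_brute(world_at(t1, "roof")) -
    hull_volume_brute(world_at(t0))
  dv_floor <- hull_volume_brute(world_at(t1, "floor")) -
    hull_volume_brute(world_at(t0))
  oracle <- (dv_full - c(dv_roof, dv_floor)) /
    sum(abs(dv_full - c(dv_roof, dv_floor)))
  i <- which(res$window_start_frame == t0)
  expect_equal(c(res$rcvc_roof[i], res$rcvc_floor[i]), oracle,
               tolerance = 0.02)
})

test_that("a single mover takes all of the contribution with the right sign", {
  rig <- default_rig()
  cfg <- strike_profile_config(
    channels = list(lower_jaw.hinge = list(
      amplitude = -18, onset_ms = 0, time_to_peak_ms = 160, return_ms = 140,
      shape = "raised_cosine")),
    fps = 150, duration_ms = 300, noise_sigma = 0, seed = 1, prey = NULL)
  sim <- simulate_strike(rig, cfg)
  res <- rcvc_series(default_endocast(rig), sim$truth$poses,
                     default_freeze_config(fps = 150))
  ok <- !res$degenerate
  # normalization on every non-degenerate window
  tot <- abs(res$rcvc_lower_jaw) + abs(res$rcvc_ceratohyal) +
    abs(res$rcvc_clavicle)
  expect_true(all(abs(tot[ok] - 1) < 1e-6))
  # opening: jaw is the sole expander
  opening <- ok & res$window_start_frame + 12 <= 160 / 1000 * 150
  expect_true(all(res$rcvc_lower_jaw[opening] > 0.98))
  # closing: the jaw's motion contracts the cavity
  closing <- ok & res$window_start_frame >= 170 / 1000 * 150
  expect_true(all(res$rcvc_lower_jaw[closing] < -0.98))
  # stationary units stay below the nullity threshold
  expect_true(all(abs(res$rcvc_ceratohyal[ok]) < 0.02))
  expect_true(all(abs(res$rcvc_clavicle[ok]) < 0.02))
})

test_that("motionless trials give degenerate windows with zero RCVC", {
  w <- make_plate_world(n_frames = 15, rate = 0)
  cfg <- freeze_window_config(5, list(roof = "roof", floor = "floor"))
  res <- rcvc_series(w$def, w$poses, cfg)
  expect_true(all(res$degenerate))
  expect_true(all(res$rcvc_roof == 0 & res$rcvc_floor == 0))
})

test_that("matched ms-scale windows at different frame rates agree", {
  rig <- default_rig()
  mk <- function(fps) {
    cfg <- strike_profile_config(
      channels = list(
        lower_jaw.hinge = list(amplitude = -15, onset_ms = 0,
                               time_to_peak_ms = 180, return_ms = 100,
                               shape = "raised_cosine"),
        ceratohyal_R.hinge = list(amplitude = -18, onset_ms = 60,
                                  time_to_peak_ms = 180, return_ms = 60,
                                  shape = "raised_cosine"),
        ceratohyal_L.hinge = list(amplitude = -18, onset_ms = 60,
                                  time_to_peak_ms = 180, return_ms = 60,
                                  shape = "raised_cosine")),
      fps = fps, duration_ms = 320, noise_sigma = 0, seed = 1, prey = NULL)
    sim <- simulate_strike(rig, cfg)
    units <- list(lower_jaw = "lower_jaw",
                  ceratohyal = c("ceratohyal_R", "ceratohyal_L"))
    rcvc_series(default_endocast(rig), sim$truth$poses,
                freeze_window_config(round(0.04 * fps), units))
  }
  hi <- mk(250)   # 10-frame window = 40 ms
  lo <- mk(125)   #  5-frame window = 40 ms
  ok_lo <- !lo$degenerate
  hi_interp <- stats::approx(hi$center_time_ms, hi$rcvc_lower_jaw,
                             xout = lo$center_time_ms[ok_lo], rule = 2)$y
  rms <- sqrt(mean((hi_interp - lo$rcvc_lower_jaw[ok_lo])^2))
  expect_lt(rms, 0.05)
})

test_that("freeze configuration is validated", {
  expect_error(freeze_window_config(1, list(a = "a")), "window")
  expect_error(freeze_window_config(5, list(a = "x", b = "x")), "overlap")
  expect_error(freeze_window_config(5, list(a = "neurocranium")),
               "neurocranium")
  expect_error(freeze_window_config(5, list("x")), "named")
  expect_equal(default_freeze_config(500)$window, 20L)
  expect_equal(default_freeze_config(150)$window, 12L)
})
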