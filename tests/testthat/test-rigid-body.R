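ref_tetra <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.5, 0.5, 1.5))

test_that("points CSV round-trips losslessly", {
  sim <- simulate_strike(default_rig(), default_strike_config(
    noise_sigma = 0.029, seed = 2, duration_ms = 999, pre_roll_ms = 50))
  expect_equal(n_frames(sim$markers), 500)
  f <- tempfile(fileext = ".csv")
  write_points_csv(sim$markers, f)
  back <- read_points_csv(f, fps = 500)
  expect_identical(back$markers, sim$markers$markers)
  expect_lt(max(abs(back$coords - sim$markers$coords)), 1e-9)
})

test_that("points CSV handles missing values and rejects bad headers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a_X,a_Y,a_Z", "1,2,3", "4,5,6", "NaN,NaN,NaN"), f)
  m <- read_points_csv(f, fps = 150)
  expect_equal(dim(m$coords), c(3, 1, 3))
  expect_true(all(is.na(m$coords[3, 1, ])))
  expect_equal(m$coords[2, 1, ], c(X = 4, Y = 5, Z = 6))
  # partial missingness marks the whole frame missing for that marker
  writeLines(c("a_X,a_Y,a_Z", "1,,3"), f)
  expect_true(all(is.na(read_points_csv(f, 150)$coords)))
  writeLines(c("a_X,a_Y,b_Z", "1,2,3"), f)
  expect_error(read_points_csv(f, 150), "triple")
  writeLines(c("a_X,a_Y,a_Z,b_X", "1,2,3,4"), f)
  expect_error(read_points_csv(f, 150), "multiple of 3")
})

test_that("estimate_rigid_transform recovers constructed transforms", {
  # identity
  fit <- estimate_rigid_transform(ref_tetra, ref_tetra)
  expect_equal(fit$transform, diag(4), tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
  # 90 degrees about z plus a translation
  R <- rot_axis_angle(c(0, 0, 1), pi / 2)
  obs <- ref_tetra %*% t(R)
  obs <- sweep(obs, 2, c(1, 2, 3), `+`)
  fit <- estimate_rigid_transform(ref_tetra, obs)
  expect_lt(max(abs(fit$transform[1:3, 1:3] - R)), 1e-10)
  expect_lt(max(abs(fit$transform[1:3, 4] - c(1, 2, 3))), 1e-10)
  # degenerate inputs
  expect_error(estimate_rigid_transform(ref_tetra[1:2, ], ref_tetra[1:2, ]),
               ">= 3")
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(estimate_rigid_transform(lin, lin), "collinear")
})

test_that("a reflected observation never yields an improper rotation", {
  obs <- ref_tetra
  obs[, 3] <- -obs[, 3]
  fit <- estimate_rigid_transform(ref_tetra, obs)
  expect_gt(det(fit$transform[1:3, 1:3]), 0)
})

test_that("Monte-Carlo rotation error stays below half a degree", {
  set.seed(11)
  errs <- numeric(300)
  for (i in seq_along(errs)) {
    axis <- stats::rnorm(3); theta <- stats::runif(1, -pi, pi)
    R <- rot_axis_angle(axis, theta)
    obs <- ref_tetra %*% t(R) + matrix(stats::rnorm(12, 0, 0.01), ncol = 3)
    fit <- estimate_rigid_transform(ref_tetra, obs)
    errs[i] <- rot_angle_between(fit$transform[1:3, 1:3], R)
  }
  expect_lt(stats::median(errs) * 180 / pi, 0.5)
})

test_that("the SVD fit agrees with a brute-force minimizer", {
  set.seed(21)
  for (i in 1:6) {
    ref <- matrix(stats::rnorm(12, sd = 2), ncol = 3)
    R <- rot_axis_angle(stats::rnorm(3), stats::runif(1, -pi, pi))
    obs <- ref %*% t(R) + matrix(stats::rnorm(12, 0, 0.05), ncol = 3)
    obs <- sweep(obs, 2, stats::rnorm(3), `+`)
    fit <- estimate_rigid_transform(ref, obs)
    brute <- brute_rigid_fit(ref, obs)
    expect_lt(rot_angle_between(fit$transform[1:3, 1:3], brute$R), 1e-4)
    expect_lt(max(abs(fit$transform[1:3, 4] - brute$t)), 1e-4)
  }
})

test_that("animate_body honours visibility rules", {
  rig <- default_rig()
  sim <- simulate_strike(rig, quick_cfg())
  set <- sim$markers
  # a 5-marker body with one marker missing for 10 frames stays valid
  co <- set$coords
  co[5:14, match("neuro_1", set$markers), ] <- NA
  set2 <- marker_set(co, set$markers, set$fps)
  ps <- animate_body(rig_body_defs(rig)$neurocranium, set2)
  expect_true(all(ps$valid))
  # only 2 visible markers at a frame invalidates it
  co2 <- set$coords
  jaw_idx <- match(c("ljaw_1"), set$markers)
  co2[7, jaw_idx, ] <- NA
  set3 <- marker_set(co2, set$markers, set$fps)
  ps2 <- animate_body(rig_body_defs(rig)$lower_jaw, set3)
  expect_false(ps2$valid[7])
  expect_true(ps2$valid[6])
  # a body that never has 3 visible markers errors
  co3 <- set$coords
  co3[, match(c("ljaw_1", "ljaw_2"), set$markers), ] <- NA
  expect_error(animate_body(rig_body_defs(rig)$lower_jaw,
                            marker_set(co3, set$markers, set$fps)),
               "never has 3")
})

test_that("fitted rotations are orthonormal and proper", {
  sim <- simulate_strike(default_rig(), quick_cfg(noise_sigma = 0.05,
                                                  seed = 4))
  poses <- animate_rig(default_rig(), sim$markers, filter_hz = NULL)
  for (nm in names(poses)) for (f in seq(1, n_frames(poses[[nm]]), by = 13)) {
    R <- poses[[nm]]$transforms[[f]][1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
})

test_that("fit_body_plane reports per-frame deformation residuals", {
  rig <- default_rig()
  sim <- simulate_strike(rig, quick_cfg())
  bp <- fit_body_plane(sim$markers, rig$markers$name[rig$markers$body ==
                                                       "body_plane"])
  expect_true(all(bp$valid))
  expect_lt(max(bp$residual), 1e-9)
  # deform one marker: the residual flags it, the fit survives
  co <- sim$markers$coords
  co[3, match("vbody_1", sim$markers$markers), 2] <-
    co[3, match("vbody_1", sim$markers$markers), 2] + 0.5
  bp2 <- fit_body_plane(marker_set(co, sim$markers$markers, 500),
                        rig$markers$name[rig$markers$body == "body_plane"])
  expect_gt(bp2$residual[3], 0.1)
  expect_true(bp2$valid[3])
})

test_that("transform CSVs round-trip in both conventions", {
  sim <- simulate_strike(default_rig(), quick_cfg())
  poses <- animate_rig(default_rig(), sim$markers, filter_hz = NULL)
  f <- tempfile(fileext = ".csv")
  write_transforms_csv(poses$lower_jaw, f)
  back <- read_transforms_csv(f, fps = 500)
  expect_equal(back$name, "lower_jaw")
  for (fr in c(1, 15, 31))
    expect_lt(max(abs(back$transforms[[fr]] - poses$lower_jaw$transforms[[fr]])),
              1e-9)
  # the file stores the row-vector (transposed) matrix
  col_reader <- read_transforms_csv(f, fps = 500, row_vector = FALSE)
  expect_equal(col_reader$transforms[[1]],
               t(poses$lower_jaw$transforms[[1]]), tolerance = 1e-9)
})
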