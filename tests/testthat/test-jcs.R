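rot_z <- strikekin:::rot_z
rot_y <- strikekin:::rot_y
rot_x <- strikekin:::rot_x

make_pose <- function(T, n = 1, fps = 500) {
  pose_series("b", rep(list(T), n), numeric(n), rep(TRUE, n), fps)
}

test_that("zyx decomposition inverts composition exactly", {
  d <- pi / 180
  # aligned poses: all channels zero
  jcs <- joint_coordinate_system("j", "p", "d")
  k <- jcs_angles(jcs, make_pose(diag(4)), make_pose(diag(4)))
  expect_equal(unlist(k[1, c("rz", "ry", "rx", "tx", "ty", "tz")]),
               c(rz = 0, ry = 0, rx = 0, tx = 0, ty = 0, tz = 0))
  # -30 degrees about the shared z axis
  T30 <- diag(4); T30[1:3, 1:3] <- rot_z(-30 * d)
  k <- jcs_angles(jcs, make_pose(diag(4)), make_pose(T30))
  expect_equal(unlist(k[1, c("rz", "ry", "rx")]),
               c(rz = -30, ry = 0, rx = 0), tolerance = 1e-10)
  # rz = -20 then rx = -10 decomposes exactly
  T2 <- diag(4); T2[1:3, 1:3] <- rot_z(-20 * d) %*% rot_x(-10 * d)
  k <- jcs_angles(jcs, make_pose(diag(4)), make_pose(T2))
  expect_equal(unlist(k[1, c("rz", "ry", "rx")]),
               c(rz = -20, ry = 0, rx = -10), tolerance = 1e-10)
})

test_that("random rotations survive a decompose/recompose round trip", {
  set.seed(9)
  for (i in seq_len(2000)) {
    ang <- c(stats::runif(1, -pi, pi), stats::runif(1, -pi / 2 + 0.05,
                                                    pi / 2 - 0.05),
             stats::runif(1, -pi, pi))
    R <- rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3])
    got <- euler_zyx(R)
    R2 <- rot_z(got[1]) %*% rot_y(got[2]) %*% rot_x(got[3])
    expect_lt(max(abs(R2 - R)), 1e-9)
  }
})

test_that("gimbal proximity is flagged with the documented convention", {
  R <- rot_z(0.4) %*% rot_y(pi / 2) %*% rot_x(0.1)
  a <- euler_zyx(R)
  expect_true(attr(a, "gimbal"))
  expect_equal(a[3], 0)                       # rx parked at zero
  # rz absorbs the observable combination; recomposition still matches
  R2 <- rot_z(a[1]) %*% rot_y(a[2]) %*% rot_x(a[3])
  expect_lt(max(abs(R2 - R)), 1e-6)
})

test_that("JCS channels are invariant to a rigid world-frame change", {
  rig <- default_rig()
  sim <- simulate_strike(rig, quick_cfg())
  poses <- animate_rig(rig, sim$markers, filter_hz = NULL)
  jcs <- default_jcs_set(rig)
  k1 <- jcs_angles(jcs$ceratohyal_R, poses$neurocranium, poses$ceratohyal_R)
  W <- strikekin:::make_transform(rot_axis_angle(c(1, 2, 3), 0.8), c(5, -4, 2))
  shift <- function(ps) {
    ps$transforms <- lapply(ps$transforms, function(T) W %*% T)
    ps
  }
  k2 <- jcs_angles(jcs$ceratohyal_R, shift(poses$neurocranium),
                   shift(poses$ceratohyal_R))
  for (c_ in c("rz", "ry", "rx", "tx", "ty", "tz"))
    expect_lt(max(abs(k1[[c_]] - k2[[c_]])), 1e-9)
})

test_that("zero_offset shifts by a constant and is idempotent", {
  jcs <- joint_coordinate_system("j", "p", "d")
  d <- pi / 180
  Ts <- lapply(c(5, 10, 20) * d, function(a) {
    T <- diag(4); T[1:3, 1:3] <- rot_z(a); T
  })
  pose <- pose_series("b", Ts, numeric(3), rep(TRUE, 3), 500)
  k <- jcs_angles(jcs, make_pose(diag(4), 3), pose)
  z1 <- zero_offset(k, 2)
  expect_equal(z1$rz[2], 0)
  expect_equal(z1$rz, k$rz - k$rz[2])
  expect_equal(zero_offset(z1, 2)$rz, z1$rz)     # idempotent
  kz <- k; kz$rz <- rep(0, 3)
  expect_equal(zero_offset(zero_offset(k, 1), 1)$rz[1], 0)
  expect_error(zero_offset(k, 9), "valid")
})

test_that("virtual_point maps bone-fixed points through poses", {
  p <- c(1.5, -0.5, 2)
  expect_equal(virtual_point(make_pose(diag(4)), p)[1, ], p)
  Tt <- diag(4); Tt[1:3, 4] <- c(1, 0, 0)
  expect_equal(virtual_point(make_pose(Tt), p)[1, ], p + c(1, 0, 0))
  R <- rot_axis_angle(c(0, 1, 0), 0.6)
  Tr <- diag(4); Tr[1:3, 1:3] <- R; Tr[1:3, 4] <- c(0, 0, 1)
  expect_equal(virtual_point(make_pose(Tr), p)[1, ],
               as.numeric(R %*% p) + c(0, 0, 1), tolerance = 1e-12)
})

test_that("muscle strain follows 100 * (L - L_i) / L_i", {
  n <- 5
  o <- matrix(0, n, 3)
  i1 <- cbind(seq(2, 1.786, length.out = n), 0, 0)
  s <- muscle_strain(o, i1, reference_frame = 1)
  expect_equal(s$strain_pct[1], 0)
  expect_equal(min(s$strain_pct), -10.7, tolerance = 1e-10)
  # constant distance: zero throughout
  s0 <- muscle_strain(o, matrix(rep(c(1, 1, 0), each = n), n), 1)
  expect_equal(s0$strain_pct, rep(0, n))
  # doubling: +100%
  i2 <- cbind(c(1, 2), 0, 0)
  expect_equal(muscle_strain(matrix(0, 2, 3), i2, 1)$strain_pct[2], 100)
  # degenerate muscle
  expect_error(muscle_strain(matrix(0, 2, 3), matrix(0, 2, 3), 1), "L_i")
  # rigid whole-animal motion leaves strain unchanged
  W <- strikekin:::make_transform(rot_axis_angle(c(1, 0, 1), 1.1), c(3, 2, 1))
  om <- strikekin:::apply_transform(W, o)
  im <- strikekin:::apply_transform(W, i1)
  expect_equal(muscle_strain(om, im, 1)$strain_pct, s$strain_pct,
               tolerance = 1e-9)
})

test_that("tongue distances track geometry and the generator stretch factor", {
  n <- 4
  tri <- function(scale = 1) {
    list(r = matrix(rep(scale * c(1.5, 0, 0), each = n), n),
         l = matrix(rep(scale * c(0, 0, 0), each = n), n),
         c_ = matrix(rep(scale * c(0.75, 1.5 * sqrt(3) / 2, 0), each = n), n))
  }
  a <- tri(1)
  d <- tongue_distances(a$r, a$l, a$c_)
  expect_equal(d$right_left, rep(1.5, n))
  expect_equal(d$right_rostral, rep(1.5, n))
  expect_equal(d$left_rostral, rep(1.5, n))
  b <- tri(1.1)
  d2 <- tongue_distances(b$r, b$l, b$c_)
  expect_equal(d2$right_left / d$right_left, rep(1.1, n))
  # generator stretch factor: two simulations differing only in the stretch
  # have tongue distances in the exact ratio (1 + s) at peak depression
  cfg1 <- default_strike_config(noise_sigma = 0, seed = 1)
  cfg0 <- cfg1; cfg0$tongue_stretch <- 0
  sim1 <- simulate_strike(default_rig(), cfg1)
  sim0 <- simulate_strike(default_rig(), cfg0)
  dist_rl <- function(sim) tongue_distances(sim$truth$soft$tongue_right,
                                            sim$truth$soft$tongue_left,
                                            sim$truth$soft$tongue_rostral)$right_left
  f_peak <- which.min(sim1$truth$channels$ceratohyal_R.hinge)
  expect_equal(dist_rl(sim1)[f_peak] / dist_rl(sim0)[f_peak],
               1 + cfg1$tongue_stretch, tolerance = 1e-9)
  expect_equal(dist_rl(sim1)[1], dist_rl(sim0)[1], tolerance = 1e-12)
})

test_that("prey kinematics recover closed-form tracks", {
  fps <- 500
  n <- 201
  t <- (seq_len(n) - 1) / fps
  # stationary
  still <- matrix(rep(c(2, 1, 0), each = n), n)
  pk <- prey_kinematics(still, fps)
  expect_lt(max(pk$displacement_cm), 1e-12)
  expect_lt(max(pk$velocity_cm_s), 1e-9)
  # constant acceleration 2000 cm/s^2
  acc <- cbind(0.5 * 2000 * t^2, 0, 0)
  pk2 <- prey_kinematics(acc, fps)
  expect_lt(max(abs(pk2$acceleration_cm_s2 - 2000)) / 2000, 0.01)
  # constant velocity 60 cm/s
  cv <- cbind(60 * t, 0, 0)
  pk3 <- prey_kinematics(cv, fps)
  expect_lt(max(abs(pk3$velocity_cm_s - 60)) / 60, 0.01)
  expect_lt(max(pk3$acceleration_cm_s2[2:(n - 1)]), 1e-6)
  expect_error(prey_kinematics(still[1:2, ], fps), ">= 3")
})

test_that("difference stencils are exact on low-order polynomials", {
  dt <- 0.01
  x <- seq(0, 1, by = dt)
  p <- 2 + 3 * x - 5 * x^2
  d1 <- strikekin:::diff_central(p, dt)
  expect_equal(d1, 3 - 10 * x, tolerance = 1e-9)
  d2 <- strikekin:::diff2_central(p, dt)
  expect_equal(d2, rep(-10, length(x)), tolerance = 1e-6)
})
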