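# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (brute-force enumeration / closed forms).

# convex hull volume by O(n^4) face enumeration: a triple of points is a hull
# face iff all other points lie on one side of its plane; volume by summing
# signed tetrahedra to the centroid. Assumes points in general position.
hull_volume_brute <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c(
      (b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    s <- pts %*% nrm - sum(nrm * a)
    if (all(s <= 1e-9 * nn) || all(s >= -1e-9 * nn)) {
      h <- abs(sum(nrm * (ctr - a))) / nn
      vol <- vol + (nn / 2) * h / 3
    }
  }
  vol
}

# independent axis-angle rotation (Rodrigues), no package code
rot_axis_angle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(theta); s <- sin(theta); v <- 1 - c_
  matrix(c(x * x * v + c_, x * y * v + z * s, x * z * v - y * s,
           x * y * v - z * s, y * y * v + c_, y * z * v + x * s,
           x * z * v + y * s, y * z * v - x * s, z * z * v + c_),
         3, 3)
}

# brute-force rigid fit: multi-start BFGS over axis-angle + translation
brute_rigid_fit <- function(reference, observed, n_starts = 8) {
  sse <- function(p) {
    th <- sqrt(sum(p[1:3]^2))
    R <- if (th < 1e-12) diag(3) else rot_axis_angle(p[1:3] / th, th)
    pred <- reference %*% t(R)
    pred <- sweep(pred, 2, p[4:6], `+`)
    sum((observed - pred)^2)
  }
  best <- NULL
  set.seed(1234)
  starts <- rbind(rep(0, 6),
                  matrix(stats::runif(6 * (n_starts - 1), -pi, pi), ncol = 6))
  starts[, 4:6] <- starts[, 4:6] * 2
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], sse, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- sqrt(sum(best$par[1:3]^2))
  R <- if (th < 1e-12) diag(3) else rot_axis_angle(best$par[1:3] / th, th)
  list(R = R, t = best$par[4:6], sse = best$value)
}

# rotation angle (rad) between two rotation matrices
rot_angle_between <- function(A, B) {
  tr <- sum(diag(t(A) %*% B))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

# small multi-body strike configuration for fast tests (151 frames @ 500 fps)
quick_cfg <- function(noise_sigma = 0, seed = 1, fps = 500,
                      duration_ms = 300) {
  rc <- function(a, onset, ttp, ret)
    list(amplitude = a, onset_ms = onset, time_to_peak_ms = ttp,
         return_ms = ret, shape = "raised_cosine")
  strike_profile_config(
    channels = list(lower_jaw.hinge = rc(-15, 20, 150, 100),
                    ceratohyal_R.hinge = rc(-18, 40, 150, 80),
                    ceratohyal_L.hinge = rc(-18, 40, 150, 80),
                    neurocranium.hinge = rc(3, 60, 120, 80)),
    fps = fps, duration_ms = duration_ms, noise_sigma = noise_sigma,
    seed = seed, prey = NULL)
}

# canonical noisy-pipeline analysis used by the acceptance criteria:
# refine ceratohyal markers, 35 Hz filter, zero at a pre-onset frame
analyze_noisy_strike <- function(rig, markers) {
  cerm <- rig$markers$name[rig$markers$body %in%
                             c("ceratohyal_R", "ceratohyal_L")]
  poses <- animate_rig(rig, markers, filter_hz = 35, refine_markers = cerm,
                       refine_window = 81)
  g <- gape_series(virtual_point(poses$upper_jaw, c(4.3, 0.15, 0)),
                   virtual_point(poses$lower_jaw, c(4.3, -0.25, 0)))
  ev <- detect_events(g, fps = markers$fps, threshold = 0.05)
  zf <- max(ev$onset_frame - 25L, 42L)
  kin <- strike_kinematics(rig, poses, zero_frame = zf)
  list(poses = poses, kin = kin, events = ev, gape = g)
}

# A hand-built two-plate geometry: static "neurocranium" holds the side
# walls, bone A carries the roof, bone B the floor. A moves up and B moves
# down at equal rates, so each contributes exactly half the volume change.
make_plate_world <- function(n_frames = 30, rate = 0.01, fps = 500) {
  jig <- function(k) 0.02 * sin(3.1 * k)
  pts <- list()
  k <- 0
  grid2 <- expand.grid(x = c(0, 0.5, 1), z = c(0, 0.5, 1))
  roof <- floor_ <- NULL
  for (i in seq_len(nrow(grid2))) {
    k <- k + 1
    roof <- rbind(roof, c(grid2$x[i] + jig(k), 0.5 + jig(k + 7) / 10,
                          grid2$z[i] + jig(k + 3)))
    floor_ <- rbind(floor_, c(grid2$x[i] + jig(k + 11), -0.5 - jig(k + 5) / 10,
                              grid2$z[i] + jig(k + 13)))
  }
  walls <- NULL
  for (y in c(-0.25, 0.25)) for (xz in list(c(0, 0.5), c(1, 0.5),
                                            c(0.5, 0), c(0.5, 1))) {
    k <- k + 1
    walls <- rbind(walls, c(xz[1] + jig(k), y + jig(k + 17), xz[2] + jig(k + 19)))
  }
  trans <- function(dy, f) {
    T <- diag(4); T[2, 4] <- dy * (f - 1); T
  }
  mk_pose <- function(dy) pose_series(
    "b", lapply(seq_len(n_frames), function(f) trans(dy, f)),
    numeric(n_frames), rep(TRUE, n_frames), fps)
  poses <- list(neurocranium = mk_pose(0), roof = mk_pose(rate),
                floor = mk_pose(-rate))
  loc <- rbind(
    data.frame(body = "roof", x = roof[, 1], y = roof[, 2], z = roof[, 3]),
    data.frame(body = "floor", x = floor_[, 1], y = floor_[, 2],
               z = floor_[, 3]),
    data.frame(body = "neurocranium", x = walls[, 1], y = walls[, 2],
               z = walls[, 3]))
  list(poses = poses,
       def = endocast_definition(loc, alpha = 1e3, bilateral_factor = 1))
}

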