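#' Strike motion profiles
#'
#' A motion channel drives one degree of freedom of one body: it rises from 0
#' to `amplitude` over `time_to_peak_ms` starting at `onset_ms`, then returns
#' toward 0 over `return_ms` (shape `"raised_cosine"`, C1-smooth) or holds the
#' peak (shape `"hold"`). Amplitudes are degrees for rotations.
#'
#' @param channel list with `amplitude`, `onset_ms`, `time_to_peak_ms`,
#'   `return_ms` (ignored for `"hold"`), `shape`.
#' @param t_ms time(s) in ms (vectorized).
#' @return channel value(s) at `t_ms`.
#' @examples
#' ch <- list(amplitude = -11.6, onset_ms = 0, time_to_peak_ms = 273.1,
#'            return_ms = 192.5, shape = "raised_cosine")
#' motion_profile(ch, 273.1)  # -11.6
#' @export
motion_profile <- function(channel, t_ms) {
  a <- channel$amplitude
  ttp <- channel$time_to_peak_ms
  ret <- if (is.null(channel$return_ms)) 0 else channel$return_ms
  shape <- if (is.null(channel$shape)) "raised_cosine" else channel$shape
  if (ttp < 0) stop("negative time-to-peak", call. = FALSE)
  if (ret < 0) stop("negative return time", call. = FALSE)
  if (a == 0) return(numeric(length(t_ms)))
  tt <- t_ms - channel$onset_ms
  out <- numeric(length(tt))
  rise <- tt >= 0 & tt <= ttp
  out[rise] <- a * (1 - cos(pi * tt[rise] / ttp)) / 2
  if (shape == "hold") {
    out[tt > ttp] <- a
  } else {
    fall <- tt > ttp & tt <= ttp + ret
    out[fall] <- a * (1 + cos(pi * (tt[fall] - ttp) / ret)) / 2
  }
  out
}

#' Strike profile configuration
#'
#' Bundles the per-body motion channels, recording parameters and noise model
#' of one synthetic strike. Defaults are not exposed here; see
#' [default_strike_config()] for the standard strike.
#'
#' @param channels named list: `<body>.hinge` and `<body>.long_axis` entries,
#'   each a channel list as in [motion_profile] (amplitudes in degrees).
#' @param fps frames per second (150 and 500 mirror the recordings; any
#'   positive rate is accepted).
#' @param duration_ms trial length (ms). Every channel must satisfy
#'   `onset + time_to_peak <= duration`.
#' @param noise_sigma isotropic Gaussian marker noise s.d. per coordinate per
#'   frame (cm); >= 0.
#' @param seed integer; identical configuration and seed give bit-identical
#'   output.
#' @param prey list controlling the prey displacement law (see
#'   [default_strike_config]); `NULL` for a stationary prey.
#' @param tongue_stretch fractional growth of the tongue triangle at peak
#'   ceratohyal depression.
#' @return An object of class `strike_profile_config`.
#' @export
strike_profile_config <- function(channels, fps = 500, duration_ms = 700,
                                  noise_sigma = 0.029, seed = 1,
                                  prey = NULL, tongue_stretch = 0.07) {
  stopifnot(fps > 0, duration_ms > 0, noise_sigma >= 0)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (ch$time_to_peak_ms < 0)
      stop("channel ", nm, ": negative time-to-peak", call. = FALSE)
    if (ch$onset_ms + ch$time_to_peak_ms > duration_ms)
      stop("channel ", nm, ": onset + time-to-peak exceeds duration",
           call. = FALSE)
  }
  structure(list(channels = channels, fps = fps, duration_ms = duration_ms,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 prey = prey, tongue_stretch = tongue_stretch),
            class = "strike_profile_config")
}

#' The standard strike configuration
#'
#' Channel amplitudes and timings follow the mean in-vivo kinematics of
#' suction strikes on non-evasive prey: jaw depression -11.6 deg peaking
#' 273.1 ms after onset (strike duration 465.6 ms), cranial elevation
#' +3.8 deg peaking 47 ms after peak gape, ceratohyal depression -20.7 deg
#' peaking 94.2 ms after peak gape, ceratohyal long-axis rotation -13.3 deg
#' peaking 151.4 ms after peak gape, clavicle retraction -22.4 deg and
#' cranial-rib retraction -7.7 deg peaking later still. The prey starts 2 cm
#' rostral of the upper jaw tip and is drawn 4.9 cm into the mouth with peak
#' velocity 63.3 cm/s (acceleration 2432.7 cm/s^2) near peak gape. Channel
#' onsets are generator conveniences chosen to reproduce those relative peak
#' times with a 40 ms pre-roll.
#'
#' @param fps frames per second (default 500).
#' @param noise_sigma marker noise s.d. (cm); default 0.029, the mean
#'   marker-tracking precision of the recordings. Use 0 for noiseless ground
#'   truth work.
#' @param seed integer RNG seed.
#' @param duration_ms trial length (default 850 ms: 150 ms quiet pre-roll,
#'   466 ms strike, post-roll for the hyoid/pectoral return).
#' @param pre_roll_ms quiet lead-in before jaw onset (default 150 ms, long
#'   enough that filter and smoother edge effects have died out by strike
#'   onset).
#' @return A [strike_profile_config].
#' @export
default_strike_config <- function(fps = 500, noise_sigma = 0.029, seed = 1,
                                  duration_ms = 850, pre_roll_ms = 150) {
  rc <- function(a, onset, ttp, ret)
    list(amplitude = a, onset_ms = onset, time_to_peak_ms = ttp,
         return_ms = ret, shape = "raised_cosine")
  jaw_onset <- pre_roll_ms
  peak_gape <- jaw_onset + 273.1
  channels <- list(
    lower_jaw.hinge = rc(-11.6, jaw_onset, 273.1, 465.56 - 273.1),
    neurocranium.hinge = rc(3.8, jaw_onset + 120,
                            peak_gape + 47.0 - (jaw_onset + 120), 200),
    ceratohyal_R.hinge = rc(-20.7, jaw_onset + 70,
                            peak_gape + 94.2 - (jaw_onset + 70), 190),
    ceratohyal_L.hinge = rc(-20.7, jaw_onset + 70,
                            peak_gape + 94.2 - (jaw_onset + 70), 190),
    ceratohyal_R.long_axis = rc(-13.3, jaw_onset + 90,
                                peak_gape + 151.4 - (jaw_onset + 90), 170),
    ceratohyal_L.long_axis = rc(-13.3, jaw_onset + 90,
                                peak_gape + 151.4 - (jaw_onset + 90), 170),
    clavicle_R.hinge = rc(-22.4, jaw_onset + 110, 300, 170),
    clavicle_L.hinge = rc(-22.4, jaw_onset + 110, 300, 170),
    cranial_rib_L.hinge = rc(-7.7, jaw_onset + 160, 300, 150)
  )
  prey <- list(start_offset = c(2.0, 0, 0.1), accel_cm_s2 = 2432.7,
               v_max_cm_s = 63.3, total_cm = 4.9,
               t_peak_v_ms = peak_gape)
  strike_profile_config(channels, fps = fps, duration_ms = duration_ms,
                        noise_sigma = noise_sigma, seed = seed, prey = prey)
}

# evaluate all channel values (radians for use in poses) at times t_ms;
# returns list per body: list(hinge = vec, long_axis = vec) in degrees
#' @keywords internal
eval_channels <- function(rig, config, t_ms) {
  out <- list()
  for (nm in names(config$channels)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[2] %in% c("hinge", "long_axis"))
      stop("channel name '", nm, "' must be <body>.hinge or <body>.long_axis",
           call. = FALSE)
    if (!parts[1] %in% names(rig$bodies))
      stop("channel for unknown body '", parts[1], "'", call. = FALSE)
    if (is.null(out[[parts[1]]]))
      out[[parts[1]]] <- list(hinge = numeric(length(t_ms)),
                              long_axis = numeric(length(t_ms)))
    out[[parts[1]]][[parts[2]]] <- motion_profile(config$channels[[nm]], t_ms)
  }
  out
}

# world pose of every body at every frame; returns named list of pose_series
#' @keywords internal
true_poses <- function(rig, config, t_ms) {
  ch <- eval_channels(rig, config, t_ms)
  n <- length(t_ms)
  ord <- body_order(rig)
  poses <- list()
  for (nm in ord) {
    body <- rig$bodies[[nm]]
    transforms <- vector("list", n)
    for (f in seq_len(n)) {
      hinge <- if (!is.null(ch[[nm]])) deg2rad(ch[[nm]]$hinge[f]) else 0
      lax <- if (!is.null(ch[[nm]])) deg2rad(ch[[nm]]$long_axis[f]) else 0
      P <- relative_pose(body, hinge, lax)
      if (!identical(body$parent, "world"))
        P <- poses[[body$parent]]$transforms[[f]] %*% P
      transforms[[f]] <- P
    }
    poses[[nm]] <- pose_series(nm, transforms, numeric(n), rep(TRUE, n),
                               config$fps)
  }
  poses
}

# closed-form prey displacement (cm) along -x at times t_ms:
# constant acceleration to v_max, then exponential velocity decay sized so
# the total path length equals total_cm
#' @keywords internal
prey_displacement <- function(prey, t_ms) {
  a <- prey$accel_cm_s2
  vm <- prey$v_max_cm_s
  D <- prey$total_cm
  t_burst <- vm / a                       # s
  d_burst <- vm^2 / (2 * a)               # cm
  if (d_burst >= D) stop("prey law: accel phase exceeds total distance",
                         call. = FALSE)
  tau <- (D - d_burst) / vm               # s
  t0 <- prey$t_peak_v_ms / 1000 - t_burst # accel start, s
  tt <- t_ms / 1000 - t0
  d <- numeric(length(tt))
  acc <- tt > 0 & tt <= t_burst
  d[acc] <- a * tt[acc]^2 / 2
  dec <- tt > t_burst
  d[dec] <- d_burst + vm * tau * (1 - exp(-(tt[dec] - t_burst) / tau))
  d
}

#' Simulate a synthetic suction-feeding strike
#'
#' Forward kinematics of the rig under the configured motion channels,
#' sampled at `fps`, plus soft-tissue points: three tongue markers tracking
#' the ceratohyal tips (with a stretch factor emulating tongue widening
#' during long-axis rotation), a prey marker following the configured
#' displacement law, and the four muscle origin/insertion beads. Isotropic
#' Gaussian noise of s.d. `noise_sigma` is added per coordinate per frame to
#' every marker. The returned ground truth holds the noiseless poses, true
#' channel values and soft-point trajectories.
#'
#' @param rig a [rig_definition] (default [default_rig()]).
#' @param config a [strike_profile_config] (default [default_strike_config()]).
#' @return list with `markers` (a [marker_set]) and `truth` (class
#'   `strike_ground_truth`: `poses`, `channels` (deg, per body/dof),
#'   `soft` (noiseless soft-point trajectories), `t_ms`, `config`).
#' @export
simulate_strike <- function(rig = default_rig(),
                            config = default_strike_config()) {
  stopifnot(inherits(rig, "rig_definition"),
            inherits(config, "strike_profile_config"))
  n <- floor(config$duration_ms / 1000 * config$fps) + 1
  t_ms <- (seq_len(n) - 1) / config$fps * 1000
  poses <- true_poses(rig, config, t_ms)
  ch <- eval_channels(rig, config, t_ms)
  # bone markers
  mk_names <- rig$markers$name
  world <- array(NA_real_, c(n, length(mk_names), 3))
  for (j in seq_along(mk_names)) {
    body <- rig$markers$body[j]
    local <- as.numeric(rig$markers[j, c("x", "y", "z")])
    world[, j, ] <- virtual_point(poses[[body]], local)
  }
  # soft points
  soft <- soft_point_trajectories(rig, config, poses, ch, t_ms)
  soft_names <- names(soft)
  all_names <- c(mk_names, soft_names)
  all_world <- array(NA_real_, c(n, length(all_names), 3))
  all_world[, seq_along(mk_names), ] <- world
  for (j in seq_along(soft_names))
    all_world[, length(mk_names) + j, ] <- soft[[soft_names[j]]]
  noisy <- with_seed(config$seed, {
    all_world + array(stats::rnorm(length(all_world), 0, config$noise_sigma),
                      dim(all_world))
  })
  markers <- marker_set(noisy, all_names, config$fps)
  channels <- data.frame(frame = seq_len(n), time_ms = t_ms)
  for (nm in names(ch)) {
    channels[[paste0(nm, ".hinge")]] <- ch[[nm]]$hinge
    channels[[paste0(nm, ".long_axis")]] <- ch[[nm]]$long_axis
  }
  truth <- structure(list(poses = poses, channels = channels,
                          soft = soft, t_ms = t_ms, config = config),
                     class = "strike_ground_truth")
  list(markers = markers, truth = truth)
}

# tongue, prey and muscle bead trajectories (noiseless)
#' @keywords internal
soft_point_trajectories <- function(rig, config, poses, ch, t_ms) {
  n <- length(t_ms)
  lm <- rig$landmarks
  lmrow <- function(nm) lm[lm$name == nm, ]
  lpt <- function(nm) {
    r <- lmrow(nm)
    virtual_point(poses[[r$body]], as.numeric(r[, c("x", "y", "z")]))
  }
  traj <- list()
  # tongue: right/left points just medial of the ceratohyal tips, rostral
  # point ahead of their midpoint; triangle scaled about its centroid by the
  # stretch factor times the (normalized) ceratohyal depression
  tipR <- lpt("cer_tip_R"); tipL <- lpt("cer_tip_L")
  mid <- (tipR + tipL) / 2
  tr <- tipR + matrix(rep(c(0, 0.15, -0.25), each = n), n)
  tl <- tipL + matrix(rep(c(0, 0.15, 0.25), each = n), n)
  tc <- mid + matrix(rep(c(0.7, 0.1, 0), each = n), n)
  dep <- if (!is.null(ch$ceratohyal_R)) ch$ceratohyal_R$hinge else numeric(n)
  amp <- max(abs(dep), 1e-12)
  scale <- 1 + config$tongue_stretch * abs(dep) / amp
  cen <- (tr + tl + tc) / 3
  traj$tongue_right <- cen + (tr - cen) * scale
  traj$tongue_left <- cen + (tl - cen) * scale
  traj$tongue_rostral <- cen + (tc - cen) * scale
  # prey: starts ahead of the upper jaw tip, drawn caudally (-x)
  if (!is.null(config$prey)) {
    start <- lpt("upper_jaw_tip")[1, ] + config$prey$start_offset
    d <- prey_displacement(config$prey, t_ms)
    traj$prey <- cbind(start[1] - d, rep(start[2], n), rep(start[3], n))
  } else {
    start <- lpt("upper_jaw_tip")[1, ] + c(2, 0, 0.1)
    traj$prey <- matrix(rep(start, each = n), n)
  }
  # muscle beads sit exactly at the virtual origin/insertion landmarks
  for (nm in c("rc_origin", "rc_insertion", "cch_origin", "cch_insertion"))
    traj[[nm]] <- lpt(nm)
  traj
}

#' Simulate a motion-free ("frozen specimen") recording
#'
#' Static true poses (the reference pose) with isotropic Gaussian marker
#' noise only: the protocol used to quantify JCS precision by waving a frozen
#' specimen through the X-ray volume. About 160 frames mirrors the original
#' protocol.
#'
#' @param rig a [rig_definition].
#' @param n_frames number of frames (>= 2; default 160).
#' @param noise_sigma marker noise s.d. (cm).
#' @param seed integer seed.
#' @param fps frame rate (default 500).
#' @return A [marker_set] of the rig's bone markers.
#' @export
simulate_frozen <- function(rig = default_rig(), n_frames = 160,
                            noise_sigma = 0.029, seed = 1, fps = 500) {
  stopifnot(n_frames >= 2, noise_sigma >= 0)
  local <- as.matrix(rig$markers[, c("x", "y", "z")])
  m <- nrow(local)
  coords <- array(rep(local, each = n_frames), c(n_frames, m, 3))
  coords <- with_seed(seed, {
    coords + array(stats::rnorm(length(coords), 0, noise_sigma), dim(coords))
  })
  marker_set(coords, rig$markers$name, fps)
}

# evaluate an expression with a temporary RNG seed, restoring global state
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
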