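#' Joint coordinate systems
#'
#' A JCS pairs an anatomical coordinate system (ACS) fixed in a proximal bone
#' with one fixed in a distal bone. Per frame, the relative transform
#' `(proximal_pose %*% acs_proximal)^-1 %*% (distal_pose %*% acs_distal)` is
#' decomposed into Euler rotations in fixed zyx order (intrinsic, right-hand
#' rule) and translations along the proximal ACS axes. The rotation order is
#' immutable; axis sign semantics are free text carried into outputs (e.g.
#' "rz < 0 = jaw depression").
#'
#' @param name JCS name.
#' @param proximal_body,distal_body body names (must match the pose series).
#' @param acs_proximal,acs_distal 4x4 rigid transforms placing each ACS in its
#'   bone-local frame.
#' @param semantics optional named character vector documenting sign
#'   conventions per channel.
#' @return An object of class `joint_coordinate_system`.
#' @export
joint_coordinate_system <- function(name, proximal_body, distal_body,
                                    acs_proximal = diag(4),
                                    acs_distal = diag(4),
                                    semantics = character()) {
  for (A in list(acs_proximal, acs_distal))
    if (!is_rotation_matrix(A[1:3, 1:3]))
      stop("ACS pose is not a rigid transform", call. = FALSE)
  structure(list(name = name, proximal_body = proximal_body,
                 distal_body = distal_body, acs_proximal = acs_proximal,
                 acs_distal = acs_distal, rotation_order = "zyx",
                 semantics = semantics),
            class = "joint_coordinate_system")
}

#' Decompose a rotation matrix in intrinsic zyx order
#'
#' Returns angles `(rz, ry, rx)` in radians such that
#' `R = rot_z(rz) %*% rot_y(ry) %*% rot_x(rx)` (right-hand rule). Near gimbal
#' lock (`|cos(ry)|` below `gimbal_tol`) the convention is documented and
#' fixed: `rx` is set to 0 and `rz` absorbs the remaining rotation; the
#' returned attribute `gimbal` flags the event.
#'
#' @param R 3x3 rotation matrix.
#' @param gimbal_tol threshold on `|cos(ry)|`.
#' @return numeric length-3 vector `c(rz, ry, rx)` (radians) with attribute
#'   `gimbal` (logical).
#' @export
euler_zyx <- function(R, gimbal_tol = 1e-6) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) < gimbal_tol) {
    # ry = +/- 90 deg: only rz -/+ rx observable; park rx at 0
    rz <- atan2(-R[1, 2], R[2, 2])
    out <- c(rz, ry, 0)
    attr(out, "gimbal") <- TRUE
    return(out)
  }
  rz <- atan2(R[2, 1], R[1, 1])
  rx <- atan2(R[3, 2], R[3, 3])
  out <- c(rz, ry, rx)
  attr(out, "gimbal") <- FALSE
  out
}

#' Six-DOF JCS kinematics of a bone pair
#'
#' @param jcs a [joint_coordinate_system].
#' @param proximal,distal [pose_series] for the two bodies (same frame count
#'   and fps). Frames invalid in either series are invalid in the output.
#' @return An object of class `euler_kinematics`: data frame with columns
#'   `frame`, `time_ms`, `rz`, `ry`, `rx` (degrees), `tx`, `ty`, `tz` (cm),
#'   `valid`, `gimbal`, plus attributes `jcs_name`, `semantics`,
#'   `zero_frame` (NA until [zero_offset] is applied), `fps`.
#' @export
jcs_angles <- function(jcs, proximal, distal) {
  stopifnot(inherits(jcs, "joint_coordinate_system"),
            inherits(proximal, "pose_series"), inherits(distal, "pose_series"))
  if (n_frames(proximal) != n_frames(distal))
    stop("pose series frame counts differ", call. = FALSE)
  if (proximal$fps != distal$fps) stop("pose series fps differ", call. = FALSE)
  n <- n_frames(proximal)
  out <- data.frame(frame = seq_len(n),
                    time_ms = frame_times_ms(n, proximal$fps),
                    rz = NA_real_, ry = NA_real_, rx = NA_real_,
                    tx = NA_real_, ty = NA_real_, tz = NA_real_,
                    valid = FALSE, gimbal = FALSE)
  inv_acs_p <- invert_transform(jcs$acs_proximal)
  for (f in seq_len(n)) {
    if (!proximal$valid[f] || !distal$valid[f]) next
    G <- inv_acs_p %*% invert_transform(proximal$transforms[[f]]) %*%
      distal$transforms[[f]] %*% jcs$acs_distal
    ang <- euler_zyx(G[1:3, 1:3])
    out[f, c("rz", "ry", "rx")] <- rad2deg(ang)
    out[f, c("tx", "ty", "tz")] <- G[1:3, 4]
    out$valid[f] <- TRUE
    out$gimbal[f] <- attr(ang, "gimbal")
  }
  structure(out, class = c("euler_kinematics", "data.frame"),
            jcs_name = jcs$name, semantics = jcs$semantics,
            zero_frame = NA_integer_, fps = proximal$fps)
}

#' Zero kinematic channels at a reference frame
#'
#' Shifts all six channels by their value at `reference_frame` so the
#' reference frame reads 0 -- the convention of reporting rotations relative
#' to the start of each strike. Idempotent for a fixed reference frame.
#'
#' @param k an `euler_kinematics` object (or any data frame with the six
#'   channel columns and a `valid` column).
#' @param reference_frame frame index; must be a valid frame.
#' @return the shifted object, with attribute `zero_frame` set.
#' @export
zero_offset <- function(k, reference_frame = 1L) {
  ch <- c("rz", "ry", "rx", "tx", "ty", "tz")
  if (reference_frame < 1 || reference_frame > nrow(k) ||
      !isTRUE(k$valid[reference_frame]))
    stop("reference frame ", reference_frame, " is not a valid frame",
         call. = FALSE)
  for (c_ in ch) k[[c_]] <- k[[c_]] - k[[c_]][reference_frame]
  attr(k, "zero_frame") <- as.integer(reference_frame)
  k
}

#' Muscle strain from origin and insertion trajectories
#'
#' Strain is the percent length change relative to the initial length `L_i`
#' measured at the reference frame (by convention the first frame of lower jaw
#' depression): `strain(t) = 100 * (L(t) - L_i) / L_i`. Negative strain is
#' shortening.
#'
#' @param origin_traj,insertion_traj `frames x 3` world trajectories (cm) of
#'   the muscle's origin and insertion landmarks.
#' @param reference_frame frame at which `L_i` is measured.
#' @param name muscle name carried into the output.
#' @return data frame (`strain_series`) with `frame`, `length_cm`, `strain_pct`
#'   and attributes `L_i`, `muscle`, `reference_frame`.
#' @export
muscle_strain <- function(origin_traj, insertion_traj, reference_frame = 1L,
                          name = "muscle") {
  origin_traj <- rbind3(origin_traj); insertion_traj <- rbind3(insertion_traj)
  stopifnot(nrow(origin_traj) == nrow(insertion_traj))
  L <- sqrt(rowSums((origin_traj - insertion_traj)^2))
  if (is.na(L[reference_frame]))
    stop("trajectories invalid at reference frame", call. = FALSE)
  L_i <- L[reference_frame]
  if (L_i <= 0) stop("degenerate muscle: L_i = 0", call. = FALSE)
  structure(data.frame(frame = seq_along(L), length_cm = L,
                       strain_pct = 100 * (L - L_i) / L_i),
            class = c("strain_series", "data.frame"),
            L_i = L_i, muscle = name,
            reference_frame = as.integer(reference_frame))
}

#' Pairwise distances among the three tongue markers
#'
#' @param right,left,rostral `frames x 3` world trajectories (cm).
#' @return data frame with per-frame `right_left`, `right_rostral`,
#'   `left_rostral` distances (cm).
#' @export
tongue_distances <- function(right, left, rostral) {
  right <- rbind3(right); left <- rbind3(left); rostral <- rbind3(rostral)
  stopifnot(nrow(right) == nrow(left), nrow(left) == nrow(rostral))
  d <- function(a, b) sqrt(rowSums((a - b)^2))
  data.frame(frame = seq_len(nrow(right)),
             right_left = d(right, left),
             right_rostral = d(right, rostral),
             left_rostral = d(left, rostral))
}

#' Prey displacement, velocity and acceleration
#'
#' Displacement is the scalar distance of the prey from its initial position
#' (`|p(t) - p(1)|`). Velocity and acceleration are the magnitudes of the
#' first and second time derivatives of the *position* vector (not of the
#' scalar distance), computed by second-order central differences with
#' one-sided second-order stencils at the ends.
#'
#' @param prey_traj `frames x 3` prey marker trajectory (cm), filtered
#'   upstream.
#' @param fps frame rate (frames per second).
#' @return data frame (`prey_kinematics`) with `frame`, `time_ms`,
#'   `displacement_cm`, `velocity_cm_s`, `acceleration_cm_s2`.
#' @export
prey_kinematics <- function(prey_traj, fps) {
  prey_traj <- rbind3(prey_traj)
  n <- nrow(prey_traj)
  if (n < 3) stop("need >= 3 frames", call. = FALSE)
  dt <- 1 / fps
  v <- apply(prey_traj, 2, diff_central, dt = dt)
  a <- apply(prey_traj, 2, diff2_central, dt = dt)
  disp <- sqrt(rowSums(sweep(prey_traj, 2, prey_traj[1, ])^2))
  structure(data.frame(frame = seq_len(n), time_ms = frame_times_ms(n, fps),
                       displacement_cm = disp,
                       velocity_cm_s = sqrt(rowSums(v^2)),
                       acceleration_cm_s2 = sqrt(rowSums(a^2))),
            class = c("prey_kinematics", "data.frame"))
}

# second-order first derivative: central interior, one-sided 3-point ends
#' @keywords internal
diff_central <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

# second-order second derivative: central interior, one-sided 4-point ends
#' @keywords internal
diff2_central <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  if (n >= 4) {
    d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
    d[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  } else {
    d[1] <- d[2]; d[n] <- d[n - 1]
  }
  d
}
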