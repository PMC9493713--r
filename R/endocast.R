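#' Dynamic endocast definitions
#'
#' An endocast definition attaches locator points to the oral surfaces of the
#' bones bounding the right anterior half of the oral cavity. Per frame the
#' locators are mapped to world space through the bone poses, an alpha shape
#' is computed over the constellation, and its volume doubled (bilateral
#' factor) to estimate the full oral-cavity volume.
#'
#' @param locators data frame with columns `body` and `x`, `y`, `z`
#'   (bone-local cm); >= 4 rows.
#' @param alpha circumradius threshold (cm); the conventional value is 2.
#' @param bilateral_factor multiplier applied to the unilateral volume
#'   (default 2).
#' @return An object of class `endocast_definition`.
#' @export
endocast_definition <- function(locators, alpha = 2, bilateral_factor = 2) {
  stopifnot(all(c("body", "x", "y", "z") %in% names(locators)),
            nrow(locators) >= 4, alpha > 0, bilateral_factor > 0)
  structure(list(locators = locators, alpha = alpha,
                 bilateral_factor = bilateral_factor),
            class = "endocast_definition")
}

#' Default endocast locators for the standard rig
#'
#' 43 locators over the right anterior oral cavity: palate (upper jaw), mouth
#' floor (lower jaw), medial face of the right ceratohyal, anterior face of
#' the right clavicle (posterior wall of the cavity), and the midline wall
#' (neurocranium). Positions carry small fixed irregularities so the cloud is
#' never exactly gridded (Delaunay-friendly) and every freeze unit moves some
#' locators.
#'
#' @param rig the [default_rig()] (locator geometry assumes its dimensions).
#' @param alpha circumradius threshold (cm).
#' @return An [endocast_definition].
#' @export
default_endocast <- function(rig = default_rig(), alpha = 2) {
  loc <- function(body, x, y, z) data.frame(body = body, x = x, y = y, z = z)
  jig <- function(i) 0.033 * sin(7.7 * i + 1.3)       # fixed irregularity
  out <- NULL
  i <- 0
  for (x in c(0.8, 1.6, 2.4, 3.2, 4.0)) for (z in c(0.12, 0.55, 1.0)) {
    i <- i + 1
    out <- rbind(out, loc("upper_jaw", x + jig(i), 0.15 + jig(i + 40) / 2,
                          z + jig(i + 17)))
  }
  for (x in c(0.8, 1.8, 2.8, 3.8)) for (z in c(0.1, 0.5, 0.95)) {
    i <- i + 1
    out <- rbind(out, loc("lower_jaw", x + jig(i), -0.55 + jig(i + 40) / 2,
                          z + jig(i + 17)))
  }
  ch <- rig$bodies$ceratohyal_R
  J <- joint_frame(ch)
  for (a in c(0.4, 0.9, 1.5, 2.1, 2.6, 3.0)) {
    i <- i + 1
    p <- ch$hinge_point + a * J[, 1] + (0.28 + jig(i)) * J[, 2] -
      (0.22 + jig(i + 11)) * J[, 3]
    out <- rbind(out, loc("ceratohyal_R", p[1], p[2], p[3]))
  }
  for (y in c(-1.0, -1.6)) for (z in c(0.3, 0.8)) {
    i <- i + 1
    out <- rbind(out, loc("clavicle_R", -1.2 + jig(i), y + jig(i + 23),
                          z + jig(i + 5)))
  }
  for (x in c(0.6, 1.6, 2.6)) for (y in c(-0.3, -1.0)) {
    i <- i + 1
    out <- rbind(out, loc("neurocranium", x + jig(i), y + jig(i + 29), 0.02))
  }
  endocast_definition(out, alpha = alpha)
}

# locator world positions at one frame given a named pose list
#' @keywords internal
locator_world <- function(def, poses, frame) {
  n <- nrow(def$locators)
  out <- matrix(NA_real_, n, 3)
  for (b in unique(def$locators$body)) {
    ps <- poses[[b]]
    if (is.null(ps)) stop("no pose series for body '", b, "'", call. = FALSE)
    if (!ps$valid[frame]) return(NULL)
    rows <- which(def$locators$body == b)
    out[rows, ] <- apply_transform(
      ps$transforms[[frame]],
      as.matrix(def$locators[rows, c("x", "y", "z")]))
  }
  out
}

#' Per-frame endocast volumes
#'
#' Maps the locators through the bone poses frame by frame and computes the
#' alpha-shape volume times the bilateral factor. Frames where any involved
#' body has an invalid pose are flagged invalid.
#'
#' @param def an [endocast_definition].
#' @param poses named list of [pose_series] covering every locator body.
#' @return An object of class `volume_series`: data frame with `frame`,
#'   `time_ms`, `volume_cm3`, `dv_cm3` (change from the first valid frame),
#'   `valid`.
#' @export
endocast_volumes <- function(def, poses) {
  stopifnot(inherits(def, "endocast_definition"))
  n <- n_frames(poses[[def$locators$body[1]]])
  fps <- poses[[def$locators$body[1]]]$fps
  vol <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    pts <- locator_world(def, poses, f)
    if (is.null(pts)) next
    vol[f] <- def$bilateral_factor * alpha_shape_volume(pts, def$alpha)
  }
  valid <- !is.na(vol)
  if (!any(valid)) stop("no frame with all poses valid", call. = FALSE)
  ref <- vol[which(valid)[1]]
  structure(data.frame(frame = seq_len(n), time_ms = frame_times_ms(n, fps),
                       volume_cm3 = vol, dv_cm3 = vol - ref, valid = valid),
            class = c("volume_series", "data.frame"), fps = fps)
}

#' Export per-frame endocast boundary meshes as OBJ
#'
#' @param def an [endocast_definition].
#' @param poses named list of [pose_series].
#' @param frames frame indices to export.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
export_endocast_meshes <- function(def, poses, frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (f in frames) {
    pts <- locator_world(def, poses, f)
    if (is.null(pts)) next
    mesh <- alpha_shape_mesh(pts, def$alpha)
    p <- file.path(dir, sprintf("endocast_%05d.obj", f))
    write_obj(mesh, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
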