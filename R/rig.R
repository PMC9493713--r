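#' Articulated-rig definitions for the synthetic strike generator
#'
#' A `rig_definition` describes an articulated skull as a tree of rigid
#' bodies. Each body has a parent (another body or `"world"`), a hinge point
#' and unit hinge axis (in the shared reference/CT frame, which doubles as
#' every body's local frame: all reference poses are the identity), and
#' optionally a unit long axis for bones that also rotate about their own
#' length (the ceratohyal). Markers are bone-fixed points; landmarks are
#' unmarked bone-fixed points used for gape, muscle attachments and endocast
#' locators; soft points (tongue, prey, muscle beads) are generated by
#' attachment rules at simulation time.
#'
#' World frame: right-handed, +x rostral, +y dorsal, +z toward the animal's
#' right; centimetres and milliseconds throughout.
#'
#' @param bodies named list; each element a list with `parent`, `hinge_point`
#'   (3-vector, cm), `hinge_axis` (unit 3-vector), optional `long_axis`
#'   (unit 3-vector, not parallel to the hinge axis) and optional
#'   `channel_sign` (+1/-1, used to mirror bilateral bodies).
#' @param markers data frame with columns `name`, `body`, and `x`, `y`, `z`
#'   local coordinates (cm). Bodies with >= 3 markers must have them
#'   non-collinear.
#' @param landmarks like `markers`; bone-fixed but not implanted (no beads).
#' @return An object of class `rig_definition`.
#' @seealso [default_rig()] for the standard suction-feeding roster.
#' @export
rig_definition <- function(bodies, markers, landmarks = NULL) {
  stopifnot(is.list(bodies), length(names(bodies)) == length(bodies))
  if (anyDuplicated(names(bodies))) stop("duplicate body names", call. = FALSE)
  for (nm in names(bodies)) {
    b <- bodies[[nm]]
    if (!identical(b$parent, "world") && !b$parent %in% names(bodies))
      stop("body '", nm, "': unknown parent '", b$parent, "'", call. = FALSE)
    if (abs(sqrt(sum(b$hinge_axis^2)) - 1) > 1e-9)
      stop("body '", nm, "': hinge axis must be unit length", call. = FALSE)
    if (!is.null(b$long_axis)) {
      if (abs(sqrt(sum(b$long_axis^2)) - 1) > 1e-9)
        stop("body '", nm, "': long axis must be unit length", call. = FALSE)
      if (abs(sum(b$long_axis * b$hinge_axis)) > 0.999)
        stop("body '", nm, "': long axis parallel to hinge axis", call. = FALSE)
    }
    if (is.null(b$channel_sign)) bodies[[nm]]$channel_sign <- 1
  }
  stopifnot(all(c("name", "body", "x", "y", "z") %in% names(markers)))
  if (anyDuplicated(markers$name)) stop("duplicate marker names", call. = FALSE)
  for (nm in unique(markers$body)) {
    loc <- as.matrix(markers[markers$body == nm, c("x", "y", "z")])
    if (nrow(loc) >= 3 && points_collinear(loc))
      stop("markers of body '", nm, "' are collinear", call. = FALSE)
  }
  structure(list(bodies = bodies, markers = markers, landmarks = landmarks),
            class = "rig_definition")
}

#' @export
print.rig_definition <- function(x, ...) {
  cat("<rig_definition> ", length(x$bodies), " bodies, ",
      nrow(x$markers), " markers\n", sep = "")
  for (nm in names(x$bodies))
    cat("  ", nm, " (parent ", x$bodies[[nm]]$parent, ", ",
        sum(x$markers$body == nm), " markers)\n", sep = "")
  invisible(x)
}

# joint frame of a body: columns are the ACS axes (x = long axis projected
# orthogonal to the hinge axis, z = hinge axis, y = z cross x)
#' @keywords internal
joint_frame <- function(body) {
  z <- unitize(body$hinge_axis, "hinge axis")
  x0 <- if (!is.null(body$long_axis)) body$long_axis else {
    ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ref
  }
  x <- unitize(x0 - sum(x0 * z) * z, "long axis projection")
  y <- cross3(z, x)
  cbind(x, y, z)
}

#' The standard suction-feeding rig
#'
#' An articulated lungfish-like skull: neurocranium elevating on a body-plane
#' pseudo-rigid body, upper jaw fused to the neurocranium, lower jaw on a
#' mediolateral hinge at the jaw joint, bilateral curved ceratohyals with
#' independent depression and long-axis rotation channels (left side
#' mirrored), bilateral clavicles, and a left cranial rib on an oblique
#' "bucket-handle" axis. Marker roster per bone: 5 neurocranium, 3 upper jaw,
#' 3 lower jaw, 3 per ceratohyal, 3 per clavicle, 3 cranial rib, 6 body plane
#' (4 ventral + 2 dorsal). Landmarks carry the jaw-tip gape points, the
#' ceratohyal tips (tongue attachment region) and muscle origins/insertions
#' (rectus cervicis: clavicle to ceratohyal; costoclavicular hypaxials:
#' cranial rib to clavicle).
#'
#' All coordinates are the CT/reference pose in cm; origin near the jaw
#' joint, +x rostral, +y dorsal, +z right. Skull length about 8 cm, sized to
#' a ~50 cm animal.
#'
#' @return A [rig_definition].
#' @export
default_rig <- function() {
  # right-ceratohyal anatomical axes (shared by locators and mirror side)
  ch_p0 <- c(-0.6, -0.9, 0.8)
  ch_x <- unitize(c(2.9, -0.6, -0.5))
  ch_z0 <- c(-0.5, 0, sqrt(3) / 2)               # frontal plane, ~30 deg off sagittal
  ch_z <- unitize(ch_z0 - sum(ch_z0 * ch_x) * ch_x)
  ch_y <- cross3(ch_z, ch_x)
  if (ch_y[2] < 0) { ch_z <- -ch_z; ch_y <- -ch_y }  # negative rz = depression
  mirror <- function(v) v * c(1, 1, -1)
  cl_p0 <- c(-1.9, -1.4, 0.9)
  cl_x <- unitize(c(0.5, 0.85, -0.2))
  rib_p0 <- c(-2.6, 0.2, -0.5)
  rib_z <- unitize(c(0.25, 0.9, -0.35))
  rib_x <- unitize(c(-0.6, -0.75, -0.2))
  bodies <- list(
    body_plane = list(parent = "world", hinge_point = c(-2, 0, 0),
                      hinge_axis = c(0, 0, 1)),
    neurocranium = list(parent = "body_plane", hinge_point = c(-2.2, 0.4, 0),
                        hinge_axis = c(0, 0, 1)),
    upper_jaw = list(parent = "neurocranium", hinge_point = c(0, 0, 0),
                     hinge_axis = c(0, 0, 1)),
    lower_jaw = list(parent = "neurocranium", hinge_point = c(0, -0.15, 0),
                     hinge_axis = c(0, 0, 1), long_axis = c(1, 0, 0)),
    ceratohyal_R = list(parent = "neurocranium", hinge_point = ch_p0,
                        hinge_axis = ch_z, long_axis = ch_x),
    ceratohyal_L = list(parent = "neurocranium", hinge_point = mirror(ch_p0),
                        hinge_axis = mirror(ch_z), long_axis = mirror(ch_x),
                        channel_sign = -1),
    clavicle_R = list(parent = "body_plane", hinge_point = cl_p0,
                      hinge_axis = c(0, 0, -1), long_axis = cl_x),
    clavicle_L = list(parent = "body_plane", hinge_point = mirror(cl_p0),
                      hinge_axis = c(0, 0, 1), long_axis = mirror(cl_x),
                      channel_sign = 1),
    cranial_rib_L = list(parent = "body_plane", hinge_point = rib_p0,
                         hinge_axis = rib_z, long_axis = rib_x)
  )
  mk <- function(name, body, p) data.frame(name = name, body = body,
                                           x = p[1], y = p[2], z = p[3])
  ch_pt <- function(a, b, c_) ch_p0 + a * ch_x + b * ch_y + c_ * ch_z
  cl_y <- cross3(c(0, 0, -1), cl_x)
  cl_pt <- function(a, b) cl_p0 + a * cl_x + b * cl_y
  rib_xo <- unitize(rib_x - sum(rib_x * rib_z) * rib_z)
  rib_pt <- function(a, b) rib_p0 + a * rib_xo + b * rib_z
  markers <- rbind(
    mk("neuro_1", "neurocranium", c(1.5, 1.1, 0.6)),
    mk("neuro_2", "neurocranium", c(1.5, 1.1, -0.6)),
    mk("neuro_3", "neurocranium", c(3.2, 1.4, 0.0)),
    mk("neuro_4", "neurocranium", c(-0.4, 1.6, 0.3)),
    mk("neuro_5", "neurocranium", c(2.3, 2.0, -0.2)),
    mk("ujaw_1", "upper_jaw", c(4.7, 0.3, 0.05)),
    mk("ujaw_2", "upper_jaw", c(1.2, 0.45, 1.15)),
    mk("ujaw_3", "upper_jaw", c(1.2, 0.45, -1.15)),
    mk("ljaw_1", "lower_jaw", c(4.5, -0.3, 0.1)),
    mk("ljaw_2", "lower_jaw", c(0.5, -0.45, 1.05)),
    mk("ljaw_3", "lower_jaw", c(0.5, -0.45, -1.0)),
    mk("cerR_1", "ceratohyal_R", ch_pt(0.4, 1.1, 0)),
    mk("cerR_2", "ceratohyal_R", ch_pt(1.7, -0.8, 0.8)),
    mk("cerR_3", "ceratohyal_R", ch_pt(3.0, -0.45, -0.95)),
    mk("cerL_1", "ceratohyal_L", mirror(ch_pt(0.4, 1.1, 0))),
    mk("cerL_2", "ceratohyal_L", mirror(ch_pt(1.7, -0.8, 0.8))),
    mk("cerL_3", "ceratohyal_L", mirror(ch_pt(3.0, -0.45, -0.95))),
    mk("clavR_1", "clavicle_R", cl_pt(0.3, 0.25)),
    mk("clavR_2", "clavicle_R", cl_pt(1.2, -0.30)),
    mk("clavR_3", "clavicle_R", cl_pt(2.0, 0.20)),
    mk("clavL_1", "clavicle_L", mirror(cl_pt(0.3, 0.25))),
    mk("clavL_2", "clavicle_L", mirror(cl_pt(1.2, -0.30))),
    mk("clavL_3", "clavicle_L", mirror(cl_pt(2.0, 0.20))),
    mk("rib_1", "cranial_rib_L", rib_pt(0.2, 0.15)),
    mk("rib_2", "cranial_rib_L", rib_pt(0.9, -0.25)),
    mk("rib_3", "cranial_rib_L", rib_pt(1.5, 0.10)),
    mk("vbody_1", "body_plane", c(3, -2.1, 0.8)),
    mk("vbody_2", "body_plane", c(1, -2.3, -0.8)),
    mk("vbody_3", "body_plane", c(-1, -2.2, 0.8)),
    mk("vbody_4", "body_plane", c(-3, -2.0, -0.8)),
    mk("dbody_1", "body_plane", c(0.5, 2.6, 0.2)),
    mk("dbody_2", "body_plane", c(-2.5, 2.4, -0.3))
  )
  ch_tip <- ch_p0 + 3.1 * ch_x - 0.1 * ch_y
  landmarks <- rbind(
    mk("upper_jaw_tip", "upper_jaw", c(4.3, 0.15, 0)),
    mk("lower_jaw_tip", "lower_jaw", c(4.3, -0.25, 0)),
    mk("cer_tip_R", "ceratohyal_R", ch_tip),
    mk("cer_tip_L", "ceratohyal_L", mirror(ch_tip)),
    mk("rc_origin", "clavicle_R", cl_pt(0.4, 0.1)),
    mk("rc_insertion", "ceratohyal_R", ch_pt(2.4, 0, 0.1)),
    mk("cch_origin", "cranial_rib_L", rib_pt(0.5, 0)),
    mk("cch_insertion", "clavicle_L", mirror(cl_pt(0.5, 0.1)))
  )
  rig_definition(bodies, markers, landmarks)
}

# topologically-sorted body order (parents before children)
#' @keywords internal
body_order <- function(rig) {
  out <- character()
  remaining <- names(rig$bodies)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      p <- rig$bodies[[nm]]$parent
      identical(p, "world") || p %in% out
    }, TRUE)]
    if (!length(ready)) stop("cycle in body parents", call. = FALSE)
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# pose of one body relative to its parent for channel values (radians)
#' @keywords internal
relative_pose <- function(body, hinge_rad = 0, long_rad = 0) {
  J <- joint_frame(body)
  s <- body$channel_sign
  R <- J %*% rot_z(s * hinge_rad) %*% rot_x(s * long_rad) %*% t(J)
  make_transform(R, body$hinge_point - R %*% body$hinge_point)
}

#' Default joint coordinate systems for a rig
#'
#' Builds one JCS per mobile body, placed at the body's hinge with the ACS
#' z-axis along the hinge (depression/retraction) axis and x along the long
#' axis -- the placements used for jaw depression (lower jaw vs upper jaw),
#' ceratohyal depression and long-axis rotation (vs neurocranium), cranial
#' elevation (neurocranium vs body plane), clavicle retraction and cranial
#' rib retraction. Proximal and distal ACS coincide at the reference pose, so
#' all channels are 0 at rest.
#'
#' @param rig a [rig_definition].
#' @return named list of [joint_coordinate_system] objects.
#' @export
default_jcs_set <- function(rig) {
  prox <- c(lower_jaw = "upper_jaw", ceratohyal_R = "neurocranium",
            ceratohyal_L = "neurocranium", neurocranium = "body_plane",
            clavicle_R = "body_plane", clavicle_L = "body_plane",
            cranial_rib_L = "body_plane")
  sem <- c(lower_jaw = "rz<0 = jaw depression",
           ceratohyal_R = "rz<0 = depression; rx<0 = internal long-axis rotation",
           ceratohyal_L = "mirrored side; signs follow the right convention",
           neurocranium = "rz>0 = cranial elevation (vs body plane)",
           clavicle_R = "rz<0 = retraction",
           clavicle_L = "rz<0 = retraction",
           cranial_rib_L = "rz<0 = retraction (bucket-handle)")
  out <- list()
  for (nm in intersect(names(prox), names(rig$bodies))) {
    body <- rig$bodies[[nm]]
    acs <- make_transform(joint_frame(body), body$hinge_point)
    out[[nm]] <- joint_coordinate_system(
      name = nm, proximal_body = prox[[nm]], distal_body = nm,
      acs_proximal = acs, acs_distal = acs,
      semantics = sem[[nm]])
  }
  out
}

#' Rigid-body definitions for every marked body of a rig
#'
#' @param rig a [rig_definition].
#' @param min_markers bodies with fewer markers are skipped.
#' @return named list of [rigid_body_def].
#' @export
rig_body_defs <- function(rig, min_markers = 3) {
  out <- list()
  for (nm in names(rig$bodies)) {
    rows <- rig$markers[rig$markers$body == nm, ]
    if (nrow(rows) < min_markers) next
    out[[nm]] <- rigid_body_def(nm, rows$name,
                                as.matrix(rows[, c("x", "y", "z")]))
  }
  out
}
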