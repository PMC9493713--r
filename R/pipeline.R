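#' Low-pass filter every marker trajectory of a set
#'
#' Applies the zero-phase Butterworth filter to each coordinate of each
#' marker. Markers with missing frames are left unfiltered with a warning
#' (gap-filling is out of scope; filter valid segments upstream if needed).
#'
#' @param set a [marker_set].
#' @param cutoff_hz cutoff (Hz), conventionally 35.
#' @param order filter order per pass (default 4).
#' @return a filtered [marker_set].
#' @export
filter_marker_set <- function(set, cutoff_hz = 35, order = 4) {
  stopifnot(inherits(set, "marker_set"))
  coords <- set$coords
  for (j in seq_along(set$markers)) {
    tr <- matrix(coords[, j, ], ncol = 3)
    if (anyNA(tr)) {
      warning("marker '", set$markers[j], "' has missing frames; not filtered")
      next
    }
    coords[, j, ] <- lowpass_filter(tr, cutoff_hz, set$fps, order)
  }
  marker_set(coords, set$markers, set$fps)
}

#' Fit pose series for every marked body of a rig
#'
#' Optionally low-pass filters the marker trajectories first (the default
#' workflow: filter marker coordinates at 35 Hz, then fit rigid bodies), then
#' runs [animate_body] per body. Optionally refines given markers with the
#' sliding-polynomial smoother before filtering (the treatment applied to
#' noisy ceratohyal markers).
#'
#' @param rig a [rig_definition].
#' @param set a [marker_set] containing the rig's markers.
#' @param filter_hz low-pass cutoff in Hz, or `NULL` to skip filtering.
#' @param refine_markers character vector of marker names to pass through
#'   [smooth_trajectory_poly] first (default none).
#' @param refine_window,refine_order smoothing parameters.
#' @return named list of [pose_series].
#' @export
animate_rig <- function(rig, set, filter_hz = 35, refine_markers = character(),
                        refine_window = 11, refine_order = 2) {
  stopifnot(inherits(rig, "rig_definition"), inherits(set, "marker_set"))
  if (length(refine_markers)) {
    coords <- set$coords
    for (nm in intersect(refine_markers, set$markers)) {
      j <- match(nm, set$markers)
      coords[, j, ] <- smooth_trajectory_poly(matrix(coords[, j, ], ncol = 3),
                                              refine_window, refine_order)
    }
    set <- marker_set(coords, set$markers, set$fps)
  }
  if (!is.null(filter_hz)) set <- filter_marker_set(set, filter_hz)
  lapply(rig_body_defs(rig), animate_body, set = set)
}

#' Zeroed JCS kinematics for every default joint of a rig
#'
#' Runs [jcs_angles] for each JCS of [default_jcs_set] and zeroes all
#' channels at `zero_frame`.
#'
#' @param rig a [rig_definition].
#' @param poses named list of [pose_series] (from [animate_rig]).
#' @param zero_frame reference frame for [zero_offset] (default 1, the start
#'   of the trial/strike).
#' @return named list of `euler_kinematics` data frames.
#' @export
strike_kinematics <- function(rig, poses, zero_frame = 1L) {
  jcs <- default_jcs_set(rig)
  out <- list()
  for (nm in names(jcs)) {
    j <- jcs[[nm]]
    if (is.null(poses[[j$proximal_body]]) || is.null(poses[[j$distal_body]]))
      next
    out[[nm]] <- zero_offset(jcs_angles(j, poses[[j$proximal_body]],
                                        poses[[j$distal_body]]), zero_frame)
  }
  out
}

#' Write kinematics / volume / strain series as CSV
#' @param x a data frame (e.g. `euler_kinematics`, `volume_series`).
#' @param path output path.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
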