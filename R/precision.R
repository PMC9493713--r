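#' Marker-tracking precision from intra-body distances
#'
#' Rigid-body markers keep constant pairwise distances, so the standard
#' deviation over frames of each unfiltered intra-body marker-to-marker
#' distance measures tracking precision. For isotropic per-coordinate noise
#' of s.d. sigma and marker separations well above sigma, each distance s.d.
#' approaches `sigma * sqrt(2)`.
#'
#' @param set an unfiltered [marker_set].
#' @param bodies named list mapping body name to its marker names (e.g. from
#'   [rig_body_defs] definitions or a rig's marker table). Bodies with < 2
#'   markers are skipped with a warning.
#' @return An object of class `precision_report`: list with `pairs` (data
#'   frame: body, marker_a, marker_b, sd_cm, mean_cm), `per_body` (mean of
#'   its pair s.d.s), `mean_cm` (grand mean of per-body means), `max_cm`.
#' @export
marker_precision <- function(set, bodies) {
  stopifnot(inherits(set, "marker_set"))
  pairs <- NULL
  for (nm in names(bodies)) {
    mks <- bodies[[nm]]
    if (length(mks) < 2) {
      warning("body '", nm, "' has < 2 markers; skipped")
      next
    }
    for (i in seq_len(length(mks) - 1)) for (j in (i + 1):length(mks)) {
      a <- marker_trajectory(set, mks[i])
      b <- marker_trajectory(set, mks[j])
      d <- sqrt(rowSums((a - b)^2))
      d <- d[!is.na(d)]
      pairs <- rbind(pairs, data.frame(
        body = nm, marker_a = mks[i], marker_b = mks[j],
        sd_cm = stats::sd(d), mean_cm = mean(d)))
    }
  }
  if (is.null(pairs)) stop("no usable bodies", call. = FALSE)
  per_body <- tapply(pairs$sd_cm, pairs$body, mean)
  structure(list(pairs = pairs, per_body = per_body,
                 mean_cm = mean(per_body), max_cm = max(pairs$sd_cm)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report> mean of per-body pairwise-distance s.d.: ",
      signif(x$mean_cm, 3), " cm (max ", signif(x$max_cm, 3), " cm)\n", sep = "")
  for (nm in names(x$per_body))
    cat("  ", nm, ": ", signif(x$per_body[[nm]], 3), " cm\n", sep = "")
  invisible(x)
}

#' Write a precision report as CSV
#' @param report a `precision_report`.
#' @param path output path.
#' @export
write_precision_csv <- function(report, path) {
  utils::write.csv(report$pairs, path, row.names = FALSE)
  invisible(path)
}

#' JCS precision from a motion-free recording
#'
#' For poses fitted to a recording of a specimen with no joint motion (e.g. a
#' frozen specimen moved through the X-ray volume, or [simulate_frozen]
#' output), the standard deviation of each JCS degree of freedom over frames
#' is the precision threshold of that channel: a frozen joint should read
#' constant, so all spread is measurement noise.
#'
#' @param jcs a [joint_coordinate_system].
#' @param proximal,distal [pose_series] fitted to the motion-free recording.
#' @return named numeric vector: s.d. of `rz`, `ry`, `rx` (deg) and `tx`,
#'   `ty`, `tz` (cm).
#' @export
jcs_precision <- function(jcs, proximal, distal) {
  k <- jcs_angles(jcs, proximal, distal)
  ok <- k$valid
  vapply(c("rz", "ry", "rx", "tx", "ty", "tz"),
         function(c_) stats::sd(k[[c_]][ok]), numeric(1))
}
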