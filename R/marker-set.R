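#' Marker trajectory sets
#'
#' A `marker_set` holds frame-indexed 3D coordinates for a roster of named
#' markers: an array of dimension `frames x markers x 3` (cm), a frame rate
#' (frames per second), and the marker names. Missing observations (untracked
#' marker at a frame) are `NA` for all three coordinates of that marker/frame.
#'
#' @param coords numeric array `frames x markers x 3`, or a single `markers x 3`
#'   matrix (interpreted as one frame).
#' @param markers character vector of marker names (unique).
#' @param fps frame rate, frames per second (> 0).
#' @return An object of class `marker_set`.
#' @examples
#' m <- marker_set(array(0, c(2, 1, 3)), "tip", fps = 500)
#' n_frames(m)
#' @export
marker_set <- function(coords, markers, fps) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (length(markers) != dim(coords)[2])
    stop("marker name count (", length(markers), ") != coordinate columns (",
         dim(coords)[2], ")", call. = FALSE)
  if (anyDuplicated(markers)) stop("duplicate marker names", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  finite <- is.finite(coords) | is.na(coords)
  if (!all(finite)) stop("non-finite, non-NA coordinates present", call. = FALSE)
  dimnames(coords) <- list(NULL, markers, c("X", "Y", "Z"))
  structure(list(coords = coords, markers = as.character(markers), fps = fps),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", n_frames(x), " frames x ", length(x$markers),
      " markers @ ", x$fps, " fps\n", sep = "")
  cat("  markers:", paste(utils::head(x$markers, 8), collapse = ", "),
      if (length(x$markers) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of frames in a marker set or pose series
#' @param x a `marker_set` or `pose_series`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.marker_set <- function(x) dim(x$coords)[1]

#' Extract one marker's trajectory
#' @param set a `marker_set`.
#' @param marker marker name.
#' @return `frames x 3` matrix.
#' @export
marker_trajectory <- function(set, marker) {
  stopifnot(inherits(set, "marker_set"))
  if (!marker %in% set$markers) stop("unknown marker: ", marker, call. = FALSE)
  tr <- set$coords[, marker, , drop = FALSE]
  matrix(tr, ncol = 3, dimnames = list(NULL, c("X", "Y", "Z")))
}

#' Frame times in milliseconds
#' @param x a `marker_set`, `pose_series`, or frame count with `fps` given.
#' @param fps frames per second (only when `x` is a count).
#' @export
frame_times_ms <- function(x, fps = NULL) {
  if (inherits(x, "marker_set") || inherits(x, "pose_series")) {
    n <- n_frames(x); fps <- x$fps
  } else {
    n <- x
    if (is.null(fps)) stop("fps required", call. = FALSE)
  }
  (seq_len(n) - 1) / fps * 1000
}

#' Read a points CSV (one `name_X,name_Y,name_Z` column triple per marker)
#'
#' The dialect mirrors marker-tracking exports: a header row of column names
#' grouped in `_X`, `_Y`, `_Z` triples, one row per video frame, blank cells or
#' `NaN`/`NA` tokens marking untracked markers. Frame rate is not stored in the
#' file and must be supplied.
#'
#' @param path file path.
#' @param fps frame rate of the recording (frames per second).
#' @return A [marker_set].
#' @export
read_points_csv <- function(path, fps) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  nm <- names(df)
  if (length(nm) %% 3 != 0)
    stop("column count ", length(nm), " is not a multiple of 3", call. = FALSE)
  base <- sub("_[XYZ]$", "", nm)
  suff <- sub("^.*_", "", nm)
  for (i in seq(1, length(nm), by = 3)) {
    ok <- identical(suff[i:(i + 2)], c("X", "Y", "Z")) &&
      length(unique(base[i:(i + 2)])) == 1
    if (!ok)
      stop("columns ", i, "-", i + 2, " (starting at '", nm[i],
           "') do not form a name_X,name_Y,name_Z triple", call. = FALSE)
  }
  markers <- base[seq(1, length(nm), by = 3)]
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric cells in ", path, call. = FALSE)
  n <- nrow(mat)
  coords <- array(NA_real_, c(n, length(markers), 3))
  for (j in seq_along(markers))
    coords[, j, ] <- mat[, (3 * j - 2):(3 * j), drop = FALSE]
  # a marker missing any coordinate at a frame is missing entirely
  miss <- apply(is.na(coords), c(1, 2), any)
  for (k in 1:3) coords[, , k][miss] <- NA_real_
  marker_set(coords, markers, fps)
}

#' @rdname read_points_csv
#' @param set a [marker_set] to write.
#' @param digits significant digits written (default keeps full precision).
#' @export
write_points_csv <- function(set, path, digits = 17) {
  stopifnot(inherits(set, "marker_set"))
  n <- n_frames(set)
  m <- length(set$markers)
  flat <- matrix(NA_real_, n, 3 * m)
  for (j in seq_len(m)) flat[, (3 * j - 2):(3 * j)] <- set$coords[, j, ]
  header <- as.vector(t(outer(set$markers, c("X", "Y", "Z"),
                              function(a, b) paste(a, b, sep = "_"))))
  txt <- apply(flat, 1, function(r)
    paste(ifelse(is.na(r), "NaN", formatC(r, digits = digits, format = "g")),
          collapse = ","))
  writeLines(c(paste(header, collapse = ","), txt), path)
  invisible(path)
}
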