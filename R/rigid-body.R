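#' Rigid body definitions and pose series
#'
#' A `rigid_body_def` names a bone, lists the (>= 3) markers implanted in it,
#' and stores each marker's bone-local reference coordinates taken from the CT
#' pose. Optional virtual constraint points (e.g. points placed at a joint or
#' symphysis whose world position is supplied per frame from another source)
#' participate in the fit at a configurable weight.
#'
#' @param name body name.
#' @param markers character vector of marker names (length >= 3 together with
#'   any virtual points).
#' @param reference `length(markers) x 3` matrix of bone-local coordinates (cm).
#' @param virtual optional data frame / list with elements `name`, `local`
#'   (n x 3 matrix), `weight` (numeric) for virtual constraint points.
#' @return An object of class `rigid_body_def`.
#' @export
rigid_body_def <- function(name, markers, reference, virtual = NULL) {
  reference <- rbind3(reference)
  stopifnot(length(markers) == nrow(reference))
  nall <- length(markers) + if (is.null(virtual)) 0L else length(virtual$name)
  if (nall < 3) stop("body '", name, "' needs >= 3 points", call. = FALSE)
  allref <- reference
  if (!is.null(virtual)) allref <- rbind(allref, rbind3(virtual$local))
  if (points_collinear(allref))
    stop("reference points of body '", name, "' are collinear", call. = FALSE)
  structure(list(name = name, markers = as.character(markers),
                 reference = reference, virtual = virtual),
            class = "rigid_body_def")
}

#' @keywords internal
points_collinear <- function(pts, tol = 1e-9) {
  pts <- rbind3(pts)
  if (nrow(pts) < 3) return(TRUE)
  c0 <- sweep(pts, 2, colMeans(pts))
  sv <- svd(c0, nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}

#' Per-frame rigid-body poses
#'
#' Container for a body's per-frame 4x4 homogeneous transforms (bone-local to
#' world, column-vector convention), per-frame fit residual RMSD (cm) and a
#' validity flag. Frames with fewer than 3 visible points are invalid and their
#' transform is `NA`.
#'
#' @param name body name.
#' @param transforms list (length frames) of 4x4 matrices (or `NA`).
#' @param residual numeric vector of per-frame RMSD (cm).
#' @param valid logical vector.
#' @param fps frame rate (frames per second).
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(name, transforms, residual, valid, fps) {
  stopifnot(length(transforms) == length(residual),
            length(valid) == length(residual))
  for (i in seq_along(transforms)) {
    if (!valid[i]) next
    T <- transforms[[i]]
    if (!is_rotation_matrix(T[1:3, 1:3]))
      stop("frame ", i, ": rotation block not orthonormal/proper", call. = FALSE)
    if (residual[i] < 0) stop("negative residual at frame ", i, call. = FALSE)
  }
  structure(list(name = name, transforms = transforms, residual = residual,
                 valid = valid, fps = fps), class = "pose_series")
}

#' @export
n_frames.pose_series <- function(x) length(x$transforms)

#' @export
print.pose_series <- function(x, ...) {
  cat("<pose_series> body '", x$name, "', ", n_frames(x), " frames @ ",
      x$fps, " fps, ", sum(!x$valid), " invalid; mean residual ",
      signif(mean(x$residual[x$valid]), 3), " cm\n", sep = "")
  invisible(x)
}

#' Least-squares rigid transform between corresponded point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the weighted
#' sum of squared distances `sum(w_i * |observed_i - (R reference_i + t)|^2)`
#' (Kabsch/Umeyama via SVD). A reflection is never returned: if the best
#' orthogonal map is improper the smallest singular direction is flipped.
#'
#' @param reference n x 3 matrix of bone-local points (cm).
#' @param observed n x 3 matrix of world points (cm), corresponded by row.
#' @param weights optional non-negative weights (default all 1).
#' @return list with `transform` (4x4, local -> world) and `residual`
#'   (weighted RMSD, cm).
#' @examples
#' ref <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' fit <- estimate_rigid_transform(ref, ref)
#' fit$residual  # 0
#' @export
estimate_rigid_transform <- function(reference, observed, weights = NULL) {
  reference <- rbind3(reference); observed <- rbind3(observed)
  stopifnot(nrow(reference) == nrow(observed))
  n <- nrow(reference)
  if (n < 3) stop("need >= 3 corresponded points, got ", n, call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  if (points_collinear(reference[weights > 0, , drop = FALSE]) ||
      points_collinear(observed[weights > 0, , drop = FALSE]))
    stop("degenerate fit: effective points are collinear", call. = FALSE)
  w <- weights / sum(weights)
  cr <- colSums(reference * w); co <- colSums(observed * w)
  A <- sweep(reference, 2, cr); B <- sweep(observed, 2, co)
  H <- t(A * w) %*% B                       # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # proper rotation only
  t <- co - R %*% cr
  T <- make_transform(R, t)
  pred <- apply_transform(T, reference)
  residual <- sqrt(sum(w * rowSums((observed - pred)^2)))
  list(transform = T, residual = residual)
}

#' Fit per-frame rigid-body poses to tracked markers
#'
#' For each frame, fits [estimate_rigid_transform] using the markers of `def`
#' that are visible in that frame (plus any virtual constraint points at their
#' weights). Frames with fewer than 3 visible points are flagged invalid; no
#' interpolation is performed.
#'
#' @param def a [rigid_body_def].
#' @param set a [marker_set] containing (at least) the body's markers.
#' @param virtual_world optional list mapping virtual point name to a
#'   `frames x 3` matrix of world coordinates.
#' @return A [pose_series].
#' @export
animate_body <- function(def, set, virtual_world = NULL) {
  stopifnot(inherits(def, "rigid_body_def"), inherits(set, "marker_set"))
  missing_m <- setdiff(def$markers, set$markers)
  if (length(missing_m))
    stop("markers not in trajectory set: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  n <- n_frames(set)
  idx <- match(def$markers, set$markers)
  obs <- set$coords[, idx, , drop = FALSE]
  ref <- def$reference
  wts <- rep(1, length(def$markers))
  vref <- NULL; vw <- NULL
  if (!is.null(def$virtual)) {
    vref <- rbind3(def$virtual$local)
    vw <- def$virtual$weight
    if (is.null(virtual_world) ||
        !all(def$virtual$name %in% names(virtual_world)))
      stop("virtual_world trajectories required for: ",
           paste(def$virtual$name, collapse = ", "), call. = FALSE)
  }
  transforms <- vector("list", n)
  residual <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (f in seq_len(n)) {
    o <- matrix(obs[f, , ], ncol = 3)
    vis <- !is.na(o[, 1])
    r_f <- ref[vis, , drop = FALSE]
    o_f <- o[vis, , drop = FALSE]
    w_f <- wts[vis]
    if (!is.null(vref)) {
      vo <- t(vapply(def$virtual$name,
                     function(nm) virtual_world[[nm]][f, ], numeric(3)))
      vvis <- !is.na(vo[, 1])
      r_f <- rbind(r_f, vref[vvis, , drop = FALSE])
      o_f <- rbind(o_f, vo[vvis, , drop = FALSE])
      w_f <- c(w_f, vw[vvis])
    }
    if (nrow(r_f) < 3 || points_collinear(r_f)) {
      transforms[[f]] <- NA
      next
    }
    fit <- estimate_rigid_transform(r_f, o_f, w_f)
    transforms[[f]] <- fit$transform
    residual[f] <- fit$residual
    valid[f] <- TRUE
  }
  if (!any(valid))
    stop("body '", def$name, "' never has 3 visible non-collinear points",
         call. = FALSE)
  pose_series(def$name, transforms, residual, valid, set$fps)
}

#' Fit the pseudo-rigid body plane to superficial body markers
#'
#' Convenience wrapper: builds a reference from the markers' positions at the
#' first frame where all are visible, then rigid-fits every frame. The
#' residual column doubles as a deformation indicator for this pseudo-rigid
#' body; no deformation correction is applied.
#'
#' @param set a [marker_set].
#' @param markers names of the body-plane markers (>= 3).
#' @return A [pose_series] named `"body_plane"`.
#' @export
fit_body_plane <- function(set, markers) {
  stopifnot(inherits(set, "marker_set"), length(markers) >= 3)
  idx <- match(markers, set$markers)
  if (anyNA(idx)) stop("unknown body-plane markers", call. = FALSE)
  full <- apply(!is.na(set$coords[, idx, 1, drop = FALSE]), 1, all)
  if (!any(full)) stop("no frame with all body-plane markers visible", call. = FALSE)
  f0 <- which(full)[1]
  ref <- matrix(set$coords[f0, idx, ], ncol = 3)
  def <- rigid_body_def("body_plane", markers, ref)
  animate_body(def, set)
}

#' Map a bone-fixed (virtual) point through a pose series
#'
#' @param pose a [pose_series].
#' @param local length-3 bone-local coordinates (cm).
#' @return `frames x 3` matrix of world coordinates; `NA` rows at invalid frames.
#' @export
virtual_point <- function(pose, local) {
  stopifnot(inherits(pose, "pose_series"), length(local) == 3)
  out <- matrix(NA_real_, n_frames(pose), 3)
  for (f in which(pose$valid))
    out[f, ] <- apply_transform(pose$transforms[[f]], local)
  out
}

#' Write / read per-body transform CSV (animation-package dialect)
#'
#' One body per file: 16 columns per frame holding the 4x4 transform in
#' row-major order under the row-vector convention (`point %*% M`, translation
#' in the 4th row) -- the dialect common to animation-package exports. The
#' internal column-vector matrices are transposed on the way out and back.
#'
#' @param pose a [pose_series].
#' @param path file path.
#' @export
write_transforms_csv <- function(pose, path) {
  stopifnot(inherits(pose, "pose_series"))
  n <- n_frames(pose)
  flat <- matrix(NA_real_, n, 16)
  # row-major of the transposed (row-vector) matrix == column-major of T
  for (f in which(pose$valid)) flat[f, ] <- as.vector(pose$transforms[[f]])
  header <- paste0(pose$name, "_", sprintf("%02d", 1:16))
  txt <- apply(flat, 1, function(r)
    paste(ifelse(is.na(r), "NaN", formatC(r, digits = 17, format = "g")),
          collapse = ","))
  writeLines(c(paste(header, collapse = ","), txt), path)
  invisible(path)
}

#' @rdname write_transforms_csv
#' @param fps frame rate of the recording.
#' @param row_vector if `TRUE` (default) the file follows the row-vector
#'   convention above; set `FALSE` to read column-vector (row-major of `T`)
#'   exports.
#' @export
read_transforms_csv <- function(path, fps, row_vector = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  if (ncol(df) != 16) stop("expected 16 columns, got ", ncol(df), call. = FALSE)
  name <- sub("_[0-9]+$", "", names(df)[1])
  mat <- as.matrix(df)
  n <- nrow(mat)
  transforms <- vector("list", n)
  valid <- rep(FALSE, n)
  residual <- rep(0, n)
  for (f in seq_len(n)) {
    if (anyNA(mat[f, ])) { transforms[[f]] <- NA; next }
    M <- matrix(mat[f, ], 4, 4, byrow = TRUE)  # file is row-major
    T <- if (row_vector) t(M) else M
    transforms[[f]] <- T
    valid[f] <- TRUE
  }
  residual[!valid] <- NA_real_
  pose_series(name, transforms, residual, valid, fps)
}
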