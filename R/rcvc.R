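#' Digitally freeze a bone relative to the neurocranium
#'
#' Within the window `[t0, t0 + window]`, each body of the freeze unit keeps
#' its pose *relative to the neurocranium* fixed at its frame-`t0` value
#' while the neurocranium moves as recorded:
#' `P_frozen(f) = P_neuro(f) %*% P_neuro(t0)^-1 %*% P_unit(t0)`.
#' All other bodies are untouched. This is the elementary operation of the
#' RCVC (relative contribution to volume change) analysis.
#'
#' @param poses named list of [pose_series].
#' @param unit character vector of body names forming the freeze unit (a
#'   single bone or a bilateral pair).
#' @param neurocranium name of the neurocranium body in `poses`.
#' @param t0 window start frame.
#' @param window window length in frames (>= 2 for RCVC; >= 1 here).
#' @return the pose list with the unit's poses replaced inside the window.
#' @export
freeze_bone <- function(poses, unit, neurocranium, t0, window) {
  frames <- t0:(t0 + window)
  neuro <- poses[[neurocranium]]
  if (is.null(neuro)) stop("unknown neurocranium body", call. = FALSE)
  if (max(frames) > n_frames(neuro)) stop("window exceeds trial", call. = FALSE)
  for (b in unit) {
    ps <- poses[[b]]
    if (is.null(ps)) stop("unknown freeze body '", b, "'", call. = FALSE)
    if (!all(ps$valid[frames]) || !all(neuro$valid[frames]))
      stop("invalid frames inside freeze window", call. = FALSE)
    rel0 <- invert_transform(neuro$transforms[[t0]]) %*% ps$transforms[[t0]]
    for (f in frames)
      poses[[b]]$transforms[[f]] <- neuro$transforms[[f]] %*% rel0
  }
  poses
}

#' Freeze-window configuration for RCVC
#'
#' @param window window length N in frames: the conventional increments are
#'   20 frames (40 ms) at 500 fps and 12 frames at 150 fps.
#' @param units named list of freeze units; each a character vector of body
#'   names (bilateral pairs are frozen together). Units must be disjoint.
#' @param neurocranium reference body name.
#' @return An object of class `freeze_window_config`.
#' @export
freeze_window_config <- function(window, units, neurocranium = "neurocranium") {
  stopifnot(window >= 2, length(units) >= 1)
  all_bodies <- unlist(units)
  if (anyDuplicated(all_bodies)) stop("freeze units overlap", call. = FALSE)
  if (neurocranium %in% all_bodies)
    stop("the neurocranium cannot be a freeze unit", call. = FALSE)
  if (is.null(names(units)) || any(names(units) == ""))
    stop("freeze units must be named", call. = FALSE)
  structure(list(window = as.integer(window), units = units,
                 neurocranium = neurocranium),
            class = "freeze_window_config")
}

#' Default freeze units for the standard rig
#'
#' Lower jaw, bilateral ceratohyals (one mirrored unit) and bilateral
#' clavicles. The cranial rib is excluded by default: it does not bound the
#' oral cavity, so its motion does not directly change endocast volume. Set
#' `per_side = TRUE` to split the bilateral pairs.
#'
#' @param fps frame rate the trial was recorded at; picks the 20-frame
#'   (500 fps) or 12-frame (150 fps) increment, scaling to roughly 40 ms for
#'   other rates.
#' @param per_side freeze left/right bones separately.
#' @return A [freeze_window_config].
#' @export
default_freeze_config <- function(fps = 500, per_side = FALSE) {
  window <- if (fps == 500) 20L else if (fps == 150) 12L
    else max(2L, as.integer(round(0.040 * fps)))
  units <- if (per_side) list(
    lower_jaw = "lower_jaw",
    ceratohyal_R = "ceratohyal_R", ceratohyal_L = "ceratohyal_L",
    clavicle_R = "clavicle_R", clavicle_L = "clavicle_L")
  else list(
    lower_jaw = "lower_jaw",
    ceratohyal = c("ceratohyal_R", "ceratohyal_L"),
    clavicle = c("clavicle_R", "clavicle_L"))
  freeze_window_config(window, units)
}

#' Relative contribution to volume change (RCVC)
#'
#' For each rolling window `[t, t + N]` (advancing one frame) and each freeze
#' unit i: `dV_full = V(t+N) - V(t)` with nothing frozen, `dV_frozen_i`
#' likewise with unit i frozen at its frame-`t` pose relative to the
#' neurocranium, and
#' `RCVC_i = (dV_full - dV_frozen_i) / sum_j |dV_full - dV_frozen_j|`.
#' Positive values mean the unit's motion contributes to expansion, negative
#' to contraction; `sum_i |RCVC_i| = 1` on every non-degenerate window.
#' Windows with a zero denominator are flagged and report 0 for all units.
#' Windows truncated by the trial end are dropped, not shortened. Each
#' window's value is timestamped at the window centre.
#'
#' @param def an [endocast_definition].
#' @param poses named list of [pose_series] (all bodies the locators and
#'   freeze units need).
#' @param config a [freeze_window_config].
#' @return An object of class `rcvc_result`: data frame with
#'   `window_start_frame`, `center_time_ms`, `dv_full`, then per unit
#'   `dv_frozen_<unit>` and `rcvc_<unit>`, plus `degenerate` flag.
#' @export
rcvc_series <- function(def, poses, config) {
  stopifnot(inherits(def, "endocast_definition"),
            inherits(config, "freeze_window_config"))
  N <- config$window
  first <- poses[[def$locators$body[1]]]
  n <- n_frames(first)
  fps <- first$fps
  if (n <= N) stop("trial shorter than one freeze window", call. = FALSE)
  # full volumes once per frame
  vol_full <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    pts <- locator_world(def, poses, f)
    if (!is.null(pts)) vol_full[f] <- def$bilateral_factor *
        alpha_shape_volume(pts, def$alpha)
  }
  units <- config$units
  starts <- seq_len(n - N)
  res <- data.frame(window_start_frame = starts,
                    center_time_ms = (starts - 1 + N / 2) / fps * 1000,
                    dv_full = NA_real_)
  for (u in names(units)) {
    res[[paste0("dv_frozen_", u)]] <- NA_real_
    res[[paste0("rcvc_", u)]] <- NA_real_
  }
  res$degenerate <- FALSE
  loc_bodies <- unique(def$locators$body)
  for (t0 in starts) {
    t1 <- t0 + N
    if (is.na(vol_full[t0]) || is.na(vol_full[t1])) {
      warning("window at frame ", t0, " skipped: invalid poses")
      next
    }
    dv_full <- vol_full[t1] - vol_full[t0]
    dvf <- numeric(length(units))
    names(dvf) <- names(units)
    skip <- FALSE
    for (u in names(units)) {
      frozen <- tryCatch(
        freeze_bone(poses, units[[u]], config$neurocranium, t0, N),
        error = function(e) NULL)
      if (is.null(frozen)) { skip <- TRUE; break }
      if (!any(units[[u]] %in% loc_bodies)) {
        # unit moves no locators: frozen volume equals the full volume
        dvf[u] <- dv_full
        next
      }
      pts <- locator_world(def, frozen, t1)
      vfro <- def$bilateral_factor * alpha_shape_volume(pts, def$alpha)
      dvf[u] <- vfro - vol_full[t0]
    }
    if (skip) {
      warning("window at frame ", t0, " skipped: invalid poses")
      next
    }
    i <- which(res$window_start_frame == t0)
    res$dv_full[i] <- dv_full
    num <- dv_full - dvf
    den <- sum(abs(num))
    for (u in names(units)) res[[paste0("dv_frozen_", u)]][i] <- dvf[u]
    if (den == 0) {
      res$degenerate[i] <- TRUE
      for (u in names(units)) res[[paste0("rcvc_", u)]][i] <- 0
    } else {
      for (u in names(units)) res[[paste0("rcvc_", u)]][i] <- num[u] / den
    }
  }
  structure(res, class = c("rcvc_result", "data.frame"), fps = fps,
            window = N, units = names(units))
}

#' Write an RCVC result as CSV
#' @param res an `rcvc_result`.
#' @param path output path.
#' @export
write_rcvc_csv <- function(res, path) {
  utils::write.csv(as.data.frame(res), path, row.names = FALSE)
  invisible(path)
}
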