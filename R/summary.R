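#' Gape distance series
#'
#' Gape is operationalized as the 3D distance between an anterior upper-jaw
#' landmark and an anterior lower-jaw landmark, per frame.
#'
#' @param upper_traj,lower_traj `frames x 3` world trajectories (cm) of the
#'   jaw-tip landmarks.
#' @return numeric vector of distances (cm).
#' @export
gape_series <- function(upper_traj, lower_traj) {
  upper_traj <- rbind3(upper_traj); lower_traj <- rbind3(lower_traj)
  stopifnot(nrow(upper_traj) == nrow(lower_traj))
  unname(sqrt(rowSums((upper_traj - lower_traj)^2)))
}

#' Detect strike events from gape and kinematic channels
#'
#' Strike onset is the last frame before the gape excursion (above its
#' first-frame baseline) exceeds `threshold * (peak - baseline)`; jaw close
#' is the first frame after peak gape back below that level; strike duration
#' runs from onset to jaw close. Peaks of the supplied kinematic channels,
#' the volume series and the prey displacement are located as the first frame
#' attaining each channel's extremum (ties broken by the earliest frame), and
#' also reported in ms relative to peak gape (negative = before).
#'
#' @param gape gape series (cm), zeroed/filtered upstream as desired.
#' @param channels named list of numeric series; names ending `_max` peak at
#'   their maximum, all others at their minimum (depression/retraction
#'   conventions are negative).
#' @param volume optional volume series (peak = maximum).
#' @param prey optional prey displacement series (peak = maximum).
#' @param fps frames per second.
#' @param threshold onset threshold fraction in (0, 0.5).
#' @return An object of class `strike_events`: list with `onset_frame`,
#'   `peak_gape_frame`, `jaw_close_frame`, `duration_ms`,
#'   `time_to_peak_gape_ms`, and a data frame `peaks` (channel, frame,
#'   value, time_re_peak_gape_ms).
#' @export
detect_events <- function(gape, channels = list(), volume = NULL, prey = NULL,
                          fps, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 0.5)
    stop("threshold fraction must be in (0, 0.5)", call. = FALSE)
  n <- length(gape)
  baseline <- gape[1]
  exc <- gape - baseline
  peak_frame <- which.max(exc)
  peak <- exc[peak_frame]
  if (peak <= 0) stop("no strike: gape never exceeds its baseline", call. = FALSE)
  level <- threshold * peak
  above <- exc > level
  if (!any(above)) stop("no strike: gape never exceeds threshold", call. = FALSE)
  onset <- max(1L, which(above)[1] - 1L)
  after <- which(!above & seq_len(n) > peak_frame)
  close <- if (length(after)) after[1] else NA_integer_
  duration_ms <- if (is.na(close)) NA_real_ else (close - onset) / fps * 1000
  re_pg <- function(f) (f - peak_frame) / fps * 1000
  peaks <- NULL
  add_peak <- function(name, series, maximum) {
    f <- if (maximum) which.max(series)[1] else which.min(series)[1]
    rbind(peaks, data.frame(channel = name, frame = f, value = series[f],
                            time_re_peak_gape_ms = re_pg(f)))
  }
  for (nm in names(channels))
    peaks <- add_peak(nm, channels[[nm]], grepl("_max$", nm))
  if (!is.null(volume)) peaks <- add_peak("volume", volume, TRUE)
  if (!is.null(prey)) peaks <- add_peak("prey_distance", prey, TRUE)
  structure(list(onset_frame = onset, peak_gape_frame = peak_frame,
                 jaw_close_frame = close, duration_ms = duration_ms,
                 time_to_peak_gape_ms = (peak_frame - onset) / fps * 1000,
                 threshold = threshold, fps = fps, peaks = peaks),
            class = "strike_events")
}

#' @export
print.strike_events <- function(x, ...) {
  cat("<strike_events> onset frame ", x$onset_frame, ", peak gape frame ",
      x$peak_gape_frame, ", close frame ", x$jaw_close_frame,
      "\n  time to peak gape ", round(x$time_to_peak_gape_ms, 1),
      " ms; duration ", round(x$duration_ms, 1), " ms\n", sep = "")
  if (!is.null(x$peaks)) {
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf("  %-28s peak %8.3f at %+7.1f ms re peak gape\n",
                  x$peaks$channel[i], x$peaks$value[i],
                  x$peaks$time_re_peak_gape_ms[i]))
  }
  invisible(x)
}

#' Noise-robust peak value of a kinematic channel
#'
#' With `fit_halfwidth = 0`, simply the extremum value (first frame on ties).
#' With a positive halfwidth, a quadratic is least-squares fitted to the
#' `2 * fit_halfwidth + 1` frames around the extremum and its value at the
#' vertex (constrained to the window) is returned: an unbiased, low-variance
#' peak estimate for smooth channels with additive noise, at the cost of
#' assuming the channel is locally parabolic over the window.
#'
#' @param series numeric vector (a zeroed kinematic channel).
#' @param maximum `TRUE` for a maximum, `FALSE` (default) for a minimum
#'   (depression/retraction peaks are minima).
#' @param fit_halfwidth half-width of the quadratic fit window in frames.
#' @param exclude_edges drop this many frames at each end before searching
#'   (filter warm-up exclusion); default 0.
#' @return the peak value.
#' @export
peak_value <- function(series, maximum = FALSE, fit_halfwidth = 0,
                       exclude_edges = 0) {
  n <- length(series)
  idx <- (1 + exclude_edges):(n - exclude_edges)
  s <- series[idx]
  f <- if (maximum) which.max(s)[1] else which.min(s)[1]
  if (fit_halfwidth == 0) return(s[f])
  w <- max(1, f - fit_halfwidth):min(length(s), f + fit_halfwidth)
  tt <- w - f
  cf <- stats::lm.fit(cbind(1, tt, tt^2), s[w])$coefficients
  if (abs(cf[3]) < 1e-12) return(s[f])
  tv <- -cf[2] / (2 * cf[3])
  tv <- min(max(tv, min(tt)), max(tt))        # vertex clamped to the window
  unname(cf[1] + cf[2] * tv + cf[3] * tv^2)
}

#' Align trials at peak gape and average
#'
#' Re-times each trial so t = 0 at its peak gape, then averages over trials
#' on the union time grid (same fps required). Time points covered by fewer
#' trials use that smaller n; nothing is extrapolated. The s.e.m. is the
#' sample standard deviation over trials divided by sqrt(n); it is NA where
#' n = 1.
#'
#' @param trials list of numeric series (one channel, one element per trial).
#' @param peak_gape_frames integer vector, one per trial.
#' @param fps common frames per second.
#' @return data frame with `time_ms` (0 at peak gape), `mean`, `sem`, `n`.
#' @export
align_and_average <- function(trials, peak_gape_frames, fps) {
  stopifnot(length(trials) >= 1, length(trials) == length(peak_gape_frames))
  rel <- lapply(seq_along(trials), function(i)
    seq_along(trials[[i]]) - peak_gape_frames[i])
  lo <- min(vapply(rel, min, numeric(1)))
  hi <- max(vapply(rel, max, numeric(1)))
  grid <- lo:hi
  acc <- matrix(NA_real_, length(grid), length(trials))
  for (i in seq_along(trials))
    acc[match(rel[[i]], grid), i] <- trials[[i]]
  n <- rowSums(!is.na(acc))
  mean_ <- rowMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
  })
  out <- data.frame(time_ms = grid / fps * 1000, mean = mean_, sem = sem, n = n)
  out[n > 0, , drop = FALSE]
}

#' Table-style summary of per-trial kinematic variables
#'
#' @param trials data frame with one row per trial and one column per
#'   kinematic variable (magnitudes and timings).
#' @return data frame with `variable`, `mean`, `sem` (sample sd / sqrt(n)),
#'   `n`. With a single trial the s.e.m. is 0 by convention and flagged.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  num <- trials[vapply(trials, is.numeric, TRUE)]
  out <- data.frame(
    variable = names(num),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
    sem = vapply(num, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
    }, 0),
    n = vapply(num, function(v) sum(!is.na(v)), 0L))
  attr(out, "single_trial") <- nrow(trials) == 1
  rownames(out) <- NULL
  out
}

#' Regression of time to peak gape on body length across species
#'
#' Ordinary least squares of time to peak gape (ms) on body length (mm) over
#' a species table, the standard cross-species test of whether strike speed
#' scales with size.
#'
#' @param records data frame with columns `body_length_mm` and
#'   `time_to_peak_gape_ms` (>= 3 rows, positive values).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   slope test) and the underlying `stats::lm` fit.
#' @export
body_length_regression <- function(records) {
  stopifnot(all(c("body_length_mm", "time_to_peak_gape_ms") %in% names(records)))
  if (nrow(records) < 3) stop("need >= 3 records", call. = FALSE)
  if (any(records$body_length_mm <= 0) || any(records$time_to_peak_gape_ms <= 0))
    stop("lengths and times must be positive", call. = FALSE)
  if (stats::var(records$body_length_mm) == 0)
    stop("undefined slope: body length is constant", call. = FALSE)
  fit <- stats::lm(time_to_peak_gape_ms ~ body_length_mm, data = records)
  sm <- suppressWarnings(summary(fit))   # "perfect fit" note on exact data
  if (stats::var(records$time_to_peak_gape_ms) == 0)
    return(list(slope = 0, intercept = records$time_to_peak_gape_ms[1],
                r_squared = 0, p_value = NA_real_, fit = fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       fit = fit)
}
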