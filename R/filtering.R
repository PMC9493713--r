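#' Zero-phase low-pass Butterworth filtering
#'
#' Designs a digital low-pass Butterworth filter (bilinear transform of the
#' analog prototype) and applies it forward and backward (filtfilt) so the net
#' response has zero phase and squared magnitude. The series is extended at
#' both ends by odd reflection before filtering to suppress edge transients.
#' Motion-capture convention: rigid-body transforms are filtered per rotation /
#' translation channel by the caller; this function operates on scalar series
#' or the columns of a matrix.
#'
#' @param x numeric vector, or matrix filtered column-wise.
#' @param cutoff_hz cutoff frequency (-3 dB of the one-pass filter), Hz.
#' @param fps sampling rate, frames per second. `cutoff_hz` must be below the
#'   Nyquist frequency `fps/2`.
#' @param order filter order of each pass (default 4).
#' @return filtered series, same shape as `x`. `NA`s are not allowed.
#' @examples
#' t <- seq(0, 1, by = 1/500)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 100 * t)
#' y <- lowpass_filter(x, 35, 500)   # keeps the 5 Hz component
#' @export
lowpass_filter <- function(x, cutoff_hz, fps, order = 4) {
  if (cutoff_hz <= 0 || cutoff_hz >= fps / 2)
    stop("cutoff must lie in (0, fps/2); got ", cutoff_hz, " Hz at fps ", fps,
         call. = FALSE)
  if (is.matrix(x)) return(apply(x, 2, lowpass_filter,
                                 cutoff_hz = cutoff_hz, fps = fps, order = order))
  if (anyNA(x)) stop("NA in series; filter valid segments separately", call. = FALSE)
  ba <- butter_lowpass(order, cutoff_hz / (fps / 2))
  filtfilt_ba(ba$b, ba$a, x)
}

# Butterworth low-pass coefficients; Wn = cutoff / Nyquist in (0, 1).
# Analog prototype poles -> prewarp -> bilinear transform.
#' @keywords internal
butter_lowpass <- function(order, Wn) {
  stopifnot(order >= 1, Wn > 0, Wn < 1)
  k <- seq_len(order)
  p_analog <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit circle, LHP
  warped <- tan(pi * Wn / 2)                  # prewarped cutoff (fs = 1/2 units)
  p <- p_analog * warped
  # bilinear: z = (1 + s/2fs)/(1 - s/2fs) with 2fs = 1 in these units
  pz <- (1 + p) / (1 - p)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))  # zeros at z = -1
  gain <- sum(a) / sum(b)                        # unit DC gain
  list(b = b * gain, a = a)
}

# monic polynomial coefficients (descending powers) from roots
#' @keywords internal
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# direct-form II transposed IIR filter, state initialized at the steady state
# for a DC input equal to the first sample (suppresses startup transients)
#' @keywords internal
iir_filter <- function(b, a, x) {
  nb <- length(b); na_ <- length(a)
  m <- max(nb, na_)
  b <- c(b, rep(0, m - nb)) / a[1]
  a <- c(a, rep(0, m - na_)) / a[1]
  n <- length(x)
  y <- numeric(n)
  z <- rev(cumsum(rev(b[2:m] - a[2:m]))) * x[1]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 2) z[1:(m - 2)] <- b[2:(m - 1)] * xi + z[2:(m - 1)] - a[2:(m - 1)] * yi
    z[m - 1] <- b[m] * xi - a[m] * yi
    y[i] <- yi
  }
  y
}

# forward-backward filtering with odd-reflection padding
#' @keywords internal
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, max(3 * (length(a) - 1), 36))
  if (pad < 1) stop("series too short to filter (length ", n, ")", call. = FALSE)
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Sliding-window polynomial smoothing of a trajectory
#'
#' Savitzky-Golay-style refinement: at each frame, a least-squares polynomial
#' of the given order is fitted to the samples inside a centred window and
#' evaluated at the window centre. Near the series ends the window shrinks to
#' the available one-sided samples (the polynomial order is reduced if the
#' shrunken window cannot support it). Used to refine noisy marker
#' trajectories (e.g. ceratohyal markers) before rigid-body fitting.
#'
#' @param traj numeric vector, or a `frames x 3` matrix smoothed per column.
#' @param window odd window length in frames; `window = 1` is the identity.
#' @param order polynomial order, `order < window`.
#' @return smoothed series, same shape as `traj`.
#' @export
smooth_trajectory_poly <- function(traj, window, order = 2) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (order >= window) stop("order must be < window", call. = FALSE)
  if (is.matrix(traj))
    return(apply(traj, 2, smooth_trajectory_poly, window = window, order = order))
  n <- length(traj)
  if (window == 1) return(traj)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    idx <- lo:hi
    ord <- min(order, length(idx) - 1)
    tt <- idx - i
    X <- outer(tt, 0:ord, `^`)
    cf <- qr.coef(qr(X), traj[idx])
    out[i] <- cf[1]                       # polynomial value at window centre
  }
  out
}
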