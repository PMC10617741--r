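# Derived biomechanical measures computed from trial-level recordings:
# balance asymmetry/sensory ratios, gait variability, torque-trace processing.

#' Symmetry angle between left and right limb values
#'
#' Limb-asymmetry measure based on the arctangent of the left/right ratio,
#' expressed as a percentage of 90 degrees:
#' \code{|45 - atan(left/right) in degrees| / 90 * 100}. The absolute value is
#' reported (magnitude, not direction), so the measure is symmetric in its
#' arguments and lies in [0, 50] for non-negative inputs. \code{right = 0} is
#' handled by the arctan limit (90 degrees, i.e. 50\%).
#'
#' @param left,right mean values measured from the left and right limbs
#'   (non-negative, not both zero)
#' @return symmetry angle in percent
#' @export
symmetry_angle <- function(left, right) {
  if (left < 0 || right < 0) stop("inputs must be non-negative")
  if (left == 0 && right == 0) stop("undefined for two zero inputs")
  ang <- if (right == 0) 90 else atan(left / right) * 180 / pi
  abs(45 - ang) / 90 * 100
}

#' Romberg ratio (visual contribution to balance)
#'
#' Eyes-closed sway velocity divided by eyes-open sway velocity.
#' @param ec_sway eyes-closed sway velocity (deg/s)
#' @param eo_sway eyes-open sway velocity (deg/s), must be positive
#' @return the ratio
#' @export
romberg_ratio <- function(ec_sway, eo_sway) {
  if (eo_sway <= 0) stop("eyes-open sway velocity must be positive")
  ec_sway / eo_sway
}

#' Somatosensory ratio (somatosensory contribution to balance)
#'
#' Sway velocity on foam divided by sway velocity on the firm surface.
#' @param foam_sway sway velocity on foam (deg/s)
#' @param firm_sway sway velocity on the firm surface (deg/s), must be positive
#' @return the ratio
#' @export
somatosensory_ratio <- function(foam_sway, firm_sway) {
  if (firm_sway <= 0) stop("firm-surface sway velocity must be positive")
  foam_sway / firm_sway
}

#' Gait variability as a percentage MAD
#'
#' Median absolute deviation of repeated step measurements, reported as a
#' percentage of the median: \code{median(|s - median(s)|) / |median(s)| * 100}.
#' The raw MAD is used (no 1.4826 consistency constant). Invariant to positive
#' rescaling of the series.
#'
#' @param s numeric vector of per-step values (length >= 2, non-zero median)
#' @return percentage MAD
#' @export
mad_percent <- function(s) {
  if (length(s) < 2L) stop("need at least 2 values")
  m <- stats::median(s)
  if (m == 0) stop("zero median")
  stats::median(abs(s - m)) / abs(m) * 100
}

#' Gait speed reserve
#'
#' Ratio of maximal to usual gait speed; the capacity to increase walking
#' speed on demand.
#' @param mgs maximal gait speed (m/s)
#' @param ugs usual gait speed (m/s), must be positive
#' @return the ratio
#' @export
gait_speed_reserve <- function(mgs, ugs) {
  if (ugs <= 0) stop("usual gait speed must be positive")
  mgs / ugs
}

#' Torque trace container
#'
#' A uniformly sampled dynamometer torque signal with its sampling rate and
#' the length of the leading rest (baseline) window used for onset detection.
#'
#' @param samples numeric vector of torque values (Nm)
#' @param rate sampling rate in Hz
#' @param baseline_s leading rest period in seconds treated as baseline
#'   (default 0.5 s)
#' @return an object of class \code{"torque_trace"}
#' @export
torque_trace <- function(samples, rate, baseline_s = 0.5) {
  if (rate <= 0) stop("rate must be positive")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  nb <- max(1L, round(baseline_s * rate))
  if (nb >= length(samples)) stop("baseline window covers the whole trace")
  structure(list(samples = samples, rate = rate, baseline_n = nb),
            class = "torque_trace")
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("torque_trace: %d samples at %g Hz (%.3f s), baseline %d samples\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$baseline_n))
  invisible(x)
}

#' Zero-phase low-pass Butterworth filter for torque traces
#'
#' Second-order (by default) low-pass Butterworth filter applied forwards and
#' backwards (zero phase), so that onset timing is not shifted. Length is
#' preserved.
#'
#' @param t a \code{torque_trace}
#' @param cutoff cut-off frequency in Hz (must be below the Nyquist rate)
#' @param order filter order (default 2)
#' @return a filtered \code{torque_trace}
#' @export
butterworth_lowpass <- function(t, cutoff, order = 2) {
  stopifnot(inherits(t, "torque_trace"))
  if (cutoff >= t$rate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (t$rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(t$samples)
  npad <- min(n - 1, 10L * ceiling(t$rate / cutoff))
  x <- t$samples
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  padded <- c(head_pad, x, tail_pad)
  filtered <- as.numeric(signal::filtfilt(bf, padded))[(npad + 1):(npad + n)]
  torque_trace(filtered, t$rate, t$baseline_n / t$rate)
}

#' Contraction onset detection
#'
#' Onset is the first sample after the baseline window at which torque reaches
#' the baseline mean plus \code{delta} (default 4 Nm). The baseline is the
#' mean of the leading rest window.
#'
#' @param t a \code{torque_trace}
#' @param delta threshold above baseline in Nm (default 4)
#' @return sample index of onset
#' @export
detect_onset <- function(t, delta = 4) {
  stopifnot(inherits(t, "torque_trace"))
  base <- mean(t$samples[seq_len(t$baseline_n)])
  idx <- which(t$samples[-seq_len(t$baseline_n)] >= base + delta)
  if (!length(idx)) stop("torque never reaches baseline + delta")
  t$baseline_n + idx[1L]
}

#' Rate of torque development over early time windows
#'
#' Slope of the torque-time curve (delta torque / delta time) over windows
#' starting at contraction onset, by default 0-50, 0-100 and 0-200 ms. The
#' endpoint-difference definition is the default; a least-squares slope over
#' the window is available via \code{method = "ls"}.
#'
#' @param t a \code{torque_trace}
#' @param windows numeric vector of window lengths in ms
#'   (default \code{c(50, 100, 200)})
#' @param delta onset threshold in Nm passed to \code{\link{detect_onset}}
#' @param method \code{"endpoint"} (default) or \code{"ls"}
#' @return named numeric vector of RTD values in Nm/s
#' @export
rtd <- function(t, windows = c(50, 100, 200), delta = 4, method = c("endpoint", "ls")) {
  stopifnot(inherits(t, "torque_trace"))
  method <- match.arg(method)
  onset <- detect_onset(t, delta)
  out <- vapply(windows, function(w) {
    nw <- round(w / 1000 * t$rate)
    if (onset + nw > length(t$samples))
      stop("trace too short after onset for a ", w, " ms window")
    if (method == "endpoint") {
      (t$samples[onset + nw] - t$samples[onset]) / (w / 1000)
    } else {
      seg <- t$samples[onset:(onset + nw)]
      tt <- (0:nw) / t$rate
      unname(stats::coef(stats::lm(seg ~ tt))[2L])
    }
  }, numeric(1))
  names(out) <- sprintf("rtd_0_%d", windows)
  out
}

#' Muscle quality index
#'
#' Muscle strength per kilogram of regional lean tissue mass: the summed peak
#' torques divided by the lean mass. Callers compose the printed indices
#' (single-torque and combined extension+flexion variants; dominant limb is
#' the one with the higher measured torque, and the composite index is the
#' mean of the dominant- and non-dominant-limb indices).
#'
#' @param torques numeric vector of peak torques (Nm)
#' @param lean_mass regional lean tissue mass in kg (positive)
#' @return muscle quality in Nm/kg
#' @export
muscle_quality <- function(torques, lean_mass) {
  if (lean_mass <= 0) stop("lean mass must be positive")
  sum(torques) / lean_mass
}

#' Flexion/extension strength ratio
#'
#' Quotient of flexor and extensor peak torque; also used for the
#' dorsiflexion/plantar-flexion and hamstrings/quadriceps ratios.
#'
#' @param flexor_pt flexor peak torque (Nm/kg)
#' @param extensor_pt extensor peak torque (Nm/kg), must be positive
#' @return the ratio
#' @export
strength_ratio <- function(flexor_pt, extensor_pt) {
  if (extensor_pt <= 0) stop("extensor peak torque must be positive")
  flexor_pt / extensor_pt
}
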