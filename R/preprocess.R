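# Gravity removal and per-epoch USA/FSA synthetic-acceleration features.
#
# The waist device responds to both movement and gravity. Gravity (and slow
# posture change) lives below ~0.7 Hz; gait and other dynamic movement above.
# FSA is the epoch mean of the per-sample vector norm after a second-order
# Butterworth high-pass at 0.7 Hz per axis; USA is the same statistic on the
# unfiltered signal after per-axis, per-epoch mean subtraction, so it retains
# slow orientation change that the filter removes. Their ratio is the
# classification feature.

#' High-pass filter specification
#'
#' @param order Filter order (default 2, the device's design).
#' @param cutoff_hz Cut-off frequency in Hz (default 0.7, chosen to exclude
#'   gravitational acceleration while passing gait frequencies).
#' @param sampling_rate_hz Sampling rate in Hz (default 32).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2L, cutoff_hz = 0.7, sampling_rate_hz = 32) {
  if (order < 1L) stop("order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2)
    stop("cutoff_hz must lie in (0, Nyquist)")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 sampling_rate_hz = sampling_rate_hz),
            class = "filter_spec")
}

#' Epoching specification
#'
#' @param epoch_s Epoch length in seconds (default 10, the device's epoch).
#' @param usa_mode How the unfiltered synthetic acceleration treats gravity:
#'   `"epoch_mean_removed"` (default) subtracts the per-axis epoch mean so
#'   static gravity drops out but slow orientation change is retained;
#'   `"raw_with_gravity"` keeps the full signal (sensitivity analysis only —
#'   with gravity retained every activity's ratio far exceeds the cut-offs).
#' @param sa_stat Epoch summary of the per-sample vector norm: `"mean"`
#'   (default, mg) or `"sum"` over the epoch's samples.
#' @return An object of class `epoching_spec`.
#' @export
epoching_spec <- function(epoch_s = 10,
                          usa_mode = c("epoch_mean_removed", "raw_with_gravity"),
                          sa_stat = c("mean", "sum")) {
  if (epoch_s <= 0) stop("epoch_s must be positive")
  structure(list(epoch_s = epoch_s, usa_mode = match.arg(usa_mode),
                 sa_stat = match.arg(sa_stat)),
            class = "epoching_spec")
}

.butter_hp <- function(spec) {
  signal::butter(spec$order, spec$cutoff_hz / (spec$sampling_rate_hz / 2),
                 type = "high")
}

#' Magnitude response of the gravity-removal high-pass filter
#'
#' Evaluates the designed digital Butterworth high-pass at the given
#' frequencies. Gain is 0 at DC, 1/sqrt(2) at the cut-off, and approaches 1
#' in the pass band.
#'
#' @param spec A [filter_spec()].
#' @param freq_hz Frequencies in Hz, each in `[0, Nyquist)`.
#' @return Gains in `[0, 1]`.
#' @export
highpass_gain <- function(spec = filter_spec(), freq_hz) {
  if (any(freq_hz < 0) || any(freq_hz >= spec$sampling_rate_hz / 2))
    stop("freq_hz must lie in [0, Nyquist)")
  bf <- .butter_hp(spec)
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / spec$sampling_rate_hz)
    num <- sum(bf$b * z^(seq_along(bf$b) - 1))
    den <- sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, numeric(1))
}

# Causal single-pass filter with internal state initialized to the steady
# state for a constant input equal to the first sample. For a high-pass
# filter that steady state has output 0 and past inputs x[1], so a direct
# form I initialization with init.x = x[1], init.y = 0 suppresses the
# startup transient exactly.
.filter_axis <- function(bf, x, mode) {
  if (mode == "zero_phase") {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    n <- length(bf$a) - 1L
    as.numeric(signal::filter(bf$b, bf$a, x,
                              init.x = rep(x[1], n), init.y = rep(0, n)))
  }
}

#' Remove gravitational acceleration from a recording
#'
#' Filters each axis independently with the second-order Butterworth
#' high-pass. The default is a causal single pass (the device filters in real
#' time) with internal state initialized to the steady-state response to the
#' first sample, which suppresses the startup transient; `mode = "zero_phase"`
#' applies a forward-backward pass for offline analysis.
#'
#' @param recording A [triaxial_recording()] spanning at least one epoch
#'   (10 s at the spec's sampling rate).
#' @param spec A [filter_spec()].
#' @param mode `"causal"` (default) or `"zero_phase"`.
#' @return A filtered [triaxial_recording()] of the same length.
#' @export
remove_gravity <- function(recording, spec = filter_spec(),
                           mode = c("causal", "zero_phase")) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "triaxial_recording"))
  if (length(recording) < 10 * recording$sampling_rate_hz)
    stop("recording shorter than one 10-s epoch")
  bf <- .butter_hp(spec)
  out <- recording
  # filtered values may legitimately overshoot the device range slightly;
  # bypass the range re-check by assigning in place
  out$samples$ax <- .filter_axis(bf, recording$samples$ax, mode)
  out$samples$ay <- .filter_axis(bf, recording$samples$ay, mode)
  out$samples$az <- .filter_axis(bf, recording$samples$az, mode)
  out
}

.epoch_sa <- function(x, y, z, n_per, n_ep, stat) {
  norm <- sqrt(x^2 + y^2 + z^2)
  m <- matrix(norm[seq_len(n_per * n_ep)], nrow = n_per)
  if (stat == "mean") colMeans(m) else colSums(m)
}

.epoch_demean <- function(v, n_per, n_ep) {
  m <- matrix(v[seq_len(n_per * n_ep)], nrow = n_per)
  m <- sweep(m, 2L, colMeans(m))
  as.numeric(m)
}

#' Compute per-epoch USA/FSA features
#'
#' Splits the recording into consecutive non-overlapping epochs from sample 0
#' (half-open intervals; a trailing partial epoch is discarded). Per epoch,
#' FSA is the summary (mean by default) of the per-sample vector norm
#' sqrt(X^2 + Y^2 + Z^2) of the gravity-filtered signal; USA is the same
#' statistic on the unfiltered signal after per-axis, per-epoch mean
#' subtraction. The ratio USA/FSA is undefined (`NA`) where FSA falls below
#' the movement floor.
#'
#' @param recording A [triaxial_recording()] spanning at least one full epoch.
#' @param fspec A [filter_spec()].
#' @param espec An [epoching_spec()].
#' @param movement_floor_mg FSA below this is treated as movement-free and
#'   the ratio left undefined (default 3 mg, the device resolution).
#' @param filter_mode Passed to [remove_gravity()].
#' @return An [epoch_features()] table, one row per complete epoch.
#' @export
compute_epoch_features <- function(recording, fspec = filter_spec(),
                                   espec = epoching_spec(),
                                   movement_floor_mg = 3,
                                   filter_mode = c("causal", "zero_phase")) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(inherits(recording, "triaxial_recording"))
  fs <- recording$sampling_rate_hz
  n_per_raw <- espec$epoch_s * fs
  n_per <- as.integer(round(n_per_raw))
  if (abs(n_per_raw - n_per) > 1e-9)
    stop("epoch_s x sampling_rate_hz must be an integer number of samples")
  n_ep <- length(recording) %/% n_per
  if (n_ep == 0L) stop("recording shorter than one epoch")

  filt <- remove_gravity(recording, fspec, mode = filter_mode)
  fsa <- .epoch_sa(filt$samples$ax, filt$samples$ay, filt$samples$az,
                   n_per, n_ep, espec$sa_stat)

  if (espec$usa_mode == "epoch_mean_removed") {
    ux <- .epoch_demean(recording$samples$ax, n_per, n_ep)
    uy <- .epoch_demean(recording$samples$ay, n_per, n_ep)
    uz <- .epoch_demean(recording$samples$az, n_per, n_ep)
  } else {
    ux <- recording$samples$ax; uy <- recording$samples$ay
    uz <- recording$samples$az
  }
  usa <- .epoch_sa(ux, uy, uz, n_per, n_ep, espec$sa_stat)

  floor_stat <- if (espec$sa_stat == "sum") movement_floor_mg * n_per
                else movement_floor_mg
  ratio <- ifelse(fsa >= floor_stat, usa / fsa, NA_real_)
  epoch_features(seq_len(n_ep) - 1L, n_per, usa, fsa, ratio)
}
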