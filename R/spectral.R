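#' Construct a trial-by-channel-by-sample recording array
#'
#' Container for epoched multi-channel time series: a 3-dimensional numeric
#' array indexed `(trial, channel, sample)` plus sampling metadata. This is
#' the level at which the phase-locking statistics consume recordings; how
#' the channels were obtained (sensors, source estimates, simulation) is
#' outside its concern.
#'
#' @param data Numeric array with `dim = c(n_trials, n_channels, n_samples)`.
#' @param fs Sampling rate in Hz, positive.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param channel_names Optional character vector naming the channels.
#'
#' @return An object of class `trial_array`.
#'
#' @examples
#' x <- trial_array(array(rnorm(2 * 3 * 100), c(2, 3, 100)), fs = 1000)
#' dim(x$data)
#' @export
trial_array <- function(data, fs, t0 = 0, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trial, channel, sample)", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("all samples must be finite", call. = FALSE)
  check_scalar(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  check_scalar(t0, "t0")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 2L) {
    stop("need at least 1 trial, 1 channel and 2 samples", call. = FALSE)
  }
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == d[2])
  }
  structure(
    list(data = data, fs = fs, t0 = t0, channel_names = channel_names),
    class = "trial_array"
  )
}

#' @export
print.trial_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_array> %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
    d[1], d[2], d[3], x$fs, x$t0
  ))
  invisible(x)
}

#' Morlet wavelet coefficient at a single time and frequency
#'
#' Extracts one complex time-frequency coefficient per (trial, channel) by
#' taking the inner product of the signal with a complex Morlet wavelet --
#' a Gaussian-enveloped complex exponential -- centred at the requested
#' time:
#' \deqn{w(t) = e^{-t^2 / (2\sigma_t^2)} e^{i 2\pi f t}, \qquad
#'       \sigma_t = \mathrm{cycles} / (2\pi f).}
#' The phase of the coefficient is the instantaneous phase of the signal's
#' `freq` component at `time`; the magnitude is its envelope amplitude (up
#' to the L2 normalization of the wavelet, which cancels from every
#' statistic in this package since only phases are used downstream).
#'
#' The envelope width is parameterized by the number of cycles under the
#' Gaussian (default 7, a common choice for 40-Hz analyses giving roughly
#' 28 ms temporal and 6 Hz spectral standard deviation). Each trial is
#' de-meaned before the inner product so that DC offset cannot leak into
#' the coefficient of a short wavelet. The wavelet support is truncated at
#' `4 * sigma_t` on either side of `time`; the requested time must be at
#' least that margin away from both edges of the recording, otherwise an
#' edge-effect error reports the minimum usable margin.
#'
#' @param trials A [trial_array].
#' @param freq Analysis frequency in Hz.
#' @param time Analysis time in seconds (same clock as `t0`).
#' @param cycles Number of wavelet cycles (envelope width); positive real,
#'   default 7.
#'
#' @return An object of class `tf_coefficients`: a list with `values` (a
#'   complex `trial x channel` matrix), `freq`, `time` and
#'   `bandwidth_spec` (a verbatim record of the envelope parameter).
#'
#' @examples
#' t <- seq(0, 1 - 1 / 1000, by = 1 / 1000)
#' x <- array(cos(2 * pi * 40 * t + 0.8), c(1, 1, length(t)))
#' cf <- morlet_coefficients(trial_array(x, fs = 1000), freq = 40, time = 0.5)
#' Arg(cf$values) # ~0.8
#' @export
morlet_coefficients <- function(trials, freq, time, cycles = 7) {
  stopifnot(inherits(trials, "trial_array"))
  check_scalar(freq, "freq")
  check_scalar(time, "time")
  check_scalar(cycles, "cycles")
  if (freq <= 0) stop("`freq` must be positive", call. = FALSE)
  if (cycles <= 0) stop("`cycles` must be positive", call. = FALSE)

  d <- dim(trials$data)
  n_samples <- d[3]
  fs <- trials$fs
  sigma_t <- cycles / (2 * pi * freq)
  half_width <- 4 * sigma_t
  t_start <- trials$t0
  t_end <- trials$t0 + (n_samples - 1) / fs
  if (time - half_width < t_start || time + half_width > t_end) {
    stop(sprintf(
      paste0(
        "requested time %.4g s is too close to a recording edge: the ",
        "wavelet at %g Hz with %g cycles needs a margin of %.4g s on ",
        "either side (usable window [%.4g, %.4g] s)"
      ),
      time, freq, cycles, half_width, t_start + half_width,
      t_end - half_width
    ), call. = FALSE)
  }

  # Discrete wavelet support around the sample nearest the analysis time.
  t_axis <- trials$t0 + (seq_len(n_samples) - 1) / fs
  keep <- which(abs(t_axis - time) <= half_width)
  tau <- t_axis[keep] - time
  w <- exp(-tau^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * freq * tau)
  w <- w / sqrt(sum(Mod(w)^2)) # L2 normalization

  values <- matrix(complex(real = 0, imaginary = 0), nrow = d[1], ncol = d[2])
  for (ch in seq_len(d[2])) {
    seg <- trials$data[, ch, keep, drop = FALSE]
    seg <- matrix(seg, nrow = d[1], ncol = length(keep))
    seg <- seg - rowMeans(seg)
    values[, ch] <- seg %*% Conj(w)
  }
  if (!is.null(trials$channel_names)) colnames(values) <- trials$channel_names
  structure(
    list(
      values = values, freq = freq, time = time,
      bandwidth_spec = sprintf("morlet cycles = %g (sigma_t = %.6g s)",
        cycles, sigma_t
      )
    ),
    class = "tf_coefficients"
  )
}

#' Per-trial phase differences between two channels
#'
#' Subtracts the coefficient phases of channel `chan_b` from those of
#' `chan_a`, trial by trial, and wraps to `[0, 2*pi)`. This is the quantity
#' every statistic in the package tests: the trial-wise phase lag between
#' two regions at one time and frequency.
#'
#' @param coeffs A `tf_coefficients` object from [morlet_coefficients()].
#' @param chan_a,chan_b Channel indices (or names, when the source
#'   [trial_array] carried channel names).
#'
#' @return An [angle_sample] of length `n_trials`, labelled
#'   `"chan_a - chan_b"`.
#'
#' @examples
#' t <- seq(0, 1 - 1 / 1000, by = 1 / 1000)
#' x <- array(0, c(1, 2, length(t)))
#' x[1, 1, ] <- cos(2 * pi * 40 * t + pi / 3)
#' x[1, 2, ] <- cos(2 * pi * 40 * t + pi / 6)
#' cf <- morlet_coefficients(trial_array(x, fs = 1000), 40, 0.5)
#' phase_differences(cf, 1, 2) # ~pi/6
#' @export
phase_differences <- function(coeffs, chan_a, chan_b) {
  stopifnot(inherits(coeffs, "tf_coefficients"))
  a <- resolve_channel(coeffs, chan_a)
  b <- resolve_channel(coeffs, chan_b)
  ca <- coeffs$values[, a]
  cb <- coeffs$values[, b]
  zero <- which(Mod(ca) == 0 | Mod(cb) == 0)
  if (length(zero) > 0L) {
    stop(sprintf(
      "phase undefined: zero-magnitude coefficient in trial(s) %s",
      paste(zero, collapse = ", ")
    ), call. = FALSE)
  }
  angle_sample(Arg(ca) - Arg(cb), label = sprintf("%s - %s", chan_a, chan_b))
}

resolve_channel <- function(coeffs, chan) {
  nc <- ncol(coeffs$values)
  if (is.character(chan)) {
    idx <- match(chan, colnames(coeffs$values))
    if (is.na(idx)) stop(sprintf("unknown channel \"%s\"", chan), call. = FALSE)
    return(idx)
  }
  if (!is.numeric(chan) || length(chan) != 1L || chan < 1 || chan > nc ||
    chan != as.integer(chan)) {
    stop(sprintf("channel index must be an integer in 1..%d", nc),
      call. = FALSE
    )
  }
  as.integer(chan)
}
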