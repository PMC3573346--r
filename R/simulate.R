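#' Simulation configuration
#'
#' Bundles the parameters of the synthetic crosstalk experiment: several
#' regions of interest (ROIs) carrying 40-Hz sinusoidal sources, a set of
#' phase-locked trials (each ROI keeps a fixed phase offset, perturbed
#' trial-by-trial by zero-centred von Mises noise) and a set of unlocked
#' trials (every ROI's phase redrawn uniformly each trial), passed through
#' a linear crosstalk mixing matrix with additive spatially colored noise.
#'
#' Defaults follow the simulation conditions the statistics are evaluated
#' under: 20 locked and 20 unlocked trials, concentration `kappa = 50`,
#' 40-Hz carrier, noise RMS equal to 0.1% of signal RMS, and a moderate
#' crosstalk strength of 0.4. Sampling at 1000 Hz for 1 s puts the
#' analysis point (0.5 s) comfortably inside the wavelet's usable window.
#'
#' @param n_rois Number of regions (channels), at least 2.
#' @param n_trials_locked,n_trials_unlocked Trial counts (either may be 0,
#'   not both).
#' @param kappa Von Mises concentration of the trial-wise phase
#'   perturbation in locked trials.
#' @param carrier_freq Source oscillation frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param duration Trial length in seconds; `duration * fs >= 2`.
#' @param noise_level Ratio of mean per-channel noise RMS to mean
#'   per-channel signal RMS (0 disables noise).
#' @param crosstalk_strength Off-diagonal mixing strength in `[0, 1)`;
#'   0 is the identity (no leakage).
#' @param noise_correlation Mean off-diagonal correlation of the noise
#'   covariance, in `(-1/(n_rois-1), 1)`.
#' @param seed Integer seed governing the whole simulation.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_rois = 4L,
                       n_trials_locked = 20L,
                       n_trials_unlocked = 20L,
                       kappa = 50,
                       carrier_freq = 40,
                       fs = 1000,
                       duration = 1,
                       noise_level = 0.001,
                       crosstalk_strength = 0.4,
                       noise_correlation = 0.3,
                       seed = NULL) {
  n_rois <- check_count(n_rois, "n_rois")
  if (n_rois < 2L) stop("`n_rois` must be at least 2", call. = FALSE)
  for (nm in c("n_trials_locked", "n_trials_unlocked")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != as.integer(v)) {
      stop(sprintf("`%s` must be a non-negative integer", nm), call. = FALSE)
    }
  }
  if (n_trials_locked + n_trials_unlocked < 1) {
    stop("at least one trial is required", call. = FALSE)
  }
  check_scalar(kappa, "kappa")
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  check_scalar(carrier_freq, "carrier_freq")
  check_scalar(fs, "fs")
  check_scalar(duration, "duration")
  if (duration * fs < 2) stop("`duration * fs` must be at least 2", call. = FALSE)
  check_scalar(noise_level, "noise_level")
  if (noise_level < 0) stop("`noise_level` must be non-negative", call. = FALSE)
  check_scalar(crosstalk_strength, "crosstalk_strength")
  if (crosstalk_strength < 0 || crosstalk_strength >= 1) {
    stop("`crosstalk_strength` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_rois = n_rois,
      n_trials_locked = as.integer(n_trials_locked),
      n_trials_unlocked = as.integer(n_trials_unlocked),
      kappa = kappa, carrier_freq = carrier_freq, fs = fs,
      duration = duration, noise_level = noise_level,
      crosstalk_strength = crosstalk_strength,
      noise_correlation = noise_correlation,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw the per-trial, per-ROI phase plan
#'
#' Locked trials: one fixed base angle per ROI, drawn once per simulation
#' from the circular uniform, plus an independent zero-centred von Mises
#' perturbation with concentration `kappa` for every trial. Unlocked
#' trials: every ROI's angle redrawn uniformly on each trial, so pairwise
#' phase differences are uniform by construction.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the config's seed.
#'
#' @return A list with `base_angles` (length `n_rois`), `locked`
#'   (`n_trials_locked x n_rois` matrix) and `unlocked`
#'   (`n_trials_unlocked x n_rois` matrix), all angles in `[0, 2*pi)`.
#' @export
draw_phase_plan <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(seed, "phases"), {
    p <- config$n_rois
    base <- stats::runif(p, 0, 2 * pi)
    locked <- matrix(0, config$n_trials_locked, p)
    if (config$n_trials_locked > 0L) {
      pert <- rvonmises(config$n_trials_locked * p,
        theta = 0, kappa = config$kappa
      )
      locked <- wrap_angle(
        matrix(rep(base, each = config$n_trials_locked),
          config$n_trials_locked, p
        ) +
          matrix(as.numeric(pert), config$n_trials_locked, p)
      )
    }
    unlocked <- matrix(
      stats::runif(config$n_trials_unlocked * p, 0, 2 * pi),
      config$n_trials_unlocked, p
    )
    list(base_angles = base, locked = locked, unlocked = unlocked)
  })
}

#' Synthesize sinusoidal source time courses from a phase plan
#'
#' Produces `x(t) = sin(2*pi*f*t + phi)` per ROI and trial with unit
#' amplitude, so all channels carry equal signal power and any phase
#' structure comes solely from the plan.
#'
#' @param phases Matrix of phase offsets, `n_trials x n_rois` (one of the
#'   components of [draw_phase_plan()]'s result).
#' @param config A [sim_config()] (supplies `carrier_freq`, `fs`,
#'   `duration`).
#'
#' @return A [trial_array] of dimension
#'   `n_trials x n_rois x (duration * fs)` with `t0 = 0`.
#' @export
synthesize_sources <- function(phases, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(phases))
  if (ncol(phases) != config$n_rois) {
    stop("`phases` must have one column per ROI", call. = FALSE)
  }
  n_trials <- nrow(phases)
  n_samples <- round(config$duration * config$fs)
  t_axis <- (seq_len(n_samples) - 1) / config$fs
  data <- array(0, c(n_trials, config$n_rois, n_samples))
  carrier <- 2 * pi * config$carrier_freq * t_axis
  for (roi in seq_len(config$n_rois)) {
    # outer(trial phase, time): one sinusoid per trial with its planned shift
    data[, roi, ] <- sin(outer(phases[, roi], carrier, `+`))
  }
  trial_array(data,
    fs = config$fs, t0 = 0,
    channel_names = sprintf("ROI%d", seq_len(config$n_rois))
  )
}

#' Build a crosstalk model (mixing matrix + noise covariance)
#'
#' Stands in for the composite forward-inverse chain that produces source
#' leakage in MEG/EEG source estimates: estimated ROI time courses are a
#' linear mixture of true sources. The mixing matrix is
#' `I + strength * O`, where `O` has zero diagonal and off-diagonal weights
#' decaying exponentially with a randomly drawn inter-ROI "distance"
#' (emulating stronger leakage between nearby regions); each row of `O` is
#' scaled to unit off-diagonal sum, so `strength < 1` keeps the mixing
#' diagonally dominant. The noise covariance has unit-mean variances
#' (log-normally jittered across channels) and a constant off-diagonal
#' correlation `noise_correlation`, giving spatially colored noise.
#'
#' @param n_rois Number of regions.
#' @param crosstalk_strength Strength in `[0, 1)`; 0 yields the identity.
#' @param noise_correlation Common off-diagonal correlation of the noise;
#'   must keep the covariance positive definite
#'   (`-1/(n_rois-1) < rho < 1`).
#' @param seed Integer seed for the random ROI layout and variance jitter.
#'
#' @return An object of class `crosstalk_model`: list with `mixing`
#'   (`n_rois x n_rois`, unit diagonal) and `noise_cov` (symmetric
#'   positive definite).
#' @export
make_crosstalk_model <- function(n_rois, crosstalk_strength = 0.4,
                                 noise_correlation = 0.3, seed = NULL) {
  n_rois <- check_count(n_rois, "n_rois")
  check_scalar(crosstalk_strength, "crosstalk_strength")
  if (crosstalk_strength < 0 || crosstalk_strength >= 1) {
    stop("`crosstalk_strength` must lie in [0, 1): diagonal dominance is lost at 1",
      call. = FALSE
    )
  }
  check_scalar(noise_correlation, "noise_correlation")
  if (noise_correlation <= -1 / (n_rois - 1) || noise_correlation >= 1) {
    stop(sprintf(
      "`noise_correlation` must lie in (%.3f, 1) to keep the covariance positive definite",
      -1 / (n_rois - 1)
    ), call. = FALSE)
  }
  with_seed(derive_seed(seed, "crosstalk"), {
    pos <- stats::runif(n_rois) # ROI layout on a unit line
    d <- abs(outer(pos, pos, `-`))
    o <- exp(-d / stats::median(d[d > 0]))
    diag(o) <- 0
    o <- o / rowSums(o) # unit off-diagonal row sum
    mixing <- diag(n_rois) + crosstalk_strength * o
    sd_jitter <- exp(stats::rnorm(n_rois, 0, 0.1))
    corr <- matrix(noise_correlation, n_rois, n_rois)
    diag(corr) <- 1
    noise_cov <- outer(sd_jitter, sd_jitter) * corr
    structure(
      list(mixing = mixing, noise_cov = noise_cov),
      class = "crosstalk_model"
    )
  })
}

#' Apply crosstalk mixing and additive colored noise to source trials
#'
#' Computes `observed = mixing %*% sources + noise` per trial. Noise is
#' drawn fresh for each trial from a zero-mean Gaussian with covariance
#' `model$noise_cov`, then globally rescaled so that the ratio of mean
#' per-channel noise RMS to mean per-channel signal RMS equals
#' `noise_level` (signal = the mixed signal). With `noise_level = 0` and an
#' identity mixing the output equals the input exactly.
#'
#' @param sources A [trial_array] of source time courses.
#' @param model A [make_crosstalk_model()] result with matching `n_rois`.
#' @param noise_level Target noise-to-signal RMS ratio, non-negative.
#' @param seed Integer seed for the noise draw.
#'
#' @return A [trial_array] of the same dimensions as `sources`.
#' @export
apply_crosstalk <- function(sources, model, noise_level = 0, seed = NULL) {
  stopifnot(inherits(sources, "trial_array"), inherits(model, "crosstalk_model"))
  check_scalar(noise_level, "noise_level")
  if (noise_level < 0) stop("`noise_level` must be non-negative", call. = FALSE)
  d <- dim(sources$data)
  p <- d[2]
  if (nrow(model$mixing) != p) {
    stop(sprintf(
      "dimension mismatch: model has %d ROIs, sources have %d channels",
      nrow(model$mixing), p
    ), call. = FALSE)
  }
  mixed <- sources$data
  for (tr in seq_len(d[1])) {
    mixed[tr, , ] <- model$mixing %*% matrix(sources$data[tr, , ], p, d[3])
  }
  if (noise_level > 0) {
    noise <- with_seed(derive_seed(seed, "noise"), {
      l <- chol(model$noise_cov)
      out <- array(0, d)
      for (tr in seq_len(d[1])) {
        z <- matrix(stats::rnorm(p * d[3]), p, d[3])
        out[tr, , ] <- crossprod(l, z)
      }
      out
    })
    signal_rms <- mean(sqrt(apply(mixed^2, 2, mean)))
    noise_rms <- mean(sqrt(apply(noise^2, 2, mean)))
    mixed <- mixed + noise * (noise_level * signal_rms / noise_rms)
  }
  trial_array(mixed,
    fs = sources$fs, t0 = sources$t0,
    channel_names = sources$channel_names
  )
}

#' Run the full synthetic crosstalk experiment
#'
#' Convenience wrapper chaining [draw_phase_plan()],
#' [synthesize_sources()], [make_crosstalk_model()] and
#' [apply_crosstalk()]: returns observed (mixed, noisy) trial arrays for
#' the locked and unlocked trial sets, ready for Morlet phase extraction.
#' Fully reproducible from `config$seed` (or the `seed` override).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return A list with `locked` and `unlocked` [trial_array]s (either may
#'   be `NULL` if its trial count is 0), the `model`, the `plan` and the
#'   resolved `config`.
#'
#' @examples
#' sim <- simulate_experiment(sim_config(n_rois = 3, seed = 7))
#' sim$locked
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  plan <- draw_phase_plan(config, seed = seed)
  model <- make_crosstalk_model(
    config$n_rois, config$crosstalk_strength,
    config$noise_correlation,
    seed = derive_seed(seed, "model")
  )
  mix_one <- function(phases, stage) {
    if (nrow(phases) == 0L) {
      return(NULL)
    }
    src <- synthesize_sources(phases, config)
    apply_crosstalk(src, model, config$noise_level,
      seed = derive_seed(seed, stage)
    )
  }
  list(
    locked = mix_one(plan$locked, "locked"),
    unlocked = mix_one(plan$unlocked, "unlocked"),
    model = model, plan = plan, config = config
  )
}
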