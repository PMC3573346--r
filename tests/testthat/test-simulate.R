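base_cfg <- function(...) {
  sim_config(
    n_rois = 3, n_trials_locked = 20, n_trials_unlocked = 20,
    seed = 101, ...
  )
}

test_that("config validation enforces the documented ranges", {
  expect_error(sim_config(n_rois = 1), "at least 2")
  expect_error(sim_config(crosstalk_strength = 1), "\\[0, 1\\)")
  expect_error(sim_config(noise_level = -0.1), "non-negative")
  expect_error(
    sim_config(n_trials_locked = 0, n_trials_unlocked = 0),
    "at least one trial"
  )
})

test_that("locked trials share fixed offsets, unlocked trials do not", {
  # near-degenerate concentration: pairwise differences become constant
  cfg <- base_cfg(kappa = 1e6)
  plan <- draw_phase_plan(cfg)
  d12 <- wrap_angle(plan$locked[, 1] - plan$locked[, 2])
  expect_lt(diff(range(wrap_diff(d12, d12[1]))), 0.01)

  # unlocked: pairwise differences pass a Rayleigh uniformity check
  ok <- vapply(1:100, function(seed) {
    cfg <- sim_config(
      n_rois = 2, n_trials_locked = 0,
      n_trials_unlocked = 200, seed = seed
    )
    plan <- draw_phase_plan(cfg)
    d <- plan$unlocked[, 1] - plan$unlocked[, 2]
    rayleigh_pvalue(plv(d), 200) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("locked pairwise spread matches the difference-distribution oracle", {
  # difference of two independent von Mises(0, kappa) perturbations:
  # resultant length = (quadrature resultant of one)^2
  kappa <- 20
  rho_expected <- oracle_vm_resultant(kappa)^2
  cfg <- sim_config(
    n_rois = 2, n_trials_locked = 500, n_trials_unlocked = 0,
    kappa = kappa, seed = 55
  )
  plan <- draw_phase_plan(cfg)
  rho_hat <- plv(plan$locked[, 1] - plan$locked[, 2])
  # MC tolerance ~ 3 / sqrt(2 * n) for a concentrated distribution
  expect_lt(abs(rho_hat - rho_expected), 3 / sqrt(2 * 500))
})

test_that("synthesized sources carry the planned phases", {
  cfg <- base_cfg()
  # all-zero plan: identical waveforms in every ROI and trial
  src0 <- synthesize_sources(matrix(0, 4, 3), cfg)
  expect_equal(src0$data[1, 1, ], src0$data[3, 2, ])

  # Morlet round trip: a sine with offset phi reads as phi - pi/2 on the
  # cosine-referenced analytic phase; at t = 0.5 s the 40-Hz carrier term
  # is a whole number of cycles and drops out
  phases <- matrix(c(0.5, 1.7, 3.9, 2.2, 0.1, 5.0), 2, 3)
  src <- synthesize_sources(phases, cfg)
  cf <- morlet_coefficients(src, cfg$carrier_freq, 0.5)
  expect_lt(
    max(wrap_diff(Arg(cf$values), phases - pi / 2)),
    0.05
  )

  # planned pairwise offset of pi/2 shows up as a pi/2 phase difference
  src2 <- synthesize_sources(
    matrix(c(pi / 2, pi / 2, 0, 0, 1, 1), 2, 3), cfg
  )
  cf2 <- morlet_coefficients(src2, 40, 0.5)
  d <- as.numeric(phase_differences(cf2, 1, 2))
  expect_lt(max(wrap_diff(d, pi / 2)), 0.05)
})

test_that("per-trial RMS is constant under identity mixing", {
  cfg <- base_cfg(crosstalk_strength = 0, noise_level = 0)
  sim <- simulate_experiment(cfg)
  rms <- apply(sim$locked$data, c(1, 2), function(x) sqrt(mean(x^2)))
  expect_lt(max(abs(rms - rms[1, 1])), 1e-10)
})

test_that("the crosstalk model is well formed across strengths", {
  m0 <- make_crosstalk_model(4, crosstalk_strength = 0, seed = 1)
  expect_equal(m0$mixing, diag(4))
  for (s in c(0.2, 0.5, 0.9)) {
    m <- make_crosstalk_model(5, crosstalk_strength = s, seed = 2)
    expect_equal(diag(m$mixing), rep(1, 5))
    expect_equal(rowSums(m$mixing - diag(5)), rep(s, 5))
    expect_true(all(eigen(m$noise_cov, symmetric = TRUE)$values > 0))
    expect_equal(m$noise_cov, t(m$noise_cov))
  }
  expect_error(make_crosstalk_model(4, 1), "diagonal dominance")
})

test_that("crosstalk inflates apparent phase locking of unlocked sources", {
  mean_plv <- function(strength) {
    vapply(1:100, function(seed) {
      cfg <- sim_config(
        n_rois = 3, n_trials_locked = 0,
        n_trials_unlocked = 20, noise_level = 0,
        crosstalk_strength = strength, seed = seed
      )
      sim <- simulate_experiment(cfg)
      cf <- morlet_coefficients(sim$unlocked, 40, 0.5)
      plv(phase_differences(cf, 1, 2))
    }, numeric(1))
  }
  plv_mixed <- mean_plv(0.5)
  plv_clean <- mean_plv(0)
  expect_gt(mean(plv_mixed), mean(plv_clean))
})

test_that("mixing and noise application honour their contracts", {
  cfg <- base_cfg()
  src <- synthesize_sources(draw_phase_plan(cfg)$locked, cfg)
  ident <- make_crosstalk_model(3, 0, seed = 9)

  # identity mixing, no noise: exact pass-through
  out <- apply_crosstalk(src, ident, noise_level = 0)
  expect_identical(out$data, src$data)

  # measured noise-to-signal RMS ratio lands within 5% of the request
  out_noisy <- apply_crosstalk(src, ident, noise_level = 0.001, seed = 10)
  noise <- out_noisy$data - src$data
  ratio <- mean(sqrt(apply(noise^2, 2, mean))) /
    mean(sqrt(apply(src$data^2, 2, mean)))
  expect_lt(abs(ratio - 0.001) / 0.001, 0.05)

  # fixed seed: bit-identical repetition
  again <- apply_crosstalk(src, ident, noise_level = 0.001, seed = 10)
  expect_identical(out_noisy$data, again$data)

  bad <- make_crosstalk_model(4, 0.3, seed = 11)
  expect_error(apply_crosstalk(src, bad, 0), "dimension mismatch")
})

test_that("the full simulation is reproducible end to end", {
  cfg <- base_cfg(noise_level = 0.01, crosstalk_strength = 0.4)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$locked$data, s2$locked$data)
  expect_identical(s1$unlocked$data, s2$unlocked$data)
  expect_identical(s1$model, s2$model)
})

test_that("fitted concentration of extracted phases matches the oracle", {
  # locked trials, no mixing, no noise: the Morlet phase differences of one
  # pair follow the difference of two von Mises(0, kappa) draws; fit kappa
  # by inverting the resultant relation and compare with the oracle's
  # inversion of the expected resultant
  kappa <- 20
  cfg <- sim_config(
    n_rois = 2, n_trials_locked = 200, n_trials_unlocked = 0,
    kappa = kappa, crosstalk_strength = 0, noise_level = 0, seed = 77
  )
  sim <- simulate_experiment(cfg)
  d <- phase_differences(morlet_coefficients(sim$locked, 40, 0.5), 1, 2)
  kappa_hat <- oracle_kappa_from_resultant(plv(d))
  kappa_expected <- oracle_kappa_from_resultant(oracle_vm_resultant(kappa)^2)
  # delta-method spread of the fitted concentration at n = 200 is ~15%;
  # allow ~2.3 sigma
  expect_lt(abs(kappa_hat - kappa_expected) / kappa_expected, 0.35)
})
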