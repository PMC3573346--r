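#' ROC curve from positive and negative statistic pools
#'
#' Builds a receiver operating characteristic curve by sweeping every
#' observed statistic as a detection threshold: a case whose statistic is
#' equal to or more significant than the threshold is labelled a positive.
#' For each distinct threshold one point `(FPR, TPR)` is recorded, with
#' `TPR = TP / P` and `FPR = FP / N`; the endpoints `(0, 0)` and `(1, 1)`
#' are appended and the area under the curve is computed by trapezoidal
#' integration. Ties between positive and negative statistics contribute
#' half-steps (diagonal segments), so the AUC equals the Mann--Whitney
#' pairwise comparison probability with ties counted one half.
#'
#' @param pos_stats,neg_stats Numeric vectors of statistics from
#'   known-positive and known-negative cases.
#' @param higher_is_significant If `TRUE` (default) larger statistics mean
#'   stronger evidence; set `FALSE` for statistics like p-values where
#'   smaller is more significant.
#'
#' @return An object of class `roc_result`: list with `points` (a
#'   data.frame of `fpr`, `tpr` in sweep order), `auc`, `auc_sd`
#'   (`NA` here; filled by [run_benchmark()] across replicate sets),
#'   `n_pos`, `n_neg`.
#'
#' @examples
#' roc_curve(c(3, 4, 5), c(0, 1, 2))$auc # 1
#' @export
roc_curve <- function(pos_stats, neg_stats, higher_is_significant = TRUE) {
  for (nm in c("pos_stats", "neg_stats")) {
    v <- get(nm)
    if (length(v) < 1L) {
      stop(sprintf("`%s` must be non-empty", nm), call. = FALSE)
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-finite statistic in `%s` at index %s", nm,
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (!higher_is_significant) {
    pos_stats <- -pos_stats
    neg_stats <- -neg_stats
  }
  thr <- sort(unique(c(pos_stats, neg_stats)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_stats >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_stats >= t), numeric(1))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(
      points = data.frame(fpr = fpr, tpr = tpr),
      auc = auc, auc_sd = NA_real_,
      n_pos = length(pos_stats), n_neg = length(neg_stats)
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.4f%s  (%d positives, %d negatives, %d points)\n",
    x$auc, if (is.na(x$auc_sd)) "" else sprintf(" +/- %.4f", x$auc_sd),
    x$n_pos, x$n_neg, nrow(x$points)
  ))
  invisible(x)
}

#' Classification rate and error rate of a detector
#'
#' `classification_rate()` is the proportion of correctly assigned
#' positive and negative detections, `(TP + TN) / (P + N)`;
#' `error_rate()` is its complement `1 - (TP + TN) / (P + N)`. Both are
#' provided under separate names because the proportion-correct quantity
#' is sometimes labelled an "error" in the phase-locking literature while
#' error-rate figures plot the complement; benchmark output reports both
#' so no silent choice is made.
#'
#' @param detections Logical vector: did the test call this case positive?
#' @param truth Logical vector of the same length: is the case truly
#'   positive?
#'
#' @return A number in `[0, 1]`.
#'
#' @examples
#' classification_rate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)) # 2/3
#' @export
classification_rate <- function(detections, truth) {
  if (!is.logical(detections) || !is.logical(truth)) {
    stop("`detections` and `truth` must be logical vectors", call. = FALSE)
  }
  if (length(detections) != length(truth) || length(truth) < 1L) {
    stop("`detections` and `truth` must have equal positive length",
      call. = FALSE
    )
  }
  mean(detections == truth)
}

#' @rdname classification_rate
#' @export
error_rate <- function(detections, truth) {
  1 - classification_rate(detections, truth)
}

#' Threshold test results into detections
#'
#' Converts a list of [test_result]s into logical detections at
#' significance level `alpha`, optionally Bonferroni-corrected by dividing
#' `alpha` by the number of simultaneous comparisons (for an all-pairs
#' analysis of `r` regions that is `choose(r, 2)` -- e.g. 231 pairs for 22
#' regions).
#'
#' @param results List of [test_result]s, each carrying a p-value.
#' @param alpha Nominal significance level (e.g. 0.05).
#' @param bonferroni_m Number of simultaneous tests, or `NULL` for no
#'   correction.
#'
#' @return Logical vector, one detection flag per result.
#' @export
significance_detections <- function(results, alpha = 0.05,
                                    bonferroni_m = NULL) {
  stopifnot(is.list(results))
  check_scalar(alpha, "alpha")
  level <- if (is.null(bonferroni_m)) {
    alpha
  } else {
    alpha / check_count(bonferroni_m, "bonferroni_m")
  }
  vapply(results, function(r) {
    stopifnot(inherits(r, "test_result"))
    if (is.null(r$p_value)) {
      stop(sprintf(
        paste0(
          "method %s carries no p-value; use its permutation ",
          "significance wrapper before thresholding"
        ), r$method
      ), call. = FALSE)
    }
    r$p_value < level
  }, logical(1))
}

#' Benchmark grid specification
#'
#' Describes the evaluation design for [run_benchmark()]: which methods to
#' compare and over which simulation conditions, how many simulation
#' iterations to run, and how the iterations are grouped into replicate
#' sets for AUC error bounds. The default grid mirrors the evaluation
#' design the statistics are assessed under: 5 replicate sets of 4
#' iterations (20 positive and 20 negative simulations per condition),
#' with the mean AUC across sets reported as the value and the standard
#' deviation as the interval.
#'
#' @param methods Character subset of `c("USTPL", "PLV", "PLI", "PBI")`.
#' @param noise_levels,n_trials,kappas Numeric vectors of conditions;
#'   their Cartesian product is evaluated.
#' @param n_replicate_sets,iterations_per_set Grouping of iterations;
#'   `n_replicate_sets * iterations_per_set` simulations are run per
#'   condition for each of the positive and negative arms.
#' @param seed Integer seed for the whole benchmark.
#'
#' @return An object of class `benchmark_grid`.
#' @export
benchmark_grid <- function(methods = c("USTPL", "PLV", "PLI", "PBI"),
                           noise_levels = 0.001,
                           n_trials = 20L,
                           kappas = 50,
                           n_replicate_sets = 5L,
                           iterations_per_set = 4L,
                           seed = NULL) {
  methods <- match.arg(methods, c("USTPL", "PLV", "PLI", "PBI"),
    several.ok = TRUE
  )
  stopifnot(
    length(noise_levels) >= 1L, length(n_trials) >= 1L,
    length(kappas) >= 1L
  )
  n_replicate_sets <- check_count(n_replicate_sets, "n_replicate_sets")
  iterations_per_set <- check_count(iterations_per_set, "iterations_per_set")
  structure(
    list(
      methods = methods, noise_levels = noise_levels,
      n_trials = as.integer(n_trials), kappas = kappas,
      n_replicate_sets = n_replicate_sets,
      iterations_per_set = iterations_per_set,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "benchmark_grid"
  )
}

#' Run the ROC / error-rate benchmark
#'
#' For every condition in the grid, runs `n_replicate_sets *
#' iterations_per_set` positive simulations (phase-locked trials plus an
#' unlocked baseline) and as many negative simulations (two unlocked trial
#' sets passing through the same crosstalk model), extracts trial-wise
#' phase differences for every ROI pair with a Morlet wavelet at the
#' carrier frequency halfway through the trial, and scores each pair with
#' each method:
#'
#' * `USTPL`: minus the asymptotic chi-squared p-value of the uniform
#'   scores test between the stimulus and baseline sets (continuous score;
#'   more significant is larger),
#' * `PLV`: minus the standard Rayleigh p-value of the stimulus set,
#' * `PLI`: the phase lag index of the stimulus set,
#' * `PBI`: the magnitude of the phase bifurcation index between the two
#'   sets (a stimulus-locked/baseline-random pair drives PBI strongly
#'   negative, so the magnitude is the detection-relevant quantity).
#'
#' Scores are pooled across iterations and pairs within each replicate
#' set, an ROC is computed per set and per method, and the mean and
#' standard deviation of the AUC across sets are reported. For the
#' p-value-producing methods (USTPL, PLV) detection error rates at
#' `alpha = 0.05`, with and without Bonferroni correction by the number of
#' pairs, are also reported (both the proportion-correct and its
#' complement).
#'
#' @param grid A [benchmark_grid()].
#' @param sim_config_base A [sim_config()] supplying the non-varied
#'   simulation parameters (number of ROIs, carrier, sampling, crosstalk
#'   strength, noise correlation); `noise_level`, `kappa` and the trial
#'   counts are overridden per condition.
#' @param null_positives If `TRUE`, the positive arm is generated without
#'   phase locking too (both arms unlocked), so every method's true AUC is
#'   0.5. Used for null calibration of the harness itself.
#'
#' @return A data.frame with one row per (method, condition):
#'   columns `method`, `noise_level`, `n_trials`, `kappa`, `auc`,
#'   `auc_sd`, `classification_rate_unc`, `classification_rate_bonf`,
#'   `error_rate_unc`, `error_rate_bonf` (the last four `NA` for PLI and
#'   PBI, which produce no direct p-value).
#'
#' @examples
#' \donttest{
#' g <- benchmark_grid(
#'   methods = c("USTPL", "PLV"), n_replicate_sets = 2,
#'   iterations_per_set = 2, seed = 1
#' )
#' run_benchmark(g, sim_config(n_rois = 3, seed = 1))
#' }
#' @export
run_benchmark <- function(grid, sim_config_base = sim_config(),
                          null_positives = FALSE) {
  stopifnot(inherits(grid, "benchmark_grid"),
    inherits(sim_config_base, "sim_config")
  )
  conditions <- expand.grid(
    noise_level = grid$noise_levels, n_trials = grid$n_trials,
    kappa = grid$kappas, KEEP.OUT.ATTRS = FALSE
  )
  n_iter <- grid$n_replicate_sets * grid$iterations_per_set
  n_pairs <- choose(sim_config_base$n_rois, 2)
  alpha <- 0.05
  out <- list()

  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    cfg <- sim_config(
      n_rois = sim_config_base$n_rois,
      n_trials_locked = cond$n_trials,
      n_trials_unlocked = cond$n_trials,
      kappa = cond$kappa,
      carrier_freq = sim_config_base$carrier_freq,
      fs = sim_config_base$fs,
      duration = sim_config_base$duration,
      noise_level = cond$noise_level,
      crosstalk_strength = sim_config_base$crosstalk_strength,
      noise_correlation = sim_config_base$noise_correlation
    )
    # scores[[method]][[arm]]: matrix iteration x pair
    scores <- lapply(grid$methods, function(m) {
      list(
        pos = matrix(NA_real_, n_iter, n_pairs),
        neg = matrix(NA_real_, n_iter, n_pairs)
      )
    })
    names(scores) <- grid$methods

    for (arm in c("pos", "neg")) {
      for (it in seq_len(n_iter)) {
        it_seed <- derive_seed(
          grid$seed,
          sprintf("cond%d-%s-iter%d", ci, arm, it)
        )
        cfg_arm <- cfg
        if (arm == "neg" || null_positives) {
          # negatives: the "stimulus" set is unlocked too
          cfg_arm$n_trials_locked <- 0L
          cfg_arm$n_trials_unlocked <- 2L * cond$n_trials
        }
        sim <- simulate_experiment(cfg_arm, seed = it_seed)
        if (arm == "pos" && !null_positives) {
          stim_ta <- sim$locked
          base_ta <- sim$unlocked
          stim_rows <- seq_len(cond$n_trials)
          base_rows <- seq_len(cond$n_trials)
        } else {
          stim_ta <- base_ta <- sim$unlocked
          stim_rows <- seq_len(cond$n_trials)
          base_rows <- cond$n_trials + seq_len(cond$n_trials)
        }
        mid <- sim_config_base$duration / 2
        cf_stim <- morlet_coefficients(stim_ta, cfg$carrier_freq, mid)
        cf_base <- if (identical(stim_ta, base_ta)) {
          cf_stim
        } else {
          morlet_coefficients(base_ta, cfg$carrier_freq, mid)
        }
        pair <- 0L
        for (a in seq_len(cfg$n_rois - 1L)) {
          for (b in (a + 1L):cfg$n_rois) {
            pair <- pair + 1L
            stim <- angle_sample(
              (Arg(cf_stim$values[stim_rows, a]) -
                Arg(cf_stim$values[stim_rows, b]))
            )
            base <- angle_sample(
              (Arg(cf_base$values[base_rows, a]) -
                Arg(cf_base$values[base_rows, b]))
            )
            for (m in grid$methods) {
              scores[[m]][[arm]][it, pair] <- switch(m,
                USTPL = -ustpl_test(stim, base, mode = "asymptotic")$p_value,
                PLV = -rayleigh_pvalue(plv(stim), length(stim)),
                PLI = pli(stim),
                PBI = abs(pbi(stim, base))
              )
            }
          }
        }
      }
    }

    set_of <- rep(seq_len(grid$n_replicate_sets),
      each = grid$iterations_per_set
    )
    for (m in grid$methods) {
      aucs <- vapply(seq_len(grid$n_replicate_sets), function(s) {
        rows <- set_of == s
        roc_curve(
          as.numeric(scores[[m]]$pos[rows, ]),
          as.numeric(scores[[m]]$neg[rows, ])
        )$auc
      }, numeric(1))
      row <- data.frame(
        method = m, noise_level = cond$noise_level,
        n_trials = cond$n_trials, kappa = cond$kappa,
        auc = mean(aucs), auc_sd = stats::sd(aucs),
        classification_rate_unc = NA_real_,
        classification_rate_bonf = NA_real_,
        error_rate_unc = NA_real_, error_rate_bonf = NA_real_
      )
      if (m %in% c("USTPL", "PLV")) {
        # scores are -p, so detection at level a is score > -a
        pvals <- c(
          as.numeric(-scores[[m]]$pos),
          as.numeric(-scores[[m]]$neg)
        )
        truth <- rep(c(TRUE, FALSE), each = n_iter * n_pairs)
        row$classification_rate_unc <-
          classification_rate(pvals < alpha, truth)
        row$classification_rate_bonf <-
          classification_rate(pvals < alpha / n_pairs, truth)
        row$error_rate_unc <- 1 - row$classification_rate_unc
        row$error_rate_bonf <- 1 - row$classification_rate_bonf
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
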