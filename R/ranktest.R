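#' Circular rank (uniform scores) transformation of two angle populations
#'
#' Pools the two populations, ranks all angles jointly from 0 in the
#' positive direction (rank 1 is the angle closest to zero going
#' counter-clockwise, rank `n` the angle closest to `2*pi`), and maps rank
#' `r` to the uniform score `beta = 2*pi*r/n`. The scores are therefore
#' exactly equally spaced on the unit circle, and within each population the
#' circular order of the original angles is preserved. This transformation
#' makes the joint configuration of scores identical for every data set of
#' a given size, so the null distribution of any statistic of the scores
#' depends only on which ranks each population occupies.
#'
#' Ties between angles (possible with quantized phases) are broken by a
#' random shuffle among the tied values, seeded by `tie_seed` for
#' reproducibility. Average ranks are deliberately not used: they would
#' destroy the exact equal spacing of scores that the null distribution of
#' the test statistic assumes.
#'
#' @param pop1,pop2 [angle_sample]s (or numeric angle vectors, radians).
#' @param tie_seed Integer seed controlling tie-breaking; ignored when all
#'   pooled angles are distinct.
#'
#' @return An object of class `ranked_pair`: a list with elements
#'   `scores_1`, `scores_2` (uniform scores per population, radians),
#'   `n1`, `n2`, `n` and `tie_seed`.
#'
#' @examples
#' rp <- circular_ranks(c(0.1, 0.3), c(0.2, 0.4))
#' rp$scores_1 # pi/2, 3*pi/2
#' @export
circular_ranks <- function(pop1, pop2, tie_seed = NULL) {
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  n1 <- length(pop1)
  n2 <- length(pop2)
  n <- n1 + n2
  pooled <- c(as.numeric(pop1), as.numeric(pop2))
  has_ties <- anyDuplicated(pooled) > 0L
  r <- if (has_ties) {
    with_seed(tie_seed, rank(pooled, ties.method = "random"))
  } else {
    rank(pooled)
  }
  beta <- 2 * pi * r / n
  structure(
    list(
      scores_1 = beta[seq_len(n1)],
      scores_2 = beta[n1 + seq_len(n2)],
      n1 = n1, n2 = n2, n = n,
      tie_seed = if (has_ties) tie_seed else NULL
    ),
    class = "ranked_pair"
  )
}

#' Uniform scores test statistic
#'
#' From the uniform scores of population `k`, computes the squared resultant
#' \deqn{R_k^2 = \Big(\sum_i \cos\beta_i^{(k)}\Big)^2 +
#'              \Big(\sum_i \sin\beta_i^{(k)}\Big)^2}
#' and its normalization
#' \deqn{R_k^* = \frac{2 (n - 1) R_k^2}{n_1 n_2},}
#' whose null distribution approaches chi-squared with 2 degrees of freedom
#' as `n = n1 + n2` grows (the classical two-sample uniform-scores /
#' Wheeler--Watson--Mardia result). Because all `n` uniform scores sum to
#' the zero vector, the two population resultants are equal and opposite,
#' so `R_squared` does not depend on `k`.
#'
#' The `normalization` argument controls how the resultant enters the
#' normalized statistic: `"squared"` (default) uses \eqn{R_k^2} as above,
#' which is the form with the chi-squared(2) limit; `"root"` substitutes
#' the unsquared length \eqn{R_k} and is provided only for comparison with
#' presentations that write the normalization in terms of `R` -- it does
#' not have the chi-squared(2) limit and is never used by the test.
#'
#' @param ranked A `ranked_pair` from [circular_ranks()].
#' @param k Which population's scores to use, 1 or 2 (the statistic is the
#'   same either way; see above).
#' @param normalization `"squared"` or `"root"`.
#'
#' @return A list with `R_squared` and `R_star`, both non-negative.
#'
#' @examples
#' rp <- circular_ranks(c(0.1, 0.2), c(3.2, 3.3))
#' ust_statistic(rp)
#' @export
ust_statistic <- function(ranked, k = 1L, normalization = c("squared", "root")) {
  stopifnot(inherits(ranked, "ranked_pair"))
  normalization <- match.arg(normalization)
  if (!k %in% c(1L, 2L)) stop("`k` must be 1 or 2", call. = FALSE)
  beta <- if (k == 1L) ranked$scores_1 else ranked$scores_2
  r2 <- sum(cos(beta))^2 + sum(sin(beta))^2
  num <- if (normalization == "squared") r2 else sqrt(r2)
  list(
    R_squared = r2,
    R_star = 2 * (ranked$n - 1) * num / (ranked$n1 * ranked$n2)
  )
}

#' Uniform scores test for phase locking (two-sample test on the circle)
#'
#' Tests whether two populations of phase angles -- typically trial-wise
#' phase differences from a stimulus period and from an empirical baseline
#' such as a prestimulus interval -- come from the same circular
#' distribution. The angles are jointly transformed to uniform scores
#' ([circular_ranks()]); the squared resultant of one population's scores,
#' normalized to `R*` ([ust_statistic()]), is referred either to its
#' asymptotic chi-squared(2) distribution or to the permutation
#' distribution over reassignments of scores to populations.
#'
#' Modes:
#' * `"asymptotic"`: p-value from the upper tail of chi-squared with 2
#'   degrees of freedom, appropriate for `n = n1 + n2 > 40`.
#' * `"permutation"`: Monte-Carlo permutation of population labels over the
#'   fixed score configuration, add-one p-value
#'   `(1 + #\{R*_perm >= R*_obs\}) / (1 + n_permutations)`. When the full
#'   enumeration `choose(n, n1)` does not exceed `exact_cap`, all label
#'   assignments are enumerated instead and the p-value is exact.
#' * `"auto"` (default): asymptotic when `n > 40`, otherwise
#'   permutation/exact.
#'
#' The test is symmetric in its two arguments and invariant under a common
#' rotation of all angles. It detects any distributional difference
#' (concentration or mean direction) but does not by itself say which
#' population is more strongly phase locked.
#'
#' @inheritParams circular_ranks
#' @param mode `"auto"`, `"asymptotic"` or `"permutation"`.
#' @param n_permutations Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer seed for the permutation draw and tie-breaking.
#' @param exact_cap Largest `choose(n, n1)` for which full enumeration
#'   replaces Monte-Carlo permutation (default `1e5`).
#'
#' @return A [test_result] with `method = "USTPL"`, the observed `R*`
#'   statistic, the p-value, and the resolution mode actually used
#'   (`"asymptotic"`, `"permutation"` or `"exact"`).
#'
#' @examples
#' stim <- rvonmises(25, theta = pi / 4, kappa = 4, seed = 1)
#' base <- rvonmises(25, theta = 0, kappa = 4, seed = 2)
#' ustpl_test(stim, base)
#' @export
ustpl_test <- function(pop1, pop2, mode = c("auto", "asymptotic", "permutation"),
                       n_permutations = 1000L, seed = NULL,
                       exact_cap = 1e5) {
  mode <- match.arg(mode)
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  n1 <- length(pop1)
  n2 <- length(pop2)
  if (n1 < 2L || n2 < 2L) {
    stop("each population needs at least 2 angles", call. = FALSE)
  }
  n <- n1 + n2
  if (mode == "auto") {
    mode <- if (n > 40L) "asymptotic" else "permutation"
  }
  ranked <- circular_ranks(pop1, pop2, tie_seed = derive_seed(seed, "ties"))
  obs <- ust_statistic(ranked)$R_star

  if (mode == "asymptotic") {
    p <- stats::pchisq(obs, df = 2, lower.tail = FALSE)
    return(test_result("USTPL", obs, p,
      n1 = n1, n2 = n2, mode = "asymptotic"
    ))
  }

  n_permutations <- check_count(n_permutations, "n_permutations")
  # Scores are fixed under relabelling: permuting trials only changes which
  # ranks belong to population 1, so work directly on the score vector.
  beta <- c(ranked$scores_1, ranked$scores_2)
  stat_of <- function(idx) {
    b <- beta[idx]
    2 * (n - 1) * (sum(cos(b))^2 + sum(sin(b))^2) / (n1 * n2)
  }
  if (choose(n, n1) <= exact_cap) {
    assignments <- utils::combn(n, n1)
    null_values <- apply(assignments, 2L, stat_of)
    p <- mean(null_values >= obs - 1e-12)
    return(test_result("USTPL", obs, p,
      n1 = n1, n2 = n2, mode = "exact",
      n_permutations = ncol(assignments), seed = seed
    ))
  }
  null_values <- with_seed(derive_seed(seed, "perm"), {
    vapply(
      seq_len(n_permutations),
      function(i) stat_of(sample.int(n, n1)),
      numeric(1)
    )
  })
  p <- (1 + sum(null_values >= obs - 1e-12)) / (1 + n_permutations)
  test_result("USTPL", obs, p,
    n1 = n1, n2 = n2, mode = "permutation",
    n_permutations = n_permutations, seed = seed
  )
}

#' Permutation p-value for an arbitrary two-sample statistic
#'
#' Generic label-permutation test: pools the two angle populations, redraws
#' the population labels preserving group sizes, and recomputes
#' `statistic_fn` for each permutation. The p-value uses the add-one
#' (conservative) estimator `(1 + #\{null >= observed\}) /
#' (1 + n_permutations)`, so it is never zero. Used by the significance
#' wrappers for PLI and PBI, which have no analytic null distribution.
#'
#' @param statistic_fn Function taking two angle vectors and returning a
#'   single number; larger values must indicate a stronger effect.
#' @inheritParams ustpl_test
#'
#' @return A list with `p` (the add-one p-value), `observed` and
#'   `null_values` (numeric vector of length `n_permutations`).
#'
#' @examples
#' f <- function(a, b) abs(plv(a) - plv(b))
#' permutation_pvalue(f, rvonmises(20, 0, 4, seed = 1),
#'   rvonmises(20, 0, 0, seed = 2),
#'   seed = 3
#' )$p
#' @export
permutation_pvalue <- function(statistic_fn, pop1, pop2,
                               n_permutations = 1000L, seed = NULL) {
  stopifnot(is.function(statistic_fn))
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  n_permutations <- check_count(n_permutations, "n_permutations")
  n1 <- length(pop1)
  pooled <- c(as.numeric(pop1), as.numeric(pop2))
  n <- length(pooled)
  observed <- statistic_fn(as.numeric(pop1), as.numeric(pop2))
  null_values <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, n1)
      val <- tryCatch(
        statistic_fn(pooled[idx], pooled[-idx]),
        error = function(e) {
          stop(sprintf(
            "statistic_fn failed on permutation %d: %s", i,
            conditionMessage(e)
          ), call. = FALSE)
        }
      )
      val
    }, numeric(1))
  })
  p <- (1 + sum(null_values >= observed - 1e-12)) / (1 + n_permutations)
  list(p = p, observed = observed, null_values = null_values)
}

#' Container for a two-sample test outcome
#'
#' Light-weight record shared by all tests and significance wrappers in the
#' package.
#'
#' @param method One of `"USTPL"`, `"PLV"`, `"PLI"`, `"WPLI"`, `"PBI"`.
#' @param statistic Observed statistic value.
#' @param p_value P-value in `(0, 1]`, or `NULL` for raw index methods.
#' @param n1,n2 Population sizes.
#' @param mode How the p-value was obtained: `"asymptotic"`,
#'   `"permutation"` or `"exact"`.
#' @param n_permutations,seed Permutation metadata, when applicable.
#' @param extra Optional named list of method-specific metadata (e.g. the
#'   signed mean for PLI).
#'
#' @return An object of class `test_result` (a named list).
#' @export
test_result <- function(method, statistic, p_value = NULL, n1, n2,
                        mode = NA_character_, n_permutations = NULL,
                        seed = NULL, extra = NULL) {
  method <- match.arg(method, c("USTPL", "PLV", "PLI", "WPLI", "PBI"))
  if (!is.null(p_value)) {
    stopifnot(is.numeric(p_value), length(p_value) == 1L)
    if (!(p_value > 0 && p_value <= 1)) {
      stop("p_value must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      method = method, statistic = statistic, p_value = p_value,
      n1 = as.integer(n1), n2 = as.integer(n2), mode = mode,
      n_permutations = n_permutations, seed = seed, extra = extra
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$method))
  cat(sprintf("  statistic = %.6g\n", x$statistic))
  if (!is.null(x$p_value)) {
    cat(sprintf("  p value   = %.4g  (%s", x$p_value, x$mode))
    if (!is.null(x$n_permutations)) {
      cat(sprintf(", %d permutations", x$n_permutations))
    }
    cat(")\n")
  }
  cat(sprintf("  n1 = %d, n2 = %d\n", x$n1, x$n2))
  invisible(x)
}
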