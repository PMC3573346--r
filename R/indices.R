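#' Phase lag index
#'
#' The PLI is the magnitude of the mean sign of the sine of the phase
#' differences:
#' \deqn{\mathrm{PLI} = \left| \langle \mathrm{sign}[\sin\theta] \rangle \right|.}
#' It measures the asymmetry of phase differences around the real axis:
#' coupling at exactly 0 or \eqn{\pi} lag -- the signature of instantaneous
#' crosstalk or volume conduction -- contributes nothing, which is the
#' index's reason for existing. Angles whose sine is exactly zero
#' (\eqn{\theta \in \{0, \pi\}}) contribute 0 to the average, diluting the
#' index toward zero rather than being dropped, so the trial count stays
#' honest.
#'
#' Only the magnitude is reported (leading and lagging are not
#' distinguished); the signed mean is available via `signed_mean_sign()`
#' when directionality matters.
#'
#' Note PLI is *not* invariant under a common rotation of the angles:
#' rotating all phase differences changes which trials lead and which lag.
#'
#' @param sample An [angle_sample] or numeric vector of angles (radians).
#'
#' @return A number in `[0, 1]`.
#'
#' @examples
#' pli(c(0.3, 1.2, 2.9)) # all sines positive -> 1
#' pli(c(pi / 4, -pi / 4)) # signs cancel -> 0
#' @export
pli <- function(sample) {
  abs(signed_mean_sign(sample))
}

#' @rdname pli
#' @export
signed_mean_sign <- function(sample) {
  sample <- as_angle_sample(sample)
  mean(sign(sin(as.numeric(sample))))
}

#' Weighted phase lag index
#'
#' WPLI weights each trial's sign contribution by the magnitude of the
#' imaginary part of the cross-spectral term \eqn{X = A e^{i\theta}}:
#' \deqn{\mathrm{WPLI} =
#'   \frac{\left| \langle |\Im\{X\}| \, \mathrm{sign}[\sin\theta] \rangle \right|}
#'        {\langle |\Im\{X\}| \rangle}
#'   = \frac{|\langle \Im\{X\} \rangle|}{\langle |\Im\{X\}| \rangle}.}
#' Trials whose cross-spectrum lies near the real axis (small
#' \eqn{|\Im\{X\}|}, i.e. near-zero-lag) are down-weighted, making the
#' index less sensitive to noise around the crosstalk axis. When all
#' imaginary magnitudes are equal the weighting degenerates and WPLI
#' equals PLI.
#'
#' @param values Complex vector of per-trial cross-spectral terms.
#'
#' @return A number in `[0, 1]`.
#'
#' @examples
#' wpli(c(2i, -1i)) # |2 - 1| / (2 + 1) = 1/3
#' @export
wpli <- function(values) {
  if (!is.complex(values) || length(values) < 1L) {
    stop("`values` must be a non-empty complex vector", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("all values must be finite", call. = FALSE)
  im <- Im(values)
  denom <- mean(abs(im))
  if (denom == 0) {
    stop("WPLI is undefined: all imaginary parts are exactly zero (0/0)",
      call. = FALSE
    )
  }
  abs(mean(im)) / denom
}

#' Phase bifurcation index
#'
#' Contrasts the phase locking of two trial populations against their
#' pooled phase locking:
#' \deqn{\mathrm{PBI} = (\mathrm{PLV}_1 - \mathrm{PLV}_{all})
#'                      (\mathrm{PLV}_2 - \mathrm{PLV}_{all}),}
#' where \eqn{\mathrm{PLV}_{all}} is computed on the concatenation of the
#' two populations. The index is positive when both populations are
#' individually locked at different preferred phases (the pooled PLV drops
#' below both), near zero when locking is unchanged, and negative when one
#' population is locked and the other is not.
#'
#' @param pop1,pop2 [angle_sample]s (or numeric angle vectors, radians).
#'
#' @return A number in `[-1, 1]`. Symmetric in its arguments.
#'
#' @examples
#' pbi(rep(0, 10), rep(pi, 10)) # bimodal split -> 1
#' @export
pbi <- function(pop1, pop2) {
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  plv_all <- plv(c(as.numeric(pop1), as.numeric(pop2)))
  (plv(pop1) - plv_all) * (plv(pop2) - plv_all)
}

#' Permutation significance for PLI and PBI
#'
#' PLI and PBI do not come with an analytic null distribution, so their
#' significance is assessed by a label-permutation test
#' ([permutation_pvalue()]): trials are pooled and population labels
#' redrawn, preserving group sizes. The permuted statistic is
#' `|PLI(pop1) - PLI(pop2)|` for PLI and `|PBI(pop1, pop2)|` for PBI;
#' 1000 permutations by default.
#'
#' @inheritParams ustpl_test
#'
#' @return A [test_result] with permutation metadata; `statistic` is the
#'   observed permuted quantity (see above), with the raw index values in
#'   `$extra`.
#'
#' @examples
#' stim <- rvonmises(30, theta = 0, kappa = 8, seed = 1)
#' base <- rvonmises(30, theta = 0, kappa = 0, seed = 2)
#' pbi_significance(stim, base, n_permutations = 200, seed = 3)
#' @export
pli_significance <- function(pop1, pop2, n_permutations = 1000L, seed = NULL) {
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  res <- permutation_pvalue(
    function(a, b) abs(pli(a) - pli(b)),
    pop1, pop2,
    n_permutations = n_permutations, seed = seed
  )
  test_result("PLI", res$observed, res$p,
    n1 = length(pop1), n2 = length(pop2), mode = "permutation",
    n_permutations = n_permutations, seed = seed,
    extra = list(
      pli_1 = pli(pop1), pli_2 = pli(pop2),
      signed_mean_1 = signed_mean_sign(pop1),
      signed_mean_2 = signed_mean_sign(pop2)
    )
  )
}

#' @rdname pli_significance
#' @export
pbi_significance <- function(pop1, pop2, n_permutations = 1000L, seed = NULL) {
  pop1 <- as_angle_sample(pop1, "pop1")
  pop2 <- as_angle_sample(pop2, "pop2")
  res <- permutation_pvalue(
    function(a, b) abs(pbi(a, b)),
    pop1, pop2,
    n_permutations = n_permutations, seed = seed
  )
  test_result("PBI", res$observed, res$p,
    n1 = length(pop1), n2 = length(pop2), mode = "permutation",
    n_permutations = n_permutations, seed = seed,
    extra = list(pbi = pbi(pop1, pop2))
  )
}
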