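#' Von Mises density
#'
#' Density of the von Mises distribution, the circular analogue of the
#' normal distribution:
#' \deqn{f(x \mid \theta, \kappa) =
#'   \frac{e^{\kappa \cos(x - \theta)}}{2 \pi I_0(\kappa)},}
#' where \eqn{\theta} is the mean direction, \eqn{\kappa \ge 0} the
#' concentration and \eqn{I_0} the modified Bessel function of order 0.
#' At \eqn{\kappa = 0} the density reduces to the circular uniform
#' \eqn{1 / 2\pi}. For large \eqn{\kappa} the Bessel term is evaluated on
#' the exponentially scaled branch to avoid overflow.
#'
#' @param x Numeric vector of angles (radians); any finite values, wrapped
#'   internally.
#' @param theta Mean direction in radians.
#' @param kappa Concentration parameter, a single non-negative number.
#'
#' @return Numeric vector of densities, same length as `x`.
#'
#' @examples
#' dvonmises(0, theta = 0, kappa = 0) # 1 / (2 * pi)
#' dvonmises(c(0, pi), theta = 0, kappa = 2)
#' @seealso [rvonmises()] for sampling, [plv()] for the resultant length.
#' @export
dvonmises <- function(x, theta, kappa) {
  check_scalar(theta, "theta")
  check_scalar(kappa, "kappa")
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  # exp(kappa * (cos(..) - 1)) / (2 pi I0(kappa) exp(-kappa)) is stable in kappa
  exp(kappa * (cos(x - theta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Draws i.i.d. angles using the Best--Fisher rejection sampler (wrapped
#' Cauchy envelope). `kappa = 0` falls back to the circular uniform.
#'
#' @inheritParams dvonmises
#' @param n Number of draws, a positive integer.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return An [angle_sample] of `n` angles in `[0, 2*pi)`.
#'
#' @examples
#' a <- rvonmises(100, theta = 0, kappa = 4, seed = 1)
#' plv(a) # close to besselI(4, 1) / besselI(4, 0)
#' @export
rvonmises <- function(n, theta, kappa, seed = NULL) {
  check_scalar(theta, "theta")
  check_scalar(kappa, "kappa")
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  n <- check_count(n, "n")
  with_seed(seed, {
    if (kappa == 0) {
      return(angle_sample(stats::runif(n, 0, 2 * pi)))
    }
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r0 <- (1 + b^2) / (2 * b)
    out <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- n - got
      z <- cos(pi * stats::runif(m))
      f <- (1 + r0 * z) / (r0 + z)
      cc <- kappa * (r0 - f)
      u2 <- stats::runif(m)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      k <- sum(ok)
      if (k > 0L) {
        sgn <- sign(stats::runif(k) - 0.5)
        out[(got + 1L):(got + k)] <- theta + sgn * acos(f[ok])
        got <- got + k
      }
    }
    angle_sample(out)
  })
}

#' Phase locking value
#'
#' The PLV is the length of the mean resultant vector of the phase angles:
#' each angle \eqn{\theta_i} is taken as a unit vector
#' \eqn{(\cos\theta_i, \sin\theta_i)} and the magnitude of the trial
#' average is returned. It ranges from 0 (no phase consistency) to 1
#' (all angles identical, complete phase locking).
#'
#' @param sample An [angle_sample] or numeric vector of angles (radians).
#'
#' @return A single number in `[0, 1]`.
#'
#' @examples
#' plv(c(0, 0, 0)) # 1
#' plv(c(0, pi)) # 0
#' plv(c(0, pi / 2)) # sqrt(2) / 2
#' @export
plv <- function(sample) {
  sample <- as_angle_sample(sample)
  sqrt(mean(cos(sample))^2 + mean(sin(sample))^2)
}

#' Rayleigh significance of a phase locking value
#'
#' Approximate p-value of the Rayleigh test of circular uniformity given an
#' observed PLV on `n` trials. Two formulas are available:
#'
#' * `"standard"` (default): `exp(-n * plv^2)`, the conventional large-`n`
#'   approximation for the Rayleigh statistic. Valid for roughly `n > 50`;
#'   conservative use at smaller `n` is common in the phase-locking
#'   literature.
#' * `"as_printed"`: `exp(-plv)`, a simplification that appears in some
#'   published accounts of PLV significance. It does not depend on the
#'   number of trials and is not a calibrated p-value; it is provided
#'   verbatim for comparability and never used by default. See the methods
#'   vignette for the discrepancy between the two forms.
#'
#' @param plv_value Observed PLV, in `[0, 1]`.
#' @param n Number of trials the PLV was computed from.
#' @param formula `"standard"` or `"as_printed"`.
#'
#' @return A p-value in `(0, 1]`.
#'
#' @examples
#' rayleigh_pvalue(0.5, n = 40)
#' rayleigh_pvalue(0.5, n = 40, formula = "as_printed")
#' @export
rayleigh_pvalue <- function(plv_value, n, formula = c("standard", "as_printed")) {
  formula <- match.arg(formula)
  if (!is.numeric(plv_value) || length(plv_value) != 1L ||
    !is.finite(plv_value) || plv_value < 0 || plv_value > 1) {
    stop("`plv_value` must be a single number in [0, 1]", call. = FALSE)
  }
  n <- check_count(n, "n")
  switch(formula,
    standard = exp(-n * plv_value^2),
    as_printed = exp(-plv_value)
  )
}

# --- small shared validators -------------------------------------------------

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
    x != as.integer(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  as.integer(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a top-level seed, so that pipeline
# stages are independently reproducible. Kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
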