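#' Construct a sample of phase angles
#'
#' `angle_sample()` is the unit of data for all statistical tests in this
#' package: a finite set of phase angles on the circle, typically trial-wise
#' phase differences between two regions of interest. Angles are stored in
#' radians, wrapped to the half-open fundamental domain `[0, 2*pi)`. The
#' anchor at 0 matters for the circular rank transformation (ranking starts
#' from zero in the positive direction), so wrapping happens silently on
#' construction rather than being left to callers.
#'
#' @param angles Numeric vector of phase angles in radians. Any finite real
#'   values are accepted and wrapped to `[0, 2*pi)`.
#' @param label Optional single string tagging the population the angles were
#'   sampled from (e.g. `"prestim"`, `"stim"`).
#'
#' @return An object of class `angle_sample`: a numeric vector of wrapped
#'   angles with a `label` attribute.
#'
#' @examples
#' a <- angle_sample(c(-pi / 4, 0, pi / 4), label = "stim")
#' as.numeric(a)
#' @export
angle_sample <- function(angles, label = NULL) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L) {
    stop("an angle sample must contain at least one angle", call. = FALSE)
  }
  if (!all(is.finite(angles))) {
    stop("all angles must be finite", call. = FALSE)
  }
  if (!is.null(label)) {
    stopifnot(is.character(label), length(label) == 1L)
  }
  structure(wrap_angle(angles), label = label, class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<angle_sample> n = %d%s\n", length(x),
    if (is.null(lab)) "" else sprintf(", label = \"%s\"", lab)
  ))
  print(as.numeric(x), ...)
  invisible(x)
}

# Wrap radians into [0, 2*pi). `%%` already returns values in [0, 2*pi) for
# finite input except when rounding puts x %% 2pi == 2pi for tiny negatives.
wrap_angle <- function(x) {
  out <- x %% (2 * pi)
  out[out >= 2 * pi] <- 0
  out
}

as_angle_sample <- function(x, arg = "sample") {
  if (inherits(x, "angle_sample")) return(x)
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric angles or an angle_sample", arg),
      call. = FALSE
    )
  }
  angle_sample(x)
}
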