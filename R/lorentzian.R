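#' Sample excitabilities from a Lorentzian distribution
#'
#' Draws the per-neuron excitability parameters \eqn{\eta_j} from the
#' Lorentzian (Cauchy) density
#' \deqn{L(\eta) = \frac{1}{\pi}\frac{\Delta}{(\eta-\bar\eta)^2+\Delta^2}.}
#' The default deterministic mode places the values on the quantile grid
#' \eqn{\eta_j = \bar\eta + \Delta\,\tan\!\big(\tfrac{\pi}{2}
#' \tfrac{2j - n - 1}{n + 1}\big)}, a quenched, reproducible sampling whose
#' empirical distribution converges to \eqn{L}.  Random mode draws i.i.d.
#' Cauchy variates, reproducible under a fixed seed.
#'
#' @param center Distribution centre \eqn{\bar\eta}.
#' @param half_width Half-width \eqn{\Delta} (>= 0).
#' @param count Number of values (integer >= 1).
#' @param mode `"deterministic"` (quantile grid, default) or `"random"`.
#' @param seed Optional integer seed used in random mode.
#'
#' @return Numeric vector of length `count`.
#' @examples
#' eta <- sample_lorentzian(-5, 1, 1001)
#' median(eta)  # -5 by symmetry of the quantile grid
#' @export
sample_lorentzian <- function(center, half_width, count,
                              mode = c("deterministic", "random"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(center)) stop("'center' must be finite")
  if (!is.finite(half_width) || half_width < 0)
    stop("'half_width' must be >= 0")
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("'count' must be an integer >= 1")
  if (half_width == 0) return(rep(center, count))
  if (mode == "deterministic") {
    j <- seq_len(count)
    center + half_width * tan(pi / 2 * (2 * j - count - 1) / (count + 1))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    center + half_width * stats::rcauchy(count)
  }
}

#' Proportion of neurons that are not intrinsic oscillators
#'
#' A QIF neuron with zero synaptic input fires periodically only when its
#' excitability is positive.  Under Lorentzian heterogeneity the fraction
#' of non-oscillating neurons (those with \eqn{\eta < 0}) has the closed
#' form
#' \deqn{\int_{-\infty}^{0} L(\eta)\,d\eta =
#'   \frac{1}{\pi}\Big(\frac{\pi}{2} -
#'   \arctan\frac{\bar\eta}{\Delta}\Big),}
#' which is strictly positive whenever there is any heterogeneity: the
#' network rhythm is an emergent property, not synchrony of cellular
#' oscillators.
#'
#' @inheritParams sample_lorentzian
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_non_oscillatory(0, 1)    # 0.5
#' fraction_non_oscillatory(-5, 1)   # ~0.937
#' @export
fraction_non_oscillatory <- function(center, half_width) {
  if (!is.finite(half_width) || half_width <= 0)
    stop("'half_width' must be > 0")
  if (!is.finite(center)) stop("'center' must be finite")
  (pi / 2 - atan(center / half_width)) / pi
}
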