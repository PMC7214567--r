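#' Principal branch of the Lambert W function on [-1/e, 0]
#'
#' Solves `w * exp(w) = z` for the principal branch `W0`, the branch with
#' `w in [-1, 0]` on the domain needed to invert the paralyzable model
#' (`z = -R' * tau` always lies in `[-1/e, 0]`).  Halley iterations seeded
#' from the branch-point expansion near `z = -1/e` and from `w = z`
#' elsewhere; convergence is quadratic-plus and verified against an
#' independent bisection in the test suite.
#'
#' @param z numeric vector with `-1/e <= z <= 0`.
#' @param tol relative convergence tolerance.
#' @return `W0(z)`, in `[-1, 0]`.
#' @examples
#' lambert_w0(-0.3064954)  # ~ -0.5108256 = ln(0.6)
#' @export
lambert_w0 <- function(z, tol = 1e-12) {
  em1 <- exp(-1)
  if (any(!is.finite(z))) stop("'z' must be finite")
  if (any(z < -em1 - 1e-12))
    stop("no real solution: z below the branch point -1/e")
  if (any(z > 0)) stop("'z' must be <= 0 (observed rates are non-negative)")
  z <- pmax(z, -em1)
  # branch-point series seed: w = -1 + p - p^2/3 + 11 p^3/72, p = sqrt(2(1+e z))
  p <- sqrt(pmax(2 * (1 + exp(1) * z), 0))
  w <- ifelse(z < -0.25,
              -1 + p * (1 + p * (-1 / 3 + p * 11 / 72)),
              z)
  near_branch <- p < 1e-6  # series already accurate to O(p^4); Halley degenerate
  for (i in seq_len(60L)) {
    ew <- exp(w)
    f <- w * ew - z
    # Halley step
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- ifelse(near_branch | denom == 0, 0, f / denom)
    w <- w - step
    if (all(abs(step) <= tol * pmax(abs(w), 1e-300))) break
  }
  pmin(pmax(w, -1), 0)
}

#' N-term Taylor series of W0 around zero
#'
#' `W0(z) ~ sum_{n=1}^{N} (-n)^(n-1) / n! * z^n`, convergent for
#' `|z| < 1/e`.  This is the truncated-series correction path; the exact
#' solver [lambert_w0()] is the reference.
#'
#' @inheritParams lambert_w0
#' @param n_terms number of series terms N (>= 1).
#' @return Truncated series value.
#' @export
lambert_w0_series <- function(z, n_terms = 10L) {
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L) stop("'n_terms' must be >= 1")
  n <- seq_len(n_terms)
  # (-n)^(n-1)/n! computed in log space for numerical hygiene at large N
  coef <- (-1)^(n - 1) * exp((n - 1) * log(n) - lgamma(n + 1))
  out <- numeric(length(z))
  for (k in n) out <- out + coef[k] * z^k
  out
}

#' Settings for the dead-time correction
#'
#' @param method `"exact"` (iterative Lambert-W solve, the reference) or
#'   `"truncated_series"` (N-term Taylor sum).
#' @param n_terms series truncation N (default 10).
#' @param branch_margin fraction of `1/e` in (0, 1); observed `R' * tau`
#'   above `branch_margin / e` is flagged with a warning because the two
#'   solution branches coincide at the maximum and floating-point noise can
#'   flip sides.
#' @param solver_tolerance relative tolerance of the exact inverse.
#' @return An object of class `correction_settings`.
#' @export
correction_settings <- function(method = c("exact", "truncated_series"),
                                n_terms = 10L, branch_margin = 0.999,
                                solver_tolerance = 1e-12) {
  method <- match.arg(method)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L) stop("'n_terms' must be >= 1")
  if (!(branch_margin > 0) || !(branch_margin < 1))
    stop("'branch_margin' must be a fraction of 1/e in (0, 1)")
  structure(list(method = method, n_terms = n_terms,
                 branch_margin = branch_margin,
                 solver_tolerance = solver_tolerance),
            class = "correction_settings")
}

#' Dead-time-corrected (true) count rate
#'
#' Inverts the paralyzable model `R' = Rt * exp(-Rt * tau)` on the
#' sub-maximum branch: `Rt = -W0(-R' * tau) / tau`.  Rates with
#' `R' * tau > 1/e` exceed the theoretical maximum observed rate and raise
#' an error rather than being clamped: from a single reading one cannot
#' tell whether the detector is above or below the peak.
#'
#' @param observed observed count rate, cps; vectorised.
#' @param tau resolving time in seconds (> 0).
#' @param settings a [correction_settings()] object.
#' @return True count rate in cps, always `<= 1/tau`.
#' @examples
#' correct_rate(observed_rate(1e5, 1.3e-6), 1.3e-6)  # 1e5
#' @export
correct_rate <- function(observed, tau, settings = correction_settings()) {
  if (any(observed < 0)) stop("'observed' must be >= 0")
  if (any(!(tau > 0))) stop("'tau' must be > 0")
  stopifnot(inherits(settings, "correction_settings"))
  em1 <- exp(-1)
  x <- observed * tau
  if (any(x > em1 * (1 + 1e-12)))
    stop("observed rate above theoretical maximum (e*tau)^-1; ",
         "the paralyzable model cannot be inverted")
  x <- pmin(x, em1)
  if (any(x > settings$branch_margin * em1))
    warning("observed rate within ",
            format(100 * (1 - settings$branch_margin)),
            "% of the maximum: solution branch ambiguous near R'_max")
  rt_tau <- switch(settings$method,
    exact = -lambert_w0(-x, tol = settings$solver_tolerance),
    truncated_series = -lambert_w0_series(-x, settings$n_terms))
  rt_tau / tau
}

#' Activity estimated from an observed count rate
#'
#' Dead-time-corrects the observed rate and converts to activity through
#' the window sensitivity: `A = Rt * F * exp(mu_e d) / C`.  With both
#' quantification factors at 1 (point source in air) this is the plain
#' corrected-rate-over-sensitivity estimate.
#'
#' @inheritParams correct_rate
#' @param sensitivity window sensitivity C in cps/Bq (> 0).
#' @param factors a [quantification_factors()] object.
#' @return Activity in Bq.
#' @export
estimate_activity <- function(observed, tau, sensitivity,
                              factors = quantification_factors(),
                              settings = correction_settings()) {
  if (any(!(sensitivity > 0))) stop("'sensitivity' must be > 0")
  stopifnot(inherits(factors, "quantification_factors"))
  correct_rate(observed, tau, settings) *
    factors$background_tissue_factor * factors$absorption_factor /
    sensitivity
}

#' Dead-time correction factor Rt / R'
#'
#' @inheritParams correct_rate
#' @return Dimensionless factor >= 1; 1 at zero observed rate.
#' @export
correction_factor <- function(observed, tau,
                              settings = correction_settings()) {
  rt <- correct_rate(observed, tau, settings)
  ifelse(observed == 0, 1, rt / observed)
}
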