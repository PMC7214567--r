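# Dead-time estimators: dual/triple-source method, graphical log-linear
# fit of a decaying source, maximum-count-rate method, and window-fraction
# (pile-up) diagnostics.

#' Dual-source dead-time estimate
#'
#' Resolving time from two sources measured separately and together:
#' `tau = 2 R'_12 / (R'_1 + R'_2)^2 * ln((R'_1 + R'_2) / R'_12)`.
#' Exact (up to counting noise) for equal-activity sources under the
#' paralyzable model; for unequal sources the relative error is of order
#' [dual_source_error_bound()].  All rates must be background-subtracted.
#'
#' @param r1,r2 net observed rates of the two sources alone, cps (> 0).
#' @param r12 net observed rate with both sources present, cps (> 0).
#' @param total_activity optional activity (Bq) the estimate refers to,
#'   carried through for reporting.
#' @return An object of class `dual_source_result` with fields `tau` (s),
#'   `total_activity`, `component_rates` and `valid`.  `r12 >= r1 + r2`
#'   would imply `tau <= 0` and yields a flagged invalid result rather
#'   than an error.
#' @examples
#' tau <- 1e-6
#' r1 <- observed_rate(1e5, tau); r12 <- observed_rate(2e5, tau)
#' dual_source_tau(r1, r1, r12)$tau  # 1e-6, exactly
#' @export
dual_source_tau <- function(r1, r2, r12, total_activity = NA_real_) {
  if (!(r1 > 0) || !(r2 > 0) || !(r12 > 0))
    stop("all rates must be > 0 (background-subtracted)")
  tau <- 2 * r12 / (r1 + r2)^2 * log((r1 + r2) / r12)
  structure(list(tau = tau, total_activity = total_activity,
                 component_rates = c(r1 = r1, r2 = r2, r12 = r12),
                 valid = is.finite(tau) && tau > 0),
            class = "dual_source_result")
}

#' @export
print.dual_source_result <- function(x, ...) {
  cat(sprintf("<dual-source estimate: tau = %.4g us%s%s>\n",
              x$tau * 1e6,
              if (is.na(x$total_activity)) ""
              else sprintf(" at %.4g MBq", x$total_activity / 1e6),
              if (x$valid) "" else " [INVALID: r12 >= r1 + r2]"))
  invisible(x)
}

#' Leading-order error bound of the dual-source estimate
#'
#' For unequal true rates the relative error of [dual_source_tau()] is of
#' order `(Rt1 - Rt2)^2 / (4 (Rt1 + Rt2)^2)`; it vanishes for equal
#' sources and stays below 1% while the single-source share of the total
#' lies between 44% and 55%.
#'
#' @param rt1,rt2 true rates of the two sources, cps (> 0).
#' @return Dimensionless leading-order relative error.
#' @export
dual_source_error_bound <- function(rt1, rt2) {
  if (any(!(rt1 > 0)) || any(!(rt2 > 0))) stop("rates must be > 0")
  (rt1 - rt2)^2 / (4 * (rt1 + rt2)^2)
}

#' Dual-source estimates from a triple-source measurement schedule
#'
#' Walks a measurement series acquired with the source-combination
#' pattern 1, 2, 1+2, 3, 1+2+3 (possibly repeated through decay) and emits
#' one dual-source dead-time estimate per combined frame: frames 1, 2 and
#' 1+2 give a tau at activity level A(1+2), and frames 1+2, 3 and 1+2+3 a
#' tau at A(1+2+3).  More generally, every frame whose source set splits
#' into two disjoint sets that were themselves measured is used, the
#' component frames being matched by nearest acquisition time.  Because
#' the component frames are acquired minutes before the combined frame,
#' their net rates are decay-aligned: scaled by the ratio of their sources'
#' activity at the combined frame to that at their own frame (a <= 1%
#' effect for 99mTc at these spacings).  Rates are background-subtracted
#' with the pooled [background_rate()] when background frames exist.
#'
#' @param series a [measurement_series()].
#' @param detector,window labels selecting the frames.
#' @return A data frame of class `dual_source_schedule` with one row per
#'   combined frame: `combination`, `t_start` (s), `total_activity` (Bq),
#'   the three net rates (cps), `tau` (s) and `valid`.  Combined frames
#'   with no measured decomposition are skipped with a message.
#' @export
triple_source_schedule <- function(series, detector, window) {
  stopifnot(inherits(series, "measurement_series"))
  m <- series$measurements
  sub <- m[m$detector_id == detector & m$window == window, , drop = FALSE]
  if (!nrow(sub)) stop("no frames for that detector/window")
  bg <- tryCatch(background_rate(series, detector, window),
                 error = function(e) 0)
  src <- sub[sub$source_ids != "", , drop = FALSE]
  measured_sets <- unique(src$source_ids)

  # net, decay-aligned rate of the set's nearest frame to time t_ref
  aligned <- function(set, ref_frame) {
    cand <- src[src$source_ids == set, , drop = FALSE]
    i <- which.min(abs(cand$t_start - ref_frame$t_start))
    f <- cand[i, ]
    rate <- net_rate(f, bg)
    ids <- split_source_ids(set)
    a_own <- frame_activity(series, f)
    a_ref <- sum(vapply(ids, function(id) {
      s <- as.list(series$sources[series$sources$source_id == id, ])
      frame_average_activity(s, ref_frame$t_start, ref_frame$duration)
    }, 0))
    as.numeric(rate) * a_ref / a_own
  }

  rows <- list()
  for (i in seq_len(nrow(src))) {
    f <- src[i, ]
    ids <- split_source_ids(f$source_ids)
    if (length(ids) < 2L) next
    # partitions of the set into two measured, disjoint subsets
    parts <- list()
    for (a in measured_sets) {
      a_ids <- split_source_ids(a)
      if (!length(a_ids) || !all(a_ids %in% ids) ||
          length(a_ids) >= length(ids)) next
      b <- paste(sort(setdiff(ids, a_ids)), collapse = "+")
      if (b %in% measured_sets && a < b) parts[[length(parts) + 1L]] <- c(a, b)
    }
    if (!length(parts)) {
      message("no measured decomposition for combination '",
              f$source_ids, "'; skipped")
      next
    }
    # nearest-in-time partition if several are available
    score <- vapply(parts, function(p) {
      sum(vapply(p, function(set) {
        min(abs(src$t_start[src$source_ids == set] - f$t_start))
      }, 0))
    }, 0)
    p <- parts[[which.min(score)]]
    r1 <- aligned(p[1], f)
    r2 <- aligned(p[2], f)
    r12 <- as.numeric(net_rate(f, bg))
    if (r1 <= 0 || r2 <= 0 || r12 <= 0) {
      message("non-positive net rate for combination '", f$source_ids,
              "'; skipped")
      next
    }
    est <- dual_source_tau(r1, r2, r12,
                           total_activity = frame_activity(series, f))
    rows[[length(rows) + 1L]] <- data.frame(
      combination = f$source_ids, t_start = f$t_start,
      total_activity = est$total_activity,
      r1 = r1, r2 = r2, r12 = r12, tau = est$tau, valid = est$valid)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(combination = character(), t_start = numeric(),
               total_activity = numeric(), r1 = numeric(), r2 = numeric(),
               r12 = numeric(), tau = numeric(), valid = logical())
  rownames(out) <- NULL
  class(out) <- c("dual_source_schedule", "data.frame")
  out
}

#' @export
print.dual_source_schedule <- function(x, ...) {
  cat(sprintf("Dual-source dead-time estimates (%d combination(s))\n",
              nrow(x)))
  if (nrow(x)) {
    df <- data.frame(combination = x$combination,
                     activity_MBq = signif(x$total_activity / 1e6, 4),
                     tau_us = signif(x$tau * 1e6, 4),
                     valid = x$valid)
    print.data.frame(df, row.names = FALSE)
    ok <- x$valid
    if (any(ok))
      cat(sprintf("mean tau = %.4g us (sd %.2g us, n = %d)\n",
                  mean(x$tau[ok]) * 1e6, stats::sd(x$tau[ok]) * 1e6,
                  sum(ok)))
  }
  invisible(x)
}

#' Graphical (decaying-source) estimate of sensitivity and dead time
#'
#' Under the paralyzable model, `R'/A = C * exp(-C * tau * A)`, so
#' `ln(R'/A)` is linear in activity with intercept `ln(C)` and slope
#' `-C * tau`.  An unweighted least-squares line through the measured
#' points therefore yields both the sensitivity and the dead time without
#' assuming that low-rate points are loss-free.
#'
#' `graphical_fit()` is generic: the default method takes raw
#' (activity, net rate) points; the [measurement_series()] method builds
#' the points from the frames of one detector/window, subtracting the
#' pooled background and optionally excluding frames beyond a
#' model-validity cutoff (see [pdm_validity_filter()]).
#'
#' @param x activities in Bq (> 0), or a [measurement_series()].
#' @param ... passed between methods.
#' @return An object of class `graphical_fit` with components
#'   `sensitivity` (cps/Bq), `tau` (s), `se_sensitivity`, `se_tau`
#'   (first-order propagation of the linear-fit covariance),
#'   `r_squared`, `n_used`, `n_excluded` and the underlying `lm` fit.
#' @examples
#' a <- seq(10e6, 340e6, length.out = 20)
#' r <- observed_rate(7.8e-4 * a, 1.3e-6)
#' fit <- graphical_fit(a, r)
#' coef(fit)  # C = 7.8e-4 cps/Bq, tau = 1.3e-6 s
#' @export
graphical_fit <- function(x, ...) UseMethod("graphical_fit")

#' @rdname graphical_fit
#' @param net_rate background-subtracted observed rates in cps.
#' @param exclude optional logical vector (or predicate
#'   `function(activity, net_rate)` returning one) marking points to leave
#'   out of the fit; excluded points are counted, never silently dropped.
#' @export
graphical_fit.default <- function(x, net_rate, exclude = NULL, ...) {
  activity <- as.numeric(x)
  rate <- as.numeric(net_rate)
  if (length(activity) != length(rate))
    stop("'activity' and 'net_rate' lengths differ")
  drop <- rep(FALSE, length(activity))
  if (is.function(exclude)) drop <- drop | exclude(activity, rate)
  else if (!is.null(exclude)) drop <- drop | as.logical(exclude)
  nonpos <- !drop & (!(activity > 0) | !(rate > 0))
  use <- !drop & !nonpos
  if (sum(use) < 2L)
    stop("fewer than 2 usable points for the graphical fit")
  a <- activity[use]
  y <- log(rate[use] / a)
  fit <- stats::lm(y ~ a)
  b <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on (intended) numerically perfect fits
  V <- suppressWarnings(stats::vcov(fit))
  C <- exp(b[[1]])
  tau <- -b[[2]] / C
  # first-order (delta-method) propagation of the (intercept, slope) cov
  g <- c(-tau, -1 / C)  # d tau / d(b0, b1)
  se_tau <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(sensitivity = C, tau = tau,
                 se_sensitivity = C * sqrt(V[1, 1]),
                 se_tau = se_tau, r_squared = r2,
                 n_used = sum(use),
                 n_excluded = sum(drop) + sum(nonpos),
                 n_nonpositive = sum(nonpos),
                 points = data.frame(activity = activity, rate = rate,
                                     used = use),
                 lm = fit),
            class = "graphical_fit")
}

#' @rdname graphical_fit
#' @param detector,window labels selecting the frames (series method).
#' @param activity_cutoff,ow_rate_cutoff optional model-validity cutoffs:
#'   frames with total activity (Bq) or raw rate (cps) above the cutoff
#'   are excluded from the fit and reported in `n_excluded`.
#' @export
graphical_fit.measurement_series <- function(x, detector, window,
                                             activity_cutoff = NULL,
                                             ow_rate_cutoff = NULL, ...) {
  m <- x$measurements
  sub <- m[m$detector_id == detector & m$window == window &
             m$source_ids != "", , drop = FALSE]
  if (!nrow(sub)) stop("no source frames for that detector/window")
  bg <- tryCatch(background_rate(x, detector, window),
                 error = function(e) 0)
  pts <- data.frame(
    activity = vapply(seq_len(nrow(sub)),
                      function(i) frame_activity(x, sub[i, ]), 0),
    rate = as.numeric(net_rate(sub, bg)))
  split <- pdm_validity_filter(pts, ow_rate_cutoff = ow_rate_cutoff,
                               activity_cutoff = activity_cutoff,
                               allow_none = TRUE)
  drop <- !seq_len(nrow(pts)) %in% split$included_idx
  graphical_fit(pts$activity, pts$rate, exclude = drop, ...)
}

#' @export
print.graphical_fit <- function(x, ...) {
  cat("Graphical dead-time fit (unweighted LS of ln(R'/A) vs A)\n")
  cat(sprintf("  sensitivity C = %.4g kcps/MBq (SE %.2g)\n",
              x$sensitivity * 1e3, x$se_sensitivity * 1e3))
  cat(sprintf("  dead time tau = %.4g us (SE %.2g)\n",
              x$tau * 1e6, x$se_tau * 1e6))
  cat(sprintf("  R^2 = %.6g; points used = %d, excluded = %d\n",
              x$r_squared, x$n_used, x$n_excluded))
  invisible(x)
}

#' @export
summary.graphical_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.graphical_fit <- function(object, ...) {
  c(sensitivity = object$sensitivity, tau = object$tau)
}

#' Predicted observed count rate from a graphical fit
#'
#' @param object a [graphical_fit()].
#' @param newdata optional data frame with an `activity` column (Bq);
#'   defaults to the fitted points.
#' @param ... unused.
#' @return Predicted net observed rates in cps.
#' @export
predict.graphical_fit <- function(object, newdata = NULL, ...) {
  a <- if (is.null(newdata)) object$points$activity else newdata$activity
  observed_rate(object$sensitivity * a, object$tau)
}

#' @export
residuals.graphical_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
plot.graphical_fit <- function(x, ...) {
  p <- x$points
  with(p, graphics::plot(activity / 1e6, log(rate / activity),
                         pch = ifelse(used, 16, 1),
                         xlab = "Activity (MBq)", ylab = "ln(R'/A)", ...))
  aa <- seq(min(p$activity), max(p$activity), length.out = 200)
  graphics::lines(aa / 1e6,
                  log(x$sensitivity) - x$sensitivity * x$tau * aa)
  graphics::legend("topright", bty = "n", pch = c(16, 1),
                   legend = c("used", "excluded"))
  invisible(x)
}

#' Dead time from the maximum observed count rate
#'
#' Inverts `R'_max = (e * tau)^-1`: given the peak of the measured
#' count-rate curve, `tau = 1 / (e * R'_max)` (the MCR method).
#'
#' @param max_observed_rate peak observed rate in cps (> 0).
#' @return Resolving time in seconds.
#' @examples
#' tau_from_mcr(391.3e3) * 1e6  # ~0.94 us
#' @export
tau_from_mcr <- function(max_observed_rate) {
  if (any(!(max_observed_rate > 0)))
    stop("'max_observed_rate' must be > 0")
  1 / (exp(1) * max_observed_rate)
}

#' Window fraction versus open-window rate, with fitted loss slope
#'
#' Pairs simultaneous photopeak- and open-window frames (same detector,
#' start time and duration), forms the per-frame window fraction
#' (photopeak net rate over open-window net rate) and fits an unweighted
#' least-squares line of fraction against open-window rate over the whole
#' rate range.  The slope is reported as the percentage-point change in
#' window fraction per 100 kcps (slope in 1/cps times 1e5, times 100), the
#' customary pile-up figure of merit.
#'
#' @param series a [measurement_series()].
#' @param detector detector label.
#' @param photopeak_window,open_window window names.
#' @return An object of class `window_fraction_fit` with the paired
#'   `points` (ow_rate, fraction), `loss_per_100kcps` (percent),
#'   `se_per_100kcps`, `n_pairs` and the underlying `lm`.  Unpaired
#'   frames are skipped with a message.
#' @export
window_fraction_series <- function(series, detector, photopeak_window,
                                   open_window = "OW") {
  stopifnot(inherits(series, "measurement_series"))
  m <- series$measurements
  pick <- function(w) m[m$detector_id == detector & m$window == w &
                          m$source_ids != "", , drop = FALSE]
  pp <- pick(photopeak_window)
  ow <- pick(open_window)
  if (!nrow(pp) || !nrow(ow))
    stop("no source frames for one of the windows")
  bg_pp <- tryCatch(background_rate(series, detector, photopeak_window),
                    error = function(e) 0)
  bg_ow <- tryCatch(background_rate(series, detector, open_window),
                    error = function(e) 0)
  key <- function(d) paste(d$t_start, d$duration)
  common <- intersect(key(pp), key(ow))
  n_skip <- (nrow(pp) - length(common)) + (nrow(ow) - length(common))
  if (n_skip) message(n_skip, " unpaired frame(s) skipped")
  pp <- pp[match(common, key(pp)), ]
  ow <- ow[match(common, key(ow)), ]
  r_ow <- as.numeric(net_rate(ow, bg_ow))
  r_pp <- as.numeric(net_rate(pp, bg_pp))
  ok <- r_ow > 0
  pts <- data.frame(t_start = ow$t_start[ok], ow_rate = r_ow[ok],
                    fraction = r_pp[ok] / r_ow[ok])
  if (nrow(pts) < 2L) stop("fewer than 2 usable frame pairs")
  fit <- stats::lm(fraction ~ ow_rate, data = pts)
  slope <- stats::coef(fit)[[2]]
  se <- sqrt(suppressWarnings(stats::vcov(fit))[2, 2])
  structure(list(points = pts,
                 loss_per_100kcps = slope * 1e5 * 100,
                 se_per_100kcps = se * 1e5 * 100,
                 base_fraction = stats::coef(fit)[[1]],
                 n_pairs = nrow(pts), lm = fit),
            class = "window_fraction_fit")
}

#' @export
print.window_fraction_fit <- function(x, ...) {
  cat(sprintf(paste0("Window-fraction fit: %+.3g%% per 100 kcps ",
                     "(SE %.2g), base fraction %.4g, n = %d\n"),
              x$loss_per_100kcps, x$se_per_100kcps, x$base_fraction,
              x$n_pairs))
  invisible(x)
}

#' @export
plot.window_fraction_fit <- function(x, ...) {
  with(x$points, graphics::plot(ow_rate / 1e3, fraction,
                                xlab = "Open-window rate (kcps)",
                                ylab = "Window fraction", ...))
  graphics::abline(x$lm$coefficients[1],
                   x$lm$coefficients[2] * 1e3, lty = 2)
  invisible(x)
}

#' Partition measurement points at a model-validity cutoff
#'
#' The paralyzable model stops applying above some count rate (a sharp,
#' step-like drop in observed rate on real cameras); points beyond a
#' user-chosen cutoff are excluded from fits.  The cutoff is manual —
#' there is no automatic breakdown detection — and excluded points are
#' always reported, never silently dropped.
#'
#' @param points data frame with columns `activity` (Bq) and/or `rate`
#'   (cps) (an `ow_rate` column is accepted as the rate).
#' @param ow_rate_cutoff,activity_cutoff at least one cutoff, in cps / Bq.
#' @param allow_none internal: allow both cutoffs `NULL` (keep all).
#' @return List with `included`, `excluded` (data frames) and
#'   `included_idx`, `excluded_idx` (row indices into `points`).
#' @export
pdm_validity_filter <- function(points, ow_rate_cutoff = NULL,
                                activity_cutoff = NULL,
                                allow_none = FALSE) {
  stopifnot(is.data.frame(points))
  if (is.null(ow_rate_cutoff) && is.null(activity_cutoff) && !allow_none)
    stop("provide 'ow_rate_cutoff' and/or 'activity_cutoff'")
  keep <- rep(TRUE, nrow(points))
  if (!is.null(activity_cutoff)) {
    if (is.null(points$activity)) stop("points lack an 'activity' column")
    keep <- keep & points$activity <= activity_cutoff
  }
  if (!is.null(ow_rate_cutoff)) {
    rate <- if (!is.null(points$rate)) points$rate else points$ow_rate
    if (is.null(rate)) stop("points lack a 'rate'/'ow_rate' column")
    keep <- keep & rate <= ow_rate_cutoff
  }
  list(included = points[keep, , drop = FALSE],
       excluded = points[!keep, , drop = FALSE],
       included_idx = which(keep), excluded_idx = which(!keep))
}
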