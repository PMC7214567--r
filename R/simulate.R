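# Synthetic counting-experiment generator.  Rate-level simulation: true
# rates from the decay law and the sensitivities, observed rates from the
# closed-form paralyzable model, counts from a seeded Poisson draw.  This
# mirrors the rate-level physics the estimators assume, keeps noiseless
# runs exactly on the model curve, and is fast enough for replicate
# studies; an event-level thinning check lives in the test suite only.

#' Simulation configuration
#'
#' @param detector a [detector_config()].
#' @param sources list of [radioactive_source()] objects (or a source
#'   data frame as in [measurement_series()]).
#' @param schedule data frame of frames with columns `t_start` (s),
#'   `duration` (s) and `source_ids` (`"+"`-joined labels, `""` for a
#'   background frame); frames must not overlap in time.
#' @param poisson_noise draw Poisson counts (`TRUE`) or emit the exact
#'   expected counts (`FALSE`; counts are then generally fractional so
#'   that noiseless series sit on the model curve to machine precision).
#' @param seed integer seed; fully determines the output when noise is on.
#' @param breakdown optional `list(threshold_ow_rate =, drop_fraction =)`:
#'   when the observed open-window rate exceeds the threshold, all window
#'   rates are multiplied by `1 - drop_fraction`, a phenomenological stand-in
#'   for the step-like high-rate breakdown of real cameras.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(detector, sources, schedule,
                              poisson_noise = TRUE, seed = 1L,
                              breakdown = NULL) {
  stopifnot(inherits(detector, "detector_config"))
  need <- c("t_start", "duration", "source_ids")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)))
    stop("'schedule' needs columns: ", paste(need, collapse = ", "))
  if (any(!(schedule$duration > 0))) stop("durations must be > 0")
  sch <- schedule[order(schedule$t_start), , drop = FALSE]
  if (nrow(sch) > 1L &&
      any(sch$t_start[-1L] < (sch$t_start + sch$duration)[-nrow(sch)]))
    stop("schedule frames overlap in time")
  if (!is.null(breakdown)) {
    stopifnot(is.list(breakdown),
              breakdown$threshold_ow_rate > 0,
              breakdown$drop_fraction > 0, breakdown$drop_fraction < 1)
  }
  structure(list(detector = detector,
                 sources = sources_to_frame(sources),
                 schedule = sch, poisson_noise = isTRUE(poisson_noise),
                 seed = as.integer(seed), breakdown = breakdown),
            class = "simulation_config")
}

#' Expected observed rates of one frame, per window
#'
#' Composition of the forward model: the open-window true rate is the sum
#' over sources of sensitivity times frame-averaged activity, plus the
#' open-window ambient rate; the paralyzable model gives the observed
#' open-window rate; each photopeak window then receives that rate times
#' its rate-dependent window fraction, plus its own ambient rate (losses
#' are driven by the whole spectrum, not by the photopeak alone).  With a
#' breakdown regime configured, rates above the threshold are scaled by
#' `1 - drop_fraction`.
#'
#' @param config a [simulation_config()].
#' @param frame one schedule row (list or single-row data frame).
#' @return Named numeric vector of observed rates (cps), one per window,
#'   with attribute `broken_down` (logical).
#' @export
expected_observed_rates <- function(config, frame) {
  stopifnot(inherits(config, "simulation_config"))
  det <- config$detector
  ids <- split_source_ids(frame$source_ids)
  if (!all(ids %in% config$sources$source_id)) stop("unknown source id")
  own <- if (is.null(det$open_window)) NULL else
    det$windows[[det$open_window]]
  if (is.null(own)) stop("simulation requires an open window")
  a <- sum(vapply(ids, function(id) {
    s <- as.list(config$sources[config$sources$source_id == id, ])
    frame_average_activity(s, frame$t_start, frame$duration)
  }, 0))
  ow_true <- own$sensitivity * a + own$background_rate
  ow_obs <- observed_rate(ow_true, det$tau_system)
  rates <- vapply(det$windows, function(w) {
    if (identical(w$window$name, det$open_window)) ow_obs
    else ow_obs * window_fraction_at_rate(w$base_window_fraction,
                                          w$fraction_slope, ow_obs) +
      w$background_rate
  }, 0)
  broken <- !is.null(config$breakdown) &&
    ow_obs > config$breakdown$threshold_ow_rate
  if (broken) rates <- rates * (1 - config$breakdown$drop_fraction)
  structure(rates, broken_down = broken)
}

#' Simulate a measurement series
#'
#' Generates counts for every frame and window of the schedule:
#' `Poisson(rate * duration)` under the seeded generator, or the exact
#' expected counts when noise is off.  The returned series carries full
#' provenance in its metadata — seed, noise flag, the true parameters
#' (tau, sensitivities, window-fraction model) and the start times of any
#' frames in the breakdown regime — so tests can use it as an oracle.
#' The caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @return A [measurement_series()].
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  det <- config$detector
  wins <- names(det$windows)
  rows <- vector("list", nrow(config$schedule))
  broken_at <- numeric()
  if (config$poisson_noise) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed))
        rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(config$seed)
  }
  for (i in seq_len(nrow(config$schedule))) {
    fr <- config$schedule[i, ]
    rates <- expected_observed_rates(config, fr)
    if (isTRUE(attr(rates, "broken_down")))
      broken_at <- c(broken_at, fr$t_start)
    expected <- as.numeric(rates) * fr$duration
    counts <- if (config$poisson_noise)
      stats::rpois(length(expected), expected) else expected
    rows[[i]] <- data.frame(detector_id = det$detector_id,
                            window = wins, t_start = fr$t_start,
                            duration = fr$duration, counts = counts,
                            source_ids = fr$source_ids)
  }
  truth <- list(tau_system = det$tau_system,
                sensitivity = vapply(det$windows, `[[`, 0, "sensitivity"),
                base_window_fraction =
                  vapply(det$windows, `[[`, 0, "base_window_fraction"),
                fraction_slope =
                  vapply(det$windows, `[[`, 0, "fraction_slope"),
                breakdown = config$breakdown)
  measurement_series(do.call(rbind, rows), config$sources,
                     metadata = list(simulated = TRUE, seed = config$seed,
                                     poisson_noise = config$poisson_noise,
                                     truth = truth,
                                     breakdown_t_start = broken_at))
}

# Table-1-style source-combination schedule.  Each "dual" set acquires
# sources 1, 2 and 1+2 in consecutive frames; a "triple" set continues
# with 3 and 1+2+3.  Sets are placed at the given start times.
combination_schedule <- function(set_starts, set_kinds, frame_duration,
                                 background_duration, end_pad = 300) {
  frames <- list(data.frame(t_start = 0, duration = background_duration,
                            source_ids = ""))
  for (k in seq_along(set_starts)) {
    combos <- if (set_kinds[k] == "triple")
      c("s1", "s2", "s1+s2", "s3", "s1+s2+s3")
    else c("s1", "s2", "s1+s2")
    frames[[length(frames) + 1L]] <- data.frame(
      t_start = set_starts[k] + (seq_along(combos) - 1) * frame_duration,
      duration = frame_duration, source_ids = combos)
  }
  sch <- do.call(rbind, frames)
  rbind(sch, data.frame(t_start = max(sch$t_start + sch$duration) + end_pad,
                        duration = background_duration, source_ids = ""))
}

#' Ready-made simulation presets
#'
#' `make_intrinsic_preset()` emulates an intrinsic (collimator-free)
#' triple-source counting experiment: three 99mTc sources of 125, 125 and
#' 250 MBq measured in 60-s frames with 300-s background frames before and
#' after, in the source-combination pattern 1, 2, 1+2 (, 3, 1+2+3).  Two
#' full triple-source sets plus thirteen dual-source sets are spread over
#' ~28.7 h of decay, giving 49 source frames per detector and 17
#' dual-source dead-time estimates, with the single sources decaying from
#' 125 to ~4.5 MBq.  Detector parameters: open-window sensitivity 0.78
#' kcps/MBq, system dead time 1.30 us, photopeak (126.5-154.6 keV) base
#' window fraction 0.48/0.78 with a pile-up loss of 9.5 percentage points
#' per 100 kcps.
#'
#' `make_phantom_preset()` emulates an extrinsic (LEHR-collimated)
#' scatter-phantom experiment: two sources of 1.4 GBq (2.8 GBq combined)
#' through ~24 h of decay, system dead time 0.92 us, open-window
#' sensitivity 0.09 kcps/MBq, photopeak base window fraction 0.55 with a
#' loss of 5.1 percentage points per 100 kcps.
#'
#' @param poisson_noise,seed passed to [simulation_config()].
#' @param breakdown if `TRUE`, add a step-like high-rate breakdown (30%
#'   rate drop above 200 kcps observed open-window rate) to exercise
#'   model-validity filtering.
#' @param background_ow ambient open-window rate in cps (default 0; the
#'   sources are shielded and the room assumed quiet, which keeps
#'   noiseless runs exactly on the model curve).
#' @return A [simulation_config()].
#' @export
make_intrinsic_preset <- function(poisson_noise = TRUE, seed = 1L,
                                  breakdown = FALSE, background_ow = 0) {
  det <- detector_config(
    "det1", tau_system = 1.30e-6,
    windows = list(
      window_channel(energy_window("OW", 0, 1022),
                     sensitivity = 0.78e-3,
                     background_rate = background_ow),
      window_channel(energy_window("Tc", 126.5, 154.6),
                     sensitivity = 0.48e-3,
                     base_window_fraction = 0.48 / 0.78,
                     fraction_slope = -0.095 / 1e5)),
    open_window = "OW")
  sources <- list(
    radioactive_source("s1", 125e6),
    radioactive_source("s2", 125e6),
    radioactive_source("s3", 250e6))
  set_starts <- 600 + (seq_len(15) - 1) * 7350
  kinds <- c("triple", "triple", rep("dual", 13))
  sch <- combination_schedule(set_starts, kinds, 60, 300)
  simulation_config(det, sources, sch, poisson_noise = poisson_noise,
                    seed = seed,
                    breakdown = if (breakdown)
                      list(threshold_ow_rate = 2e5, drop_fraction = 0.3))
}

#' @rdname make_intrinsic_preset
#' @export
make_phantom_preset <- function(poisson_noise = TRUE, seed = 1L,
                                breakdown = FALSE, background_ow = 0) {
  det <- detector_config(
    "det1", tau_system = 0.92e-6,
    windows = list(
      window_channel(energy_window("OW", 0, 1022),
                     sensitivity = 0.09e-3,
                     background_rate = background_ow),
      window_channel(energy_window("Tc", 126.5, 154.6),
                     sensitivity = 0.55 * 0.09e-3,
                     base_window_fraction = 0.55,
                     fraction_slope = -0.051 / 1e5)),
    open_window = "OW")
  sources <- list(
    radioactive_source("p1", 1.4e9),
    radioactive_source("p2", 1.4e9))
  set_starts <- 600 + (seq_len(13) - 1) * 7200
  sch <- combination_schedule(set_starts, rep("dual", 13), 60, 300)
  # phantom sets use source labels p1/p2
  sch$source_ids <- gsub("s1", "p1", gsub("s2", "p2", sch$source_ids))
  simulation_config(det, sources, sch, poisson_noise = poisson_noise,
                    seed = seed,
                    breakdown = if (breakdown)
                      list(threshold_ow_rate = 1.6e5, drop_fraction = 0.3))
}
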