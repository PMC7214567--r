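# Independent oracles and fixture builders used across the test files.

# Bisection solve of w * exp(w) = z on [-1, 0]; independent of the
# package's Halley solver.
lambert_bisect <- function(z, tol = 1e-13) {
  vapply(z, function(zz) {
    lo <- -1; hi <- 0
    flo <- lo * exp(lo) - zz
    if (flo == 0) return(lo)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- mid * exp(mid) - zz
      # w e^w is increasing on [-1, 0]
      if (fm == 0 || (hi - lo) < tol) return(mid)
      if (fm < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0)
}

# Event-level paralyzable detector: Poisson arrivals at rate rt over time
# t_total; an arrival is recorded iff no other arrival occurred within the
# preceding tau (every arrival, recorded or not, extends the dead period).
event_level_observed_rate <- function(rt, tau, t_total) {
  n <- stats::rpois(1, rt * t_total)
  arrivals <- sort(stats::runif(n, 0, t_total))
  if (n == 0) return(0)
  gaps <- c(Inf, diff(arrivals))
  sum(gaps > tau) / t_total
}

# Table-1-shaped noiseless series: sources 1, 2, 1+2, 3, 1+2+3 in 60-s
# frames plus bracketing 300-s backgrounds.  With the default (very long)
# half-life the sources are effectively constant, making both estimators
# exact; pass half_life = tc99m_half_life for a decaying variant.
table1_config <- function(tau = 1.2e-6, sensitivity = 7.8e-4,
                          half_life = 1e12, t0 = 600,
                          a = c(125e6, 125e6, 250e6),
                          include_triple = TRUE) {
  det <- detector_config(
    "det1", tau_system = tau,
    windows = list(window_channel(energy_window("OW", 0, 1022),
                                  sensitivity = sensitivity)),
    open_window = "OW")
  sources <- list(
    radioactive_source("s1", a[1], half_life = half_life),
    radioactive_source("s2", a[2], half_life = half_life),
    radioactive_source("s3", a[3], half_life = half_life))
  combos <- c("s1", "s2", "s1+s2")
  if (include_triple) combos <- c(combos, "s3", "s1+s2+s3")
  sch <- rbind(
    data.frame(t_start = 0, duration = 300, source_ids = ""),
    data.frame(t_start = t0 + (seq_along(combos) - 1) * 60,
               duration = 60, source_ids = combos),
    data.frame(t_start = t0 + length(combos) * 60 + 300,
               duration = 300, source_ids = ""))
  simulation_config(det, sources, sch, poisson_noise = FALSE)
}
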