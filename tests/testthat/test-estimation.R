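test_that("net rate subtracts background and floors at zero with a flag", {
  m <- list(counts = 6000, duration = 60)
  expect_equal(as.numeric(net_rate(m, 2)), 98)
  expect_equal(as.numeric(net_rate(m, 0)), 100)
  low <- net_rate(list(counts = 30, duration = 60), 2)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "low_count"))
})

test_that("background rate pools all background frames", {
  mk <- function(counts, t) data.frame(
    detector_id = "d1", window = "OW", t_start = t, duration = 300,
    counts = counts, source_ids = "")
  src <- data.frame(source_id = "s1", reference_activity = 1e6,
                    reference_time = 0, half_life = tc99m_half_life)
  one <- measurement_series(mk(600, 0), src)
  expect_equal(background_rate(one, "d1", "OW"), 2)
  two <- measurement_series(rbind(mk(600, 0), mk(660, 1000)), src)
  expect_equal(background_rate(two, "d1", "OW"), 2.1)
  zero <- measurement_series(mk(0, 0), src)
  expect_equal(background_rate(zero, "d1", "OW"), 0)
  expect_error(background_rate(one, "d1", "Tc"), "no background")
})

test_that("dual-source estimate is exact for equal-activity noiseless sources", {
  tau <- 1e-6
  for (rt_tau in seq(0.01, 0.9, by = 0.045)) {
    rt <- rt_tau / tau
    r1 <- observed_rate(rt / 2, tau)
    r12 <- observed_rate(rt, tau)
    est <- dual_source_tau(r1, r1, r12)
    expect_true(est$valid)
    expect_equal(est$tau, tau, tolerance = 1e-12)
  }
  # worked example: tau = 1 us, Rt1 = Rt2 = 100 kcps
  est <- dual_source_tau(90483.74, 90483.74, 163746.15)
  expect_equal(est$tau, 1e-6, tolerance = 1e-6)
})

test_that("dual-source error scales with the leading-order unequal-source bound", {
  # the exact second-order error is ~ bound * (4 - Rt*tau)(1 - Rt*tau),
  # so a factor-4 envelope of the leading-order bound holds everywhere
  tau <- 1e-6
  rmax <- max_observed_rate(tau)
  for (f in seq(0.30, 0.70, by = 0.05)) {
    for (q in seq(0.35, 0.95, by = 0.06)) {
      rt_tot <- correct_rate(q * rmax, tau)
      r1 <- observed_rate(f * rt_tot, tau)
      r2 <- observed_rate((1 - f) * rt_tot, tau)
      r12 <- observed_rate(rt_tot, tau)
      est <- dual_source_tau(r1, r2, r12)
      bound <- dual_source_error_bound(f * rt_tot, (1 - f) * rt_tot)
      err <- abs(est$tau - tau) / tau
      expect_lt(err, 4 * bound + 0.005)
    }
  }
})

test_that("unequal-source error bound follows the closed form", {
  expect_equal(dual_source_error_bound(5e4, 5e4), 0)
  expect_equal(dual_source_error_bound(0.44 * 2e5, 0.56 * 2e5), 0.0036)
  expect_equal(dual_source_error_bound(0.40 * 1e5, 0.60 * 1e5), 0.01)
})

test_that("a combined rate at or above the sum of singles is flagged invalid", {
  est <- dual_source_tau(1e4, 1e4, 2e4)
  expect_equal(est$tau, 0)
  expect_false(est$valid)
  expect_false(dual_source_tau(1e4, 1e4, 2.1e4)$valid)
})

test_that("the triple-source schedule yields one tau per combined frame", {
  ser <- simulate_series(table1_config(tau = 1.2e-6))
  sched <- triple_source_schedule(ser, "det1", "OW")
  expect_equal(nrow(sched), 2)
  expect_setequal(sched$combination, c("s1+s2", "s1+s2+s3"))
  expect_true(all(sched$valid))
  # constant-activity noiseless sources: recovery is essentially exact
  expect_equal(sched$tau, rep(1.2e-6, 2), tolerance = 1e-8)
  # the combined-frame activity levels A(1+2) and A(1+2+3)
  expect_equal(sched$total_activity, c(250e6, 500e6), tolerance = 1e-6)

  # decaying 99mTc variant: decay alignment keeps the error below 0.5%
  ser_tc <- simulate_series(table1_config(tau = 1.2e-6,
                                          half_life = tc99m_half_life))
  sched_tc <- triple_source_schedule(ser_tc, "det1", "OW")
  expect_equal(sched_tc$tau, rep(1.2e-6, 2), tolerance = 5e-3)

  # without the three-source frame only the A(1+2) estimate remains
  ser_dual <- simulate_series(table1_config(include_triple = FALSE))
  sched_dual <- triple_source_schedule(ser_dual, "det1", "OW")
  expect_equal(nrow(sched_dual), 1)
  expect_equal(sched_dual$combination, "s1+s2")
})

test_that("an intrinsic-style run yields 17 dual-source estimates from 49 frames", {
  ser <- simulate_series(make_intrinsic_preset(poisson_noise = FALSE))
  m <- ser$measurements
  expect_equal(sum(m$source_ids != "" & m$window == "OW"), 49)
  for (w in c("OW", "Tc")) {
    sched <- triple_source_schedule(ser, "det1", w)
    expect_equal(nrow(sched), 17)
    expect_true(all(sched$valid))
  }
})

test_that("graphical fit recovers C and tau exactly from noiseless model points", {
  C <- 0.78e-3; tau <- 1.3e-6
  a <- seq(10e6, 340e6, length.out = 25)
  fit <- graphical_fit(a, observed_rate(C * a, tau))
  expect_equal(fit$sensitivity, C, tolerance = 1e-9)
  expect_equal(fit$tau, tau, tolerance = 1e-9)
  expect_equal(fit$n_used, 25)
  expect_equal(fit$n_excluded, 0)
  expect_equal(unname(coef(fit)), c(C, tau), tolerance = 1e-9)
  # prediction reproduces the input curve
  expect_equal(predict(fit), observed_rate(C * a, tau), tolerance = 1e-9)

  # zero dead time: flat log-ratio, sensitivity exact
  fit0 <- graphical_fit(a, C * a)
  expect_equal(fit0$sensitivity, C, tolerance = 1e-12)
  expect_equal(fit0$tau, 0, tolerance = 1e-18)
})

test_that("a two-point graphical fit matches the closed-form line", {
  a <- c(100e6, 200e6)
  r <- c(70e3, 120e3)
  y <- log(r / a)
  slope <- (y[2] - y[1]) / (a[2] - a[1])
  intercept <- y[1] - slope * a[1]
  fit <- graphical_fit(a, r)
  expect_equal(fit$sensitivity, exp(intercept), tolerance = 1e-12)
  expect_equal(fit$tau, -slope / exp(intercept), tolerance = 1e-12)
  expect_error(graphical_fit(a[1], r[1]), "fewer than 2")
})

test_that("graphical tau is unbiased under Poisson noise (within 1 SE of the mean)", {
  taus <- ses <- numeric(50)
  for (i in seq_len(50)) {
    ser <- simulate_series(make_intrinsic_preset(seed = 1000 + i))
    fit <- graphical_fit(ser, "det1", "OW")
    taus[i] <- fit$tau; ses[i] <- fit$se_tau
  }
  bias <- mean(taus) - 1.30e-6
  expect_lt(abs(bias), mean(ses))
})

test_that("uncorrected ambient background biases the graphical tau upward", {
  cfg <- make_intrinsic_preset(poisson_noise = FALSE, background_ow = 100)
  ser <- simulate_series(cfg)
  m <- ser$measurements
  src <- m[m$source_ids != "" & m$window == "OW", ]
  a <- vapply(seq_len(nrow(src)), function(i) {
    ids <- strsplit(src$source_ids[i], "+", fixed = TRUE)[[1]]
    sum(vapply(ids, function(id) {
      s <- as.list(ser$sources[ser$sources$source_id == id, ])
      s$reference_activity * 2^(-(src$t_start[i] - s$reference_time) /
                                  s$half_life)
    }, 0))
  }, 0)
  raw <- src$counts / src$duration  # background NOT subtracted
  fit_raw <- graphical_fit(a, raw)
  expect_gt(fit_raw$tau, 1.30e-6)
  # subtracting the pooled measured background restores tau (to first order)
  fit_net <- graphical_fit(ser, "det1", "OW")
  expect_equal(fit_net$tau, 1.30e-6, tolerance = 1e-2)
  expect_gt(fit_raw$tau, fit_net$tau)
})

test_that("MCR dead time inverts the maximum observed rate", {
  expect_equal(tau_from_mcr(max_observed_rate(1.3e-6)), 1.3e-6)
  expect_equal(tau_from_mcr(391.3e3) * 1e6, 0.94, tolerance = 1e-3)
  expect_equal(tau_from_mcr(282.9e3) * 1e6, 1.30, tolerance = 1e-3)
  expect_error(tau_from_mcr(0), "> 0")
})

test_that("window-fraction series recovers the generating pile-up slope", {
  ser <- simulate_series(make_intrinsic_preset(poisson_noise = FALSE))
  wf <- window_fraction_series(ser, "det1", "Tc")
  expect_equal(wf$loss_per_100kcps, -9.5, tolerance = 1e-9)
  expect_equal(wf$base_fraction, 0.48 / 0.78, tolerance = 1e-9)
  expect_equal(wf$n_pairs, 49)

  # constant fraction: zero slope
  cfg0 <- table1_config()
  det0 <- detector_config(
    "det1", tau_system = 1.2e-6,
    windows = list(
      window_channel(energy_window("OW", 0, 1022), 7.8e-4),
      window_channel(energy_window("Tc", 126.5, 154.6), 4.8e-4,
                     base_window_fraction = 0.6)),
    open_window = "OW")
  cfg0$detector <- det0
  wf0 <- window_fraction_series(simulate_series(cfg0), "det1", "Tc")
  expect_equal(wf0$loss_per_100kcps, 0, tolerance = 1e-9)
  expect_equal(wf0$base_fraction, 0.6, tolerance = 1e-9)

  # Poisson noise: fitted slope within 3 SE of the generator slope
  wf_n <- window_fraction_series(
    simulate_series(make_intrinsic_preset(seed = 7)), "det1", "Tc")
  expect_lt(abs(wf_n$loss_per_100kcps - (-9.5)), 3 * wf_n$se_per_100kcps)
})

test_that("model-validity filtering excludes exactly the flagged frames", {
  cfg <- make_intrinsic_preset(poisson_noise = FALSE, breakdown = TRUE)
  ser <- simulate_series(cfg)
  broken_t <- ser$metadata$breakdown_t_start
  expect_gt(length(broken_t), 0)
  m <- ser$measurements
  src <- m[m$source_ids != "" & m$window == "OW", ]
  pts <- data.frame(
    t_start = src$t_start,
    activity = vapply(seq_len(nrow(src)), function(i) {
      ids <- strsplit(src$source_ids[i], "+", fixed = TRUE)[[1]]
      sum(vapply(ids, function(id) {
        s <- as.list(ser$sources[ser$sources$source_id == id, ])
        s$reference_activity * 2^(-(src$t_start[i] - s$reference_time) /
                                    s$half_life)
      }, 0))
    }, 0),
    rate = src$counts / src$duration)
  split <- pdm_validity_filter(pts, activity_cutoff = 350e6)
  expect_setequal(split$excluded$t_start, broken_t)
  # cutoff above everything: nothing excluded
  all_in <- pdm_validity_filter(pts, activity_cutoff = 1e12)
  expect_equal(nrow(all_in$excluded), 0)
  # cutoff below everything: downstream fit has too few points
  expect_error(graphical_fit(ser, "det1", "OW", activity_cutoff = 1),
               "fewer than 2 usable")
  expect_error(pdm_validity_filter(pts), "provide")
})

test_that("excluding breakdown frames restores the graphical tau", {
  cfg <- make_intrinsic_preset(poisson_noise = FALSE, breakdown = TRUE)
  ser <- simulate_series(cfg)
  fit <- graphical_fit(ser, "det1", "OW", activity_cutoff = 350e6)
  expect_equal(fit$tau, 1.30e-6, tolerance = 1e-9)
  expect_equal(fit$n_excluded, length(ser$metadata$breakdown_t_start))
})
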