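test_that("config validation rejects bad bands, fractions, and rates", {
  expect_error(synth_config(band_fractions = c("0.7-12" = 0.8,
                                               "12-35" = 0.4)),
               "sum")
  expect_error(synth_config(lfp_fs = 300), "twice")
  expect_error(synth_config(band_fractions = c(nonsense = 0.5)), "names")
  expect_error(unit_spec("BS", base_rate = -1))
  expect_error(unit_spec("BS", kappa = -0.5))
})

test_that("gen_lfp is deterministic given the seed", {
  cfg <- synth_config(seed = 5, duration_s = 20)
  a <- gen_lfp(cfg)
  b <- gen_lfp(cfg)
  expect_identical(a$samples, b$samples)
  c2 <- gen_lfp(synth_config(seed = 6, duration_s = 20))
  expect_false(identical(a$samples, c2$samples))
})

test_that("a single in-band tone is assigned its whole band's power", {
  cfg <- synth_config(seed = 1, duration_s = 60,
                      band_fractions = c("12-35" = 1.0),
                      component_mode = "tone")
  lfp <- gen_lfp(cfg)
  bp <- relative_band_power(multitaper_psd(lfp))
  expect_gte(bp$fractions[["12-35"]], 0.99)
})

test_that("injected band fractions are recovered within 0.02 on a 300 s trace", {
  cfg <- synth_config(seed = 2, duration_s = 300)
  lfp <- gen_lfp(cfg)
  truth <- attr(lfp, "true_fractions")
  bp <- relative_band_power(multitaper_psd(lfp))
  expect_true(all(abs(bp$fractions - truth) < 0.02))
  # control-rest level in the lowest band, as a point check
  expect_equal(unname(bp$fractions[["0.7-12"]]), 0.7351, tolerance = 0.02)
})

test_that("spike generator matches its analytic rate and Poisson limit", {
  u <- unit_spec("BS", base_rate = 5)
  tr <- gen_spike_train(u, lfp = NULL, seed = 3, t_start = 0, t_stop = 200,
                        refractory_ms = 0)
  rate <- length(tr$times) / 200
  se <- sqrt(5 / 200)
  expect_lt(abs(rate - 5), 3 * se)
  expect_equal(isi_cv(tr), 1.0, tolerance = 0.05)
  expect_false(is.unsorted(tr$times, strictly = TRUE))
})

test_that("movement gain scales the in-window rate", {
  ev <- gen_events(400, seed = 4)
  u <- unit_spec("BS", base_rate = 5, movement_gain = 2)
  tr <- gen_spike_train(u, lfp = NULL, events = ev$events, seed = 5,
                        t_start = 0, t_stop = 400)
  move <- restrict_train(tr, ev$movement_intervals)
  rest <- restrict_train(tr, ev$rest_intervals)
  r_move <- length(move$times) / move$total_time
  r_rest <- length(rest$times) / rest$total_time
  expect_equal(r_move / r_rest, 2, tolerance = 0.15)
})

test_that("von Mises coupling yields the Bessel-ratio vector length", {
  cfg <- synth_config(seed = 6, duration_s = 150)
  lfp <- gen_lfp(cfg)
  ph <- instantaneous_phase(lfp, c(12, 35))
  for (k in c(0, 0.5, 1, 2)) {
    u <- unit_spec("BS", base_rate = 40, coupling_band = c(12, 35),
                   kappa = k, preferred_phase_deg = 45)
    tr <- gen_spike_train(u, lfp, seed = 7, refractory_ms = 0)
    s <- phase_lock_summary(spike_phases(tr, ph))
    expect_equal(s$vector_length, besselI(k, 1) / besselI(k, 0),
                 tolerance = 0.025)
    if (k >= 1) expect_circ_equal(s$mean_angle_deg, 45, tol = 5)
  }
})

test_that("recovered vector length is monotone in injected kappa", {
  cfg <- synth_config(seed = 8, duration_s = 100)
  lfp <- gen_lfp(cfg)
  ph <- instantaneous_phase(lfp, c(12, 35))
  rs <- vapply(c(0, 0.5, 1, 2), function(k) {
    u <- unit_spec("NS", base_rate = 30, coupling_band = c(12, 35),
                   kappa = k)
    tr <- gen_spike_train(u, lfp, seed = 9, refractory_ms = 0)
    phase_lock_summary(spike_phases(tr, ph))$vector_length
  }, 0.0)
  expect_true(all(diff(rs) > 0))
})

test_that("waveform generator hits the representable duration exactly", {
  bs <- unit_spec("BS", trough_to_peak_ms = 0.42, waveform_noise_sd = 0)
  wf <- gen_waveforms(bs, 5, seed = 1)
  expect_equal(trough_to_peak(wf$snippets[1, ], wf$fs), 17 / 40000 * 1000)
  ns <- unit_spec("NS", trough_to_peak_ms = 0.22, waveform_noise_sd = 0)
  wf2 <- gen_waveforms(ns, 5, seed = 1)
  expect_equal(trough_to_peak(wf2$snippets[1, ], wf2$fs), 9 / 40000 * 1000)
  # zero noise and same seed: identical matrices
  expect_identical(wf$snippets, gen_waveforms(bs, 5, seed = 1)$snippets)
  expect_error(gen_waveforms(unit_spec("NS", trough_to_peak_ms = 0.01), 5),
               "2 samples")
})

test_that("thinning bound is asserted finite", {
  u <- unit_spec("BS", base_rate = 5, kappa = 0)
  u$kappa <- Inf # bypass constructor validation to hit the runtime guard
  expect_error(gen_spike_train(u, lfp = NULL, seed = 1, t_start = 0,
                               t_stop = 10),
               "finite|missing value")
})

test_that("gen_session produces a valid bundle with ground truth", {
  s <- small_session(seed = 3)
  b <- s$bundle
  expect_s3_class(b, "session_bundle")
  expect_equal(length(b$trains), 2)
  expect_equal(nrow(s$ground_truth$units), 2)
  expect_true(all(abs(s$ground_truth$band_fractions -
                        synth_template("control", 3)$band_fractions) < 1e-9))
  # determinism: regenerate and compare everything
  s2 <- small_session(seed = 3)
  expect_identical(b$lfp$synth1$samples, s2$bundle$lfp$synth1$samples)
  expect_identical(b$trains$u01$times, s2$bundle$trains$u01$times)
  expect_identical(b$waveforms$u02$snippets, s2$bundle$waveforms$u02$snippets)
  expect_identical(b$events$beam_times, s2$bundle$events$beam_times)
})

test_that("zero-unit session is valid and loadable", {
  cfg <- synth_config(seed = 10, duration_s = 30, units = list())
  s <- gen_session(cfg)
  expect_equal(length(s$bundle$trains), 0)
  expect_equal(nrow(s$ground_truth$units), 0)
  dir <- withr::local_tempdir()
  save_session(s$bundle, dir)
  loaded <- load_session(dir)
  expect_equal(length(loaded$trains), 0)
  expect_identical(loaded$lfp$synth1$samples, s$bundle$lfp$synth1$samples)
})

test_that("realized session rate sits within 3 SE of the analytic rate", {
  s <- small_session(seed = 4)
  gt <- s$ground_truth$units
  ev <- s$bundle$movement_intervals
  move_frac <- sum(ev[, 2] - ev[, 1]) / s$bundle$duration_s
  for (i in seq_len(nrow(gt))) {
    u <- gt$unit_id[i]
    expected <- gt$base_rate[i] *
      (1 + (gt$movement_gain[i] - 1) * move_frac)
    observed <- length(s$bundle$trains[[u]]$times) / s$bundle$duration_s
    se <- sqrt(expected / s$bundle$duration_s)
    # 2 ms refractory pruning removes ~rate*0.2% of spikes
    expect_lt(abs(observed - expected), 3 * se + 0.02 * expected)
  }
})
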