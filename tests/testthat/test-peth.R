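# events with beam times on a regular grid and movement windows [0, len] s
make_events <- function(n_trials = 100, spacing = 5, move_len = 0.3,
                        t0 = 2) {
  beams <- t0 + spacing * (seq_len(n_trials) - 1)
  event_series(beams, cbind(beams, beams + move_len))
}

test_that("a flat Poisson process yields a flat PETH at its rate", {
  ev <- make_events(200)
  tr <- make_poisson_train(5, max(ev$beam_times) + 3, seed = 1)
  p <- build_peth(tr, ev)
  se <- sqrt(5 / (200 * 0.005)) # Poisson SE per unsmoothed bin
  z <- (p$raw_rate - 5) / se
  expect_lt(max(abs(z)), 5)     # 500 bins: allow the expected extremes
  expect_equal(mean(z^2), 1, tolerance = 0.25)
  expect_equal(mean(p$rate), 5, tolerance = 0.1)
  expect_equal(p$baseline_rate, 5, tolerance = 3 * sqrt(5 / (200 * 0.6)))
})

test_that("single spike lands in its 5 ms bin, unsmoothed", {
  ev <- event_series(10, cbind(10, 10.3))
  tr <- spike_train(10.002, 0, 20)
  p <- build_peth(tr, ev, smooth = FALSE)
  b <- which(p$bin_edges == 0)
  expect_equal(unname(p$counts[1, b]), 1)
  expect_equal(sum(p$counts), 1)
  expect_equal(p$rate[b], 1 / 0.005)
})

test_that("smoothing conserves rate mass and the smoother is 5-point Gaussian", {
  ev <- make_events(50)
  tr <- make_poisson_train(8, max(ev$beam_times) + 3, seed = 2)
  ps <- build_peth(tr, ev, smooth = TRUE)
  pu <- build_peth(tr, ev, smooth = FALSE)
  # edge renormalization perturbs total mass only at the two boundary bins
  expect_equal(sum(ps$rate) * 0.005, sum(pu$rate) * 0.005, tolerance = 1e-4)
  # interior impulse response: normalized 5-point Gaussian, sigma = 1 bin
  k <- exp(-((-2):2)^2 / 2)
  k <- k / sum(k)
  impulse <- numeric(101)
  impulse[51] <- 1
  sm <- spikefield:::.gauss_smooth(impulse)
  expect_equal(sm[49:53], k)
  expect_equal(sum(sm), 1)
})

test_that("PETH of merged trains equals sum of part PETHs before smoothing", {
  ev <- make_events(30)
  t_stop <- max(ev$beam_times) + 3
  a <- make_poisson_train(3, t_stop, seed = 3)
  b <- make_poisson_train(4, t_stop, seed = 4)
  merged <- spike_train(sort(union(a$times, b$times)), 0, t_stop)
  pm <- build_peth(merged, ev, smooth = FALSE)
  pa <- build_peth(a, ev, smooth = FALSE)
  pb <- build_peth(b, ev, smooth = FALSE)
  expect_equal(pm$counts, pa$counts + pb$counts)
})

test_that("movement gain is recovered in-window by the PETH", {
  ev <- make_events(100, move_len = 0.3)
  u <- unit_spec("BS", base_rate = 5, movement_gain = 2)
  tr <- gen_spike_train(u, lfp = NULL, events = ev, seed = 5, t_start = 0,
                        t_stop = max(ev$beam_times) + 3)
  p <- build_peth(tr, ev)
  in_win <- p$bin_centers > 0.02 & p$bin_centers < 0.28
  out_win <- p$bin_centers < -0.05
  expect_equal(mean(p$rate[in_win]), 10, tolerance = 0.8)
  expect_equal(mean(p$rate[out_win]), 5, tolerance = 0.5)
  expect_equal(p$movement_rate / p$baseline_rate, 2, tolerance = 0.1)
})

test_that("baseline_rate reads the [-0.6, 0) window", {
  ev <- make_events(50)
  # all spikes strictly after each event
  times <- as.vector(outer(c(0.05, 0.1, 0.2), ev$beam_times, "+"))
  tr <- spike_train(sort(times), 0, max(ev$beam_times) + 3)
  p <- build_peth(tr, ev)
  expect_equal(peth_baseline_rate(p), 0)
  expect_error(build_peth(tr, ev, window = c(-0.2, 0.5)), "baseline")
})

test_that("modulation test flags gain and respects the null", {
  ev <- make_events(100, move_len = 0.3)
  t_stop <- max(ev$beam_times) + 3
  u2 <- unit_spec("BS", base_rate = 5, movement_gain = 2)
  tr2 <- gen_spike_train(u2, lfp = NULL, events = ev, seed = 6,
                         t_start = 0, t_stop = t_stop)
  m2 <- modulation_test(build_peth(tr2, ev))
  expect_true(m2$modulated)
  expect_lt(m2$p, 0.001)

  # identical rates in both windows every trial -> p = 1
  times <- as.vector(outer(c(-0.45, -0.15, 0.07, 0.22), ev$beam_times, "+"))
  trsame <- spike_train(sort(times), 0, t_stop)
  psame <- build_peth(trsame, ev, window = c(-1, 1.5))
  # movement window is 0.3 s with 2 spikes -> 6.67/s; baseline 0.6 s with
  # 2 spikes -> 3.33/s; construct instead equal *rates*: 1 spike in move,
  # 2 in baseline
  times2 <- as.vector(outer(c(-0.45, -0.15, 0.1), ev$beam_times, "+"))
  tr_eq <- spike_train(sort(times2), 0, t_stop)
  p_eq <- build_peth(tr_eq, ev)
  # per-trial: baseline 2/0.6 = 3.33, movement 1/0.3 = 3.33 -> all diffs 0
  m_eq <- modulation_test(p_eq)
  expect_equal(m_eq$p, 1)
  expect_false(m_eq$modulated)

  expect_error(modulation_test(build_peth(tr2, make_events(5))), "10 trials")
})
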