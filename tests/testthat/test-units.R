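test_that("trough_to_peak measures index arithmetic exactly", {
  # trough at sample 40, post-trough maximum at sample 57, fs 40 kHz
  snippet <- numeric(80)
  snippet[30:50] <- -0.5 * (0.5 + 0.5 * cos(pi * (30:50 - 40) / 10))
  snippet[40] <- -1
  snippet[51:70] <- 0.3 * exp(-abs(51:70 - 57) / 5)
  snippet[57] <- 0.45
  expect_equal(trough_to_peak(snippet, 40000), (57 - 40) / 40000 * 1000)

  adjacent <- c(rep(0, 10), -1, 1, rep(0, 10))
  expect_equal(trough_to_peak(adjacent, 40000), 0.025)
})

test_that("trough_to_peak is invariant to scaling and offset", {
  u <- unit_spec("BS", trough_to_peak_ms = 0.42, waveform_noise_sd = 0)
  w <- gen_waveforms(u, 1, seed = 1)$snippets[1, ]
  d0 <- trough_to_peak(w, 40000)
  expect_equal(trough_to_peak(5.3 * w, 40000), d0)
  expect_equal(trough_to_peak(w + 2.7, 40000), d0)
})

test_that("monotone post-trough decay is flagged non-canonical", {
  snippet <- c(seq(0, -1, length.out = 20), seq(-1, -2, length.out = 40))
  expect_error(trough_to_peak(snippet, 40000),
               class = "non_canonical_waveform")
})

test_that("classification boundary at 0.32 ms with ties to BS", {
  expect_identical(classify_unit(0.42), "BS")
  expect_identical(classify_unit(0.22), "NS")
  expect_identical(classify_unit(0.32), "BS")
  expect_identical(classify_unit(0.319), "NS")
})

test_that("refractory criterion counts violating ISI fraction", {
  expect_true(as.logical(refractory_ok(seq(0, 10, by = 0.1))))
  bursty <- cumsum(rep(c(0.001, 0.1), 50))
  expect_false(as.logical(refractory_ok(bursty)))
  # 5 violations in 1000 ISIs = 0.5% < 1%
  isis <- rep(0.05, 1000)
  isis[seq(100, 900, length.out = 5)] <- 0.001
  expect_true(as.logical(refractory_ok(cumsum(c(0, isis)))))
  low <- refractory_ok(c(1.0))
  expect_true(as.logical(low))
  expect_true(attr(low, "low_count"))
})

test_that("detect_spikes finds injected templates and respects suppression", {
  u <- unit_spec("BS", trough_to_peak_ms = 0.42)
  inj <- c(0.1, 0.2, 0.31, 0.42, 0.5, 0.6, 0.66, 0.75, 0.85, 0.95)
  bb <- gen_broadband(u, inj, duration_s = 1, noise_sd = 0.02, seed = 3)
  det <- detect_spikes(bb$x, bb$fs, threshold = -0.5)
  expect_equal(nrow(det$waveforms$snippets), 10)
  # detection at the downward crossing, within 0.2 ms of the injected trough
  expect_true(all(abs(det$times - inj) < 2e-4))

  # threshold below the floor: nothing
  none <- detect_spikes(bb$x, bb$fs, threshold = -50)
  expect_equal(length(none$times), 0)
  expect_equal(nrow(none$waveforms$snippets), 0)

  # two crossings 0.5 ms apart with 1 ms dead time -> one detection
  fs <- 40000
  x <- rep(0, 400)
  x[100:102] <- -1
  x[120:122] <- -1 # 20 samples = 0.5 ms later
  det2 <- detect_spikes(x, fs, threshold = -0.5, dead_time_ms = 1)
  expect_equal(length(det2$times), 1)

  expect_error(detect_spikes(rep(0, 10), fs, -1), "shorter")
})

test_that("detection count is monotone non-increasing in threshold magnitude", {
  u <- unit_spec("BS", trough_to_peak_ms = 0.42)
  bb <- gen_broadband(u, seq(0.05, 0.95, by = 0.05), noise_sd = 0.1,
                      seed = 9)
  counts <- vapply(c(-0.2, -0.4, -0.6, -0.8, -1.1),
                   function(th) length(detect_spikes(bb$x, bb$fs, th)$times),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("classification is perfect on class-templated waveforms", {
  set.seed(11)
  n_units <- 200
  durations <- ifelse(seq_len(n_units) %% 2 == 0, 0.42, 0.22)
  correct <- vapply(seq_len(n_units), function(i) {
    u <- unit_spec(ifelse(durations[i] > 0.3, "BS", "NS"),
                   trough_to_peak_ms = durations[i],
                   waveform_noise_sd = 0.10)
    wf <- gen_waveforms(u, 20, seed = i)
    d <- trough_to_peak(colMeans(wf$snippets), wf$fs)
    classify_unit(d) == u$class_label
  }, TRUE)
  expect_equal(mean(correct), 1.0)
})

test_that("classify_units builds a coherent table and flags non-canonical units", {
  s <- small_session(seed = 2)
  tab <- classify_units(s$bundle$waveforms, s$bundle$trains)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$class_label, c("BS", "NS"))
  expect_true(all(tab$refractory_ok))
  gt <- s$ground_truth$units
  expect_equal(tab$class_label[match(gt$unit_id, tab$unit_id)],
               gt$class_label)
})
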