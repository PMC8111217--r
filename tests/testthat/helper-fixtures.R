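# shared fixtures, all generated in code

make_tone <- function(freq = 20, duration_s = 10, fs = 1000, amp = 1,
                      phase = 0) {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  amp * cos(2 * pi * freq * t + phase)
}

# spike train with exponential ISIs at a given rate
make_poisson_train <- function(rate = 5, duration_s = 100, seed = 1) {
  set.seed(seed)
  isi <- stats::rexp(ceiling(rate * duration_s * 1.5) + 50, rate)
  times <- cumsum(isi)
  times <- times[times < duration_s]
  spike_train(times, 0, duration_s)
}

# train from explicit ISIs
train_from_isis <- function(isis, t0 = 0.1) {
  times <- t0 + cumsum(c(0, isis))
  spike_train(times, 0, max(times) + 0.1)
}

# small synthetic session for structural tests
small_session <- function(seed = 1, condition = "control") {
  gen_session(synth_template(condition, seed = seed, n_bs = 1, n_ns = 1,
                             duration_s = 120))
}

expect_circ_equal <- function(actual_deg, expected_deg, tol = 2) {
  d <- ((actual_deg - expected_deg + 180) %% 360) - 180
  expect_lt(abs(d), tol)
}
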