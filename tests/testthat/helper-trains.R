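# Toy click-train constructors used across the suite.

# constant-rate burst: n clicks at `rate` c/s
const_train <- function(rate, n, id = "t1", start = 0, freq = 125, ...) {
  click_train(id, start + (seq_len(n) - 1) / rate, freq, ...)
}

# train following a given sequence of instantaneous rates (c/s), one ICI each
rate_train <- function(rates, id = "t1", start = 0, freq = 125, ...) {
  click_train(id, start + cumsum(c(0, 1 / rates)), freq, ...)
}

# clean unimodal rise-fall burst (mushroom shape), n ICIs
mushroom_rates <- function(n = 120, base = 300, peak = 800) {
  u <- (seq_len(n) - 0.5) / n
  base + (peak - base) * sin(pi * u)
}

# oscillating burst (wiggle shape) with `cycles` rate maxima, n ICIs
wiggle_rates <- function(n = 150, mid = 500, amp = 180, cycles = 3) {
  u <- (seq_len(n) - 0.5) / n
  mid - amp * cos(2 * pi * cycles * u)
}

# foraging-shaped rates: slow search, geometric approach, rising buzz
foraging_rates <- function(n_search = 300, n_buzz = 20) {
  c(rep(60, n_search),
    exp(seq(log(60), log(300), length.out = 40)),
    exp(seq(log(300), log(600), length.out = n_buzz)))
}

expect_identical_trains <- function(a, b) {
  expect_equal(a$times, b$times)
  expect_equal(a$freq, b$freq)
  expect_identical(a$id, b$id)
}
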