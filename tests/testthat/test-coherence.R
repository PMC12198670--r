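test_that("default windowing reproduces the 0.504-Hz spectral resolution", {
  w <- windowing_config()
  expect_equal(w$window_s, 1.984)
  expect_lt(abs(w$resolution_hz - 0.504), 0.001)
  expect_identical(w$total_samples, 3968L)
})

test_that("self-coherence is 1 and coherence is symmetric and scale invariant", {
  w <- windowing_config(n_windows = 4)
  set.seed(1)
  x <- rnorm(w$total_samples)
  y <- rnorm(w$total_samples)
  cs <- wavelet_coherence(x, x, default_bank, w)
  expect_true(all(abs(cs$coherence - 1) < 1e-10))

  ab <- wavelet_coherence(x, y, default_bank, w)
  ba <- wavelet_coherence(y, x, default_bank, w)
  expect_equal(ab$coherence, ba$coherence)
  sc <- wavelet_coherence(-3.7 * x, 0.01 * y, default_bank, w)
  expect_equal(sc$coherence, ab$coherence, tolerance = 1e-10)
})

test_that("coherence stays in [0, 1] on heterogeneous inputs", {
  w <- windowing_config(n_windows = 2)
  set.seed(42)
  for (i in 1:12) {
    x <- switch(1 + i %% 4,
      rnorm(w$total_samples),
      sin(2 * pi * runif(1, 1, 60) * seq_len(w$total_samples) / 250),
      cumsum(rnorm(w$total_samples)),
      rexp(w$total_samples) - 1)
    y <- rnorm(w$total_samples)
    cs <- wavelet_coherence(x, y, default_bank, w)
    expect_true(all(cs$coherence >= 0 & cs$coherence <= 1))
  }
})

test_that("independent noise sits at a small-sample bias level that falls with window length", {
  set.seed(11)
  bias <- sapply(c(248, 496), function(L) {
    w <- windowing_config(n_windows = 4, window_samples = L)
    mean(replicate(25, {
      x <- rnorm(w$total_samples); y <- rnorm(w$total_samples)
      mean(wavelet_coherence(x, y, bank_subset_alpha(), w)$coherence)
    }))
  })
  expect_lt(bias[2], 0.9)
  expect_lt(bias[2], bias[1])  # more in-window averaging, less bias
})

test_that("band summaries follow their definitions", {
  spec <- coh_fixture(cf = c(8.27, 9.89, 11.65, 13.55),
                      coherence = c(0.2, 0.4, 0.6, 0.9))
  expect_equal(band_mean(spec, "alpha"), mean(c(0.2, 0.4, 0.6)))
  expect_equal(band_mean(coh_fixture(10, 0.37), "alpha"), 0.37)
  expect_equal(band_mean(coh_fixture(1:5 + 8, rep(0.25, 5)), c(8, 13)), 0.25)
  expect_error(band_mean(spec, c(70, 80)), "no center frequency")

  expect_equal(band_peak_frequency(spec, "alpha"), 11.65)
  flat <- coh_fixture(c(8.27, 9.89, 11.65), rep(0.5, 3))
  expect_equal(band_peak_frequency(flat, "alpha"), 8.27)  # tie -> lowest cf
  expect_error(band_peak_frequency(spec, c(100, 120)), "no center frequency")
})

test_that("snap_to_bank returns the nearest center frequency", {
  expect_equal(snap_to_bank(10.2, default_bank),
               default_bank$cfs[which.min(abs(default_bank$cfs - 10.2))])
})

test_that("length and NA violations are rejected", {
  w <- windowing_config(n_windows = 2)
  x <- rnorm(w$total_samples)
  expect_error(wavelet_coherence(x[-1], x[-1], default_bank, w), "does not equal")
  expect_error(wavelet_coherence(x, x[-1], default_bank, w), "equal length")
  bad <- x; bad[5] <- NA
  expect_error(wavelet_coherence(bad, x, default_bank, w), "finite")
})
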