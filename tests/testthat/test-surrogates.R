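test_that("AAFT surrogates conserve the value multiset exactly", {
  set.seed(3)
  for (n in c(8, 17, 64, 255, 1024)) {
    x <- switch(1 + n %% 3, rnorm(n), rexp(n), rt(n, df = 3))
    s <- aaft(x)
    expect_identical(sort(s), sort(x))
    expect_false(identical(s, x) && n > 16)  # order actually randomized
  }
})

test_that("AAFT rejects constant or too-short signals and is seed-reproducible", {
  expect_error(aaft(rep(1, 100)), "constant")
  expect_error(aaft(rnorm(4)), "length")
  x <- rnorm(64)
  expect_identical(aaft(x, seed = 4), aaft(x, seed = 4))
  expect_false(identical(aaft(x, seed = 4), aaft(x, seed = 5)))
})

test_that("AAFT approximately preserves the power spectrum of Gaussian input", {
  set.seed(21)
  n <- 256
  cors <- replicate(50, {
    x <- as.numeric(stats::filter(rnorm(n + 20), rep(0.3, 4), sides = 1))[-(1:20)]
    px <- Mod(fft(x))[2:(n / 2)]^2
    ps <- Mod(fft(aaft(x)))[2:(n / 2)]^2
    cor(px, ps)
  })
  expect_gte(mean(cors), 0.9)
})

test_that("surrogating both signals removes deterministic coupling", {
  w <- windowing_config(n_windows = 4)
  set.seed(8)
  # strongly phase-coupled pair
  x <- as.numeric(stats::filter(rnorm(w$total_samples), rep(0.5, 3), sides = 2))
  x[is.na(x)] <- 0
  y <- x + 0.1 * rnorm(w$total_samples)
  coupled <- mean(wavelet_coherence(x, y, bank_subset_alpha(), w)$coherence)
  bm <- surrogate_band_means(x, y, "alpha", default_bank, w,
                             surrogate_config(n_surrogates = 20, seed = 1))
  null_ref <- mean(replicate(20, {
    a <- rnorm(w$total_samples); b <- rnorm(w$total_samples)
    mean(wavelet_coherence(a, b, bank_subset_alpha(), w)$coherence)
  }))
  expect_gt(coupled, max(bm))             # surrogates lose the coupling
  expect_lt(abs(mean(bm) - null_ref), 0.1)  # and land at the independent null
})

test_that("threshold statistic is monotone in the percentile and seeded", {
  w <- windowing_config(n_windows = 2)
  set.seed(5)
  x <- rnorm(w$total_samples); y <- rnorm(w$total_samples)
  cfg50 <- surrogate_config(20, "percentile", percentile = 50, seed = 7)
  cfg95 <- surrogate_config(20, "percentile", percentile = 95, seed = 7)
  t50 <- coherence_threshold(x, y, "alpha", default_bank, w, cfg50)
  t95 <- coherence_threshold(x, y, "alpha", default_bank, w, cfg95)
  expect_lte(as.numeric(t50), as.numeric(t95))
  expect_identical(attr(t50, "band_means"), attr(t95, "band_means"))
  again <- coherence_threshold(x, y, "alpha", default_bank, w, cfg50)
  expect_identical(as.numeric(t50), as.numeric(again))
  cfg_med <- surrogate_config(20, "median", seed = 7)
  expect_equal(as.numeric(coherence_threshold(x, y, "alpha", default_bank, w, cfg_med)),
               median(attr(t50, "band_means")))
})

test_that("significance masks follow the strict exceedance rule", {
  bm <- tibble::tibble(trial = rep(1:3, each = 2),
                       band = rep(c("alpha", "beta"), 3),
                       band_mean = c(0.6, 0.2, 0.4, 0.5, 0.3, 0.3))
  thr0 <- dplyr::mutate(bm[, 1:2], threshold = 0)
  expect_true(all(significance_mask(bm, thr0)$retained))
  thr_hi <- dplyr::mutate(bm[, 1:2], threshold = 1)
  expect_false(any(significance_mask(bm, thr_hi)$retained))
  thr <- dplyr::mutate(bm[, 1:2], threshold = c(0.5, 0.5, 0.4, 0.4, 0.1, 0.3))
  m <- significance_mask(bm, thr)
  expect_identical(m$retained, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  ret <- attr(m, "retention")
  expect_equal(ret$retained_frac[ret$band == "alpha"], 2 / 3)
})
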