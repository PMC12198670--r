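# shared small fixtures; heavier simulations live in the files that need them

default_bank <- wavelet_bank()
default_win <- windowing_config()

# quick coherence spectrum tibble for unit fixtures
coh_fixture <- function(cf, coherence) {
  out <- tibble::tibble(cf = cf, coherence = coherence)
  class(out) <- c("coh_spectrum", class(out))
  out
}

# brute-force cross-correlation argmax (oracle for generator delays)
xcorr_peak_lag <- function(a, b, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[seq_len(length(a) - l)] * b[seq_len(length(a) - l) + l])
    else sum(b[seq_len(length(b) + l)] * a[seq_len(length(b) + l) - l])
  }, numeric(1))
  lags[which.max(cc)]
}

bank_subset_alpha <- function() cmcwave:::bank_subset(default_bank, 8, 12)
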