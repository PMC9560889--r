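# Shared helpers: small deterministic signal builders used across test files.

ar2_series <- function(n = 2000, a1 = 0.5, a2 = -0.3, sd = 0.1, seed = 1) {
  set.seed(seed)
  e <- rnorm(n, 0, sd)
  y <- numeric(n)
  for (t in 3:n) y[t] <- a1 * y[t - 1] + a2 * y[t - 2] + e[t]
  y
}

sine_at <- function(f, fs, n, phase = 0) {
  sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# dominant FFT frequency of a series in Hz
peak_frequency <- function(v, fs) {
  n <- length(v)
  spec <- Mod(stats::fft(v))[seq_len(n %/% 2)]
  (which.max(spec) - 1) * fs / n
}
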