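# Shared fixtures, all generated in code.

logistic_map <- function(n, r = 4, x0 = 0.2) {
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

sinusoid <- function(n, period, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * (seq_len(n) - 1) / period + phase)
}

# sinusoid plus seeded Gaussian noise, returned with the clean component
noisy_sinusoid <- function(n, period, amplitude = 1, noise_sd = 0.1, seed = 1) {
  clean <- sinusoid(n, period, amplitude)
  set.seed(seed)
  list(clean = clean, noisy = clean + rnorm(n, 0, noise_sd))
}

default_sink_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_spiral_sink(spiral_sink_system(noise_sd = 0))
    cache
  }
})
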