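# Shared fixtures, built in code at test time.

# naive double-loop transcription of the per-sample Gaussian mixture:
# the independent oracle for the vectorized density evaluation
naive_rvkde_density <- function(samples, bandwidths, v) {
  n <- nrow(samples); d <- ncol(samples)
  total <- 0
  for (i in seq_len(n)) {
    dist2 <- sum((v - samples[i, ])^2)
    total <- total + (1 / (sqrt(2 * pi) * bandwidths[i]))^d *
      exp(-dist2 / (2 * bandwidths[i]^2))
  }
  total / n
}

# draw from a two-component Gaussian mixture with known parameters
draw_known_mixture <- function(n, w2 = 0.1, mu1 = c(0, 0), mu2 = c(3, 3),
                               seed = 1) {
  set.seed(seed)
  n2 <- stats::rbinom(1, n, w2)
  x <- rbind(
    matrix(stats::rnorm((n - n2) * length(mu1)), ncol = length(mu1)),
    sweep(matrix(stats::rnorm(n2 * length(mu2)), ncol = length(mu2)), 2, mu2, `+`)
  )
  list(x = x, labels = c(rep(0L, n - n2), rep(1L, n2)),
       means = rbind(mu1, mu2), weights = c(1 - w2, w2))
}

small_cohort <- function(n_cases = 150, seed = 42) {
  generate_cohort(cohort_config(n_cases = n_cases, rng_seed = seed))
}
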