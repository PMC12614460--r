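# Two well-separated Gaussian blobs with a 0/1 outcome.
make_blobs <- function(n0 = 60, n1 = 60, sep = 3, p = 2, seed = 1) {
  withr::with_seed(seed, {
    x0 <- matrix(rnorm(n0 * p, -sep / 2), ncol = p)
    x1 <- matrix(rnorm(n1 * p, sep / 2), ncol = p)
  })
  tb <- tibble::as_tibble(as.data.frame(rbind(x0, x1)))
  names(tb) <- paste0("f", seq_len(p))
  tb$rupture <- rep(c(0L, 1L), c(n0, n1))
  tb
}

# Pure-noise features with an imbalanced outcome.
make_noise_cohort <- function(n = 200, prevalence = 0.1, p = 2, seed = 1) {
  withr::with_seed(seed, {
    tb <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), ncol = p)))
  })
  names(tb) <- paste0("f", seq_len(p))
  n1 <- round(n * prevalence)
  tb$rupture <- rep(c(1L, 0L), c(n1, n - n1))
  tb
}
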