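# Small in-code fixtures shared across test files.

random_complex_matrix <- function(nr, nc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
}

# planted low-rank + sparse instance; the ground truth is the oracle
planted_instance <- function(n = 40L, rank = 2L, support_frac = 0.05,
                             magnitude = 10, seed = 1L) {
  set.seed(seed)
  A <- random_complex_matrix(n, rank)
  B <- random_complex_matrix(rank, n)
  L0 <- A %*% B
  S0 <- matrix(0 + 0i, n, n)
  support <- sample(n * n, round(support_frac * n * n))
  S0[support] <- magnitude * exp(1i * runif(length(support), 0, 2 * pi))
  list(M = L0 + S0, L0 = L0, S0 = S0, support = sort(support))
}

rel_frob <- function(x, y) {
  sqrt(sum(Mod(x - y)^2)) / sqrt(sum(Mod(y)^2))
}

small_ll_phantom <- function(grid = 32L, n_frames = 12L, noise_sigma = 0.005,
                             seed = 1L) {
  set.seed(seed)
  make_look_locker_series(phantom_spec(grid = c(grid, grid),
                                       n_frames = n_frames,
                                       noise_sigma = noise_sigma))
}

fit_myocardial_t1 <- function(series, truth) {
  img <- reconstruct_images(series)
  sig <- apply(img, 3, function(fr) mean(fr[truth$myo_mask]))
  fit_t1_look_locker(truth$times, sig)
}
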