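test_that("Look-Locker T1 fit inverts noiseless three-parameter curves", {
  t <- seq(0.05, 6, length.out = 50)

  # B/A = 2: the correction is the identity
  s1 <- abs(1 - 2 * exp(-t / 0.5))
  f1 <- fit_t1_look_locker(t, s1)
  expect_true(f1$converged)
  expect_equal(f1$T1, 0.5, tolerance = 1e-5)

  # B/A = 1.8: closed-form correction gives T1 = 0.5 * (1.8 - 1) = 0.4
  s2 <- abs(1 - 1.8 * exp(-t / 0.5))
  f2 <- fit_t1_look_locker(t, s2)
  expect_equal(f2$T1_star, 0.5, tolerance = 1e-5)
  expect_equal(f2$T1, 0.4, tolerance = 1e-4)

  # scale invariance of the corrected T1
  f3 <- fit_t1_look_locker(t, 37 * s2)
  expect_equal(f3$T1, f2$T1, tolerance = 1e-8)

  # degenerate input: reported, not raised
  expect_false(fit_t1_look_locker(t, rep(1, 50))$converged)
  expect_error(fit_t1_look_locker(t[1:3], s1[1:3]), ">= 4")
})

test_that("noisy T1 fits recover the truth within 1% on average", {
  t <- seq(0.05, 6, length.out = 50)
  clean <- 1 - 2 * exp(-t / 1.2)
  set.seed(31)
  t1_hat <- vapply(1:50, function(r) {
    fit_t1_look_locker(t, abs(clean + rnorm(50, sd = 0.01)))$T1
  }, numeric(1))
  expect_lt(abs(mean(t1_hat) - 1.2) / 1.2, 0.01)
})

test_that("background noise std matches the Rayleigh closed form", {
  img <- matrix(0, 20, 20)
  expect_equal(background_noise_std(img, matrix(TRUE, 20, 20)), 0)

  sigma <- 0.7
  set.seed(17)
  noise <- matrix(Mod(complex(real = rnorm(80^2, sd = sigma),
                              imaginary = rnorm(80^2, sd = sigma))), 80, 80)
  expect_equal(background_noise_std(noise, matrix(TRUE, 80, 80)),
               sigma * sqrt(2 - pi / 2), tolerance = 0.05)

  # locality: a bright pixel outside the ROI changes nothing
  roi <- corner_roi_mask(c(80, 80))
  before <- background_noise_std(noise, roi)
  noise[40, 40] <- 1e6
  expect_identical(background_noise_std(noise, roi), before)
  expect_error(background_noise_std(noise, matrix(FALSE, 80, 80)), "empty")
})

test_that("tensor fit recovers planted tensors, FA/MD closed forms hold", {
  dirs <- fibonacci_directions(12)
  b <- c(0, rep(1000, 12))
  g <- rbind(c(0, 0, 1), dirs)

  make_signals <- function(D) exp(-b * rowSums((g %*% D) * g))

  iso <- fit_diffusion_tensor(b, g, make_signals(diag(rep(1e-3, 3))))
  expect_equal(iso$FA, 0, tolerance = 1e-8)
  expect_equal(iso$MD, 1e-3, tolerance = 1e-9)

  stick <- fit_diffusion_tensor(b, g, make_signals(diag(c(1, 0, 0) * 1e-3)))
  expect_equal(stick$FA, 1, tolerance = 1e-6)

  D <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  fit <- fit_diffusion_tensor(b, g, make_signals(D))
  expect_equal(fit$eigenvalues, c(1.7, 0.3, 0.3) * 1e-3, tolerance = 1e-6)
  expect_equal(fit$MD, 0.76667e-3, tolerance = 1e-4)
  expect_equal(fit$FA, 0.799022, tolerance = 1e-4)

  # FA invariance under rotation of the gradient frame and scaling
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  fit_rot <- fit_diffusion_tensor(b, g %*% R, make_signals(D))
  expect_equal(fit_rot$FA, fit$FA, tolerance = 1e-8)
  fit_scaled <- fit_diffusion_tensor(b, g, make_signals(D / 2))
  expect_equal(fit_scaled$MD, fit$MD / 2, tolerance = 1e-6)
  expect_equal(fit_scaled$FA, fit$FA, tolerance = 1e-6)

  # rank-deficient design: all directions collinear
  g_bad <- matrix(rep(c(1, 0, 0), 13), ncol = 3, byrow = TRUE)
  expect_error(fit_diffusion_tensor(b, g_bad, make_signals(D)),
               "rank-deficient")
  expect_error(fit_diffusion_tensor(b, g, -make_signals(D)), "positive")
})
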