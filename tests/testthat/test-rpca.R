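test_that("complex soft-thresholding shrinks moduli and preserves phase", {
  expect_equal(complex_soft_threshold(0 + 0i, 0.5), 0 + 0i)
  expect_equal(complex_soft_threshold(3 + 4i, 0), 3 + 4i)

  # modulus 5 shrinks to 4, direction unchanged
  expect_equal(complex_soft_threshold(3 + 4i, 1), 2.4 + 3.2i, tolerance = 1e-12)

  # independent oracle: numerically minimise tau*|x| + 0.5*|x - z|^2
  z <- 3 + 4i; tau <- 1
  obj <- function(p) tau * sqrt(p[1]^2 + p[2]^2) +
    0.5 * ((p[1] - Re(z))^2 + (p[2] - Im(z))^2)
  opt <- optim(c(Re(z), Im(z)), obj, method = "BFGS")
  expect_equal(complex(real = opt$par[1], imaginary = opt$par[2]),
               complex_soft_threshold(z, tau), tolerance = 1e-5)

  set.seed(42)
  z <- random_complex_matrix(5, 4)
  out <- complex_soft_threshold(z, 0.8)
  small <- Mod(z) <= 0.8
  expect_true(all(out[small] == 0 + 0i))          # exact zeros
  expect_equal(Arg(out[!small]), Arg(z[!small]), tolerance = 1e-12)
  expect_equal(Mod(out[!small]), Mod(z[!small]) - 0.8, tolerance = 1e-12)

  expect_error(complex_soft_threshold(1 + 1i, -0.1), "nonnegative")
})

test_that("singular value thresholding matches an independent SVD oracle", {
  X <- random_complex_matrix(6, 4, seed = 11)
  expect_equal(singular_value_threshold(X, 0), X, tolerance = 1e-12)

  D <- diag(c(5, 1))
  expect_equal(singular_value_threshold(D, 2), diag(c(3, 0)),
               tolerance = 1e-12)

  out <- singular_value_threshold(X, 0.7)
  expect_equal(svd(out, nu = 0, nv = 0)$d,
               pmax(svd(X, nu = 0, nv = 0)$d - 0.7, 0), tolerance = 1e-10)

  expect_error(singular_value_threshold(matrix(c(1, NA, 2, 3), 2), 0.1),
               "finite")
  expect_error(singular_value_threshold(X, -1), "nonnegative")
})

test_that("rpca_decompose handles degenerate and clean low-rank input", {
  z <- rpca_decompose(matrix(0 + 0i, 5, 7),
                      solver_config(lambda_eff = 1 / sqrt(7)))
  expect_true(z$converged)
  expect_equal(z$L, matrix(0 + 0i, 5, 7))
  expect_equal(z$S, matrix(0 + 0i, 5, 7))

  # exactly low-rank M, nothing sparse to find
  set.seed(3)
  M <- random_complex_matrix(40, 2) %*% random_complex_matrix(2, 40)
  fit <- rpca_decompose(M, solver_config(lambda_eff = 1 / sqrt(40)))
  expect_true(fit$converged)
  expect_lt(rel_frob(fit$L, M), 1e-5)
  expect_lt(sqrt(sum(Mod(fit$S)^2)) / sqrt(sum(Mod(M)^2)), 1e-5)
  expect_equal(fit$rank_L, 2L)
})

test_that("rpca_decompose recovers a planted low-rank + sparse decomposition", {
  inst <- planted_instance(seed = 7)
  fit <- rpca_decompose(inst$M, solver_config(lambda_eff = 1 / sqrt(40)))
  expect_true(fit$converged)
  expect_lt(rel_frob(fit$L, inst$L0), 1e-4)
  expect_identical(which(Mod(fit$S) > 0), inst$support)
  # conservation at convergence
  expect_lte(rel_frob(fit$L + fit$S, inst$M), 1e-7)
})

test_that("rpca_decompose is equivariant under column permutation and scaling", {
  inst <- planted_instance(seed = 21)
  cfg <- solver_config(lambda_eff = 1 / sqrt(40))
  fit <- rpca_decompose(inst$M, cfg)

  set.seed(4)
  perm <- sample(ncol(inst$M))
  fitp <- rpca_decompose(inst$M[, perm], cfg)
  expect_lt(max(Mod(fitp$L - fit$L[, perm])) / max(Mod(fit$L)), 1e-10)
  expect_lt(max(Mod(fitp$S - fit$S[, perm])) / max(Mod(fit$S)), 1e-10)

  fits <- rpca_decompose(3.5 * inst$M, cfg)
  expect_lt(rel_frob(fits$L, 3.5 * fit$L), 1e-8)
  expect_lt(rel_frob(fits$S + 1e-30, 3.5 * fit$S + 1e-30), 1e-6)
})

test_that("non-convergence is reported, not raised", {
  inst <- planted_instance(seed = 2)
  fit <- expect_silent(
    rpca_decompose(inst$M, solver_config(lambda_eff = 1 / sqrt(40),
                                         max_iter = 2L)))
  expect_false(fit$converged)
  expect_gt(fit$final_residual, fit$config$tol)
})

test_that("solver input validation rejects bad arguments", {
  expect_error(solver_config(lambda_eff = -1), "positive")
  expect_error(solver_config(rho = 1), "greater than 1")
  expect_error(solver_config(tol = 0), "positive")
  expect_error(rpca_decompose(matrix(c(1, Inf, 0, 1), 2),
                              solver_config(lambda_eff = 0.5)), "finite")
  expect_error(rpca_decompose(matrix(1, 2, 2), solver_config()), "lambda_eff")
})
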