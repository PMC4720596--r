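test_that("Look-Locker phantom follows the inversion-recovery model", {
  set.seed(1)
  ph <- make_look_locker_series(
    phantom_spec(grid = c(32, 32), noise_sigma = 0,
                 times = seq(0.05, 12, length.out = 12)))
  truth <- ph$truth
  # late inversion times (about 8 T1) approach the equilibrium amplitude A
  late <- Re(ph$images[, , length(truth$times)])
  expect_lt(max(abs(late - truth$a_map) / pmax(truth$a_map, 0.1)), 0.02)

  # noiseless model inversion recovers the myocardial T1* to < 0.1%
  fit <- fit_myocardial_t1(ph$kspace, truth)
  expect_true(fit$converged)
  expect_lt(abs(fit$T1_star - 1.2) / 1.2, 1e-3)
  expect_lt(abs(fit$T1 - 1.2) / 1.2, 1e-3)        # B = 2A makes T1 = T1*
  expect_error(make_look_locker_series(
    phantom_spec(times = c(0.1, 0.1, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))),
    "strictly increasing")
})

test_that("noisy Look-Locker fits are unbiased under the generating model", {
  t1_hat <- vapply(1:50, function(r) {
    ph <- small_ll_phantom(grid = 24L, noise_sigma = 0.01, seed = 100 + r)
    fit_myocardial_t1(ph$kspace, ph$truth)$T1
  }, numeric(1))
  se <- sd(t1_hat) / sqrt(length(t1_hat))
  expect_lt(abs(mean(t1_hat) - 1.2), 3 * se + 1e-3)
})

test_that("cine phantom: static limit is rank 1, dynamic frames are full rank", {
  static <- make_cine_series(phantom_spec(grid = c(32, 32), n_frames = 6,
                                          noise_sigma = 0),
                             radius_amplitude = 0)
  d <- svd(casoratify(static$kspace), nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-8 * d[1]), 1L)

  set.seed(2)
  dyn <- make_cine_series(phantom_spec(grid = c(64, 64), n_frames = 20))
  dd <- svd(casoratify(dyn$kspace), nu = 0, nv = 0)$d
  expect_equal(sum(dd > 1e-8 * dd[1]), 20L)

  totals <- apply(Mod(dyn$images), 3, sum)
  expect_lt(sd(totals) / mean(totals), 0.1)
})

test_that("DWI phantom obeys the tensor signal model", {
  set.seed(3)
  spec <- phantom_spec(grid = c(32, 32), noise_sigma = 0,
                       bvals = c(0, rep(1000, 12)),
                       directions = rbind(c(0, 0, 1), fibonacci_directions(12)))
  ph <- make_dwi_set(spec)
  # b = 0 frame equals s0 everywhere
  expect_lt(max(abs(Mod(ph$images[, , 1]) - ph$truth$s0_map)), 1e-10)

  # isotropic fluid region: identical signal in all directions at fixed b
  fluid_px <- which(abs(ph$truth$fa) < 1e-6 & ph$truth$md > 2e-3,
                    arr.ind = FALSE)[1]
  sig <- Mod(ph$images)[fluid_px + (1:12) * 32 * 32]
  expect_lt(diff(range(sig)) / mean(sig), 1e-10)

  # noiseless voxelwise fit recovers the planted eigenvalues to < 0.1%
  maps <- fa_md_maps(Mod(ph$images), ph$truth$bvals, ph$truth$directions,
                     mask = ph$truth$object_mask)
  core <- ph$truth$object_mask & ph$truth$fa > 0.7     # tract interior
  expect_lt(max(abs(maps$fa[core] - ph$truth$fa[core])), 1e-3)
  expect_lt(max(abs(maps$md[core] - ph$truth$md[core]) / ph$truth$md[core]),
            1e-3)

  expect_error(make_dwi_set(phantom_spec(
    grid = c(32, 32), bvals = c(0, rep(1000, 5)),
    directions = rbind(c(0, 0, 1), fibonacci_directions(5)))),
    "at least 6")
})

test_that("spike injection is seeded, ledgered and complete", {
  ph <- small_ll_phantom(seed = 4)
  none <- add_spikes(ph$kspace, spike_model(n_spikes = 0L, seed = 1))
  expect_identical(none$corrupted$data, ph$kspace$data)
  expect_equal(nrow(none$ledger), 0L)

  model <- spike_model(n_spikes = 7L, kernel_half_width = 2L, seed = 99)
  a <- add_spikes(ph$kspace, model)
  b <- add_spikes(ph$kspace, model)
  expect_identical(a$corrupted$data, b$corrupted$data)
  expect_identical(a$ledger, b$ledger)

  expect_equal(length(unique(a$ledger$spike)), 7L)
  expect_lte(nrow(a$ledger), 7L * 5L)

  # ledger completeness: the difference is exactly the ledgered additions
  diff <- a$corrupted$data - ph$kspace$data
  added <- array(0 + 0i, dim(diff))
  idx <- cbind(a$ledger$sample_kx, a$ledger$sample_ky, a$ledger$frame)
  for (r in seq_len(nrow(a$ledger)))
    added[idx[r, 1], idx[r, 2], idx[r, 3]] <-
      added[idx[r, 1], idx[r, 2], idx[r, 3]] + a$ledger$value[r]
  expect_equal(diff, added, tolerance = 1e-14)
  expect_true(all(Mod(diff[added == 0 + 0i]) == 0))

  # spike centres respect the central exclusion window
  excl <- central_window_mask(dim(ph$kspace$data)[1:2],
                              ph$kspace$center_index, 16)
  expect_false(any(excl[cbind(a$ledger$kx, a$ledger$ky)]))
})

test_that("spikes amplify the background noise of reconstructed images", {
  for (seed in 1:3) {
    ph <- small_ll_phantom(grid = 48L, seed = seed)
    sim <- add_spikes(ph$kspace, spike_model(n_spikes = c(3L, 10L),
                                             seed = seed * 13))
    expect_gt(background_noise_std(reconstruct_images(sim$corrupted)),
              background_noise_std(reconstruct_images(ph$kspace)))
  }
})
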