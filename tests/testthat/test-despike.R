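# End-to-end pipeline behaviour on small phantoms. The full-scale surrogate
# experiments live in test-acceptance.R.

test_that("a spike-free low-rank series passes through almost unchanged", {
  ph <- make_cine_series(phantom_spec(grid = c(32, 32), n_frames = 8,
                                      noise_sigma = 0))
  res <- despike(ph$kspace, despike_config(kappa = 6))
  expect_lt(sqrt(sum(Mod(res$spikes$data)^2) / sum(Mod(ph$kspace$data)^2)),
            1e-4)
  expect_lt(rel_frob(res$clean$data, ph$kspace$data), 1e-4)
  # idempotence in image space: reconstruction changes by < 1%
  expect_lt(rel_frob(reconstruct_images(res$clean),
                     reconstruct_images(ph$kspace)), 0.01)
})

test_that("injected spikes are captured and removed from the clean series", {
  ph <- small_ll_phantom(grid = 64L, seed = 5)
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 8L, seed = 3))
  res <- despike(sim$corrupted, despike_config(kappa = 5))
  expect_true(all(res$diagnostics$converged))

  led <- sim$ledger
  idx <- cbind(led$sample_kx, led$sample_ky, led$frame)
  resid <- res$clean$data[idx] - ph$kspace$data[idx]
  removed <- 1 - sum(Mod(resid)^2) / sum(Mod(led$value)^2)
  expect_gte(removed, 0.9)

  # the low-rank component keeps the full rank of the corrupted series
  d <- svd(casoratify(res$clean), nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-8 * d[1]), dim(ph$kspace$data)[3])
  expect_equal(res$diagnostics$rank_L, dim(ph$kspace$data)[3])
})

test_that("clean + spikes conserves the measurement; exactly so at refills", {
  ph <- small_ll_phantom(grid = 32L, seed = 6)
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 5L, seed = 8))
  res <- despike(sim$corrupted, despike_config(kappa = 5))
  total <- res$clean$data + res$spikes$data
  expect_lt(rel_frob(total, sim$corrupted$data), 1e-6)
  refilled <- res$diagnostics$refilled_mask
  expect_identical(total[refilled], sim$corrupted$data[refilled])
})

test_that("frame order does not affect the despiked output", {
  ph <- small_ll_phantom(grid = 32L, seed = 9)
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 4L, seed = 10))
  cfg <- despike_config(kappa = 5)
  res <- despike(sim$corrupted, cfg)

  set.seed(11)
  perm <- sample(dim(ph$kspace$data)[3])
  permuted <- kspace_series(sim$corrupted$data[, , perm])
  res_p <- despike(permuted, cfg)
  unperm <- array(0 + 0i, dim(res_p$clean$data))
  unperm[, , perm] <- res_p$clean$data
  expect_lt(max(Mod(unperm - res$clean$data)) / max(Mod(res$clean$data)),
            1e-8)
})

test_that("single-frame mode decomposes each frame independently", {
  set.seed(20)
  ph <- make_cine_series(phantom_spec(grid = c(32, 32), n_frames = 4))
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 3L, seed = 12))
  cfg <- despike_config(kappa = 3, mode = "singleframe")
  res <- despike(sim$corrupted, cfg)
  expect_length(res$diagnostics$converged, 4L)

  # frame 2 alone gives the same answer as frame 2 of the joint call
  single <- kspace_series(frame_as_matrix(sim$corrupted, 2),
                          center_index = sim$corrupted$center_index)
  res1 <- despike(single, cfg)
  expect_equal(res1$clean$data[, , 1], res$clean$data[, , 2],
               tolerance = 1e-12)
})

test_that("grouped despiking equals manual per-group runs", {
  set.seed(13)
  ph <- make_dwi_set(phantom_spec(grid = c(32, 32)))
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 6L, seed = 14))
  kappas <- c("100" = 6, "1000" = 5)
  res <- despike_grouped(sim$corrupted, kappa_by_group = kappas)

  bv <- ph$truth$bvals
  for (g in unique(bv)) {
    sel <- which(bv == g)
    sub <- kspace_series(sim$corrupted$data[, , sel, drop = FALSE],
                         center_index = sim$corrupted$center_index)
    manual <- despike(sub, despike_config(kappa = kappas[[as.character(g)]]))
    expect_identical(res$clean$data[, , sel], manual$clean$data)
  }
  expect_error(despike_grouped(sim$corrupted, c("100" = 6)), "no kappa")
})

test_that("a single off-centre spike's stripe artifact is suppressed", {
  set.seed(21)
  ph <- make_cine_series(phantom_spec(grid = c(64, 64), n_frames = 8))
  sim <- add_spikes(ph$kspace, spike_model(n_spikes = 1L, seed = 2))
  res <- despike(sim$corrupted, despike_config(kappa = 6))
  expect_lt(background_noise_std(reconstruct_images(res$clean)),
            background_noise_std(reconstruct_images(sim$corrupted)))
})

test_that("despike validates its configuration", {
  ph <- small_ll_phantom(grid = 32L, n_frames = 8L, seed = 15)
  expect_error(despike(ph$kspace, despike_config(kappa = 5,
                                                 center_window = 64)),
               "larger than the k-space grid")
  expect_error(despike_config(kappa = 0), "positive")
  expect_error(despike_config(kappa = 5, center_window = 7), "even")
  one <- kspace_series(ph$kspace$data[, , 1, drop = FALSE])
  expect_error(despike(one, despike_config(kappa = 5)), "at least 2 frames")
})
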